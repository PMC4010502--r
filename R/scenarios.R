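#' Scenario specification
#'
#' A scenario is a property-ordering rule, a constrained/unconstrained flag,
#' a replicate count and a seed. The four orderings are: `"random"` (uniform
#' shuffle — the baseline); `"nonaboriginal_large_first"` (largest to
#' smallest, all non-aboriginal properties before any aboriginal ones —
#' large holders can afford the required environmental impact assessments and
#' aboriginal land has no short-term clearing plans);
#' `"nonaboriginal_small_first"` (same tenure partition, smallest first —
#' assessments deter large holders); `"directed"` (descending area-weighted
#' mean suitability regardless of tenure — clearing steered to the most
#' productive land).
#'
#' @param ordering One of `"random"`, `"nonaboriginal_large_first"`,
#'   `"nonaboriginal_small_first"`, `"directed"`.
#' @param constrained Apply the percentage caps? (Buffers and protection
#'   always apply.)
#' @param n_runs Number of replicate runs (>= 1; 100 in the reference
#'   analysis, since per-property targets are stochastic in every scenario).
#' @param seed Integer seed from which all per-run streams are derived.
#' @return A `scenario_spec` list.
#' @export
scenario_spec <- function(ordering = c("random", "nonaboriginal_large_first",
                                       "nonaboriginal_small_first", "directed"),
                          constrained = TRUE,
                          n_runs = 100,
                          seed = 1L) {
  ordering <- match.arg(ordering)
  if (n_runs < 1) abort("n_runs must be >= 1")
  structure(
    list(ordering = ordering, constrained = constrained,
         n_runs = as.integer(n_runs), seed = as.integer(seed)),
    class = "scenario_spec"
  )
}

#' Area-weighted mean suitability of properties
#'
#' The mean suitability index of a property is the area-weighted mean over
#' ALL its land units, including unclearable ones (buffered, protected,
#' unsuitable, already cleared) — the whole-property land quality a directed
#' clearing program would rank on.
#'
#' @param x A [landscape()].
#' @param prop_id Optional property id(s); defaults to every property.
#' @return A tibble with columns `prop_id`, `mean_suitability`.
#' @export
property_mean_suitability <- function(x, prop_id = NULL) {
  stopifnot(inherits(x, "landscape"))
  out <- x$units %>%
    group_by(.data$prop_id) %>%
    summarise(mean_suitability = sum(.data$suitability * .data$area_ha) /
                sum(.data$area_ha), .groups = "drop")
  if (!is.null(prop_id)) {
    miss <- setdiff(prop_id, out$prop_id)
    if (length(miss) > 0) {
      abort(paste0("unknown property: ", paste(miss, collapse = ", ")))
    }
    out <- out[match(prop_id, out$prop_id), ]
  }
  out
}

#' Order properties for a clearing scenario
#'
#' Returns a permutation of all property ids under the scenario's ordering
#' rule. For the tenure-partitioned orderings, government land is grouped
#' with private land as "non-aboriginal". Ties in size or mean suitability
#' break by ascending `prop_id` for determinism. The `"random"` ordering
#' draws from R's current random-number stream; seed it (or let
#' [simulate_run()] do so) for reproducibility.
#'
#' @param x A [landscape()].
#' @param ordering See [scenario_spec()].
#' @return A character vector: a permutation of `x$properties$prop_id`.
#' @export
order_properties <- function(x, ordering = c("random",
                                             "nonaboriginal_large_first",
                                             "nonaboriginal_small_first",
                                             "directed")) {
  stopifnot(inherits(x, "landscape"))
  ordering <- match.arg(ordering)
  p <- x$properties
  if (nrow(p) == 0) abort("landscape has no properties")
  switch(
    ordering,
    random = sample(p$prop_id),
    nonaboriginal_large_first = {
      ab <- p$tenure == "aboriginal"
      c(p$prop_id[!ab][order(-p$total_area_ha[!ab], p$prop_id[!ab])],
        p$prop_id[ab][order(-p$total_area_ha[ab], p$prop_id[ab])])
    },
    nonaboriginal_small_first = {
      ab <- p$tenure == "aboriginal"
      c(p$prop_id[!ab][order(p$total_area_ha[!ab], p$prop_id[!ab])],
        p$prop_id[ab][order(p$total_area_ha[ab], p$prop_id[ab])])
    },
    directed = {
      ms <- property_mean_suitability(x)
      ms <- ms[match(p$prop_id, ms$prop_id), ]
      p$prop_id[order(-ms$mean_suitability, p$prop_id)]
    }
  )
}

#' Draw per-property clearing targets
#'
#' Each property selected for clearing receives a target total cleared
#' fraction (existing plus new) drawn from
#' `Uniform[target_lower, target_upper]` — 30% to 70% under the default
#' policy. Historical per-property clearing spans 1--100%, but future
#' clearing is assumed to fall in this band: owners clear at least a
#' worthwhile minimum and at most the property cap. Draws come from R's
#' current random-number stream.
#'
#' @param n Number of draws.
#' @param policy A [cap_policy()] supplying the bounds.
#' @return A numeric vector of fractions in `[target_lower, target_upper]`.
#' @export
draw_property_target <- function(n = 1, policy = cap_policy()) {
  if (policy$target_lower > policy$target_upper) {
    abort("target_lower must not exceed target_upper")
  }
  runif(n, policy$target_lower, policy$target_upper)
}
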