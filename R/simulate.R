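#' Simulate clearing of a single property
#'
#' Clears the property's clearable units in strictly decreasing suitability
#' order (ties broken by ascending `type_id`, then `unit_id`), taking from
#' each unit the minimum of its area, the property's remaining target, and
#' the cap headrooms via [allowable_clearing()]. A unit whose headroom is
#' exhausted is skipped and processing moves to the next-most-suitable unit.
#' Processing stops when the property's total cleared fraction (existing plus
#' new) reaches `target_fraction`, or when clearable land runs out. A
#' property whose existing clearing already meets the target clears nothing.
#'
#' @param x A [landscape()].
#' @param ledger A [init_ledger()] ledger for `x`; updated in place.
#' @param policy A [cap_policy()].
#' @param prop_id A property id in `x`.
#' @param target_fraction Target total cleared fraction in \[0, 1\].
#' @return A tibble of this property's clearing events (`step`, `unit_id`,
#'   `area_ha`); the ledger is modified by reference.
#' @export
simulate_property <- function(x, ledger, policy, prop_id, target_fraction) {
  p <- match(prop_id, ledger$prop_ids)
  if (is.na(p)) abort(paste0("unknown property: ", prop_id))
  if (target_fraction < 0 || target_fraction > 1) {
    abort("target_fraction must be in [0, 1]")
  }
  step0 <- ledger$ev_step
  remaining <- target_fraction * ledger$prop_base[[p]] - ledger$prop_cleared[[p]]
  eps <- 1e-9 * max(1, ledger$prop_base[[p]])
  for (i in ledger$prop_units[[p]]) {
    if (remaining <= eps) break
    take <- allow_idx(ledger, policy, i, remaining)
    if (take > eps) {
      apply_idx(ledger, i, take)
      remaining <- remaining - take
    }
  }
  steps <- seq_len(ledger$ev_step - step0) + step0
  tibble(
    step = steps,
    unit_id = ledger$u_id[ledger$ev_unit[steps]],
    area_ha = ledger$ev_area[steps]
  )
}

#' Simulate one replicate clearing run
#'
#' One pass of the clearing algorithm: order all properties by the
#' scenario's rule, draw each selected property's clearing target from the
#' uniform band, and clear it under the cap ledger. Constrained runs stop at
#' the catchment cap — after the property that crosses it in
#' `"complete_last_property"` overshoot mode, or exactly at it in
#' `"truncate"` mode. Unconstrained runs visit every property (buffers,
#' protection and the suitability-zero exclusion still apply). Per-run
#' ordering and per-property target draws use dedicated random streams
#' derived from `(spec$seed, run_index)` and `(spec$seed, run_index,
#' prop_id)`, so each run is independently reproducible.
#'
#' @param x A [landscape()].
#' @param policy A [cap_policy()]; its `constrained` flag is overridden by
#'   the scenario's.
#' @param spec A [scenario_spec()].
#' @param run_index Replicate number (1-based).
#' @return A `clearing_run` object: `run_id`, `events` (tibble: `run_id`,
#'   `step`, `prop_id`, `unit_id`, `area_ha`, `suitability`, `type_id`,
#'   `sc_id`), `property` (per-property new cleared area and selection flag),
#'   and `ledger` (the final [ledger_snapshot()] tibbles).
#' @export
simulate_run <- function(x, policy = cap_policy(), spec = scenario_spec(),
                         run_index = 1L) {
  stopifnot(inherits(x, "landscape"), inherits(policy, "cap_policy"),
            inherits(spec, "scenario_spec"))
  policy$constrained <- spec$constrained
  ledger <- init_ledger(x, policy)

  set.seed(derive_seed(spec$seed, run_index, "order"))
  prop_order <- order_properties(x, spec$ordering)

  cap_area <- policy$catchment_cap * ledger$catchment_base
  eps <- .CASCADR_REL_TOL * ledger$catchment_base
  targets <- setNames(rep(NA_real_, length(prop_order)), prop_order)
  for (prop in prop_order) {
    if (policy$constrained && ledger$catchment_cleared >= cap_area - eps) break
    set.seed(derive_seed(spec$seed, run_index, prop, "target"))
    tf <- draw_property_target(1, policy)
    targets[prop] <- tf
    simulate_property(x, ledger, policy, prop, tf)
  }

  snap <- ledger_snapshot(ledger)
  events <- snap$events
  events$run_id <- run_index
  events$suitability <- ledger$u_suit[ledger$ev_unit[seq_len(ledger$ev_step)]]
  events <- events[c("run_id", "step", "prop_id", "unit_id", "area_ha",
                     "suitability", "type_id", "sc_id")]
  property <- snap$property %>%
    mutate(new_cleared_ha = .data$cleared_ha - .data$initial_cleared_ha,
           target_fraction = unname(targets[.data$prop_id]),
           selected = .data$new_cleared_ha > 0)
  structure(
    list(run_id = run_index, events = events, property = property,
         ledger = snap[c("subcatchment", "veg_type", "catchment")],
         spec = spec, policy = policy),
    class = "clearing_run"
  )
}

#' @export
print.clearing_run <- function(x, ...) {
  cat(sprintf("<clearing_run %d> %d events, %.1f ha new clearing (%.2f%% of catchment total)\n",
              x$run_id, nrow(x$events), sum(x$events$area_ha),
              100 * x$ledger$catchment$cleared_fraction))
  invisible(x)
}

#' Run a clearing scenario
#'
#' Replicates [simulate_run()] `spec$n_runs` times with independent per-run
#' random streams. Identical inputs give identical results.
#'
#' @inheritParams simulate_run
#' @return A `scenario_result`: a list of `clearing_run`s with the spec and
#'   policy attached. Use [tidy()] for per-run totals, [glance()] for
#'   scenario averages, and the `summarize_*` family for the reported
#'   statistics.
#' @export
run_scenario <- function(x, policy = cap_policy(), spec = scenario_spec()) {
  runs <- lapply(seq_len(spec$n_runs), function(r) {
    simulate_run(x, policy, spec, run_index = r)
  })
  structure(
    list(runs = runs, spec = spec, policy = policy,
         catchment_area_ha = x$catchment_area_ha),
    class = "scenario_result"
  )
}

#' @export
print.scenario_result <- function(x, ...) {
  tt <- tidy(x)
  cat(sprintf("<scenario_result> ordering=%s, %s, %d runs\n",
              x$spec$ordering,
              if (x$spec$constrained) "constrained" else "unconstrained",
              length(x$runs)))
  cat(sprintf("  mean new clearing: %.0f ha; mean total cleared: %.2f%%\n",
              mean(tt$new_cleared_ha), 100 * mean(tt$total_cleared_fraction)))
  invisible(x)
}

#' @rdname run_scenario
#' @param x A `scenario_result`.
#' @param ... Unused.
#' @export
tidy.scenario_result <- function(x, ...) {
  purrr::map_dfr(x$runs, function(r) {
    tibble(
      run_id = r$run_id,
      n_properties_cleared = sum(r$property$selected),
      new_cleared_ha = sum(r$property$new_cleared_ha),
      total_cleared_ha = r$ledger$catchment$cleared_ha,
      total_cleared_fraction = r$ledger$catchment$cleared_fraction
    )
  })
}

#' @rdname run_scenario
#' @export
glance.scenario_result <- function(x, ...) {
  tt <- tidy(x)
  tibble(
    ordering = x$spec$ordering,
    constrained = x$spec$constrained,
    n_runs = length(x$runs),
    avg_n_properties_cleared = mean(tt$n_properties_cleared),
    avg_new_cleared_ha = mean(tt$new_cleared_ha),
    avg_total_cleared_fraction = mean(tt$total_cleared_fraction)
  )
}

#' @rdname run_scenario
#' @param object A `scenario_result`.
#' @export
autoplot.scenario_result <- function(object, ...) {
  tt <- tidy(object)
  ggplot2::ggplot(tt, ggplot2::aes(x = 100 * .data$total_cleared_fraction)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey35") +
    ggplot2::labs(
      x = "total cleared (% of catchment, existing + new)",
      y = "runs",
      title = sprintf("Cleared catchment fraction across %d runs (%s, %s)",
                      length(object$runs), object$spec$ordering,
                      if (object$spec$constrained) "constrained" else "unconstrained")
    )
}
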