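#' Property and tenure summary of a scenario
#'
#' Averages over replicate runs: the number of properties that received new
#' clearing, their mean size, total new cleared area and its split between
#' aboriginal and non-aboriginal (private plus government) tenure, and the
#' mean suitability of the selected properties (area-weighted across ALL
#' land of the selected properties). Areas count NEW clearing only, so a
#' tenure class whose properties never reach the front of the queue reports
#' zero even where it has existing clearing.
#'
#' @param results A [run_scenario()] `scenario_result`, or a list of
#'   `clearing_run`s.
#' @param x The [landscape()] the runs were made on.
#' @return A one-row tibble of scenario averages.
#' @export
summarize_properties <- function(results, x) {
  runs <- as_run_list(results)
  stopifnot(inherits(x, "landscape"))
  ms <- property_mean_suitability(x)
  props <- x$properties %>% left_join(ms, by = "prop_id")
  per_run <- purrr::map_dfr(runs, function(r) {
    pr <- r$property %>%
      left_join(props[c("prop_id", "tenure", "mean_suitability")], by = "prop_id")
    sel <- pr %>% filter(.data$selected)
    ab <- sum(sel$new_cleared_ha[sel$tenure == "aboriginal"])
    tibble(
      n_cleared = nrow(sel),
      size = if (nrow(sel) > 0) mean(sel$baseline_ha) else NA_real_,
      total_new = sum(pr$new_cleared_ha),
      ab_new = ab,
      nonab_new = sum(pr$new_cleared_ha) - ab,
      suit = if (nrow(sel) > 0) {
        sum(sel$mean_suitability * sel$baseline_ha) / sum(sel$baseline_ha)
      } else NA_real_
    )
  })
  tibble(
    avg_n_properties_with_clearing = mean(per_run$n_cleared),
    avg_size_of_clearing_properties_ha = mean(per_run$size, na.rm = TRUE),
    avg_total_new_cleared_ha = mean(per_run$total_new),
    avg_cleared_aboriginal_ha = mean(per_run$ab_new),
    avg_cleared_nonaboriginal_ha = mean(per_run$nonab_new),
    avg_selected_property_suitability = mean(per_run$suit, na.rm = TRUE)
  )
}

as_run_list <- function(results) {
  if (inherits(results, "scenario_result")) return(results$runs)
  if (inherits(results, "clearing_run")) return(list(results))
  stopifnot(is.list(results), length(results) >= 1,
            all(vapply(results, inherits, logical(1), "clearing_run")))
  results
}

#' Average percentage cleared by sub-catchment
#'
#' For each sub-catchment, the mean over runs of
#' `100 x (existing + new cleared area) / sub-catchment area`, alongside the
#' "current" column (existing clearing only). A `Total` row gives the
#' catchment-level percentages; because sub-catchments partition the
#' catchment, their cleared areas sum to the catchment total.
#'
#' @inheritParams summarize_properties
#' @return A tibble: `sc_id`, `current_pct`, `avg_pct`, with a final `Total`
#'   row.
#' @export
percent_cleared_by_subcatchment <- function(results, x) {
  runs <- as_run_list(results)
  stopifnot(inherits(x, "landscape"))
  mats <- vapply(runs, function(r) r$ledger$subcatchment$cleared_fraction,
                 numeric(nrow(x$subcatchments)))
  mats <- matrix(mats, nrow = nrow(x$subcatchments))
  sc0 <- runs[[1]]$ledger$subcatchment
  out <- tibble(
    sc_id = sc0$sc_id,
    current_pct = 100 * sc0$initial_cleared_ha / sc0$baseline_ha,
    avg_pct = 100 * rowMeans(mats)
  )
  tot_base <- sum(sc0$baseline_ha)
  tot_cur <- sum(sc0$initial_cleared_ha)
  tot_avg <- mean(vapply(runs, function(r) {
    sum(r$ledger$subcatchment$cleared_ha)
  }, numeric(1)))
  bind_rows(out, tibble(sc_id = "Total",
                        current_pct = 100 * tot_cur / tot_base,
                        avg_pct = 100 * tot_avg / tot_base))
}

#' Average percentage cleared by vegetation type
#'
#' For each vegetation type, the mean over runs of
#' `100 x (existing + new cleared area) / pre-clearing extent`. Types with
#' zero pre-clearing extent are excluded with a warning.
#'
#' @inheritParams summarize_properties
#' @return A tibble: `type_id`, `group_id`, `current_pct`, `avg_pct`.
#' @seealso [vegtype_summary()] for the across-type mean and SD.
#' @export
percent_cleared_by_vegtype <- function(results, x) {
  runs <- as_run_list(results)
  stopifnot(inherits(x, "landscape"))
  vt0 <- runs[[1]]$ledger$veg_type
  zero <- vt0$baseline_ha <= 0
  if (any(zero)) {
    warn(paste0("excluding vegetation type(s) with zero pre-clearing extent: ",
                paste(vt0$type_id[zero], collapse = ", ")))
  }
  mats <- vapply(runs, function(r) r$ledger$veg_type$cleared_ha,
                 numeric(nrow(vt0)))
  mats <- matrix(mats, nrow = nrow(vt0))
  out <- tibble(
    type_id = vt0$type_id,
    current_pct = 100 * vt0$initial_cleared_ha / vt0$baseline_ha,
    avg_pct = 100 * rowMeans(mats) / vt0$baseline_ha
  )[!zero, ]
  out %>% left_join(x$veg_types[c("type_id", "group_id")], by = "type_id") %>%
    select("type_id", "group_id", "current_pct", "avg_pct")
}

#' Across-type mean and standard deviation of percentage cleared
#'
#' The summary reported per scenario: the mean and the standard deviation of
#' the per-type average cleared percentages across all vegetation types.
#' The population SD (divisor n) is the default; with ~98 types the
#' difference from the sample SD is negligible, but determinism requires a
#' choice.
#'
#' @param per_type Output of [percent_cleared_by_vegtype()].
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return A one-row tibble: `n_types`, `mean_pct`, `sd_pct`.
#' @export
vegtype_summary <- function(per_type, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  v <- per_type$avg_pct
  n <- length(v)
  s2 <- sum((v - mean(v))^2) / if (sd_type == "population") n else (n - 1)
  tibble(n_types = n, mean_pct = mean(v), sd_pct = sqrt(s2))
}

#' Spearman rank correlations between scenarios
#'
#' Pairwise Spearman rank correlation (average ranks for ties) of per-type
#' cleared percentages between scenarios, with two-sided p-values. A
#' constant vector has undefined rank correlation and is reported as `NA`.
#'
#' @param vectors A named list of equal-length numeric vectors (per-type
#'   percentages per scenario), or a numeric matrix/data frame with one
#'   column per scenario.
#' @return A `spearman_matrix`: list of symmetric matrices `rho` and `p`
#'   with unit diagonal. `tidy()` returns the lower triangle as a tibble.
#' @export
spearman_matrix <- function(vectors) {
  if (is.matrix(vectors) || is.data.frame(vectors)) {
    vectors <- as.list(as.data.frame(vectors))
  }
  k <- length(vectors)
  if (k < 2) abort("need at least two vectors")
  n <- unique(vapply(vectors, length, integer(1)))
  if (length(n) != 1) abort("all vectors must have equal length")
  if (n < 3) abort("vectors must have length >= 3")
  nm <- names(vectors)
  if (is.null(nm)) nm <- paste0("scenario_", seq_len(k))
  rho <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  pval <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  diag(rho) <- 1
  diag(pval) <- 0
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      xi <- vectors[[i]]
      xj <- vectors[[j]]
      if (stats::sd(xi) == 0 || stats::sd(xj) == 0) next
      rho[i, j] <- rho[j, i] <- cor(xi, xj, method = "spearman")
      ct <- suppressWarnings(cor.test(xi, xj, method = "spearman"))
      pval[i, j] <- pval[j, i] <- ct$p.value
    }
  }
  structure(list(rho = rho, p = pval), class = "spearman_matrix")
}

#' @export
print.spearman_matrix <- function(x, ...) {
  cat("Spearman rank correlations (rho):\n")
  print(round(x$rho, 4))
  invisible(x)
}

#' @rdname spearman_matrix
#' @param x A `spearman_matrix`.
#' @param ... Unused.
#' @export
tidy.spearman_matrix <- function(x, ...) {
  nm <- rownames(x$rho)
  k <- length(nm)
  purrr::map_dfr(seq_len(k - 1), function(i) {
    purrr::map_dfr(seq(i + 1, k), function(j) {
      tibble(scenario_a = nm[i], scenario_b = nm[j],
             rho = x$rho[i, j], p_value = x$p[i, j])
    })
  })
}

#' Most- and least-cleared vegetation types
#'
#' The `k` vegetation types with the highest and lowest average cleared
#' percentages; ties break by ascending `type_id`.
#'
#' @param per_type Output of [percent_cleared_by_vegtype()].
#' @param k Number of types at each extreme.
#' @return A tibble: `extreme` (`"top"`/`"bottom"`), `rank`, `type_id`,
#'   `avg_pct`.
#' @export
extreme_vegtypes <- function(per_type, k = 5) {
  if (k > nrow(per_type)) abort("k exceeds the number of vegetation types")
  top_ord <- order(-per_type$avg_pct, per_type$type_id)
  bot_ord <- order(per_type$avg_pct, per_type$type_id)
  bind_rows(
    tibble(extreme = "top", rank = seq_len(k),
           type_id = per_type$type_id[top_ord[seq_len(k)]],
           avg_pct = per_type$avg_pct[top_ord[seq_len(k)]]),
    tibble(extreme = "bottom", rank = seq_len(k),
           type_id = per_type$type_id[bot_ord[seq_len(k)]],
           avg_pct = per_type$avg_pct[bot_ord[seq_len(k)]])
  )
}

#' How much of the catchment can one property clear?
#'
#' Under a flat per-property cap, a single large property can claim a
#' disproportionate share of the catchment-wide clearing allowance: a
#' 400,000 ha property clearing its full 70% uses ~5% of a 5.2 Mha catchment
#' — a quarter of a 20% catchment cap.
#'
#' @param property_area_ha Property area (ha).
#' @param catchment_area_ha Catchment area (ha).
#' @param property_cap Per-property cap fraction.
#' @param catchment_cap Catchment cap fraction.
#' @return A one-row tibble: `pct_of_catchment` (the property's maximal
#'   clearing as % of the catchment) and `pct_of_catchment_cap` (that value
#'   as % of the catchment-wide allowance).
#' @export
single_property_share <- function(property_area_ha, catchment_area_ha,
                                  property_cap = 0.70, catchment_cap = 0.20) {
  stopifnot(property_area_ha > 0, catchment_area_ha > 0,
            property_cap > 0, property_cap <= 1,
            catchment_cap > 0, catchment_cap <= 1)
  pct <- 100 * property_cap * property_area_ha / catchment_area_ha
  tibble(pct_of_catchment = pct,
         pct_of_catchment_cap = pct / (catchment_cap * 100) * 100)
}

#' Plot average percentage cleared by sub-catchment
#'
#' @param tbl Output of [percent_cleared_by_subcatchment()].
#' @return A ggplot.
#' @export
plot_subcatchment_clearing <- function(tbl) {
  d <- tbl %>% filter(.data$sc_id != "Total") %>%
    tidyr::pivot_longer(c("current_pct", "avg_pct"),
                        names_to = "series", values_to = "pct")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$sc_id, y = .data$pct,
                                  fill = .data$series)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(
      values = c(current_pct = "grey60", avg_pct = "grey20"),
      labels = c(current_pct = "current", avg_pct = "scenario average")) +
    ggplot2::labs(x = NULL, y = "% cleared", fill = NULL) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot the most- and least-cleared vegetation types
#'
#' @param tbl Output of [extreme_vegtypes()].
#' @return A ggplot, faceted into top and bottom panels.
#' @export
plot_extreme_vegtypes <- function(tbl) {
  ggplot2::ggplot(tbl, ggplot2::aes(x = factor(.data$type_id),
                                    y = .data$avg_pct)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::facet_wrap(~extreme, scales = "free") +
    ggplot2::labs(x = "vegetation type", y = "average % cleared")
}
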