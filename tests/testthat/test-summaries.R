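scenario_for <- function(x, ordering = "random", n_runs = 2, seed = 13,
                         constrained = TRUE,
                         overshoot = "truncate") {
  run_scenario(x, cap_policy(overshoot_mode = overshoot),
               scenario_spec(ordering, constrained = constrained,
                             n_runs = n_runs, seed = seed))
}

test_that("property summaries average runs and split tenure exactly", {
  sp <- generate_fixture("singleprop")
  pol <- cap_policy(constrained = FALSE)
  led <- init_ledger(sp, pol)
  simulate_property(sp, led, pol, "P1", 0.5)
  run <- structure(list(
    run_id = 1L,
    events = ledger_snapshot(led)$events,
    property = dplyr::mutate(ledger_snapshot(led)$property,
                             new_cleared_ha = cleared_ha - initial_cleared_ha,
                             selected = new_cleared_ha > 0),
    ledger = ledger_snapshot(led)[c("subcatchment", "veg_type", "catchment")]
  ), class = "clearing_run")
  s <- summarize_properties(list(run), sp)
  expect_equal(s$avg_n_properties_with_clearing, 1)
  expect_equal(s$avg_size_of_clearing_properties_ha, 1000)
  expect_equal(s$avg_total_new_cleared_ha, 500)
  expect_equal(s$avg_cleared_aboriginal_ha, 0)
  expect_equal(s$avg_cleared_nonaboriginal_ha, 500)
  expect_equal(s$avg_selected_property_suitability, 200)

  # averaging two identical runs changes nothing
  s2 <- summarize_properties(list(run, run), sp)
  expect_equal(s2, s)
})

test_that("tenure split sums to the total and decompositions conserve area", {
  L <- small_landscape()
  res <- scenario_for(L, n_runs = 3)
  s <- summarize_properties(res, L)
  expect_equal(s$avg_cleared_aboriginal_ha + s$avg_cleared_nonaboriginal_ha,
               s$avg_total_new_cleared_ha, tolerance = 1e-9)
  for (r in res$runs) {
    new_total <- sum(r$events$area_ha)
    sc_new <- sum(r$ledger$subcatchment$cleared_ha -
                    r$ledger$subcatchment$initial_cleared_ha)
    vt_new <- sum(r$ledger$veg_type$cleared_ha -
                    r$ledger$veg_type$initial_cleared_ha)
    expect_equal(sc_new, new_total, tolerance = 1e-9)
    expect_equal(vt_new, new_total, tolerance = 1e-9)
    expect_equal(r$ledger$catchment$cleared_ha -
                   r$ledger$catchment$initial_cleared_ha,
                 new_total, tolerance = 1e-9)
  }
})

test_that("aboriginal-last orderings clear zero aboriginal land when the cap binds early", {
  D <- default_landscape()
  res <- run_scenario(D, cap_policy(overshoot_mode = "truncate"),
                      scenario_spec("nonaboriginal_large_first",
                                    n_runs = 2, seed = 3))
  s <- summarize_properties(res, D)
  expect_equal(s$avg_cleared_aboriginal_ha, 0)
  expect_gt(s$avg_cleared_nonaboriginal_ha, 0)
})

test_that("sub-catchment percentages include existing clearing and a Total row", {
  cb <- generate_fixture("capbound")
  res <- scenario_for(cb, n_runs = 2, seed = 7)
  tbl <- percent_cleared_by_subcatchment(res, cb)
  sc1 <- tbl[tbl$sc_id == "SC1", ]
  expect_equal(sc1$current_pct, 60, tolerance = 1e-9)
  expect_equal(sc1$avg_pct, 60, tolerance = 1e-9) # grandfathered: unchanged
  tot <- tbl[tbl$sc_id == "Total", ]
  run_tot <- mean(vapply(res$runs, function(r) r$ledger$catchment$cleared_ha,
                         numeric(1)))
  expect_equal(tot$avg_pct, 100 * run_tot / cb$catchment_area_ha)
  # order of runs in the list does not matter
  tbl_rev <- percent_cleared_by_subcatchment(rev(res$runs), cb)
  expect_equal(tbl_rev, tbl)
})

test_that("vegetation-type percentages use pre-clearing baselines", {
  cb <- generate_fixture("capbound")
  res <- scenario_for(cb, n_runs = 2, seed = 7)
  tbl <- percent_cleared_by_vegtype(res, cb)
  expect_equal(tbl$current_pct, 12) # 600 of 5000 ha pre-clearing
  expect_gt(tbl$avg_pct, tbl$current_pct)

  # untouched landscape: per-type values equal existing percentages
  tiny <- generate_fixture("tiny3")
  led <- init_ledger(tiny, cap_policy())
  snap <- ledger_snapshot(led)
  run0 <- structure(list(run_id = 1L, events = snap$events[0, ],
                         property = dplyr::mutate(snap$property,
                                                  new_cleared_ha = 0,
                                                  selected = FALSE),
                         ledger = snap[c("subcatchment", "veg_type",
                                         "catchment")]),
                    class = "clearing_run")
  t0 <- percent_cleared_by_vegtype(list(run0), tiny)
  expect_equal(t0$avg_pct, t0$current_pct)
  expect_equal(t0$current_pct, c(100 * 500 / 5500, 0))
})

test_that("across-type mean and SD use the population divisor by default", {
  per_type <- tibble::tibble(type_id = 1:4, group_id = 1L,
                             current_pct = 0, avg_pct = c(10, 20, 30, 40))
  vs <- vegtype_summary(per_type)
  expect_equal(vs$mean_pct, 25)
  expect_equal(vs$sd_pct, sqrt(mean((c(10, 20, 30, 40) - 25)^2)))
  vs2 <- vegtype_summary(per_type, sd_type = "sample")
  expect_equal(vs2$sd_pct, stats::sd(c(10, 20, 30, 40)))
})

test_that("Spearman matrix matches hand-rank oracle, symmetry and bounds", {
  expect_equal(spearman_matrix(list(a = 1:5, b = 1:5))$rho["a", "b"], 1)
  expect_equal(spearman_matrix(list(a = 1:5, b = 5:1))$rho["a", "b"], -1)
  expect_equal(
    spearman_matrix(list(a = c(1, 2, 3, 4, 5), b = c(1, 3, 2, 5, 4)))$rho["a", "b"],
    0.8)

  set.seed(29)
  vecs <- list(s1 = runif(10), s2 = runif(10), s3 = sample(1:10),
               s4 = c(1, 1, 2, 2, 3, 3, 4, 4, 5, 5)) # ties
  sm <- spearman_matrix(vecs)
  expect_equal(sm$rho, t(sm$rho))
  expect_equal(unname(diag(sm$rho)), rep(1, 4))
  expect_true(all(abs(sm$rho) <= 1 + 1e-12))
  for (i in 1:3) {
    for (j in (i + 1):4) {
      expect_equal(sm$rho[i, j], oracle_spearman(vecs[[i]], vecs[[j]]),
                   tolerance = 1e-12)
    }
  }
  # constant vector: undefined, reported missing
  smc <- spearman_matrix(list(a = rep(2, 5), b = 1:5))
  expect_true(is.na(smc$rho["a", "b"]))
  expect_identical(nrow(tidy(sm)), 6L)
})

test_that("extreme vegetation types match a full-sort oracle", {
  per_type <- tibble::tibble(
    type_id = c(5L, 2L, 9L, 1L, 7L, 3L),
    group_id = 1L, current_pct = 0,
    avg_pct = c(12, 40, 3, 40, 25, 8)
  )
  ex <- extreme_vegtypes(per_type, k = 2)
  # ties at 40 break by ascending type_id
  expect_equal(ex$type_id[ex$extreme == "top"], c(1L, 2L))
  expect_equal(ex$type_id[ex$extreme == "bottom"], c(9L, 3L))

  full <- extreme_vegtypes(per_type, k = 6)
  srt <- per_type[order(-per_type$avg_pct, per_type$type_id), ]
  expect_equal(full$type_id[full$extreme == "top"], srt$type_id)
  expect_error(extreme_vegtypes(per_type, k = 7), "exceeds")

  # argmax with the ascending-type_id tie-break
  expect_equal(extreme_vegtypes(per_type, k = 1)$type_id[1],
               min(per_type$type_id[per_type$avg_pct == max(per_type$avg_pct)]))
})

test_that("one large property can claim a quarter of the catchment allowance", {
  share <- single_property_share(400000, 5200000, 0.70, 0.20)
  expect_equal(share$pct_of_catchment, 100 * 0.7 * 400000 / 5200000)
  expect_equal(round(share$pct_of_catchment), 5)
  expect_equal(share$pct_of_catchment_cap, share$pct_of_catchment / 20 * 100)

  expect_equal(single_property_share(1000, 100000, 0.5)$pct_of_catchment, 0.5)
  expect_equal(single_property_share(100, 100, 1, 1)$pct_of_catchment, 100)
})

test_that("plots build without error", {
  cb <- generate_fixture("capbound")
  res <- scenario_for(cb, n_runs = 2, seed = 7)
  expect_s3_class(autoplot(res), "ggplot")
  expect_s3_class(plot_subcatchment_clearing(
    percent_cleared_by_subcatchment(res, cb)), "ggplot")
  per_type <- tibble::tibble(type_id = 1:6, group_id = 1L, current_pct = 0,
                             avg_pct = 1:6)
  expect_s3_class(plot_extreme_vegtypes(extreme_vegtypes(per_type, 2)),
                  "ggplot")
  expect_s3_class(glance(res), "tbl_df")
})
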