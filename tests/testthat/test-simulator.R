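test_that("a lone unconstrained property clears exactly to its target", {
  sp <- generate_fixture("singleprop")
  pol <- cap_policy(constrained = FALSE)
  led <- init_ledger(sp, pol)
  ev <- simulate_property(sp, led, pol, "P1", 0.5)
  expect_equal(sum(ev$area_ha), 500)
  # under the caps, the catchment cap truncates the same draw at 20%
  polc <- cap_policy(overshoot_mode = "truncate")
  ledc <- init_ledger(sp, polc)
  evc <- simulate_property(sp, ledc, polc, "P1", 0.5)
  expect_equal(sum(evc$area_ha), 200)
})

test_that("a property with only buffered land clears nothing", {
  sp <- generate_fixture("singleprop")
  sp$units$buffered <- TRUE
  pol <- cap_policy()
  led <- init_ledger(sp, pol)
  ev <- simulate_property(sp, led, pol, "P1", 0.7)
  expect_identical(nrow(ev), 0L)
  expect_equal(led$catchment_cleared, 0)
})

test_that("existing clearing already above the draw precludes new clearing", {
  cb <- generate_fixture("capbound")
  pol <- cap_policy()
  led <- init_ledger(cb, pol)
  # P1 is 60% cleared; a 0.5 target is already met
  ev <- simulate_property(cb, led, pol, "P1", 0.5)
  expect_identical(nrow(ev), 0L)
})

test_that("engine equals the brute-force oracle event-for-event on fixtures", {
  pol_t <- cap_policy(overshoot_mode = "truncate")
  pol_c <- cap_policy()
  cases <- list(
    list(x = generate_fixture("tiny3"), order = c("P1", "P2", "P3"),
         targets = c(P1 = 0.5, P2 = 0.6, P3 = 0.4)),
    list(x = generate_fixture("tiny3"), order = c("P3", "P1", "P2"),
         targets = c(P1 = 0.7, P2 = 0.7, P3 = 0.7)),
    list(x = generate_fixture("capbound"), order = c("P1", "P2"),
         targets = c(P1 = 0.7, P2 = 0.65)),
    list(x = generate_fixture("capbound"), order = c("P2", "P1"),
         targets = c(P1 = 0.3, P2 = 0.45))
  )
  set.seed(41)
  for (rep in 1:4) {
    tiny <- generate_fixture("tiny3")
    cases[[length(cases) + 1]] <- list(
      x = tiny, order = sample(tiny$properties$prop_id),
      targets = setNames(runif(3, 0.3, 0.7), tiny$properties$prop_id)
    )
  }
  for (cs in cases) {
    for (pol in list(pol_t, pol_c)) {
      got <- engine_run(cs$x, cs$order, cs$targets, pol)
      want <- oracle_run(cs$x, cs$order, cs$targets, pol)
      expect_identical(nrow(got$events), nrow(want))
      expect_equal(got$events$unit_id, want$unit_id)
      expect_equal(got$events$area_ha, want$area_ha, tolerance = 1e-9)
      expect_true(isTRUE(replay_ledger(got$ledger)))
    }
  }
})

test_that("the grandfathered sub-catchment receives zero events in any run", {
  cb <- generate_fixture("capbound")
  for (seed in 1:3) {
    run <- simulate_run(cb, cap_policy(overshoot_mode = "truncate"),
                        scenario_spec("random", n_runs = 1, seed = seed), 1)
    expect_false(any(run$events$sc_id == "SC1"))
    sc1 <- run$ledger$subcatchment
    expect_equal(sc1$cleared_fraction[sc1$sc_id == "SC1"], 0.60)
  }
})

test_that("runs are deterministic and replicate counts honoured", {
  L <- small_landscape()
  spec <- scenario_spec("random", n_runs = 3, seed = 17)
  pol <- cap_policy(overshoot_mode = "truncate")
  a <- run_scenario(L, pol, spec)
  b <- run_scenario(L, pol, spec)
  expect_identical(length(a$runs), 3L)
  for (i in 1:3) expect_equal(a$runs[[i]]$events, b$runs[[i]]$events)
  # different runs of the same scenario differ (independent streams)
  expect_false(identical(a$runs[[1]]$events$prop_id,
                         a$runs[[2]]$events$prop_id))
})

test_that("within each property's event stream suitability never increases", {
  L <- small_landscape()
  run <- simulate_run(L, cap_policy(), scenario_spec("random", n_runs = 1,
                                                     seed = 5), 1)
  by_prop <- split(run$events, run$events$prop_id)
  for (ev in by_prop) {
    expect_true(all(diff(ev$suitability[order(ev$step)]) <= 0))
  }
})

test_that("cap invariants hold on constrained runs; exclusions never cleared", {
  L <- small_landscape()
  pol <- cap_policy(overshoot_mode = "truncate")
  tol <- 1e-6
  uncl <- L$units$unit_id[!is_clearable(L$units)]
  led0 <- init_ledger(L, pol)
  for (seed in 1:3) {
    run <- simulate_run(L, pol, scenario_spec("random", n_runs = 1,
                                              seed = seed), 1)
    expect_identical(intersect(run$events$unit_id, uncl), integer(0))

    pr <- run$property
    expect_true(all(pr$cleared_fraction <=
                      pmax(0.70, pr$initial_cleared_ha / pr$baseline_ha) *
                      (1 + tol)))
    sc <- run$ledger$subcatchment
    expect_true(all(sc$cleared_fraction <=
                      pmax(0.40, sc$initial_cleared_ha / sc$baseline_ha) *
                      (1 + tol)))
    vt <- run$ledger$veg_type
    expect_true(all(vt$cleared_fraction <=
                      pmax(0.30, vt$initial_cleared_ha /
                             pmax(vt$baseline_ha, 1e-12)) * (1 + tol)))
    expect_lte(run$ledger$catchment$cleared_fraction, 0.20 * (1 + tol))

    # grandfathering: features initialized above a cap gain nothing
    over_p <- pr$initial_cleared_ha > 0.70 * pr$baseline_ha
    expect_equal(sum(pr$new_cleared_ha[over_p]), 0)
    over_v <- vt$initial_cleared_ha > 0.30 * vt$baseline_ha
    expect_equal(sum(vt$cleared_ha[over_v] - vt$initial_cleared_ha[over_v]), 0)
  }
})

test_that("relaxing the caps never reduces total clearing at matched seeds", {
  L <- small_landscape()
  pol <- cap_policy(overshoot_mode = "truncate")
  for (seed in c(3, 11)) {
    con <- simulate_run(L, pol, scenario_spec("random", constrained = TRUE,
                                              n_runs = 1, seed = seed), 1)
    unc <- simulate_run(L, pol, scenario_spec("random", constrained = FALSE,
                                              n_runs = 1, seed = seed), 1)
    expect_gte(sum(unc$events$area_ha), sum(con$events$area_ha))
  }
  # strict when the catchment cap binds on the default landscape
  D <- default_landscape()
  conD <- simulate_run(D, pol, scenario_spec("random", constrained = TRUE,
                                             n_runs = 1, seed = 1), 1)
  uncD <- simulate_run(D, pol, scenario_spec("random", constrained = FALSE,
                                             n_runs = 1, seed = 1), 1)
  expect_gt(sum(uncD$events$area_ha), sum(conD$events$area_ha))
})

test_that("with caps off and all land clearable, mean clearing tends to 50%", {
  cfg <- small_config(seed = 19)
  cfg$existing_cleared_fraction <- 0
  cfg$buffered_fraction <- 0
  cfg$protected_fraction <- 0
  cfg$suitability_zero_fraction <- 0
  L <- generate_landscape(cfg)
  res <- run_scenario(L, cap_policy(),
                      scenario_spec("random", constrained = FALSE,
                                    n_runs = 100, seed = 23))
  fr <- tidy(res)$total_cleared_fraction
  # Monte-Carlo error: per-run fractions are size-weighted means of 40
  # uniform draws (sd ~0.04), so the 100-run mean has se ~0.004
  expect_lt(abs(mean(fr) - 0.50), 0.02)
})

test_that("complete-last-property runs end at or just above the catchment cap", {
  D <- default_landscape()
  res <- run_scenario(D, cap_policy(overshoot_mode = "complete_last_property"),
                      scenario_spec("random", constrained = TRUE,
                                    n_runs = 20, seed = 2))
  fr <- tidy(res)$total_cleared_fraction
  expect_true(all(fr >= 0.20 - 1e-6))
  expect_true(mean(fr) >= 0.20 && mean(fr) <= 0.21)
})
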