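test_that("suitability index sums the four land-use percentages", {
  prof <- data.frame(
    pasture_pct = c(0, 100, 80),
    irrigated_crop_perennial_pct = c(0, 100, 30),
    irrigated_annual_hort_pct = c(0, 100, 20),
    rainfed_crop_perennial_pct = c(0, 100, 10)
  )
  expect_identical(compute_suitability_index(prof), c(0L, 400L, 140L))
  expect_error(compute_suitability_index(transform(prof, pasture_pct = c(-1, 100, 80))),
               "0, 100")
  expect_error(compute_suitability_index(prof[-1]), "missing")
})

test_that("suitability index is monotone non-decreasing in each field", {
  set.seed(11)
  cols <- c("pasture_pct", "irrigated_crop_perennial_pct",
            "irrigated_annual_hort_pct", "rainfed_crop_perennial_pct")
  for (rep in 1:20) {
    base <- as.data.frame(as.list(setNames(runif(4, 0, 90), cols)))
    bumped <- base
    j <- sample(4, 1)
    bumped[[j]] <- bumped[[j]] + runif(1, 0, 10)
    expect_gte(compute_suitability_index(bumped),
               compute_suitability_index(base))
  }
})

test_that("group clearing is allocated proportionally to types and conserved", {
  # one group at a 10% clearing rate
  g <- tibble::tibble(group_id = 1L, pre_clearing_area_ha = 10000,
                      cleared_area_ha = 1000)
  tt <- tibble::tibble(type_id = 1:3, group_id = 1L,
                       pre_clearing_area_ha = c(2000, 3000, 5000))
  out <- allocate_group_clearing(tt, g)
  expect_equal(out$existing_cleared_ha, c(200, 300, 500))

  # zero clearing stays zero
  g0 <- dplyr::mutate(g, cleared_area_ha = 0)
  expect_equal(allocate_group_clearing(tt, g0)$existing_cleared_ha, rep(0, 3))

  # three groups, seven types: frozen against a by-hand proportional split
  groups <- tibble::tibble(
    group_id = 1:3,
    pre_clearing_area_ha = c(10000, 6000, 4000),
    cleared_area_ha = c(1000, 0, 3000)
  )
  types <- tibble::tibble(
    type_id = 1:7,
    group_id = c(1L, 1L, 1L, 2L, 3L, 3L, 3L),
    pre_clearing_area_ha = c(2000, 3000, 5000, 6000, 1000, 1000, 2000)
  )
  out <- allocate_group_clearing(types, groups)
  expect_equal(out$existing_cleared_ha, c(200, 300, 500, 0, 750, 750, 1500))
  sums <- tapply(out$existing_cleared_ha, out$group_id, sum)
  expect_equal(as.numeric(sums), groups$cleared_area_ha, tolerance = 1e-9)
})

test_that("group clearing allocation rejects inconsistent inputs", {
  g <- tibble::tibble(group_id = 1L, pre_clearing_area_ha = 10000,
                      cleared_area_ha = 1000)
  tt <- tibble::tibble(type_id = 1:2, group_id = 1L,
                       pre_clearing_area_ha = c(2000, 3000)) # sums to 5000
  expect_error(allocate_group_clearing(tt, g), "do not sum")
  tt2 <- tibble::tibble(type_id = 1L, group_id = 2L,
                        pre_clearing_area_ha = 100)
  expect_error(allocate_group_clearing(tt2, g), "unknown group")
})

test_that("allocation conserves area on random inputs", {
  set.seed(5)
  for (rep in 1:10) {
    n_types <- sample(2:6, 1)
    pre <- runif(n_types, 100, 5000)
    g <- tibble::tibble(group_id = 1L, pre_clearing_area_ha = sum(pre),
                        cleared_area_ha = runif(1, 0, sum(pre)))
    tt <- tibble::tibble(type_id = seq_len(n_types), group_id = 1L,
                         pre_clearing_area_ha = pre)
    out <- allocate_group_clearing(tt, g)
    expect_equal(sum(out$existing_cleared_ha), g$cleared_area_ha,
                 tolerance = 1e-9)
  }
})

test_that("validate_landscape passes fixtures and catches constructed faults", {
  for (nm in c("tiny3", "capbound", "singleprop")) {
    expect_identical(nrow(validate_landscape(generate_fixture(nm))), 0L)
  }
  L <- generate_fixture("tiny3")

  bad <- L
  bad$units$area_ha[3] <- -bad$units$area_ha[3]
  v <- validate_landscape(bad)
  expect_true("area_positive" %in% v$rule)

  short <- L
  short$units$area_ha <- short$units$area_ha * 0.99
  v <- validate_landscape(short)
  expect_true("total_area" %in% v$rule)

  conflict <- L
  conflict$units$buffered[9] <- TRUE # unit 9 is existing-cleared
  v <- validate_landscape(conflict)
  expect_true("cleared_not_buffered" %in% v$rule)

  dup <- L
  dup$units$unit_id[2] <- 99L
  dup$units[2, c("type_id", "suitability", "area_ha")] <-
    dup$units[1, c("type_id", "suitability", "area_ha")]
  v <- validate_landscape(dup)
  expect_true("unit_key_unique" %in% v$rule)
})

test_that("landscape CSV round-trip is the identity", {
  dir <- withr::local_tempdir()
  L <- generate_fixture("tiny3")
  write_landscape(L, dir)
  L2 <- read_landscape(dir)
  expect_equal(L2$units, L$units)
  expect_equal(L2$properties, L$properties)
  expect_equal(L2$subcatchments, L$subcatchments)
  expect_equal(L2$veg_types, L$veg_types)
  expect_equal(L2$veg_groups, L$veg_groups)
  expect_equal(L2$catchment_area_ha, L$catchment_area_ha)
})

test_that("landscape loading reports schema and foreign-key faults by name", {
  dir <- withr::local_tempdir()
  L <- generate_fixture("tiny3")
  write_landscape(L, dir)

  u <- readr::read_csv(file.path(dir, "units.csv"), show_col_types = FALSE)
  readr::write_csv(u[setdiff(names(u), "suitability")],
                   file.path(dir, "units.csv"))
  expect_error(read_landscape(dir), "suitability")

  write_landscape(L, dir)
  u$prop_id[5] <- "P9"
  readr::write_csv(u, file.path(dir, "units.csv"))
  expect_error(read_landscape(dir), "unknown prop_id")

  expect_error(read_landscape(file.path(dir, "nope")), "missing landscape file")
})
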