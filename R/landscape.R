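#' Clearing-suitability index of a land system
#'
#' The suitability index scores each land system by summing its percentage
#' suitability (0--100 each) for four intensive land uses: improved pasture,
#' irrigated field crops and perennial horticulture, irrigated annual
#' horticulture, and rainfed field crops and perennial horticulture. The sum
#' ranges from 0 (unsuitable for every use) to 400 (fully suitable for all
#' four); values above 100 indicate flexibility across uses and hence higher
#' relative demand for clearing.
#'
#' @param profile A data frame with one row per land system and numeric
#'   columns `pasture_pct`, `irrigated_crop_perennial_pct`,
#'   `irrigated_annual_hort_pct`, `rainfed_crop_perennial_pct`, each in
#'   \[0, 100\].
#' @return An integer vector of suitability indices in \[0, 400\], one per row.
#' @examples
#' compute_suitability_index(
#'   data.frame(
#'     pasture_pct = c(0, 100, 80),
#'     irrigated_crop_perennial_pct = c(0, 100, 30),
#'     irrigated_annual_hort_pct = c(0, 100, 20),
#'     rainfed_crop_perennial_pct = c(0, 100, 10)
#'   )
#' )
#' @export
compute_suitability_index <- function(profile) {
  cols <- c(
    "pasture_pct", "irrigated_crop_perennial_pct",
    "irrigated_annual_hort_pct", "rainfed_crop_perennial_pct"
  )
  missing_cols <- setdiff(cols, names(profile))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "`profile` is missing suitability column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  m <- as.matrix(profile[cols])
  if (!is.numeric(m) || anyNA(m) || any(m < 0) || any(m > 100)) {
    abort("all suitability percentages must be numeric and in [0, 100]")
  }
  as.integer(round(rowSums(m)))
}

#' Allocate group-level existing clearing uniformly to vegetation types
#'
#' Fine-resolution vegetation mapping (98 types) has no pre-clearing product,
#' so existing clearing is known only for the 15 broad vegetation groups.
#' Clearing is assumed uniform across the types within a group: each type's
#' existing cleared area is its pre-clearing extent times the group's cleared
#' fraction, so per-type areas sum back to the group total.
#'
#' @param veg_types A data frame with columns `type_id`, `group_id`,
#'   `pre_clearing_area_ha`.
#' @param veg_groups A data frame with columns `group_id`,
#'   `pre_clearing_area_ha` (> 0), `cleared_area_ha`.
#' @return `veg_types` as a tibble with an `existing_cleared_ha` column added.
#' @export
allocate_group_clearing <- function(veg_types, veg_groups) {
  types <- as_tibble(veg_types)
  groups <- as_tibble(veg_groups)
  unknown <- setdiff(types$group_id, groups$group_id)
  if (length(unknown) > 0) {
    abort(paste0("vegetation types reference unknown group_id: ",
                 paste(unknown, collapse = ", ")))
  }
  type_sums <- types %>%
    group_by(.data$group_id) %>%
    summarise(type_pre = sum(.data$pre_clearing_area_ha), .groups = "drop")
  chk <- left_join(groups, type_sums, by = "group_id") %>%
    mutate(type_pre = ifelse(is.na(.data$type_pre), 0, .data$type_pre))
  bad <- chk %>% filter(!near_rel(.data$type_pre, .data$pre_clearing_area_ha))
  if (nrow(bad) > 0) {
    abort(paste0(
      "per-type pre-clearing areas do not sum to the group total for group(s): ",
      paste(bad$group_id, collapse = ", ")
    ))
  }
  if (any(groups$pre_clearing_area_ha <= 0)) {
    abort("every vegetation group must have pre_clearing_area_ha > 0")
  }
  if (any(groups$cleared_area_ha < 0) ||
      any(groups$cleared_area_ha > groups$pre_clearing_area_ha * (1 + .CASCADR_REL_TOL))) {
    abort("group cleared_area_ha must lie in [0, pre_clearing_area_ha]")
  }
  rates <- groups %>%
    mutate(rate = .data$cleared_area_ha / .data$pre_clearing_area_ha) %>%
    select("group_id", "rate")
  types %>%
    left_join(rates, by = "group_id") %>%
    mutate(existing_cleared_ha = .data$pre_clearing_area_ha * .data$rate) %>%
    select(-"rate")
}

#' Assemble a landscape object
#'
#' A landscape is the purely tabular description of the catchment used by the
#' clearing simulator: atomic land units (unique combinations of property,
#' sub-catchment, vegetation type and suitability index, with buffer /
#' protected / existing-cleared flags) plus the property, sub-catchment and
#' vegetation metadata that supply cap baselines.
#'
#' @param units Tibble of land units: `unit_id`, `prop_id`, `sc_id`,
#'   `type_id`, `suitability` (integer 0--400), `area_ha` (> 0), and logical
#'   `buffered`, `protected`, `existing_cleared`.
#' @param properties Tibble: `prop_id`, `tenure` (one of `"aboriginal"`,
#'   `"private"`, `"government"`), `total_area_ha`.
#' @param subcatchments Tibble: `sc_id`, `total_area_ha`, `reserve_fraction`,
#'   `aboriginal_fraction`.
#' @param veg_types Tibble: `type_id`, `group_id`, `pre_clearing_area_ha`.
#' @param veg_groups Tibble: `group_id`, `name`, `pre_clearing_area_ha`,
#'   `cleared_area_ha`.
#' @param catchment_area_ha Total catchment area; defaults to the sum of unit
#'   areas.
#' @return An object of class `landscape`: a list of the five tibbles plus
#'   `catchment_area_ha`. Property existing-cleared areas are derived from the
#'   flagged units.
#' @seealso [validate_landscape()], [generate_landscape()]
#' @export
landscape <- function(units, properties, subcatchments, veg_types, veg_groups,
                      catchment_area_ha = sum(units$area_ha)) {
  units <- as_tibble(units)
  for (fl in c("buffered", "protected", "existing_cleared")) {
    units[[fl]] <- as.logical(units[[fl]])
  }
  properties <- as_tibble(properties)
  ec <- units %>%
    filter(.data$existing_cleared) %>%
    group_by(.data$prop_id) %>%
    summarise(existing_cleared_ha = sum(.data$area_ha), .groups = "drop")
  properties <- properties %>%
    select(-dplyr::any_of("existing_cleared_ha")) %>%
    left_join(ec, by = "prop_id") %>%
    mutate(existing_cleared_ha = ifelse(is.na(.data$existing_cleared_ha), 0,
                                        .data$existing_cleared_ha))
  structure(
    list(
      units = units,
      properties = properties,
      subcatchments = as_tibble(subcatchments),
      veg_types = as_tibble(veg_types),
      veg_groups = as_tibble(veg_groups),
      catchment_area_ha = catchment_area_ha
    ),
    class = "landscape"
  )
}

#' @export
print.landscape <- function(x, ...) {
  cat("<landscape>\n")
  cat(sprintf("  catchment area : %s ha\n", format(round(x$catchment_area_ha))))
  cat(sprintf("  units          : %d\n", nrow(x$units)))
  cat(sprintf("  properties     : %d\n", nrow(x$properties)))
  cat(sprintf("  sub-catchments : %d\n", nrow(x$subcatchments)))
  cat(sprintf("  veg types      : %d in %d groups\n",
              nrow(x$veg_types), nrow(x$veg_groups)))
  cleared <- sum(x$units$area_ha[x$units$existing_cleared])
  cat(sprintf("  existing cleared: %.2f%%\n", 100 * cleared / x$catchment_area_ha))
  invisible(x)
}

new_violation <- function(entity, id, rule, detail) {
  tibble(entity = entity, id = as.character(id), rule = rule, detail = detail)
}

#' Validate a landscape against its structural invariants
#'
#' Checks every structural rule the simulator relies on: positive unit areas,
#' suitability in \[0, 400\], uniqueness of the unit key, flag consistency,
#' foreign keys, and area conservation (units tile the catchment, each
#' property and sub-catchment, and flagged existing clearing matches the
#' per-property totals), all at relative tolerance `1e-6`.
#'
#' @param x A [landscape()] object.
#' @return A tibble of violations with columns `entity`, `id`, `rule`,
#'   `detail`; zero rows when the landscape is valid.
#' @export
validate_landscape <- function(x) {
  stopifnot(inherits(x, "landscape"))
  u <- x$units
  v <- list()

  bad <- u$area_ha <= 0 | !is.finite(u$area_ha)
  if (any(bad)) {
    v[[length(v) + 1]] <- new_violation("unit", u$unit_id[bad], "area_positive",
                                        "unit area_ha must be > 0")
  }
  bad <- u$suitability < 0 | u$suitability > 400 | u$suitability != round(u$suitability)
  if (any(bad)) {
    v[[length(v) + 1]] <- new_violation("unit", u$unit_id[bad], "suitability_range",
                                        "suitability must be an integer in [0, 400]")
  }
  dup <- duplicated(u[c("prop_id", "sc_id", "type_id", "suitability",
                        "buffered", "protected", "existing_cleared")])
  if (any(dup)) {
    v[[length(v) + 1]] <- new_violation("unit", u$unit_id[dup], "unit_key_unique",
                                        "duplicate (prop, sc, type, suitability, flags) key")
  }
  bad <- u$existing_cleared & u$buffered
  if (any(bad)) {
    v[[length(v) + 1]] <- new_violation("unit", u$unit_id[bad], "cleared_not_buffered",
                                        "existing-cleared units cannot be buffered")
  }
  for (fk in list(c("prop_id", "properties"), c("sc_id", "subcatchments"),
                  c("type_id", "veg_types"))) {
    unknown <- setdiff(u[[fk[1]]], x[[fk[2]]][[fk[1]]])
    if (length(unknown) > 0) {
      v[[length(v) + 1]] <- new_violation("unit", unknown, paste0(fk[1], "_exists"),
                                          paste("unknown", fk[1]))
    }
  }
  unknown <- setdiff(x$veg_types$group_id, x$veg_groups$group_id)
  if (length(unknown) > 0) {
    v[[length(v) + 1]] <- new_violation("veg_type", unknown, "group_id_exists",
                                        "unknown group_id")
  }

  total <- sum(u$area_ha)
  if (abs(total - x$catchment_area_ha) > .CASCADR_REL_TOL * x$catchment_area_ha) {
    v[[length(v) + 1]] <- new_violation(
      "landscape", "catchment", "total_area",
      sprintf("unit areas sum to %.3f ha, catchment_area_ha is %.3f ha",
              total, x$catchment_area_ha))
  }

  by_prop <- u %>%
    group_by(.data$prop_id) %>%
    summarise(area = sum(.data$area_ha),
              cleared = sum(.data$area_ha[.data$existing_cleared]),
              .groups = "drop")
  pj <- left_join(x$properties, by_prop, by = "prop_id") %>%
    mutate(area = ifelse(is.na(.data$area), 0, .data$area),
           cleared = ifelse(is.na(.data$cleared), 0, .data$cleared))
  bad <- abs(pj$area - pj$total_area_ha) > .CASCADR_REL_TOL * pmax(1, pj$total_area_ha)
  if (any(bad)) {
    v[[length(v) + 1]] <- new_violation("property", pj$prop_id[bad], "property_area",
                                        "unit areas do not sum to total_area_ha")
  }
  bad <- abs(pj$cleared - pj$existing_cleared_ha) >
    .CASCADR_REL_TOL * pmax(1, pj$total_area_ha)
  if (any(bad)) {
    v[[length(v) + 1]] <- new_violation("property", pj$prop_id[bad], "property_cleared",
                                        "flagged cleared unit areas do not match existing_cleared_ha")
  }
  bad <- x$properties$total_area_ha < 100 * (1 - .CASCADR_REL_TOL)
  if (any(bad)) {
    v[[length(v) + 1]] <- new_violation("property", x$properties$prop_id[bad],
                                        "property_min_size",
                                        "properties must be at least 100 ha")
  }
  bad <- !x$properties$tenure %in% c("aboriginal", "private", "government")
  if (any(bad)) {
    v[[length(v) + 1]] <- new_violation("property", x$properties$prop_id[bad],
                                        "tenure_enum", "unknown tenure")
  }

  by_sc <- u %>%
    group_by(.data$sc_id) %>%
    summarise(area = sum(.data$area_ha), .groups = "drop")
  sj <- left_join(x$subcatchments, by_sc, by = "sc_id") %>%
    mutate(area = ifelse(is.na(.data$area), 0, .data$area))
  bad <- abs(sj$area - sj$total_area_ha) > .CASCADR_REL_TOL * pmax(1, sj$total_area_ha)
  if (any(bad)) {
    v[[length(v) + 1]] <- new_violation("subcatchment", sj$sc_id[bad], "subcatchment_area",
                                        "unit areas do not sum to total_area_ha")
  }
  for (fr in c("reserve_fraction", "aboriginal_fraction")) {
    bad <- x$subcatchments[[fr]] < 0 | x$subcatchments[[fr]] > 1
    if (any(bad)) {
      v[[length(v) + 1]] <- new_violation("subcatchment", x$subcatchments$sc_id[bad],
                                          paste0(fr, "_range"),
                                          paste(fr, "must be in [0, 1]"))
    }
  }

  by_type <- u %>%
    group_by(.data$type_id) %>%
    summarise(area = sum(.data$area_ha), .groups = "drop")
  tj <- left_join(x$veg_types, by_type, by = "type_id") %>%
    mutate(area = ifelse(is.na(.data$area), 0, .data$area))
  bad <- tj$area > tj$pre_clearing_area_ha * (1 + .CASCADR_REL_TOL) + .CASCADR_REL_TOL
  if (any(bad)) {
    v[[length(v) + 1]] <- new_violation("veg_type", tj$type_id[bad], "type_extent",
                                        "mapped unit area exceeds pre-clearing extent")
  }
  gj <- x$veg_groups
  bad <- gj$cleared_area_ha > gj$pre_clearing_area_ha * (1 + .CASCADR_REL_TOL)
  if (any(bad)) {
    v[[length(v) + 1]] <- new_violation("veg_group", gj$group_id[bad], "group_cleared",
                                        "cleared_area_ha exceeds pre_clearing_area_ha")
  }

  if (length(v) == 0) {
    new_violation(character(), character(), character(), character())[0, ]
  } else {
    bind_rows(v)
  }
}

landscape_file_spec <- list(
  units = c("unit_id", "prop_id", "sc_id", "type_id", "suitability", "area_ha",
            "buffered", "protected", "existing_cleared"),
  properties = c("prop_id", "tenure", "total_area_ha"),
  subcatchments = c("sc_id", "total_area_ha", "reserve_fraction", "aboriginal_fraction"),
  vegtypes = c("type_id", "group_id", "pre_clearing_area_ha"),
  veggroups = c("group_id", "name", "pre_clearing_area_ha", "cleared_area_ha")
)

read_landscape_csv <- function(path, what) {
  want <- landscape_file_spec[[what]]
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(want, names(df))
  if (length(missing_cols) > 0) {
    abort(sprintf("%s is missing column(s): %s", basename(path),
                  paste(missing_cols, collapse = ", ")))
  }
  num_cols <- intersect(
    c("suitability", "area_ha", "total_area_ha", "pre_clearing_area_ha",
      "cleared_area_ha", "reserve_fraction", "aboriginal_fraction"),
    want
  )
  for (cc in num_cols) {
    if (!is.numeric(df[[cc]])) {
      bad_row <- which(is.na(suppressWarnings(as.numeric(df[[cc]]))))[1]
      abort(sprintf("%s: column %s is not numeric (first bad row: %s)",
                    basename(path), cc, bad_row))
    }
  }
  df[want]
}

#' Read and write landscapes as plain CSV files
#'
#' A landscape is stored as five UTF-8 CSV files in one directory:
#' `units.csv`, `properties.csv`, `subcatchments.csv`, `vegtypes.csv`,
#' `veggroups.csv`. Flags are written as 0/1; writing then reading a valid
#' landscape returns an equal object.
#'
#' @param dir Directory containing (or to receive) the five CSV files.
#' @return `read_landscape()` returns a [landscape()]; `write_landscape()`
#'   returns `dir` invisibly.
#' @export
read_landscape <- function(dir) {
  paths <- file.path(dir, paste0(names(landscape_file_spec), ".csv"))
  names(paths) <- names(landscape_file_spec)
  for (p in paths) {
    if (!file.exists(p)) abort(paste0("missing landscape file: ", p))
  }
  units <- read_landscape_csv(paths[["units"]], "units")
  properties <- read_landscape_csv(paths[["properties"]], "properties")
  subcatchments <- read_landscape_csv(paths[["subcatchments"]], "subcatchments")
  veg_types <- read_landscape_csv(paths[["vegtypes"]], "vegtypes")
  veg_groups <- read_landscape_csv(paths[["veggroups"]], "veggroups")

  for (fk in list(c("prop_id", "properties"), c("sc_id", "subcatchments"))) {
    tab <- get(fk[2])
    unknown <- setdiff(units[[fk[1]]], tab[[fk[1]]])
    if (length(unknown) > 0) {
      row <- which(units[[fk[1]]] %in% unknown)[1]
      abort(sprintf("units.csv row %d references unknown %s \"%s\"",
                    row, fk[1], unknown[1]))
    }
  }
  unknown <- setdiff(units$type_id, veg_types$type_id)
  if (length(unknown) > 0) {
    row <- which(units$type_id %in% unknown)[1]
    abort(sprintf("units.csv row %d references unknown type_id \"%s\"",
                  row, unknown[1]))
  }
  units <- units %>%
    mutate(across(all_of(c("buffered", "protected", "existing_cleared")),
                  ~ .x != 0))
  landscape(units, properties, subcatchments, veg_types, veg_groups)
}

#' @rdname read_landscape
#' @param x A [landscape()] object.
#' @export
write_landscape <- function(x, dir) {
  stopifnot(inherits(x, "landscape"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  units_out <- x$units %>%
    mutate(across(all_of(c("buffered", "protected", "existing_cleared")),
                  as.integer))
  readr::write_csv(units_out[landscape_file_spec$units],
                   file.path(dir, "units.csv"), progress = FALSE)
  readr::write_csv(x$properties[landscape_file_spec$properties],
                   file.path(dir, "properties.csv"), progress = FALSE)
  readr::write_csv(x$subcatchments[landscape_file_spec$subcatchments],
                   file.path(dir, "subcatchments.csv"), progress = FALSE)
  readr::write_csv(x$veg_types[landscape_file_spec$vegtypes],
                   file.path(dir, "vegtypes.csv"), progress = FALSE)
  readr::write_csv(x$veg_groups[landscape_file_spec$veggroups],
                   file.path(dir, "veggroups.csv"), progress = FALSE)
  invisible(dir)
}
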