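#' Cap policy for the cascade rules
#'
#' The cascade rules cap the cleared fraction of nested features: 70% of each
#' property, 40% of each sub-catchment, 30% of each vegetation type (against
#' its pre-clearing extent), and 20% of the whole catchment, with clearing
#' prohibited in buffer zones. Reaching a cap precludes further clearing of
#' that feature; features already over a cap are grandfathered (they keep
#' their clearing but gain none). Per-property clearing targets are drawn
#' uniformly between `target_lower` and `target_upper` (30--70%).
#'
#' @param property_cap,subcatchment_cap,vegetation_cap,catchment_cap Cap
#'   fractions in (0, 1\].
#' @param target_lower,target_upper Bounds of the uniform per-property
#'   clearing-target draw.
#' @param overshoot_mode `"complete_last_property"` lets the property whose
#'   clearing crosses the catchment cap finish its draw before the run stops
#'   (totals can end slightly above the cap, as observed in practice);
#'   `"truncate"` caps the final clearing event exactly at the catchment cap.
#' @param constrained `FALSE` disables the four percentage caps (buffer and
#'   protection exclusions always remain) for the unconstrained scenario.
#' @return A `cap_policy` list.
#' @export
cap_policy <- function(property_cap = 0.70,
                       subcatchment_cap = 0.40,
                       vegetation_cap = 0.30,
                       catchment_cap = 0.20,
                       target_lower = 0.30,
                       target_upper = 0.70,
                       overshoot_mode = c("complete_last_property", "truncate"),
                       constrained = TRUE) {
  overshoot_mode <- match.arg(overshoot_mode)
  caps <- c(property_cap, subcatchment_cap, vegetation_cap, catchment_cap)
  if (any(caps <= 0) || any(caps > 1)) {
    abort("all caps must lie in (0, 1]")
  }
  if (!(target_lower >= 0 && target_lower <= target_upper && target_upper <= 1)) {
    abort("need 0 <= target_lower <= target_upper <= 1")
  }
  structure(
    list(
      property_cap = property_cap,
      subcatchment_cap = subcatchment_cap,
      vegetation_cap = vegetation_cap,
      catchment_cap = catchment_cap,
      target_lower = target_lower,
      target_upper = target_upper,
      overshoot_mode = overshoot_mode,
      constrained = constrained
    ),
    class = "cap_policy"
  )
}

#' Initialize a cap ledger from a landscape
#'
#' The ledger tracks cleared area against its baseline for every cap level:
#' per property (baseline = total property area), per sub-catchment
#' (baseline = sub-catchment area), per vegetation type (baseline =
#' pre-clearing extent) and for the whole catchment. Existing clearing counts
#' toward every accumulator and denominator, which is what grandfathers
#' features that already exceed their cap. The ledger is an environment
#' (reference semantics): [apply_clearing()] updates it in place and appends
#' to its event log.
#'
#' @param x A validated [landscape()].
#' @param policy A [cap_policy()].
#' @return An object of class `cap_ledger`.
#' @export
init_ledger <- function(x, policy = cap_policy()) {
  stopifnot(inherits(x, "landscape"), inherits(policy, "cap_policy"))
  u <- x$units
  prop_ids <- x$properties$prop_id
  sc_ids <- x$subcatchments$sc_id
  type_ids <- x$veg_types$type_id

  led <- new.env(parent = emptyenv())
  led$policy <- policy
  led$prop_ids <- prop_ids
  led$sc_ids <- sc_ids
  led$type_ids <- type_ids
  led$prop_base <- setNames(x$properties$total_area_ha, prop_ids)
  led$sc_base <- setNames(x$subcatchments$total_area_ha, sc_ids)
  led$type_base <- setNames(x$veg_types$pre_clearing_area_ha,
                            as.character(type_ids))
  led$catchment_base <- x$catchment_area_ha

  ec <- u$area_ha * u$existing_cleared
  sum_by <- function(x, f, levels) {
    setNames(as.numeric(tapply(x, factor(f, levels = levels), sum,
                               default = 0)), as.character(levels))
  }
  led$prop_cleared <- sum_by(ec, u$prop_id, prop_ids)
  led$sc_cleared <- sum_by(ec, u$sc_id, sc_ids)
  led$type_cleared <- sum_by(ec, u$type_id, type_ids)
  led$catchment_cleared <- sum(ec)
  led$init_prop_cleared <- led$prop_cleared
  led$init_sc_cleared <- led$sc_cleared
  led$init_type_cleared <- led$type_cleared
  led$init_catchment_cleared <- led$catchment_cleared

  # unit lookup columns for the fast path
  led$u_prop <- match(u$prop_id, prop_ids)
  led$u_sc <- match(u$sc_id, sc_ids)
  led$u_type <- match(u$type_id, type_ids)
  led$u_area <- u$area_ha
  led$u_id <- u$unit_id
  led$u_suit <- u$suitability
  led$u_clearable <- !u$buffered & !u$protected & !u$existing_cleared &
    u$suitability > 0
  # per-property clearable units, pre-sorted by decreasing suitability
  # (ties: ascending type_id, then unit_id)
  cl <- which(led$u_clearable)
  cl <- cl[order(led$u_prop[cl], -led$u_suit[cl], u$type_id[cl], u$unit_id[cl])]
  led$prop_units <- split(cl, factor(led$u_prop[cl], levels = seq_along(prop_ids)))

  n_max <- nrow(u)
  led$ev_unit <- integer(n_max)
  led$ev_area <- numeric(n_max)
  led$ev_step <- 0L
  class(led) <- "cap_ledger"
  led
}

#' @export
print.cap_ledger <- function(x, ...) {
  cat("<cap_ledger>\n")
  cat(sprintf("  catchment cleared: %.1f / %.1f ha (%.2f%%)\n",
              x$catchment_cleared, x$catchment_base,
              100 * x$catchment_cleared / x$catchment_base))
  cat(sprintf("  events logged    : %d\n", x$ev_step))
  invisible(x)
}

#' Is a land unit available for clearing at all?
#'
#' Clearing is prohibited in buffer zones and protected areas, on land
#' already cleared, and on wholly unsuitable land (suitability index 0).
#'
#' @param units A data frame of land units (or a one-row unit).
#' @return A logical vector, one element per unit.
#' @export
is_clearable <- function(units) {
  !units$buffered & !units$protected & !units$existing_cleared &
    units$suitability > 0
}

# fast path: i is the row index of the unit in the landscape's unit table
allow_idx <- function(led, policy, i, property_remaining_ha) {
  take <- min(led$u_area[i], property_remaining_ha)
  if (!policy$constrained) return(max(0, take))
  hp <- policy$property_cap * led$prop_base[[led$u_prop[i]]] -
    led$prop_cleared[[led$u_prop[i]]]
  hs <- policy$subcatchment_cap * led$sc_base[[led$u_sc[i]]] -
    led$sc_cleared[[led$u_sc[i]]]
  hv <- policy$vegetation_cap * led$type_base[[led$u_type[i]]] -
    led$type_cleared[[led$u_type[i]]]
  take <- min(take, max(0, hp), max(0, hs), max(0, hv))
  if (policy$overshoot_mode == "truncate") {
    hc <- policy$catchment_cap * led$catchment_base - led$catchment_cleared
    take <- min(take, max(0, hc))
  }
  max(0, take)
}

#' Allowable clearing of a unit under the cascade caps
#'
#' The area that may be cleared from a unit is the minimum of the unit's
#' area, the property's remaining clearing target, and the cap headroom
#' (`max(0, cap x baseline - cleared)`) of the unit's property, sub-catchment
#' and vegetation type — plus, in `"truncate"` overshoot mode, of the whole
#' catchment (in `"complete_last_property"` mode the catchment cap acts as a
#' between-property stop rule instead). With an unconstrained policy all cap
#' headrooms are infinite. Features already at or over a cap have zero
#' headroom, so grandfathered features receive nothing.
#'
#' @param ledger A [init_ledger()] ledger.
#' @param policy A [cap_policy()].
#' @param unit A one-row data frame from the landscape's unit table (or a
#'   `unit_id` found in it).
#' @param property_remaining_ha Remaining area of the property's clearing
#'   target.
#' @return Allowable area in hectares.
#' @export
allowable_clearing <- function(ledger, policy, unit, property_remaining_ha) {
  i <- if (is.data.frame(unit)) {
    match(unit$unit_id[1], ledger$u_id)
  } else {
    match(unit, ledger$u_id)
  }
  if (is.na(i)) abort("unit not found in ledger")
  if (!ledger$u_clearable[i]) {
    abort("allowable_clearing() requires a clearable unit (see is_clearable())")
  }
  allow_idx(ledger, policy, i, property_remaining_ha)
}

apply_idx <- function(led, i, area_ha) {
  p <- led$u_prop[i]; s <- led$u_sc[i]; tt <- led$u_type[i]
  led$prop_cleared[[p]] <- led$prop_cleared[[p]] + area_ha
  led$sc_cleared[[s]] <- led$sc_cleared[[s]] + area_ha
  led$type_cleared[[tt]] <- led$type_cleared[[tt]] + area_ha
  led$catchment_cleared <- led$catchment_cleared + area_ha
  step <- led$ev_step + 1L
  if (step > length(led$ev_unit)) {
    led$ev_unit <- c(led$ev_unit, integer(length(led$ev_unit)))
    led$ev_area <- c(led$ev_area, numeric(length(led$ev_area)))
  }
  led$ev_unit[step] <- i
  led$ev_area[step] <- area_ha
  led$ev_step <- step
  invisible(led)
}

#' Record a clearing event against the ledger
#'
#' Increases all four accumulators (property, sub-catchment, vegetation type,
#' catchment) by the cleared area and appends the event to the ledger's log.
#' Attempting to clear more than [allowable_clearing()] permits is a
#' cap-violation error: the simulator must never produce one.
#'
#' @inheritParams allowable_clearing
#' @param area_ha Area to clear; must satisfy
#'   `0 < area_ha <= allowable_clearing(...) + 1e-9`.
#' @param property_remaining_ha Remaining property target used for the
#'   allowable check (defaults to `area_ha`, i.e. checks caps only).
#' @return The ledger, invisibly (it is modified in place).
#' @export
apply_clearing <- function(ledger, unit, area_ha,
                           policy = ledger$policy,
                           property_remaining_ha = area_ha) {
  i <- if (is.data.frame(unit)) {
    match(unit$unit_id[1], ledger$u_id)
  } else {
    match(unit, ledger$u_id)
  }
  if (is.na(i)) abort("unit not found in ledger")
  if (!ledger$u_clearable[i]) abort("cap violation: unit is not clearable")
  allowed <- allow_idx(ledger, policy, i, property_remaining_ha)
  if (!(area_ha > 0)) abort("area_ha must be positive")
  if (area_ha > allowed + 1e-9 * max(1, allowed)) {
    abort(sprintf("cap violation: tried to clear %.6f ha, allowable is %.6f ha",
                  area_ha, allowed))
  }
  apply_idx(ledger, i, area_ha)
}

#' Snapshot a ledger as tidy tibbles
#'
#' @param ledger A [init_ledger()] ledger.
#' @return A list of tibbles `property`, `subcatchment`, `veg_type`,
#'   `catchment` (cleared and baseline areas, cleared fractions) and `events`
#'   (the ordered clearing log).
#' @export
ledger_snapshot <- function(ledger) {
  steps <- seq_len(ledger$ev_step)
  idx <- ledger$ev_unit[steps]
  events <- tibble(
    step = steps,
    unit_id = ledger$u_id[idx],
    prop_id = ledger$prop_ids[ledger$u_prop[idx]],
    sc_id = ledger$sc_ids[ledger$u_sc[idx]],
    type_id = ledger$type_ids[ledger$u_type[idx]],
    area_ha = ledger$ev_area[steps]
  )
  list(
    property = tibble(
      prop_id = ledger$prop_ids,
      baseline_ha = unname(ledger$prop_base),
      cleared_ha = unname(ledger$prop_cleared),
      initial_cleared_ha = unname(ledger$init_prop_cleared),
      cleared_fraction = unname(ledger$prop_cleared / ledger$prop_base)
    ),
    subcatchment = tibble(
      sc_id = ledger$sc_ids,
      baseline_ha = unname(ledger$sc_base),
      cleared_ha = unname(ledger$sc_cleared),
      initial_cleared_ha = unname(ledger$init_sc_cleared),
      cleared_fraction = unname(ledger$sc_cleared / ledger$sc_base)
    ),
    veg_type = tibble(
      type_id = ledger$type_ids,
      baseline_ha = unname(ledger$type_base),
      cleared_ha = unname(ledger$type_cleared),
      initial_cleared_ha = unname(ledger$init_type_cleared),
      cleared_fraction = unname(ledger$type_cleared /
                                  pmax(ledger$type_base, 1e-12))
    ),
    catchment = tibble(
      baseline_ha = ledger$catchment_base,
      cleared_ha = ledger$catchment_cleared,
      initial_cleared_ha = ledger$init_catchment_cleared,
      cleared_fraction = ledger$catchment_cleared / ledger$catchment_base
    ),
    events = events
  )
}

#' Recompute ledger accumulators by replaying the event log
#'
#' Brute-force check of ledger integrity: starting from the initialization
#' (existing clearing only), re-applies every logged event and compares the
#' result with the live accumulators at relative tolerance `1e-6`.
#'
#' @param ledger A [init_ledger()] ledger.
#' @return `TRUE` if the replay matches; otherwise a character vector naming
#'   the mismatching accumulators.
#' @export
replay_ledger <- function(ledger) {
  steps <- seq_len(ledger$ev_step)
  idx <- ledger$ev_unit[steps]
  area <- ledger$ev_area[steps]
  prop <- ledger$init_prop_cleared
  sc <- ledger$init_sc_cleared
  ty <- ledger$init_type_cleared
  if (length(steps) > 0) {
    add_by <- function(grp, n) {
      as.numeric(tapply(area, factor(grp, levels = seq_len(n)), sum,
                        default = 0))
    }
    prop <- prop + add_by(ledger$u_prop[idx], length(prop))
    sc <- sc + add_by(ledger$u_sc[idx], length(sc))
    ty <- ty + add_by(ledger$u_type[idx], length(ty))
  }
  catch <- ledger$init_catchment_cleared + sum(area)
  bad <- character(0)
  if (!all(near_rel(prop, ledger$prop_cleared))) bad <- c(bad, "property")
  if (!all(near_rel(sc, ledger$sc_cleared))) bad <- c(bad, "subcatchment")
  if (!all(near_rel(ty, ledger$type_cleared))) bad <- c(bad, "veg_type")
  if (!near_rel(catch, ledger$catchment_cleared)) bad <- c(bad, "catchment")
  if (length(bad) == 0) TRUE else bad
}
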