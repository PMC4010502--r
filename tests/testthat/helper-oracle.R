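# Naive, from-scratch reimplementations used as independent oracles.
# Everything here recomputes state from plain data frames at every step and
# shares no code with the package's ledger fast path.

# cleared area of a feature = existing-cleared unit areas + logged new clearing
oracle_cleared <- function(units, extra, key) {
  existing <- tapply(units$area_ha * units$existing_cleared, units[[key]],
                     sum, default = 0)
  new <- tapply(extra, units[[key]], sum, default = 0)
  existing + new
}

# step-by-step clearing of one landscape under scripted property order and
# targets; returns a data frame of events (prop_id, unit_id, area_ha)
oracle_run <- function(x, order, targets, policy) {
  u <- as.data.frame(x$units)
  extra <- rep(0, nrow(u)) # new clearing per unit
  prop_area <- setNames(x$properties$total_area_ha, x$properties$prop_id)
  sc_area <- setNames(x$subcatchments$total_area_ha, x$subcatchments$sc_id)
  type_pre <- setNames(x$veg_types$pre_clearing_area_ha,
                       as.character(x$veg_types$type_id))
  catch_area <- x$catchment_area_ha
  events <- list()

  total_cleared <- function() {
    sum(u$area_ha[u$existing_cleared]) + sum(extra)
  }

  for (p in order) {
    if (policy$constrained &&
        total_cleared() >= policy$catchment_cap * catch_area -
          1e-6 * catch_area) {
      break
    }
    target_area <- targets[[p]] * prop_area[[p]]
    repeat {
      cleared_p <- sum(u$area_ha[u$existing_cleared & u$prop_id == p]) +
        sum(extra[u$prop_id == p])
      remaining <- target_area - cleared_p
      if (remaining <= 1e-9 * max(1, prop_area[[p]])) break
      cand <- which(u$prop_id == p & !u$buffered & !u$protected &
                      !u$existing_cleared & u$suitability > 0 &
                      u$area_ha - extra > 1e-12)
      if (length(cand) == 0) break
      cand <- cand[order(-u$suitability[cand], u$type_id[cand],
                         u$unit_id[cand])]
      cleared_any <- FALSE
      for (i in cand) {
        cleared_p <- sum(u$area_ha[u$existing_cleared & u$prop_id == p]) +
          sum(extra[u$prop_id == p])
        remaining <- target_area - cleared_p
        if (remaining <= 1e-9 * max(1, prop_area[[p]])) break
        take <- min(u$area_ha[i] - extra[i], remaining)
        if (policy$constrained) {
          pc <- oracle_cleared(u, extra, "prop_id")[[p]]
          sc <- oracle_cleared(u, extra, "sc_id")[[u$sc_id[i]]]
          tc <- oracle_cleared(u, extra, "type_id")[[as.character(u$type_id[i])]]
          take <- min(
            take,
            max(0, policy$property_cap * prop_area[[p]] - pc),
            max(0, policy$subcatchment_cap * sc_area[[u$sc_id[i]]] - sc),
            max(0, policy$vegetation_cap * type_pre[[as.character(u$type_id[i])]] - tc)
          )
          if (policy$overshoot_mode == "truncate") {
            take <- min(take, max(0, policy$catchment_cap * catch_area -
                                    total_cleared()))
          }
        }
        if (take > 1e-9 * max(1, prop_area[[p]])) {
          extra[i] <- extra[i] + take
          events[[length(events) + 1]] <-
            data.frame(prop_id = p, unit_id = u$unit_id[i], area_ha = take)
          cleared_any <- TRUE
        }
      }
      if (!cleared_any) break
    }
  }
  if (length(events) == 0) {
    data.frame(prop_id = character(), unit_id = integer(),
               area_ha = numeric())
  } else {
    do.call(rbind, events)
  }
}

# drive the package engine with the same script (order + targets) as the oracle
engine_run <- function(x, order, targets, policy) {
  led <- init_ledger(x, policy)
  catch_area <- led$catchment_base
  for (p in order) {
    if (policy$constrained &&
        led$catchment_cleared >= policy$catchment_cap * catch_area -
          1e-6 * catch_area) {
      break
    }
    simulate_property(x, led, policy, p, targets[[p]])
  }
  snap <- ledger_snapshot(led)
  list(events = snap$events, ledger = led, snapshot = snap)
}

# Spearman's rho by hand: average ranks then the Pearson product-moment
# formula written out
oracle_spearman <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  dx <- rx - mean(rx)
  dy <- ry - mean(ry)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# small generated landscape for tests that need realistic structure fast
small_config <- function(seed = 7) {
  generator_config(
    catchment_area_ha = 2e5, n_properties = 40, n_subcatchments = 4,
    n_veg_types = 12, n_veg_groups = 4, seed = seed
  )
}
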