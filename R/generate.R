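#' Configuration for the synthetic-landscape generator
#'
#' The defaults state the catchment the simulator emulates: a ~5.2 Mha
#' tropical savanna catchment of which 13% is protected, with the available
#' remainder split 10% government / 30% aboriginal / 60% private by area;
#' ~473 properties of 100--400,000 ha drawn from a heavy-tailed (log-normal)
#' size law; 16 sub-catchments; 98 vegetation types nested in 15 broad
#' groups; 5.4% of the catchment already cleared, with per-property cleared
#' fractions on \[0.01, 1\] averaging 0.25 among properties that have any
#' clearing; ~8% of the catchment in prohibited riparian buffers; and a
#' 0--400 suitability index whose area-weighted catchment mean is ~178, with
#' ~37.5% of unprotected, unbuffered land wholly unsuitable (index 0) so that
#' roughly 49% of the catchment is suitable, unbuffered and unprotected.
#'
#' @param catchment_area_ha Total catchment area (ha).
#' @param protected_fraction Fraction of the catchment in reserves.
#' @param tenure_mix Named fractions (`government`, `aboriginal`, `private`)
#'   of available (non-reserve) land; must sum to 1.
#' @param n_properties Number of properties tiling the catchment.
#' @param property_size_range Truncation bounds (ha) of the size law.
#' @param property_size_mean Target mean (ha) of the truncated log-normal
#'   size law before rescaling to tile the catchment.
#' @param property_size_sdlog Log-scale standard deviation of the size law.
#' @param n_subcatchments,n_veg_types,n_veg_groups Feature counts.
#' @param existing_cleared_fraction Fraction of the catchment already cleared.
#' @param cleared_prop_range,cleared_prop_mean Range and mean of per-property
#'   cleared fractions among properties with existing clearing.
#' @param buffered_fraction Fraction of the catchment inside no-clearing
#'   buffer zones.
#' @param suitability_zero_fraction Fraction of unprotected, unbuffered land
#'   with suitability 0.
#' @param suitability_positive_mean Mean suitability index of suitable land.
#' @param span_two_subcatchments_prob Probability that a property straddles a
#'   sub-catchment boundary (at most two sub-catchments per property).
#' @param seed Integer seed; identical seeds give identical landscapes.
#' @return A `generator_config` list.
#' @export
generator_config <- function(catchment_area_ha = 5.2e6,
                             protected_fraction = 0.13,
                             tenure_mix = c(government = 0.10,
                                            aboriginal = 0.30,
                                            private = 0.60),
                             n_properties = 473,
                             property_size_range = c(100, 400000),
                             property_size_mean = 15000,
                             property_size_sdlog = 1.6,
                             n_subcatchments = 16,
                             n_veg_types = 98,
                             n_veg_groups = 15,
                             existing_cleared_fraction = 0.054,
                             cleared_prop_range = c(0.01, 1.00),
                             cleared_prop_mean = 0.25,
                             buffered_fraction = 0.08,
                             suitability_zero_fraction = 0.375,
                             suitability_positive_mean = 285,
                             span_two_subcatchments_prob = 0.25,
                             seed = 1L) {
  cfg <- list(
    catchment_area_ha = catchment_area_ha,
    protected_fraction = protected_fraction,
    tenure_mix = tenure_mix,
    n_properties = as.integer(n_properties),
    property_size_range = property_size_range,
    property_size_mean = property_size_mean,
    property_size_sdlog = property_size_sdlog,
    n_subcatchments = as.integer(n_subcatchments),
    n_veg_types = as.integer(n_veg_types),
    n_veg_groups = as.integer(n_veg_groups),
    existing_cleared_fraction = existing_cleared_fraction,
    cleared_prop_range = cleared_prop_range,
    cleared_prop_mean = cleared_prop_mean,
    buffered_fraction = buffered_fraction,
    suitability_zero_fraction = suitability_zero_fraction,
    suitability_positive_mean = suitability_positive_mean,
    span_two_subcatchments_prob = span_two_subcatchments_prob,
    seed = as.integer(seed)
  )
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  fr <- c("protected_fraction", "existing_cleared_fraction", "buffered_fraction",
          "suitability_zero_fraction", "span_two_subcatchments_prob")
  for (f in fr) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) abort(paste0(f, " must be in [0, 1]"))
  }
  if (!setequal(names(cfg$tenure_mix), c("government", "aboriginal", "private")) ||
      any(cfg$tenure_mix < 0) || abs(sum(cfg$tenure_mix) - 1) > 1e-9) {
    abort("tenure_mix must name government/aboriginal/private fractions summing to 1")
  }
  if (cfg$n_veg_types < cfg$n_veg_groups) {
    abort("n_veg_types must be at least n_veg_groups")
  }
  if (cfg$n_properties * cfg$property_size_range[1] > cfg$catchment_area_ha) {
    abort("infeasible config: n_properties x minimum property size exceeds the catchment area")
  }
  if (cfg$cleared_prop_range[1] < 0 || cfg$cleared_prop_range[2] > 1 ||
      cfg$cleared_prop_range[1] > cfg$cleared_prop_range[2]) {
    abort("cleared_prop_range must be an increasing sub-interval of [0, 1]")
  }
  invisible(cfg)
}

# mean of a log-normal truncated to [a, b]
truncated_lnorm_mean <- function(meanlog, sdlog, a, b) {
  za <- (log(a) - meanlog) / sdlog
  zb <- (log(b) - meanlog) / sdlog
  p <- stats::pnorm(zb) - stats::pnorm(za)
  exp(meanlog + sdlog^2 / 2) *
    (stats::pnorm(zb - sdlog) - stats::pnorm(za - sdlog)) / p
}

# truncated log-normal property sizes with the configured target mean,
# rescaled (above the 100 ha floor) so they tile the catchment exactly
draw_property_sizes <- function(cfg) {
  a <- cfg$property_size_range[1]
  b <- cfg$property_size_range[2]
  meanlog <- stats::uniroot(
    function(m) truncated_lnorm_mean(m, cfg$property_size_sdlog, a, b) -
      cfg$property_size_mean,
    interval = c(log(a), log(b))
  )$root
  n <- cfg$n_properties
  draws <- numeric(0)
  while (length(draws) < n) {
    x <- rlnorm(2 * n, meanlog, cfg$property_size_sdlog)
    draws <- c(draws, x[x >= a & x <= b])
  }
  draws <- draws[seq_len(n)]
  budget <- cfg$catchment_area_ha - n * a
  sizes <- a + (draws - a) / sum(draws - a) * budget
  # rescaling shrinks (budget < sum of raw draws at the default config), so
  # the upper bound can only bind if the config is close to feasibility limits
  if (any(sizes > b)) {
    over <- sizes > b
    excess <- sum(sizes[over] - b)
    sizes[over] <- b
    sizes[!over] <- sizes[!over] + excess * (sizes[!over] - a) / sum(sizes[!over] - a)
  }
  sizes
}

draw_positive_suitability <- function(n, cfg) {
  m <- cfg$suitability_positive_mean / 400
  a <- 2.5
  b <- a * (1 - m) / m
  pmin(400L, pmax(1L, as.integer(round(400 * rbeta(n, a, b)))))
}

# suitability for land where the zero/positive split is not imposed by parts
draw_mixture_suitability <- function(n, cfg) {
  s <- draw_positive_suitability(n, cfg)
  s[runif(n) < cfg$suitability_zero_fraction] <- 0L
  s
}

#' Generate a seeded synthetic landscape
#'
#' Builds a complete tabular landscape with the statistical structure
#' described in [generator_config()]: heavy-tailed property sizes tiling the
#' catchment, Dirichlet sub-catchment areas with properties straddling at
#' most two sub-catchments, whole-property reserves covering the protected
#' fraction, tenure quotas filled largest-first, vegetation types nested in
#' groups, per-property buffered / unsuitable / existing-cleared / clearable
#' parts crossed with vegetation types and suitability classes into atomic
#' land units. The same seed always yields the identical landscape.
#'
#' @param config A [generator_config()].
#' @return A validated [landscape()].
#' @examples
#' L <- generate_landscape(generator_config(seed = 1))
#' nrow(validate_landscape(L)) # 0
#' @export
generate_landscape <- function(config = generator_config()) {
  validate_generator_config(config)
  cfg <- config
  set.seed(derive_seed(cfg$seed, "landscape"))

  n <- cfg$n_properties
  A <- cfg$catchment_area_ha

  sizes <- draw_property_sizes(cfg)
  prop_ids <- sprintf("P%04d", seq_len(n))

  ## sub-catchment targets: Dirichlet with unit concentration for a wide spread
  sc_ids <- sprintf("SC%02d", seq_len(cfg$n_subcatchments))
  w_sc <- rgamma(cfg$n_subcatchments, shape = 1) + 0.05
  sc_target <- A * w_sc / sum(w_sc)

  ## assign each property to one or two sub-catchments, tracking remaining
  ## target capacity so realized areas follow the Dirichlet targets
  sc_remaining <- sc_target
  prop_sc <- vector("list", n)
  for (i in seq_len(n)) {
    p_main <- pmax(sc_remaining, 0)
    if (sum(p_main) <= 0) p_main <- sc_target
    main <- sample.int(cfg$n_subcatchments, 1, prob = p_main)
    if (runif(1) < cfg$span_two_subcatchments_prob &&
        sizes[i] > 500 && cfg$n_subcatchments > 1) {
      p_sec <- p_main
      p_sec[main] <- 0
      if (sum(p_sec) <= 0) {
        p_sec <- sc_target
        p_sec[main] <- 0
      }
      sec <- sample.int(cfg$n_subcatchments, 1, prob = p_sec)
      share <- runif(1, 0.55, 0.85)
      prop_sc[[i]] <- tibble(sc = c(main, sec),
                             share = c(share, 1 - share))
    } else {
      prop_sc[[i]] <- tibble(sc = main, share = 1)
    }
    for (k in seq_len(nrow(prop_sc[[i]]))) {
      j <- prop_sc[[i]]$sc[k]
      sc_remaining[j] <- sc_remaining[j] - sizes[i] * prop_sc[[i]]$share[k]
    }
  }

  ## reserves: whole properties sampled by area until the protected target
  target_prot <- cfg$protected_fraction * A
  reserve <- rep(FALSE, n)
  if (target_prot > 0) {
    ord <- sample.int(n, n, prob = sizes)
    cum <- 0
    for (i in ord) {
      if (cum >= target_prot) break
      if (abs(cum + sizes[i] - target_prot) <= abs(cum - target_prot)) {
        reserve[i] <- TRUE
        cum <- cum + sizes[i]
      } else if (cum + sizes[i] < target_prot) {
        reserve[i] <- TRUE
        cum <- cum + sizes[i]
      } else {
        break
      }
    }
  }

  ## tenure: reserves split between government parks and indigenous protected
  ## areas; available properties fill area quotas largest-first
  tenure <- character(n)
  tenure[reserve] <- sample(c("government", "aboriginal"), sum(reserve),
                            replace = TRUE)
  avail_idx <- which(!reserve)
  quota <- cfg$tenure_mix * sum(sizes[avail_idx])
  for (i in avail_idx[order(-sizes[avail_idx])]) {
    t_pick <- names(quota)[which.max(quota)]
    tenure[i] <- t_pick
    quota[t_pick] <- quota[t_pick] - sizes[i]
  }

  ## vegetation structure: groups share the catchment; types nest in groups
  g_ids <- seq_len(cfg$n_veg_groups)
  w_g <- rgamma(cfg$n_veg_groups, shape = 1.2) + 0.05
  w_g <- w_g / sum(w_g)
  type_group <- c(g_ids,
                  sample(g_ids, cfg$n_veg_types - cfg$n_veg_groups,
                         replace = TRUE, prob = w_g))
  type_group <- sort(type_group)
  t_ids <- seq_len(cfg$n_veg_types)
  w_t <- numeric(cfg$n_veg_types)
  for (g in g_ids) {
    members <- which(type_group == g)
    ww <- rgamma(length(members), shape = 1) + 0.02
    w_t[members] <- w_g[g] * ww / sum(ww)
  }

  ## per-property vegetation types (every type appears somewhere)
  prop_types <- lapply(seq_len(n), function(i) {
    k <- 1 + min(rpois(1, 1.5), 5)
    sample.int(cfg$n_veg_types, min(k, cfg$n_veg_types), prob = w_t)
  })
  missing_types <- setdiff(t_ids, unique(unlist(prop_types)))
  if (length(missing_types) > 0) {
    hosts <- order(-sizes)[seq_along(missing_types)]
    for (k in seq_along(missing_types)) {
      prop_types[[hosts[k]]] <- union(prop_types[[hosts[k]]], missing_types[k])
    }
  }

  ## existing clearing: per-property fractions on the configured range, drawn
  ## until the catchment-wide cleared target is met
  f_clear <- rep(0, n)
  target_clear <- cfg$existing_cleared_fraction * A
  if (target_clear > 0) {
    lo <- cfg$cleared_prop_range[1]
    hi <- cfg$cleared_prop_range[2]
    m <- (cfg$cleared_prop_mean - lo) / (hi - lo)
    beta_b <- (1 - m) / m # shape1 = 1: monotone-decreasing density, mean m
    cand <- sample(which(!reserve))
    cum <- 0
    for (i in cand) {
      if (cum >= target_clear) break
      f <- lo + (hi - lo) * rbeta(1, 1, beta_b)
      rest <- target_clear - cum
      if (f * sizes[i] > rest) {
        f_adj <- rest / sizes[i]
        f <- if (f_adj >= lo) f_adj else lo
      }
      f_clear[i] <- f
      cum <- cum + f * sizes[i]
    }
  }

  ## build units property by property
  unit_list <- vector("list", n)
  b_mean <- cfg$buffered_fraction / (1 - cfg$protected_fraction)
  z_mean <- cfg$suitability_zero_fraction
  for (i in seq_len(n)) {
    Ai <- sizes[i]
    scs <- prop_sc[[i]]
    types_i <- prop_types[[i]]
    t_share <- rgamma(length(types_i), shape = 1.5) + 0.05
    t_share <- t_share / sum(t_share)

    if (reserve[i]) {
      cell <- tidyr::expand_grid(sc = scs$sc, type = types_i)
      cell$area <- Ai * rep(scs$share, each = length(types_i)) *
        rep(t_share, times = nrow(scs))
      cell$suit <- draw_mixture_suitability(nrow(cell), cfg)
      u <- tibble(
        prop_id = prop_ids[i], sc_id = sc_ids[cell$sc], type_id = cell$type,
        suitability = cell$suit, area_ha = cell$area,
        buffered = FALSE, protected = TRUE, existing_cleared = FALSE
      )
      unit_list[[i]] <- u[u$area_ha > 1e-6, ]
      next
    }

    b_i <- if (b_mean > 0) rbeta(1, 1.5, 1.5 * (1 - b_mean) / b_mean) else 0
    z_i <- rbeta(1, 3, 3 * (1 - z_mean) / max(z_mean, 1e-9))
    f_i <- f_clear[i]
    # a cleared property must have had enough suitable, unbuffered land
    if (f_i > 0 && (1 - b_i) * (1 - z_i) < f_i + 0.02) {
      z_i <- max(0, 1 - (f_i + 0.02) / (1 - b_i))
      if ((1 - b_i) * (1 - z_i) < f_i) {
        b_i <- max(0, 1 - f_i - 0.01)
        z_i <- 0
      }
    }
    a_buf <- Ai * b_i
    a_zero <- (Ai - a_buf) * z_i
    a_pos <- Ai - a_buf - a_zero
    a_clr <- min(f_i * Ai, a_pos)
    a_open <- a_pos - a_clr

    cell_w <- as.vector(outer(t_share, scs$share)) # type-major within sc
    cell_sc <- rep(scs$sc, each = length(types_i))
    cell_ty <- rep(types_i, times = nrow(scs))
    nc <- length(cell_w)

    parts <- list()
    if (a_buf > 0) {
      parts$buf <- tibble(
        sc = cell_sc, type = cell_ty, area = a_buf * cell_w,
        suit = draw_mixture_suitability(nc, cfg),
        buffered = TRUE, existing_cleared = FALSE
      )
    }
    if (a_zero > 0) {
      parts$zero <- tibble(
        sc = cell_sc, type = cell_ty, area = a_zero * cell_w,
        suit = 0L, buffered = FALSE, existing_cleared = FALSE
      )
    }
    if (a_clr > 0) {
      parts$cleared <- tibble(
        sc = cell_sc, type = cell_ty, area = a_clr * cell_w,
        suit = draw_positive_suitability(nc, cfg),
        buffered = FALSE, existing_cleared = TRUE
      )
    }
    if (a_open > 0) {
      s1 <- draw_positive_suitability(nc, cfg)
      s2 <- draw_positive_suitability(nc, cfg)
      clash <- s2 == s1
      s2[clash] <- ifelse(s1[clash] > 1, s1[clash] - 1L, s1[clash] + 1L)
      split <- runif(nc, 0.35, 0.65)
      parts$open <- tibble(
        sc = c(cell_sc, cell_sc), type = c(cell_ty, cell_ty),
        area = c(a_open * cell_w * split, a_open * cell_w * (1 - split)),
        suit = c(s1, s2), buffered = FALSE, existing_cleared = FALSE
      )
    }
    pp <- bind_rows(parts)
    u <- tibble(
      prop_id = prop_ids[i], sc_id = sc_ids[pp$sc], type_id = pp$type,
      suitability = pp$suit, area_ha = pp$area,
      buffered = pp$buffered, protected = FALSE,
      existing_cleared = pp$existing_cleared
    )
    unit_list[[i]] <- u[u$area_ha > 1e-6, ]
  }

  units <- bind_rows(unit_list)
  # collapse any residual duplicate keys (e.g. equal suitability draws in
  # different parts of the same cell with identical flags)
  units <- units %>%
    group_by(.data$prop_id, .data$sc_id, .data$type_id, .data$suitability,
             .data$buffered, .data$protected, .data$existing_cleared) %>%
    summarise(area_ha = sum(.data$area_ha), .groups = "drop")
  # preserve any sub-1e-6 relative shortfall by padding the largest unit
  deficit_by_prop <- tibble(prop_id = prop_ids, total = sizes) %>%
    left_join(units %>% group_by(.data$prop_id) %>%
                summarise(got = sum(.data$area_ha), .groups = "drop"),
              by = "prop_id") %>%
    mutate(deficit = .data$total - .data$got)
  for (r in which(abs(deficit_by_prop$deficit) > 0)) {
    idx <- which(units$prop_id == deficit_by_prop$prop_id[r])
    big <- idx[which.max(units$area_ha[idx])]
    units$area_ha[big] <- units$area_ha[big] + deficit_by_prop$deficit[r]
  }
  units <- units %>%
    arrange(.data$prop_id, .data$sc_id, .data$type_id, .data$suitability) %>%
    mutate(unit_id = dplyr::row_number()) %>%
    select("unit_id", dplyr::everything())

  properties <- tibble(prop_id = prop_ids, tenure = tenure,
                       total_area_ha = sizes)

  sc_tab <- units %>%
    group_by(.data$sc_id) %>%
    summarise(total_area_ha = sum(.data$area_ha),
              reserve_fraction = sum(.data$area_ha[.data$protected]) /
                sum(.data$area_ha),
              .groups = "drop")
  ab_area <- units %>%
    left_join(properties[c("prop_id", "tenure")], by = "prop_id") %>%
    group_by(.data$sc_id) %>%
    summarise(ab = sum(.data$area_ha[.data$tenure == "aboriginal"]) /
                sum(.data$area_ha), .groups = "drop")
  subcatchments <- sc_tab %>%
    left_join(ab_area, by = "sc_id") %>%
    rename(aboriginal_fraction = "ab")
  # guarantee every configured sub-catchment id exists
  missing_sc <- setdiff(sc_ids, subcatchments$sc_id)
  if (length(missing_sc) > 0) {
    subcatchments <- bind_rows(
      subcatchments,
      tibble(sc_id = missing_sc, total_area_ha = 0,
             reserve_fraction = 0, aboriginal_fraction = 0)
    ) %>% filter(.data$total_area_ha > 0)
  }

  type_tab <- units %>%
    group_by(.data$type_id) %>%
    summarise(pre_clearing_area_ha = sum(.data$area_ha),
              cleared = sum(.data$area_ha[.data$existing_cleared]),
              .groups = "drop")
  veg_types <- tibble(type_id = t_ids, group_id = type_group) %>%
    left_join(type_tab, by = "type_id") %>%
    mutate(pre_clearing_area_ha = ifelse(is.na(.data$pre_clearing_area_ha), 0,
                                         .data$pre_clearing_area_ha),
           cleared = ifelse(is.na(.data$cleared), 0, .data$cleared))
  veg_groups <- veg_types %>%
    group_by(.data$group_id) %>%
    summarise(pre_clearing_area_ha = sum(.data$pre_clearing_area_ha),
              cleared_area_ha = sum(.data$cleared), .groups = "drop") %>%
    mutate(name = sprintf("Vegetation group %02d", .data$group_id)) %>%
    select("group_id", "name", "pre_clearing_area_ha", "cleared_area_ha")
  veg_types <- veg_types %>% select("type_id", "group_id", "pre_clearing_area_ha")

  landscape(units, properties, subcatchments, veg_types, veg_groups,
            catchment_area_ha = A)
}

#' Compare a generated landscape's realized statistics with its targets
#'
#' Reports, for every aggregate the generator is asked to reproduce, the
#' configured target, the realized value, the relative error, and a flag for
#' relative errors above 10%. The mean property size is audited against the
#' budget-consistent target `catchment_area_ha / n_properties` (the catchment
#' area and property count jointly determine it); the raw size-law target is
#' reported alongside.
#'
#' @param x A landscape produced by [generate_landscape()].
#' @param config The [generator_config()] used to produce it.
#' @return A tibble with columns `statistic`, `target`, `realized`,
#'   `rel_error`, `flag`.
#' @export
audit_landscape <- function(x, config = generator_config()) {
  stopifnot(inherits(x, "landscape"))
  u <- x$units
  A <- x$catchment_area_ha
  prot <- sum(u$area_ha[u$protected]) / A
  reserve_props <- unique(u$prop_id[u$protected])
  avail <- x$properties %>% filter(!.data$prop_id %in% reserve_props)
  avail_area <- sum(avail$total_area_ha)
  ten <- vapply(c("government", "aboriginal", "private"), function(t) {
    sum(avail$total_area_ha[avail$tenure == t]) / avail_area
  }, numeric(1))
  cleared_frac <- sum(u$area_ha[u$existing_cleared]) / A
  clr_props <- x$properties %>% filter(.data$existing_cleared_ha > 0)
  mean_f <- mean(clr_props$existing_cleared_ha / clr_props$total_area_ha)
  mean_suit <- sum(u$suitability * u$area_ha) / A
  open_frac <- sum(u$area_ha[!u$protected & !u$buffered & u$suitability > 0]) / A
  buf_frac <- sum(u$area_ha[u$buffered]) / A
  mean_size <- mean(x$properties$total_area_ha)

  open_target <- (1 - config$protected_fraction) *
    (1 - config$buffered_fraction / (1 - config$protected_fraction)) *
    (1 - config$suitability_zero_fraction)
  suit_target <- (1 - config$suitability_zero_fraction) *
    config$suitability_positive_mean

  out <- tibble(
    statistic = c("catchment_area_ha", "n_properties", "protected_fraction",
                  "tenure_government", "tenure_aboriginal", "tenure_private",
                  "existing_cleared_fraction", "mean_cleared_fraction",
                  "mean_property_size_ha", "mean_suitability",
                  "open_suitable_fraction", "buffered_fraction"),
    target = c(config$catchment_area_ha, config$n_properties,
               config$protected_fraction,
               config$tenure_mix[["government"]],
               config$tenure_mix[["aboriginal"]],
               config$tenure_mix[["private"]],
               config$existing_cleared_fraction, config$cleared_prop_mean,
               config$catchment_area_ha / config$n_properties,
               suit_target, open_target, config$buffered_fraction),
    realized = c(A, nrow(x$properties), prot, ten[["government"]],
                 ten[["aboriginal"]], ten[["private"]], cleared_frac, mean_f,
                 mean_size, mean_suit, open_frac, buf_frac)
  ) %>%
    mutate(rel_error = abs(.data$realized - .data$target) / abs(.data$target),
           flag = .data$rel_error > 0.10)
  attr(out, "size_law_mean_ha") <- config$property_size_mean
  out
}

#' Small deterministic fixture landscapes
#'
#' Hand-specified landscapes with exact printed areas, used as oracles for
#' the cascade engine and simulator:
#' * `tiny3` — 3 properties (one spanning two sub-catchments) totalling
#'   10,000 ha, 2 sub-catchments, 2 vegetation types, one buffered unit, one
#'   500 ha existing-cleared unit.
#' * `capbound` — a 5,000 ha landscape whose first sub-catchment (1,000 ha)
#'   starts 60% cleared, above the 40% sub-catchment cap, so it is
#'   grandfathered and must receive no new clearing while the second
#'   sub-catchment (4,000 ha) remains open.
#' * `singleprop` — one 1,000 ha property holding a single suitability-200
#'   unit.
#'
#' @param name One of `"tiny3"`, `"capbound"`, `"singleprop"`.
#' @return A validated [landscape()].
#' @export
generate_fixture <- function(name = c("tiny3", "capbound", "singleprop")) {
  name <- match.arg(name)
  F <- FALSE
  T <- TRUE
  if (name == "tiny3") {
    units <- tibble(
      unit_id = 1:12,
      prop_id = c("P1", "P1", "P1", "P1",
                  "P2", "P2", "P2", "P2",
                  "P3", "P3", "P3", "P3"),
      sc_id = c("SC1", "SC1", "SC1", "SC1",
                "SC1", "SC1", "SC2", "SC2",
                "SC2", "SC2", "SC2", "SC2"),
      type_id = c(1L, 2L, 1L, 2L, 1L, 2L, 1L, 2L, 1L, 1L, 2L, 2L),
      suitability = c(300L, 150L, 0L, 100L, 250L, 50L, 200L, 0L,
                      350L, 350L, 120L, 0L),
      area_ha = c(1500, 1500, 600, 400, 1200, 800, 1000, 500,
                  500, 700, 800, 500),
      buffered = c(F, F, F, T, F, F, F, F, F, F, F, F),
      protected = F,
      existing_cleared = c(F, F, F, F, F, F, F, F, T, F, F, F)
    )
    properties <- tibble(
      prop_id = c("P1", "P2", "P3"),
      tenure = c("private", "aboriginal", "private"),
      total_area_ha = c(4000, 3500, 2500)
    )
    subcatchments <- tibble(
      sc_id = c("SC1", "SC2"),
      total_area_ha = c(6000, 4000),
      reserve_fraction = c(0, 0),
      aboriginal_fraction = c(2000 / 6000, 1500 / 4000)
    )
    veg_types <- tibble(type_id = 1:2, group_id = 1:2,
                        pre_clearing_area_ha = c(5500, 4500))
    veg_groups <- tibble(group_id = 1:2,
                         name = c("Eucalypt woodland", "Melaleuca woodland"),
                         pre_clearing_area_ha = c(5500, 4500),
                         cleared_area_ha = c(500, 0))
  } else if (name == "capbound") {
    units <- tibble(
      unit_id = 1:3,
      prop_id = c("P1", "P1", "P2"),
      sc_id = c("SC1", "SC1", "SC2"),
      type_id = 1L,
      suitability = c(200L, 200L, 100L),
      area_ha = c(600, 400, 4000),
      buffered = F,
      protected = F,
      existing_cleared = c(T, F, F)
    )
    properties <- tibble(
      prop_id = c("P1", "P2"),
      tenure = "private",
      total_area_ha = c(1000, 4000)
    )
    subcatchments <- tibble(
      sc_id = c("SC1", "SC2"),
      total_area_ha = c(1000, 4000),
      reserve_fraction = 0,
      aboriginal_fraction = 0
    )
    veg_types <- tibble(type_id = 1L, group_id = 1L,
                        pre_clearing_area_ha = 5000)
    veg_groups <- tibble(group_id = 1L, name = "Eucalypt woodland",
                         pre_clearing_area_ha = 5000, cleared_area_ha = 600)
  } else {
    units <- tibble(
      unit_id = 1L, prop_id = "P1", sc_id = "SC1", type_id = 1L,
      suitability = 200L, area_ha = 1000, buffered = F, protected = F,
      existing_cleared = F
    )
    properties <- tibble(prop_id = "P1", tenure = "private",
                         total_area_ha = 1000)
    subcatchments <- tibble(sc_id = "SC1", total_area_ha = 1000,
                            reserve_fraction = 0, aboriginal_fraction = 0)
    veg_types <- tibble(type_id = 1L, group_id = 1L,
                        pre_clearing_area_ha = 1000)
    veg_groups <- tibble(group_id = 1L, name = "Eucalypt woodland",
                         pre_clearing_area_ha = 1000, cleared_area_ha = 0)
  }
  landscape(units, properties, subcatchments, veg_types, veg_groups)
}
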