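#' Read a generator or scenario configuration file
#'
#' Configurations are YAML or JSON files whose keys mirror the
#' [generator_config()] / [scenario_spec()] arguments (`tenure_mix` as a
#' nested mapping). Unknown keys are an error, so typos fail loudly.
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` file.
#' @param what `"generator"` or `"scenario"`.
#' @return A [generator_config()] or [scenario_spec()].
#' @export
read_config <- function(path, what = c("generator", "scenario")) {
  what <- match.arg(what)
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  ctor <- if (what == "generator") generator_config else scenario_spec
  allowed <- names(formals(ctor))
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown) > 0) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  if (!is.null(raw$tenure_mix)) raw$tenure_mix <- unlist(raw$tenure_mix)
  if (!is.null(raw$property_size_range)) {
    raw$property_size_range <- as.numeric(raw$property_size_range)
  }
  if (!is.null(raw$cleared_prop_range)) {
    raw$cleared_prop_range <- as.numeric(raw$cleared_prop_range)
  }
  do.call(ctor, raw)
}

write_manifest <- function(path, entries) {
  entries$software <- list(
    package = "cascadr",
    version = as.character(utils::packageVersion("cascadr")),
    r_version = paste(R.version$major, R.version$minor, sep = ".")
  )
  entries$timestamp <- format(Sys.time(), tz = "UTC", usetz = TRUE)
  jsonlite::write_json(entries, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

file_hashes <- function(paths) {
  h <- tools::md5sum(paths)
  as.list(setNames(unname(h), basename(paths)))
}

#' Generate a landscape to disk
#'
#' Generates a synthetic landscape and writes the five landscape CSVs plus a
#' `manifest.json` recording the configuration, seed, file hashes and
#' software version. The same configuration and seed always produce
#' byte-identical CSVs.
#'
#' @param out_dir Output directory (created if needed).
#' @param config_path Optional YAML/JSON generator configuration; defaults
#'   to [generator_config()] defaults.
#' @param seed Optional seed overriding the configuration's.
#' @return The output directory, invisibly.
#' @export
cmd_generate <- function(out_dir, config_path = NULL, seed = NULL) {
  cfg <- if (is.null(config_path)) generator_config() else {
    read_config(config_path, "generator")
  }
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  validate_generator_config(cfg)
  L <- generate_landscape(cfg)
  viol <- validate_landscape(L)
  if (nrow(viol) > 0) {
    abort(paste0("generated landscape failed validation: ",
                 paste(unique(viol$rule), collapse = ", ")))
  }
  write_landscape(L, out_dir)
  files <- file.path(out_dir, paste0(names(landscape_file_spec), ".csv"))
  cfg_plain <- unclass(cfg)
  cfg_plain$tenure_mix <- as.list(cfg$tenure_mix)
  write_manifest(file.path(out_dir, "manifest.json"),
                 list(command = "generate", config = cfg_plain,
                      seed = cfg$seed, outputs = file_hashes(files)))
  invisible(out_dir)
}

#' Simulate a scenario to disk
#'
#' Loads and validates a landscape directory, runs the scenario, and writes
#' one event CSV per run (`events_run###.csv`), a per-run summary
#' (`runs.csv`), and a `manifest.json`.
#'
#' @param landscape_dir Directory written by [cmd_generate()] /
#'   [write_landscape()].
#' @param out_dir Output directory (created if needed).
#' @param scenario_path Optional YAML/JSON scenario configuration.
#' @param ordering,constrained,n_runs,seed Overrides applied on top of the
#'   scenario configuration (or the [scenario_spec()] defaults).
#' @param overshoot_mode Passed to [cap_policy()].
#' @return The [run_scenario()] result, invisibly.
#' @export
cmd_simulate <- function(landscape_dir, out_dir, scenario_path = NULL,
                         ordering = NULL, constrained = NULL, n_runs = NULL,
                         seed = NULL,
                         overshoot_mode = c("complete_last_property",
                                            "truncate")) {
  overshoot_mode <- match.arg(overshoot_mode)
  L <- read_landscape(landscape_dir)
  viol <- validate_landscape(L)
  if (nrow(viol) > 0) {
    abort(paste0("landscape failed validation: ",
                 paste(unique(viol$rule), collapse = ", ")))
  }
  spec <- if (is.null(scenario_path)) scenario_spec() else {
    read_config(scenario_path, "scenario")
  }
  if (!is.null(ordering)) spec$ordering <- ordering
  if (!is.null(constrained)) spec$constrained <- constrained
  if (!is.null(n_runs)) spec$n_runs <- as.integer(n_runs)
  if (!is.null(seed)) spec$seed <- as.integer(seed)
  spec <- scenario_spec(spec$ordering, spec$constrained, spec$n_runs, spec$seed)
  policy <- cap_policy(overshoot_mode = overshoot_mode,
                       constrained = spec$constrained)

  res <- run_scenario(L, policy, spec)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  files <- character(0)
  for (r in res$runs) {
    f <- file.path(out_dir, sprintf("events_run%03d.csv", r$run_id))
    readr::write_csv(r$events, f, progress = FALSE)
    files <- c(files, f)
  }
  runs_file <- file.path(out_dir, "runs.csv")
  readr::write_csv(tidy(res), runs_file, progress = FALSE)
  write_manifest(
    file.path(out_dir, "manifest.json"),
    list(command = "simulate",
         scenario = unclass(spec),
         policy = unclass(policy),
         landscape = file_hashes(file.path(landscape_dir, paste0(
           names(landscape_file_spec), ".csv"))),
         outputs = file_hashes(c(files, runs_file)))
  )
  invisible(res)
}

# rebuild the per-run summaries the reporters need from event CSVs
runs_from_events <- function(x, events) {
  led0 <- init_ledger(x, cap_policy())
  base_snap <- ledger_snapshot(led0)
  lapply(split(events, events$run_id), function(ev) {
    prop_new <- tapply(ev$area_ha, factor(ev$prop_id,
                                          levels = x$properties$prop_id),
                       sum, default = 0)
    sc_new <- tapply(ev$area_ha, factor(ev$sc_id,
                                        levels = x$subcatchments$sc_id),
                     sum, default = 0)
    ty_new <- tapply(ev$area_ha, factor(ev$type_id,
                                        levels = x$veg_types$type_id),
                     sum, default = 0)
    property <- base_snap$property %>%
      mutate(new_cleared_ha = as.numeric(prop_new),
             cleared_ha = .data$initial_cleared_ha + .data$new_cleared_ha,
             cleared_fraction = .data$cleared_ha / .data$baseline_ha,
             selected = .data$new_cleared_ha > 0)
    sc <- base_snap$subcatchment %>%
      mutate(cleared_ha = .data$initial_cleared_ha + as.numeric(sc_new),
             cleared_fraction = .data$cleared_ha / .data$baseline_ha)
    vt <- base_snap$veg_type %>%
      mutate(cleared_ha = .data$initial_cleared_ha + as.numeric(ty_new),
             cleared_fraction = .data$cleared_ha /
               pmax(.data$baseline_ha, 1e-12))
    catch <- base_snap$catchment %>%
      mutate(cleared_ha = .data$initial_cleared_ha + sum(ev$area_ha),
             cleared_fraction = .data$cleared_ha / .data$baseline_ha)
    structure(
      list(run_id = ev$run_id[1], events = as_tibble(ev), property = property,
           ledger = list(subcatchment = sc, veg_type = vt, catchment = catch)),
      class = "clearing_run"
    )
  })
}

#' Summarize simulation results to disk
#'
#' Reads the event CSVs of one or more scenarios and writes the summary
#' tables: per-scenario property/tenure statistics
#' (`properties_summary.csv`), percentage cleared by sub-catchment
#' (`subcatchment_pct.csv`) and by vegetation type (`vegtype_pct.csv`, with
#' across-type mean/SD in `vegtype_summary.csv`), the five most- and
#' least-cleared types (`extreme_vegtypes.csv`), and — when more than one
#' scenario is given — pairwise Spearman rank correlations of per-type
#' clearing (`spearman.csv`). Outputs are deterministic: re-running yields
#' byte-identical CSVs.
#'
#' @param results_dirs Named character vector of directories written by
#'   [cmd_simulate()] (names label the scenarios).
#' @param landscape_dir The landscape the simulations used.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
cmd_report <- function(results_dirs, landscape_dir, out_dir) {
  if (length(results_dirs) == 0) abort("no results directories given")
  if (is.null(names(results_dirs)) || any(names(results_dirs) == "")) {
    names(results_dirs) <- paste0("scenario_", seq_along(results_dirs))
  }
  L <- read_landscape(landscape_dir)
  all_runs <- lapply(results_dirs, function(d) {
    files <- sort(list.files(d, pattern = "^events_run[0-9]+\\.csv$",
                             full.names = TRUE))
    if (length(files) == 0) abort(paste0("no event files found in ", d))
    ev <- purrr::map_dfr(files, readr::read_csv, show_col_types = FALSE,
                         progress = FALSE)
    runs_from_events(L, ev)
  })
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  props <- purrr::imap_dfr(all_runs, function(runs, nm) {
    summarize_properties(runs, L) %>% mutate(scenario = nm, .before = 1)
  })
  readr::write_csv(props, file.path(out_dir, "properties_summary.csv"),
                   progress = FALSE)

  sc <- purrr::imap_dfr(all_runs, function(runs, nm) {
    percent_cleared_by_subcatchment(runs, L) %>%
      mutate(scenario = nm, .before = 1)
  })
  readr::write_csv(sc, file.path(out_dir, "subcatchment_pct.csv"),
                   progress = FALSE)

  vt_list <- lapply(all_runs, percent_cleared_by_vegtype, x = L)
  vt <- purrr::imap_dfr(vt_list, function(tbl, nm) {
    mutate(tbl, scenario = nm, .before = 1)
  })
  readr::write_csv(vt, file.path(out_dir, "vegtype_pct.csv"), progress = FALSE)
  vs <- purrr::imap_dfr(vt_list, function(tbl, nm) {
    vegtype_summary(tbl) %>% mutate(scenario = nm, .before = 1)
  })
  readr::write_csv(vs, file.path(out_dir, "vegtype_summary.csv"),
                   progress = FALSE)

  ex <- purrr::imap_dfr(vt_list, function(tbl, nm) {
    extreme_vegtypes(tbl, k = min(5, nrow(tbl))) %>%
      mutate(scenario = nm, .before = 1)
  })
  readr::write_csv(ex, file.path(out_dir, "extreme_vegtypes.csv"),
                   progress = FALSE)

  outputs <- c("properties_summary.csv", "subcatchment_pct.csv",
               "vegtype_pct.csv", "vegtype_summary.csv",
               "extreme_vegtypes.csv")
  if (length(vt_list) > 1 && nrow(vt_list[[1]]) >= 3) {
    sp <- spearman_matrix(lapply(vt_list, function(tbl) tbl$avg_pct))
    readr::write_csv(tidy(sp), file.path(out_dir, "spearman.csv"),
                     progress = FALSE)
    outputs <- c(outputs, "spearman.csv")
  }
  write_manifest(file.path(out_dir, "manifest.json"),
                 list(command = "report",
                      inputs = as.list(results_dirs),
                      outputs = file_hashes(file.path(out_dir, outputs))))
  invisible(out_dir)
}
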