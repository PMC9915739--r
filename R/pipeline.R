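#' Validate a pipeline run configuration
#'
#' The configuration is a named list (or a YAML file path) with a global
#' `seed`, a `stages` character vector, and one parameter block per stage.
#' Stage dependencies (behavior needs simulate_behavior, ensemble needs
#' simulate_traces, report needs behavior) are checked before anything
#' runs, all values are type- and range-checked, and unknown keys are
#' rejected.
#'
#' @param config A named list or a path to a YAML file.
#' @return The validated config list, invisibly; errors name every
#'   violation found.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  errs <- character(0)
  known_top <- c("seed", "stages", "simulate_behavior", "simulate_traces",
                 "simulate_images", "behavior", "ensemble", "morphology",
                 "report")
  unknown <- setdiff(names(config), known_top)
  if (length(unknown)) errs <- c(errs, paste("unknown key(s):",
                                             paste(unknown, collapse = ", ")))
  if (is.null(config$seed) || !is_scalar_number(config$seed))
    errs <- c(errs, "`seed` must be a single number")
  stages <- config$stages
  known_stages <- c("simulate_behavior", "simulate_traces", "simulate_images",
                    "behavior", "ensemble", "morphology", "report")
  if (is.null(stages) || !length(stages)) errs <- c(errs, "`stages` is empty")
  bad <- setdiff(stages, known_stages)
  if (length(bad)) errs <- c(errs, paste("unknown stage(s):",
                                         paste(bad, collapse = ", ")))
  needs <- list(behavior = "simulate_behavior",
                simulate_traces = "simulate_behavior",
                ensemble = "simulate_traces",
                morphology = "simulate_images",
                report = "behavior")
  for (st in intersect(stages, names(needs)))
    if (!needs[[st]] %in% stages)
      errs <- c(errs, sprintf("stage `%s` requires stage `%s`", st, needs[[st]]))
  sb <- config$simulate_behavior
  if (!is.null(sb)) {
    unknown <- setdiff(names(sb), c("n_sessions", "session_duration",
                                    "p_alternate", "mean_dwell", "speed",
                                    "sample_rate"))
    if (length(unknown)) errs <- c(errs, paste("simulate_behavior: unknown key(s):",
                                               paste(unknown, collapse = ", ")))
    if (!is.null(sb$p_alternate) &&
        (!is_scalar_number(sb$p_alternate) || sb$p_alternate < 0 || sb$p_alternate > 1))
      errs <- c(errs, "simulate_behavior: `p_alternate` out of range [0, 1]")
    if (!is.null(sb$n_sessions) && (!is_scalar_number(sb$n_sessions) || sb$n_sessions < 1))
      errs <- c(errs, "simulate_behavior: `n_sessions` must be >= 1")
  }
  st_cfg <- config$simulate_traces
  if (!is.null(st_cfg)) {
    unknown <- setdiff(names(st_cfg), c("n_neurons", "noise_sd", "frac_selective",
                                        "selective_gain", "tuning_width",
                                        "peak_rate", "baseline_rate",
                                        "event_amplitude"))
    if (length(unknown)) errs <- c(errs, paste("simulate_traces: unknown key(s):",
                                               paste(unknown, collapse = ", ")))
    if (!is.null(st_cfg$frac_selective) &&
        (!is_scalar_number(st_cfg$frac_selective) ||
         st_cfg$frac_selective < 0 || st_cfg$frac_selective > 1))
      errs <- c(errs, "simulate_traces: `frac_selective` out of range [0, 1]")
  }
  if (length(errs)) stop(paste(c("invalid configuration:", errs), collapse = "\n  "),
                         call. = FALSE)
  invisible(config)
}

#' Default demonstration configuration
#'
#' A small end-to-end run: one simulated session, 30 neurons, behavior
#' scoring, ensemble maps and a report.
#'
#' @param seed Global seed; default 1.
#' @return A config list accepted by [run_pipeline()].
#' @export
demo_config <- function(seed = 1) {
  list(seed = seed,
       stages = c("simulate_behavior", "behavior", "simulate_traces",
                  "ensemble", "report"),
       simulate_behavior = list(n_sessions = 1, session_duration = 480,
                                p_alternate = 0.67),
       simulate_traces = list(n_neurons = 30, frac_selective = 0.2))
}

#' Run the analysis pipeline from a configuration
#'
#' Stages execute in dependency order; every output file is CSV or JSON,
#' listed in `manifest.csv` with MD5 checksums, and the run log records the
#' global seed, the per-stage derived seeds and all parameter values. With
#' a fixed seed the outputs are byte-identical across reruns.
#'
#' @param config A config list or YAML path (see [validate_config()]).
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a list with `manifest` (data.frame file/md5), `log`,
#'   and the in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir) {
  config <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  res <- list()
  log <- list(seed = seed, stages = list())
  files <- character(0)
  emit <- function(name, writer) {
    path <- file.path(out_dir, name)
    writer(path)
    files <<- c(files, path)
  }
  stages <- config$stages
  if ("simulate_behavior" %in% stages) {
    p <- config$simulate_behavior
    cfg <- behavior_sim_config(
      n_sessions = p$n_sessions %||% 1,
      session_duration = p$session_duration %||% 480,
      p_alternate = p$p_alternate %||% 0.67,
      mean_dwell = p$mean_dwell %||% 1.5,
      speed = p$speed %||% 10,
      seed = child_seed(seed, "simulate_behavior"))
    entries <- simulate_arm_entries(cfg)
    traj <- simulate_trajectory(entries, cfg)
    res$traj <- traj; res$sim_entries <- entries
    emit("trajectory.csv", function(f) write_trajectory_csv(traj, f))
    log$stages$simulate_behavior <- list(seed = cfg$seed,
                                         p_alternate = cfg$p_alternate,
                                         n_entries = length(entries$arms))
  }
  if ("behavior" %in% stages) {
    entries <- detect_arm_entries(res$traj)
    trials <- segment_trials(res$traj, entries)
    alt <- score_alternation(entries)
    res$entries <- entries; res$trials <- trials; res$alternation <- alt
    emit("entries.csv", function(f) write_table_csv(entries, f))
    emit("trials.csv", function(f) write_table_csv(trials, f))
    emit("alternation.json", function(f)
      jsonlite::write_json(list(percent = alt$percent,
                                n_entries = alt$n_entries), f,
                           auto_unbox = TRUE, digits = NA))
    log$stages$behavior <- list(alternation_percent = alt$percent)
  }
  if ("simulate_traces" %in% stages) {
    p <- config$simulate_traces
    tcfg <- trace_sim_config(
      n_neurons = p$n_neurons %||% 30,
      noise_sd = p$noise_sd %||% 0.05,
      frac_selective = p$frac_selective %||% 0,
      selective_gain = p$selective_gain %||% 2,
      seed = child_seed(seed, "simulate_traces"))
    sim <- simulate_trace_set(res$traj, tcfg, trials = res$trials)
    res$sim_traces <- sim
    emit("traces.csv", function(f) write_traces_csv(sim$traces, f))
    log$stages$simulate_traces <- list(seed = tcfg$seed, n_neurons = tcfg$n_neurons)
  }
  if ("ensemble" %in% stages) {
    sim <- res$sim_traces
    map <- build_spatial_map(sim$traces, sim$trials, sim$bins)
    pd <- peak_position_distribution(map)
    res$map <- map; res$peak_dist <- pd
    emit("peak_distribution.csv", function(f) write_csv_stable(pd$table, f))
    sel <- tryCatch(alternation_selectivity(map), error = function(e) NULL)
    if (!is.null(sel)) {
      res$selectivity <- sel
      emit("selectivity.csv", function(f) write_csv_stable(sel$table, f))
    }
    log$stages$ensemble <- list(n_neurons = pd$n_neurons,
                                modal_bin = which.max(pd$table$proportion))
  }
  if ("report" %in% stages) {
    rep <- build_report(list(
      alternation = list(values = res$alternation$percent, groups = "all",
                         test = "none"),
      total_entries = list(values = res$alternation$n_entries, groups = "all",
                           test = "none")))
    res$report <- rep
    emit("report.json", function(f)
      jsonlite::write_json(list(tables = rep$tables, absent = rep$absent), f,
                           auto_unbox = TRUE, digits = NA, dataframe = "rows"))
    log$stages$report <- list(n_tables = length(rep$tables))
  }
  log_path <- file.path(out_dir, "run_log.json")
  jsonlite::write_json(log, log_path, auto_unbox = TRUE, digits = NA)
  files <- c(files, log_path)
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(list(manifest = manifest, log = log, results = res))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
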