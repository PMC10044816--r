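#' Load and validate a run configuration
#'
#' YAML (or JSON) configuration for [run_pipeline()].  Unknown keys are
#' rejected; defaults are filled for everything omitted.  Recognised keys:
#' `specimen` (fields of [specimen_params()]), `registry_path` (CSV, see
#' [read_registry()]), `contact` (`k_c`), `protocol` (`flexion_max`, `step`,
#' `torque_nm`), `states` (subset of [knee_state_labels()]), `torques`
#' (subset of `ir`, `er`), `reference` (`noise_sd`, or `intact_path` /
#' `sectioned_path` CSVs), `calibration` (`enabled`, `n_random`,
#' `grid_step`, `max_eval`), `output_dir`, `rng_seed`, `log_level`.
#'
#' @param path config file path.
#' @return validated config list of class `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  validate_config(raw)
}

#' @rdname load_config
#' @param raw a raw config list (as parsed from YAML).
#' @export
validate_config <- function(raw = list()) {
  known <- c("specimen", "registry_path", "contact", "protocol", "states",
             "torques", "reference", "calibration", "output_dir", "rng_seed",
             "log_level")
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("config: unknown keys: ", paste(bad, collapse = ", "))
  check_sub <- function(block, allowed) {
    bad <- setdiff(names(raw[[block]]), allowed)
    if (length(bad))
      stop("config: unknown keys in `", block, "`: ",
           paste(bad, collapse = ", "))
  }
  check_sub("specimen", names(formals(specimen_params)))
  check_sub("contact", "k_c")
  check_sub("protocol", c("flexion_max", "step", "torque_nm"))
  check_sub("reference", c("noise_sd", "intact_path", "sectioned_path"))
  check_sub("calibration", c("enabled", "n_random", "grid_step", "max_eval"))

  cfg <- list(
    specimen = do.call(specimen_params,
                       raw$specimen %||% list()),
    registry = if (!is.null(raw$registry_path))
      read_registry(raw$registry_path) else default_bundle_registry(),
    registry_path = raw$registry_path,
    contact = contact_params(raw$contact$k_c %||% 150),
    protocol = simulation_protocol(
      flexion_max = raw$protocol$flexion_max %||% 100,
      step = raw$protocol$step %||% 1,
      torque_nm = raw$protocol$torque_nm %||% 5),
    states = raw$states %||% knee_state_labels(),
    torques = raw$torques %||% c("ir", "er"),
    reference = list(noise_sd = raw$reference$noise_sd %||% 0,
                     intact_path = raw$reference$intact_path,
                     sectioned_path = raw$reference$sectioned_path),
    calibration = list(enabled = raw$calibration$enabled %||% TRUE,
                       n_random = raw$calibration$n_random %||% 12,
                       grid_step = raw$calibration$grid_step %||% 5,
                       max_eval = raw$calibration$max_eval %||% 60),
    output_dir = raw$output_dir %||% "kneeflex-run",
    rng_seed = as.integer(raw$rng_seed %||% 1L),
    log_level = raw$log_level %||% "info"
  )
  bad_states <- setdiff(cfg$states, knee_state_labels())
  if (length(bad_states))
    stop("config: unknown states: ", paste(bad_states, collapse = ", "))
  bad_t <- setdiff(cfg$torques, c("ir", "er"))
  if (length(bad_t))
    stop("config: unknown torques: ", paste(bad_t, collapse = ", "))
  class(cfg) <- "run_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# serialisable echo of the effective configuration
config_echo <- function(cfg) {
  list(specimen = unclass(cfg$specimen),
       registry_path = cfg$registry_path,
       contact = list(k_c = as.list(cfg$contact$k_c)),
       protocol = list(flexion_max = max(cfg$protocol$grid),
                       step = cfg$protocol$grid[2] - cfg$protocol$grid[1],
                       torque_nm = cfg$protocol$torque_nm),
       states = cfg$states, torques = cfg$torques,
       reference = cfg$reference, calibration = cfg$calibration,
       output_dir = cfg$output_dir, rng_seed = cfg$rng_seed,
       log_level = cfg$log_level)
}

pipeline_log <- function(cfg, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible())
  message(sprintf(...))
}

#' Run the full simulation pipeline
#'
#' Generates the synthetic specimen, calibrates it against the reference
#' kinematics (unless disabled), builds the requested knee states, sweeps
#' each under the requested torques, and writes kinematics and strain CSVs,
#' the calibration log, a comparison report (JSON and Markdown), the
#' effective configuration and a MANIFEST to the output directory.  All
#' randomness flows from the single config seed, so a fixed seed gives
#' byte-identical outputs.
#'
#' @param config a [load_config()] / [validate_config()] object.
#' @return (invisibly) list with the calibration result, per-state results
#'   and the comparison report.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest <- c()
  note <- function(f) manifest <<- c(manifest, f)

  yaml::write_yaml(config_echo(config), file.path(out, "effective-config.yaml"))
  note("effective-config.yaml")

  grid_max <- max(config$protocol$grid)
  grid_step <- config$protocol$grid[2] - config$protocol$grid[1]
  ref <- list(
    intact = if (!is.null(config$reference$intact_path))
      read_kinematics_csv(config$reference$intact_path)
    else generate_reference_kinematics(
      reference_endpoints("intact"), flexion_max = grid_max,
      step = grid_step, noise_sd = config$reference$noise_sd,
      rng_seed = config$rng_seed),
    sectioned = if (!is.null(config$reference$sectioned_path))
      read_kinematics_csv(config$reference$sectioned_path)
    else generate_reference_kinematics(
      reference_endpoints("acl_sectioned"), flexion_max = grid_max,
      step = grid_step, noise_sd = config$reference$noise_sd,
      rng_seed = config$rng_seed + 1L)
  )
  write_kinematics_csv(ref$intact, file.path(out, "reference-intact.csv"))
  write_kinematics_csv(ref$sectioned, file.path(out, "reference-sectioned.csv"))
  note("reference-intact.csv"); note("reference-sectioned.csv")

  status <- "incomplete"
  on.exit(writeLines(c(paste("status:", status), manifest),
                     file.path(out, "MANIFEST")), add = TRUE)

  if (config$calibration$enabled) {
    pipeline_log(config, "calibrating specimen (seed %d)", config$rng_seed)
    cal <- calibrate(config$specimen, ref, config$registry, config$contact,
                     seed = config$rng_seed,
                     n_random = config$calibration$n_random,
                     grid_step = config$calibration$grid_step,
                     max_eval = config$calibration$max_eval,
                     protocol = config$protocol)
    utils::write.csv(cal$log, file.path(out, "calibration-log.csv"),
                     row.names = FALSE)
    note("calibration-log.csv")
    intact <- cal$model
  } else {
    cal <- NULL
    geom <- place_attachments(generate_specimen(config$specimen),
                              config$registry)
    intact <- build_knee_model(geom, config$contact, "INTACT")
  }

  results_ir <- list(); results_er <- list()
  for (st in config$states) {
    model <- apply_state(intact, st, protocol = config$protocol)
    for (tq in config$torques) {
      pipeline_log(config, "sweep: %s / %s torque", st, tq)
      prot <- simulation_protocol(flexion_max = grid_max, step = grid_step,
                                  torque_nm = config$protocol$torque_nm,
                                  direction = tq)
      res <- run_flexion_sweep(model, prot)
      base <- sprintf("%s-%s", tolower(st), tq)
      write_kinematics_csv(res, file.path(out, paste0(base, "-kinematics.csv")))
      write_strains_csv(res, model, file.path(out, paste0(base, "-strains.csv")))
      note(paste0(base, "-kinematics.csv"))
      note(paste0(base, "-strains.csv"))
      if (tq == "ir") results_ir[[st]] <- res else results_er[[st]] <- res
    }
  }

  report <- NULL
  if ("ir" %in% config$torques && "INTACT" %in% names(results_ir)) {
    report <- compare_states(results_ir)
    write_comparison_report(report, file.path(out, "comparison-report.json"),
                            file.path(out, "comparison-report.md"))
    note("comparison-report.json"); note("comparison-report.md")
  }
  writeLines(c(sprintf("kneeflex %s", as.character(utils::packageVersion("kneeflex"))),
               sprintf("seed: %d", config$rng_seed),
               sprintf("date: %s", format(Sys.time(), "%Y-%m-%d"))),
             file.path(out, "run-log.txt"))
  note("run-log.txt")
  status <- "complete"
  invisible(list(calibration = cal, results_ir = results_ir,
                 results_er = results_er, report = report))
}
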