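#' Stage configuration: defaults and validation
#'
#' Each pipeline stage (`calibrate`, `synth`, `protocol`, `simulate`) has a
#' fixed parameter schema; [load_config()] fills defaults and rejects
#' unknown keys so a typo cannot silently change a run.
#'
#' @keywords internal
stage_schemas <- function() {
  list(
    calibrate = list(f_lo = 0.3, f_hi = 10, edge_fraction = 0.2,
                     grid_step = 1e-3),
    synth = list(tonic = 30, depth = 20, freq = 3, phase = 0,
                 duration = 50, phase_lag = 0),
    protocol = list(type = "pr", variant = "PR0", Ts = 0.020,
                    n_presentations = NULL, period = NULL,
                    pulse_rate_gain = 50, event_rate_area = 1),
    simulate = list(kind = "closed-loop", target_gain = 0.5,
                    tonic_v = 50, tonic_c = 50, depth_v = 40,
                    depth_c = 40, freq = 3, imbalance = 0, beta = NULL,
                    n_steps = 150, segment_duration = 50))
}

#' Load and validate a run configuration
#'
#' Reads a JSON or YAML file with fields `stage`, `parameters`, and
#' optionally `seed` and `output_dir`. Parameters are validated against the
#' stage schema: unknown keys are an error (named in the message), missing
#' keys are filled with defaults.
#'
#' @param path config file (`.json`, `.yaml` or `.yml`).
#' @return validated config: list with `stage`, `parameters`, `seed`,
#'   `output_dir`, class `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  validate_config(raw)
}

#' @rdname load_config
#' @param raw a list as read from file (or built in code).
#' @export
validate_config <- function(raw) {
  schemas <- stage_schemas()
  if (is.null(raw$stage) || !raw$stage %in% names(schemas))
    stop("config must name a stage, one of: ",
         paste(names(schemas), collapse = ", "))
  schema <- schemas[[raw$stage]]
  params <- if (is.null(raw$parameters)) list() else raw$parameters
  unknown <- setdiff(names(params), names(schema))
  if (length(unknown) > 0)
    stop("unknown parameter key(s) for stage '", raw$stage, "': ",
         paste(unknown, collapse = ", "))
  filled <- schema
  filled[names(params)] <- params
  structure(list(stage = raw$stage, parameters = filled,
                 seed = raw$seed,
                 output_dir = if (is.null(raw$output_dir)) "."
                              else raw$output_dir),
            class = "run_config")
}

#' Save a run configuration as JSON
#' @param config a `run_config`.
#' @param path output path.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Write a run manifest
#'
#' Records everything needed to replay a run bit-for-bit: the validated
#' configuration (including the seed), the package version, and the
#' headline results.
#'
#' @param config a `run_config`.
#' @param results_summary named list of headline outputs.
#' @param path output path (JSON).
#' @export
write_run_manifest <- function(config, results_summary, path) {
  stopifnot(inherits(config, "run_config"))
  manifest <- list(
    config = unclass(config),
    version = as.character(utils::packageVersion("istdpsim")),
    results = results_summary)
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("unwritable path: directory does not exist: ", dir)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read back a run manifest
#' @param path manifest path.
#' @export
read_run_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$config <- validate_config(m$config)
  m
}

#' Spike-train and rate-signal CSV I/O
#'
#' Spike trains are written as a single column `time_s`; rate signals as
#' two columns `time_s`, `rate_hz` (tonic plus deviation).
#'
#' @param x a [spike_train()] or [rate_signal()].
#' @param path file path.
#' @export
write_spike_train_csv <- function(x, path) {
  stopifnot(inherits(x, "spike_train"))
  utils::write.csv(data.frame(time_s = x$times), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spike_train_csv
#' @param duration observation window of the stored train (s).
#' @export
read_spike_train_csv <- function(path, duration) {
  d <- utils::read.csv(path)
  if (!"time_s" %in% names(d)) stop("expected a 'time_s' column")
  spike_train(d$time_s, duration)
}

#' @rdname write_spike_train_csv
#' @export
write_rate_signal_csv <- function(x, path) {
  stopifnot(inherits(x, "rate_signal"))
  utils::write.csv(data.frame(time_s = rate_times(x),
                              rate_hz = x$tonic + x$deviation),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spike_train_csv
#' @param tonic baseline rate used to split the stored total rate back into
#'   tonic + deviation.
#' @export
read_rate_signal_csv <- function(path, tonic) {
  d <- utils::read.csv(path)
  if (!all(c("time_s", "rate_hz") %in% names(d)))
    stop("expected 'time_s' and 'rate_hz' columns")
  dt <- d$time_s[2] - d$time_s[1]
  rate_signal(tonic, d$rate_hz - tonic, dt, t0 = d$time_s[1] - dt / 2)
}

#' Export a weight trajectory as CSV
#'
#' Columns `step`, `time_s`, `w`, `dw`.
#' @param x a [weight_trajectory()].
#' @param path file path.
#' @export
write_trajectory_csv <- function(x, path) {
  stopifnot(inherits(x, "weight_trajectory"))
  utils::write.csv(
    data.frame(step = seq_along(x$times) - 1, time_s = x$times,
               w = x$weights, dw = c(0, diff(x$weights))),
    path, row.names = FALSE)
  invisible(path)
}
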