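# Plain-text I/O: trace CSVs (column layouts mirroring raw actigraphy and
# HR-monitor exports), feature/prediction CSVs, and the validated YAML
# run configuration. All inter-stage artifacts are diffable text.

read_numeric_csv <- function(path, expected_names) {
  if (!file.exists(path)) stop_invalid("file not found: %s", path)
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  if (!identical(names(df), expected_names)) {
    stop_invalid("malformed header in %s: expected %s, got %s", path,
                 paste(expected_names, collapse = ","), paste(names(df), collapse = ","))
  }
  for (col in expected_names) {
    vals <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(vals) & !is.na(df[[col]]) & nzchar(df[[col]]))
    if (length(bad)) {
      stop_invalid("non-numeric value in %s, column %s, line %d",
                   path, col, bad[1L] + 1L) # +1 for the header line
    }
    df[[col]] <- vals
  }
  df
}

check_monotone_time <- function(time_s, path) {
  bad <- which(diff(time_s) <= 0)
  if (length(bad)) {
    stop_invalid("non-monotone timestamps in %s at line %d", path, bad[1L] + 2L)
  }
}

# Shared rate validation: infer from the median timestamp step; error when
# the inferred rate deviates > 1% from nominal, warn and record gaps when
# individual steps are missing samples.
infer_rate <- function(time_s, nominal_rate, path) {
  steps <- diff(time_s)
  med <- stats::median(steps)
  rate <- 1 / med
  if (abs(rate - nominal_rate) / nominal_rate > 0.01) {
    stop_invalid("sampling rate %.4g Hz in %s deviates > 1%% from nominal %g Hz",
                 rate, path, nominal_rate)
  }
  gaps <- which(steps > 1.5 * med)
  if (length(gaps)) {
    warning(sprintf("%s: %d timestamp gap(s) detected (missing samples)",
                    path, length(gaps)), call. = FALSE)
  }
  list(rate = rate, gaps = gaps)
}

#' Read / write accelerometer and heart-rate trace CSVs
#'
#' Accelerometer files have the header `time_s,x_g,y_g,z_g`; heart-rate
#' files `time_s,hr_bpm`. Timestamps must be strictly increasing; the
#' inferred sampling rate must be within 1% of nominal. Timestamp gaps
#' (missing samples) raise a warning and are recorded in attribute
#' `"gaps"`.
#'
#' @param path CSV path.
#' @param nominal_rate Expected sampling rate, Hz.
#' @return `read_accel_csv`: an [accel_trace()]; `read_hr_csv`: an
#'   [hr_trace()]. Writers return `path` invisibly.
#' @export
read_accel_csv <- function(path, nominal_rate = 100) {
  df <- read_numeric_csv(path, c("time_s", "x_g", "y_g", "z_g"))
  check_monotone_time(df$time_s, path)
  info <- infer_rate(df$time_s, nominal_rate, path)
  out <- accel_trace(df$x_g, df$y_g, df$z_g, sampling_rate = info$rate,
                     start_time = df$time_s[1L])
  out$time_s <- df$time_s
  attr(out, "gaps") <- info$gaps
  out
}

#' @rdname read_accel_csv
#' @export
read_hr_csv <- function(path, nominal_rate = 1) {
  df <- read_numeric_csv(path, c("time_s", "hr_bpm"))
  check_monotone_time(df$time_s, path)
  info <- infer_rate(df$time_s, nominal_rate, path)
  out <- hr_trace(df$hr_bpm, start_time = df$time_s[1L], sampling_rate = info$rate)
  out$time_s <- df$time_s
  attr(out, "gaps") <- info$gaps
  out
}

#' @rdname read_accel_csv
#' @param trace The trace to write.
#' @export
write_accel_csv <- function(trace, path) {
  stopifnot(inherits(trace, "accel_trace"))
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_accel_csv
#' @export
write_hr_csv <- function(trace, path) {
  stopifnot(inherits(trace, "hr_trace"))
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a simulated cohort to per-subject CSVs
#'
#' Writes `<subject>_accel.csv` and `<subject>_hr.csv` per session, the
#' stage schedule per subject, and a cohort manifest
#' (`subject_id,mass_kg,hr_min,hr_max,v_ift,seed`).
#'
#' @param cohort Result of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @param seed Seed echoed into the manifest.
#' @return The manifest path, invisibly.
#' @export
write_cohort_csv <- function(cohort, dir, seed = NA_integer_) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sess in cohort$sessions) {
    stem <- file.path(dir, sprintf("%s_s%d", sess$subject_id, sess$session))
    write_accel_csv(sess$accel, paste0(stem, "_accel.csv"))
    write_hr_csv(sess$hr, paste0(stem, "_hr.csv"))
    write_schedule_csv(sess$schedule, paste0(stem, "_schedule.csv"))
  }
  manifest <- data.frame(
    subject_id = cohort$profiles$subject_id,
    mass_kg = cohort$profiles$mass,
    hr_min = cohort$profiles$hr_min,
    hr_max = cohort$profiles$hr_max,
    v_ift = cohort$profiles$v_ift,
    seed = seed
  )
  mpath <- file.path(dir, "cohort_manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE, quote = FALSE)
  invisible(mpath)
}

#' Write feature and prediction tables as CSV
#'
#' Canonical interchange files between pipeline stages; fixed column
#' layouts (`subject_id,stage,velocity_kmh,pl_au,avnetforce_N,hr_bpm` and
#' `subject_id,stage,velocity_kmh,predicted_kmh,fold_id,model_tag`).
#'
#' @param table Feature or prediction data frame.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  df <- utils::read.csv(path)
  expected <- c("subject_id", "stage", "velocity_kmh", "pl_au", "avnetforce_N", "hr_bpm")
  if (!identical(names(df), expected)) {
    stop_invalid("feature CSV must have columns %s", paste(expected, collapse = ","))
  }
  df
}

.config_keys <- list(
  top = c("seed", "output_dir", "verbose", "protocol", "cohort", "preprocess", "model"),
  protocol = c("initial_velocity", "increment", "stage_period", "run_duration",
               "recovery_duration", "shuttle_length", "zone_tolerance"),
  cohort = c("n_subjects", "sessions_per_subject", "profiles", "noise"),
  preprocess = c("win_s", "k", "max_masked_frac", "trim_percent"),
  model = c("C", "epsilon", "features", "scale_scope", "estimator")
)

#' Load and validate a run configuration
#'
#' Reads a YAML file with sections `protocol`, `cohort`, `preprocess`,
#' `model` plus `seed`, `output_dir`, `verbose`. Unknown keys are
#' rejected; all component invariants are enforced at load time by
#' constructing the component objects.
#'
#' @param path YAML file path.
#' @return List of class `ift_run_config` with validated components:
#'   `protocol` ([protocol_params()]), `cohort` ([cohort_spec()]),
#'   `preprocess` (window/masking settings), `model` ([svr_config()]),
#'   `seed`, `output_dir`, `verbose`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  as_run_config(raw)
}

#' @rdname read_config
#' @param raw A nested list with the same structure as the YAML file.
#' @export
as_run_config <- function(raw = list()) {
  reject_unknown <- function(x, allowed, where) {
    unknown <- setdiff(names(x), allowed)
    if (length(unknown)) {
      stop_invalid("unknown key(s) in %s: %s", where, paste(unknown, collapse = ", "))
    }
  }
  reject_unknown(raw, .config_keys$top, "config")
  for (sec in c("protocol", "cohort", "preprocess", "model")) {
    if (!is.null(raw[[sec]])) reject_unknown(raw[[sec]], .config_keys[[sec]], sec)
  }
  protocol <- do.call(protocol_params, raw$protocol %||% list())
  cohort_args <- raw$cohort %||% list()
  if (!is.null(cohort_args$profiles)) {
    defaults <- eval(formals(cohort_spec)$profiles)
    given <- lapply(cohort_args$profiles, as.numeric)
    unknown <- setdiff(names(given), names(defaults))
    if (length(unknown)) {
      stop_invalid("unknown profile field(s) in cohort config: %s",
                   paste(unknown, collapse = ", "))
    }
    cohort_args$profiles <- utils::modifyList(defaults, given)
  }
  seed <- as.integer(raw$seed %||% 1L)
  cohort <- do.call(cohort_spec, c(cohort_args, list(seed = seed)))
  pre <- raw$preprocess %||% list()
  preprocess <- list(win_s = pre$win_s %||% 0.5, k = pre$k %||% 6,
                     max_masked_frac = pre$max_masked_frac %||% 0.2,
                     trim_percent = pre$trim_percent %||% 20)
  check_number(preprocess$win_s, "preprocess$win_s", lower = 0, allow_equal_lower = FALSE)
  check_number(preprocess$k, "preprocess$k", lower = 0, allow_equal_lower = FALSE)
  check_number(preprocess$max_masked_frac, "preprocess$max_masked_frac",
               lower = 0, upper = 1)
  check_number(preprocess$trim_percent, "preprocess$trim_percent", lower = 0, upper = 99.999)
  model_args <- raw$model %||% list()
  if (!is.null(model_args$features)) model_args$features <- unlist(model_args$features)
  model <- do.call(svr_config, model_args)
  structure(
    list(protocol = protocol, cohort = cohort, preprocess = preprocess,
         model = model, seed = seed,
         output_dir = raw$output_dir %||% ".",
         verbose = isTRUE(raw$verbose)),
    class = "ift_run_config"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
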