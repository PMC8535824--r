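#' Protocol parameters for the 30-15 Intermittent Fitness Test
#'
#' Constants of the incremental shuttle-run protocol: 30-s shuttle runs over
#' a 40-m course interspersed with 15-s walking recoveries, starting at
#' 8 km/h and increasing by 0.5 km/h every 45-s stage. The 3-m tolerance
#' zones at the ends and middle of the course are carried for the
#' simulator's turn events; within-shuttle position is not modelled.
#'
#' @param initial_velocity Velocity of stage 1, km/h.
#' @param increment Velocity increase per stage, km/h.
#' @param stage_period Total stage duration, s.
#' @param run_duration Run-phase duration, s.
#' @param recovery_duration Walking-recovery duration, s.
#' @param shuttle_length Shuttle course length, m.
#' @param zone_tolerance Pacing-zone tolerance, m.
#' @return An object of class `ift_protocol`: a validated list of the
#'   protocol constants.
#' @export
#' @examples
#' protocol_params()
protocol_params <- function(initial_velocity = 8.0,
                            increment = 0.5,
                            stage_period = 45,
                            run_duration = 30,
                            recovery_duration = 15,
                            shuttle_length = 40,
                            zone_tolerance = 3) {
  check_number(initial_velocity, "initial_velocity", lower = 0, allow_equal_lower = FALSE)
  check_number(increment, "increment", lower = 0)
  check_number(stage_period, "stage_period", lower = 0, allow_equal_lower = FALSE)
  check_number(run_duration, "run_duration", lower = 0, allow_equal_lower = FALSE)
  check_number(recovery_duration, "recovery_duration", lower = 0, allow_equal_lower = FALSE)
  check_number(shuttle_length, "shuttle_length", lower = 0, allow_equal_lower = FALSE)
  check_number(zone_tolerance, "zone_tolerance", lower = 0)
  if (abs(run_duration + recovery_duration - stage_period) > 1e-9) {
    stop_invalid("run_duration (%g) + recovery_duration (%g) must equal stage_period (%g)",
                 run_duration, recovery_duration, stage_period)
  }
  structure(
    list(initial_velocity = initial_velocity, increment = increment,
         stage_period = stage_period, run_duration = run_duration,
         recovery_duration = recovery_duration,
         shuttle_length = shuttle_length, zone_tolerance = zone_tolerance),
    class = "ift_protocol"
  )
}

#' Nominal velocity of a protocol stage
#'
#' @param stage_index 1-based stage number(s).
#' @param params An [protocol_params()] object.
#' @return Stage velocity in km/h: `initial_velocity + increment * (stage_index - 1)`.
#' @export
#' @examples
#' stage_velocity(1)  # 8.0
#' stage_velocity(28) # 21.5
stage_velocity <- function(stage_index, params = protocol_params()) {
  stopifnot(inherits(params, "ift_protocol"))
  if (length(stage_index) == 0L || !is.numeric(stage_index) ||
      any(!is.finite(stage_index)) || any(stage_index < 1) ||
      any(stage_index != floor(stage_index))) {
    stop_invalid("`stage_index` must be positive integers (1-based)")
  }
  params$initial_velocity + params$increment * (stage_index - 1)
}

# Number of stages needed to reach v_ift; errors off-grid / unreachable.
n_stages_for <- function(v_ift, params) {
  if (v_ift < params$initial_velocity - 1e-9) {
    stop_invalid("v_ift = %g km/h is below the initial velocity %g km/h",
                 v_ift, params$initial_velocity)
  }
  if (params$increment == 0) {
    if (abs(v_ift - params$initial_velocity) > 1e-9) {
      stop_invalid("v_ift = %g km/h is unreachable with a zero increment", v_ift)
    }
    return(1L)
  }
  k <- (v_ift - params$initial_velocity) / params$increment
  if (abs(k - round(k)) > 1e-6) {
    stop_invalid("v_ift = %g km/h is not on the %g km/h velocity grid",
                 v_ift, params$increment)
  }
  as.integer(round(k)) + 1L
}

#' Build the time-aligned stage schedule
#'
#' One row per completed stage, from the initial velocity up to and
#' including `v_ift`. Time origin 0 is the start of stage 1's run phase and
#' all intervals are half-open `[start, end)`: stage k occupies
#' `[(k-1) * stage_period, k * stage_period)` with the run phase first.
#'
#' @param v_ift Final test velocity (velocity of the last completed stage),
#'   km/h; must be reachable from the initial velocity in whole increments.
#' @param params An [protocol_params()] object.
#' @return A data frame of class `ift_schedule` with columns `stage`,
#'   `velocity_kmh`, `run_start_s`, `run_end_s`, `recovery_end_s`, and the
#'   protocol parameters in attribute `"params"`.
#' @export
#' @examples
#' build_schedule(8.5) # two stages, 90 s total
build_schedule <- function(v_ift, params = protocol_params()) {
  stopifnot(inherits(params, "ift_protocol"))
  check_number(v_ift, "v_ift", lower = 0)
  n <- n_stages_for(v_ift, params)
  stage <- seq_len(n)
  sched <- data.frame(
    stage = stage,
    velocity_kmh = stage_velocity(stage, params),
    run_start_s = (stage - 1) * params$stage_period,
    run_end_s = (stage - 1) * params$stage_period + params$run_duration,
    recovery_end_s = stage * params$stage_period
  )
  attr(sched, "params") <- params
  class(sched) <- c("ift_schedule", "data.frame")
  sched
}

schedule_duration <- function(schedule) {
  max(schedule$recovery_end_s)
}

#' Write / read a stage schedule as CSV
#'
#' @param schedule An [build_schedule()] data frame.
#' @param path File path.
#' @return `read_schedule_csv` returns the schedule data frame;
#'   `write_schedule_csv` returns `path` invisibly.
#' @export
write_schedule_csv <- function(schedule, path) {
  stopifnot(inherits(schedule, "ift_schedule"))
  utils::write.csv(as.data.frame(schedule), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_schedule_csv
#' @export
read_schedule_csv <- function(path) {
  df <- utils::read.csv(path)
  expected <- c("stage", "velocity_kmh", "run_start_s", "run_end_s", "recovery_end_s")
  if (!identical(names(df), expected)) {
    stop_invalid("schedule CSV must have columns %s", paste(expected, collapse = ","))
  }
  class(df) <- c("ift_schedule", "data.frame")
  df
}
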