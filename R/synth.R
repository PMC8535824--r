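# Synthetic cohort generator: protocol-faithful tri-axial accelerometer
# traces (100 Hz) and heart-rate traces (1 Hz) with the between-subject
# statistical structure the downstream analysis assumes.

#' Tri-axial accelerometer trace
#'
#' @param x,y,z Per-axis acceleration in g (gravity included in the raw
#'   signal), equal lengths, finite.
#' @param sampling_rate Samples per second.
#' @param start_time Session-clock time of the first sample, s.
#' @return Data frame of class `accel_trace` with columns
#'   `time_s,x_g,y_g,z_g` and attributes `sampling_rate`, `start_time`.
#' @export
accel_trace <- function(x, y, z, sampling_rate = 100, start_time = 0) {
  check_number(sampling_rate, "sampling_rate", lower = 0, allow_equal_lower = FALSE)
  n <- length(x)
  if (length(y) != n || length(z) != n) {
    stop_invalid("accelerometer axes must have equal lengths")
  }
  if (n == 0L) stop_invalid("accelerometer trace must be non-empty")
  if (any(!is.finite(x)) || any(!is.finite(y)) || any(!is.finite(z))) {
    stop_invalid("accelerometer samples must be finite")
  }
  out <- data.frame(
    time_s = start_time + (seq_len(n) - 1) / sampling_rate,
    x_g = as.numeric(x), y_g = as.numeric(y), z_g = as.numeric(z)
  )
  attr(out, "sampling_rate") <- sampling_rate
  attr(out, "start_time") <- start_time
  class(out) <- c("accel_trace", "data.frame")
  out
}

#' Heart-rate trace at 1 Hz
#'
#' @param hr_bpm Heart-rate samples, beats per minute, within \[20, 250\].
#' @param start_time Session-clock time of the first sample, s.
#' @param sampling_rate Samples per second (1 for the supported monitors).
#' @return Data frame of class `hr_trace` with columns `time_s,hr_bpm`.
#' @export
hr_trace <- function(hr_bpm, start_time = 0, sampling_rate = 1) {
  if (length(hr_bpm) == 0L) stop_invalid("heart-rate trace must be non-empty")
  if (any(!is.finite(hr_bpm)) || any(hr_bpm < 20) || any(hr_bpm > 250)) {
    stop_invalid("heart-rate samples must be finite and within [20, 250] bpm")
  }
  out <- data.frame(
    time_s = start_time + (seq_along(hr_bpm) - 1) / sampling_rate,
    hr_bpm = as.numeric(hr_bpm)
  )
  attr(out, "sampling_rate") <- sampling_rate
  attr(out, "start_time") <- start_time
  class(out) <- c("hr_trace", "data.frame")
  out
}

# Truncation bounds for drawn profile fields (plausibility bands from the
# cohort descriptives; draws are clamped, not resampled).
.profile_bounds <- list(
  mass = c(48.4, 94), hr_min = c(49, 79), hr_max = c(181, 209),
  v_ift = c(18.5, 21.5), force_slope = c(40, Inf), bounce = c(0, 1.2),
  hr_slope = c(0.5, Inf), hr_tau = c(8, 90),
  step_freq_base = c(1.5, 3.5), pl_noise_scale = c(0.2, Inf)
)

# Reference mid-test velocity (km/h) anchoring the resting-HR /
# response-slope coupling: athletes in a homogeneous trained cohort run at
# comparable relative intensity at this speed, so their HR levels there
# differ far less than their resting HRs do.
.hr_level_ref_kmh <- 14

#' Cohort specification for the synthetic generator
#'
#' Defaults are calibrated to the published cohort: 21 semi-professional
#' soccer players; body mass 71.93 +/- 11.14 kg; resting and maximal HR
#' 59.8 +/- 8.53 and 197.07 +/- 8.39 bpm; final test velocity
#' 19.78 +/- 0.94 km/h; per-subject slope of window Average Net Force vs
#' velocity 132.46 +/- 18.87 N per km/h; per-subject slope of window-mean
#' HR vs velocity with mean 3.92 bpm per km/h. The between-subject SD of
#' the HR response draw (0.6 by default) and the gait "bounce" (dynamic
#' amplitude at low speed, 0.4 +/- 0.35 g) are the package's own
#' calibration of between-subject heterogeneity: they reproduce the
#' published correlation ladder (HR the strongest single predictor, then
#' Average Net Force, then Player Load) — see the methods vignette for why
#' the published HR slope SD cannot be used directly under this HR model.
#' The realized HR slope couples negatively to resting HR so that HR
#' levels at a mid-test reference velocity are comparable across athletes.
#' `force_slope` and `hr_slope` are drawn per subject and stored on the
#' profile as `accel_slope` (= force_slope / mass, m s^-2 per km/h) and
#' `hr_slope`; `hr_slope` and `pl_noise_scale` use lognormal draws with
#' the stated arithmetic mean and SD, the other fields clamped normal
#' draws.
#'
#' @param n_subjects Number of subjects (LOSO needs at least 2).
#' @param seed Integer seed; all cohort randomness derives from it through
#'   per-subject substreams, so adding a subject does not perturb others.
#' @param sessions_per_subject Test sessions simulated per subject.
#' @param profiles Named list of `c(mean, sd)` pairs for the drawn fields:
#'   `mass`, `hr_min`, `hr_max`, `v_ift`, `force_slope`, `bounce`,
#'   `hr_slope`, `hr_tau`, `step_freq_base`, `pl_noise_scale`.
#' @param noise List of noise settings: `axis_sd` (accelerometer white
#'   noise per axis, g; scaled per subject by `pl_noise_scale`), `hr_sd`
#'   (HR observation noise, bpm), `window_jitter_sd` (lognormal SD of the
#'   per-run-window dynamic-amplitude jitter), `hr_drift_sd` and
#'   `hr_drift_tau` (slow autonomic HR drift: stationary SD in bpm and
#'   correlation time in s). Setting all SDs to 0 gives noise-free
#'   sessions.
#' @return An object of class `ift_cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 21,
                        seed = 1L,
                        sessions_per_subject = 1,
                        profiles = list(
                          mass = c(71.93, 11.14),
                          hr_min = c(59.8, 8.53),
                          hr_max = c(197.07, 8.39),
                          v_ift = c(19.78, 0.94),
                          force_slope = c(132.46, 18.87),
                          bounce = c(0.4, 0.3),
                          hr_slope = c(3.92, 0.7),
                          hr_tau = c(30, 5),
                          step_freq_base = c(2.6, 0.15),
                          pl_noise_scale = c(1, 0.25)
                        ),
                        noise = list(axis_sd = 0.05, hr_sd = 2,
                                     window_jitter_sd = 0.05,
                                     hr_drift_sd = 2, hr_drift_tau = 60)) {
  if (!is.numeric(n_subjects) || n_subjects < 2) {
    stop_invalid("`n_subjects` must be at least 2 (LOSO needs >= 2 subjects)")
  }
  needed <- c("mass", "hr_min", "hr_max", "v_ift", "force_slope", "bounce",
              "hr_slope", "hr_tau", "step_freq_base", "pl_noise_scale")
  missing <- setdiff(needed, names(profiles))
  if (length(missing)) {
    stop_invalid("`profiles` is missing fields: %s", paste(missing, collapse = ", "))
  }
  for (nm in needed) {
    p <- profiles[[nm]]
    if (!is.numeric(p) || length(p) != 2L || p[2] < 0) {
      stop_invalid("`profiles$%s` must be c(mean, sd) with sd >= 0", nm)
    }
  }
  noise_defaults <- list(axis_sd = 0.05, hr_sd = 2, window_jitter_sd = 0.05,
                         hr_drift_sd = 2, hr_drift_tau = 60)
  unknown_noise <- setdiff(names(noise), names(noise_defaults))
  if (length(unknown_noise)) {
    stop_invalid("unknown noise setting(s): %s", paste(unknown_noise, collapse = ", "))
  }
  noise <- utils::modifyList(noise_defaults, noise)
  for (nm in c("axis_sd", "hr_sd", "window_jitter_sd", "hr_drift_sd")) {
    check_number(noise[[nm]], paste0("noise$", nm), lower = 0)
  }
  check_number(noise$hr_drift_tau, "noise$hr_drift_tau", lower = 0,
               allow_equal_lower = FALSE)
  check_number(sessions_per_subject, "sessions_per_subject", lower = 1)
  structure(
    list(n_subjects = as.integer(n_subjects), seed = as.integer(seed),
         sessions_per_subject = as.integer(sessions_per_subject),
         profiles = profiles[needed], noise = noise),
    class = "ift_cohort_spec"
  )
}

draw_clamped_normal <- function(mean, sd, bounds) {
  if (sd == 0) return(mean)
  clamp(stats::rnorm(1, mean, sd), bounds[1], bounds[2])
}

draw_lognormal <- function(mean, sd, bounds = c(0, Inf)) {
  if (sd == 0) return(mean)
  p <- lognormal_pars(mean, sd)
  clamp(stats::rlnorm(1, p$meanlog, p$sdlog), bounds[1], bounds[2])
}

#' Draw a synthetic cohort of subject profiles
#'
#' Deterministic for a given `spec$seed`. Each subject is drawn from an
#' independent substream, so cohorts of different sizes share their common
#' subjects.
#'
#' @param spec A [cohort_spec()].
#' @param params Protocol parameters; the drawn final velocity is snapped
#'   to the protocol's velocity grid.
#' @return Data frame with one row per subject: `subject_id`, `mass`,
#'   `hr_min`, `hr_max`, `v_ift`, `accel_slope` (m s^-2 per km/h),
#'   `pl_noise_scale`, `hr_slope` (bpm per km/h), `hr_tau` (s),
#'   `step_freq_base` (Hz).
#' @export
draw_cohort <- function(spec = cohort_spec(), params = protocol_params()) {
  stopifnot(inherits(spec, "ift_cohort_spec"))
  pr <- spec$profiles
  rows <- lapply(seq_len(spec$n_subjects), function(i) {
    set.seed(derive_seed(spec$seed, i))
    mass <- draw_clamped_normal(pr$mass[1], pr$mass[2], .profile_bounds$mass)
    hr_min <- draw_clamped_normal(pr$hr_min[1], pr$hr_min[2], .profile_bounds$hr_min)
    hr_max <- draw_clamped_normal(pr$hr_max[1], pr$hr_max[2], .profile_bounds$hr_max)
    v_raw <- draw_clamped_normal(pr$v_ift[1], pr$v_ift[2], .profile_bounds$v_ift)
    v_ift <- params$initial_velocity + params$increment *
      max(0, round((v_raw - params$initial_velocity) / max(params$increment, 1e-12)))
    force_slope <- draw_clamped_normal(pr$force_slope[1], pr$force_slope[2],
                                       .profile_bounds$force_slope)
    bounce <- draw_clamped_normal(pr$bounce[1], pr$bounce[2], .profile_bounds$bounce)
    # base cardiovascular response drawn lognormal; the realized slope is
    # shifted so that HR at the reference velocity is independent of the
    # subject's resting HR (fit athletes: lower rest HR, steeper rise)
    hr_base <- draw_lognormal(pr$hr_slope[1], pr$hr_slope[2])
    hr_slope <- clamp(hr_base - (hr_min - pr$hr_min[1]) / .hr_level_ref_kmh,
                      .profile_bounds$hr_slope[1], .profile_bounds$hr_slope[2])
    hr_tau <- draw_clamped_normal(pr$hr_tau[1], pr$hr_tau[2], .profile_bounds$hr_tau)
    step_freq_base <- draw_clamped_normal(pr$step_freq_base[1], pr$step_freq_base[2],
                                          .profile_bounds$step_freq_base)
    pl_noise_scale <- draw_lognormal(pr$pl_noise_scale[1], pr$pl_noise_scale[2],
                                     .profile_bounds$pl_noise_scale)
    data.frame(
      subject_id = sprintf("S%02d", i), mass = mass, hr_min = hr_min,
      hr_max = hr_max, v_ift = v_ift, accel_slope = force_slope / mass,
      bounce_g = bounce, pl_noise_scale = pl_noise_scale, hr_slope = hr_slope,
      hr_tau = hr_tau, step_freq_base = step_freq_base
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Per-sample velocity state over a schedule. Returns velocity (km/h, the
# walking velocity during recoveries), and a run-phase flag.
velocity_state <- function(times, schedule, walk_velocity) {
  v <- rep(walk_velocity, length(times))
  run <- rep(FALSE, length(times))
  for (k in seq_len(nrow(schedule))) {
    in_run <- times >= schedule$run_start_s[k] & times < schedule$run_end_s[k]
    v[in_run] <- schedule$velocity_kmh[k]
    run[in_run] <- TRUE
  }
  list(velocity = v, run = run)
}

#' Simulate a tri-axial accelerometer trace over a test
#'
#' The raw signal is synthesised in magnitude/direction form: total
#' acceleration magnitude `1 + m(t)` g (gravity plus locomotor dynamics)
#' along a slowly wobbling unit direction, plus per-axis white noise. The
#' dynamic component during a stage run at velocity v is
#' `a_g * v * (1 - cos(step phase))` with `a_g = accel_slope / 9.80665`, so
#' the window-mean vector magnitude rises linearly with stage velocity at
#' exactly the subject's configured slope. Change-of-direction transients
#' are injected as 0.4-s half-sine pulses (amplitude proportional to
#' velocity) at shuttle-turn times `shuttle_length / v` apart. Recoveries
#' carry a low-amplitude walking signal.
#'
#' @param profile One-row data frame (or list) with the [draw_cohort()]
#'   fields.
#' @param schedule An [build_schedule()] schedule.
#' @param seed Integer seed for the noise stream.
#' @param sampling_rate Hz.
#' @param noise_sd White-noise SD per axis in g, before the subject's
#'   `pl_noise_scale` multiplier.
#' @param window_jitter_sd Lognormal SD of a per-run-window multiplicative
#'   jitter on the dynamic amplitude (stride-to-stride and pacing
#'   variability between windows); 0 disables it.
#' @param walk_velocity Recovery walking velocity, km/h.
#' @param turn_coef Turn-pulse amplitude per unit velocity, g per km/h.
#' @param step_freq_vel_slope Step-frequency increase per km/h above the
#'   initial test velocity, Hz.
#' @param wobble Amplitude of the direction wobble (dimensionless).
#' @param artifacts Optional data frame `start_s,duration_s,amplitude_g` of
#'   high-frequency artifact bursts to inject (25-Hz tone on all axes).
#' @return An [accel_trace()].
#' @export
simulate_accel <- function(profile, schedule, seed = 1L,
                           sampling_rate = 100, noise_sd = 0.05,
                           window_jitter_sd = 0.05,
                           walk_velocity = 5, turn_coef = 0.05,
                           step_freq_vel_slope = 0.04, wobble = 0.2,
                           artifacts = NULL) {
  if (nrow(schedule) == 0L) stop_invalid("schedule must be non-empty")
  profile <- as.list(profile)
  params <- attr(schedule, "params")
  v0 <- if (!is.null(params)) params$initial_velocity else min(schedule$velocity_kmh)
  total <- schedule_duration(schedule)
  n <- round(total * sampling_rate)
  t <- (seq_len(n) - 1) / sampling_rate

  st <- velocity_state(t, schedule, walk_velocity)
  a_g <- profile$accel_slope / 9.80665
  bounce <- if (is.null(profile$bounce_g)) 0 else profile$bounce_g

  freq <- ifelse(st$run,
                 profile$step_freq_base + step_freq_vel_slope * (st$velocity - v0),
                 1.8)
  phase <- cumsum(2 * pi * freq / sampling_rate)

  set.seed(seed)
  # dynamic oscillation amplitude: subject bounce + velocity-proportional
  # term, jittered per run window (walking recovery carries damped bounce)
  amp <- bounce + a_g * st$velocity
  amp[!st$run] <- 0.3 * bounce + a_g * walk_velocity
  if (window_jitter_sd > 0) {
    jp <- lognormal_pars(1, window_jitter_sd)
    jit <- stats::rlnorm(nrow(schedule), jp$meanlog, jp$sdlog)
    for (k in seq_len(nrow(schedule))) {
      in_run <- t >= schedule$run_start_s[k] & t < schedule$run_end_s[k]
      amp[in_run] <- amp[in_run] * jit[k]
    }
  }
  m <- amp * (1 - cos(phase))

  # shuttle-turn transients during run phases
  turn <- numeric(n)
  pulse_w <- 0.4
  for (k in seq_len(nrow(schedule))) {
    v <- schedule$velocity_kmh[k]
    interval <- (if (!is.null(params)) params$shuttle_length else 40) / (v / 3.6)
    t0s <- schedule$run_start_s[k] + interval * seq_len(
      max(0, floor((schedule$run_end_s[k] - schedule$run_start_s[k]) / interval))
    )
    t0s <- t0s[t0s + pulse_w <= schedule$run_end_s[k]]
    for (t0 in t0s) {
      idx <- which(t >= t0 & t < t0 + pulse_w)
      # braking then re-acceleration: zero-net-area couplet, so turns do
      # not bias the window-mean magnitude
      turn[idx] <- turn[idx] + turn_coef * v * sin(2 * pi * (t[idx] - t0) / pulse_w)
    }
  }

  magnitude <- pmax(1 + m + turn, 0)
  ux <- wobble * sin(phase / 2)
  uy <- wobble * cos(phase / 2 + 0.7)
  uz <- sqrt(pmax(0, 1 - ux^2 - uy^2))

  sd_eff <- noise_sd * profile$pl_noise_scale
  x <- magnitude * ux + stats::rnorm(n, 0, sd_eff)
  y <- magnitude * uy + stats::rnorm(n, 0, sd_eff)
  z <- magnitude * uz + stats::rnorm(n, 0, sd_eff)

  if (!is.null(artifacts) && nrow(artifacts)) {
    for (j in seq_len(nrow(artifacts))) {
      idx <- which(t >= artifacts$start_s[j] &
                   t < artifacts$start_s[j] + artifacts$duration_s[j])
      tone <- artifacts$amplitude_g[j] * sin(2 * pi * 25 * t[idx])
      x[idx] <- x[idx] + tone
      y[idx] <- y[idx] + tone
      z[idx] <- z[idx] + tone
    }
  }

  accel_trace(x, y, z, sampling_rate = sampling_rate, start_time = 0)
}

#' Simulate a heart-rate trace over a test
#'
#' First-order on/off kinetics `dHR/dt = (HRss(t) - HR) / hr_tau`,
#' integrated exactly on the 1-s grid (piecewise-constant drive). During a
#' stage run at velocity v the steady state is
#' `HRss = hr_min + hr_slope * v`; during the 15-s walking recovery after
#' that stage HR relaxes toward the elevated post-exercise level
#' `hr_min + hr_slope * (v - recovery_drop)` — a brief walk pulls HR down
#' relative to the preceding effort, not to a walking steady state. Both
#' levels are clipped to `[hr_min, hr_max]`. Unless `start_hr` is given,
#' HR starts at the fixed point of the per-stage map — the state a
#' warmed-up subject entering stage 1 would carry — which makes
#' window-mean HR exactly linear in stage velocity whenever the clip does
#' not bind. Gaussian observation noise is added and the observed series
#' clipped to `[20, hr_max]`.
#'
#' @inheritParams simulate_accel
#' @param noise_sd Observation-noise SD, bpm.
#' @param drift_sd,drift_tau Slow autonomic drift added to the latent HR:
#'   a stationary first-order autoregressive process with SD `drift_sd`
#'   bpm and correlation time `drift_tau` s; `drift_sd = 0` disables it.
#' @param recovery_drop Velocity-equivalent drop of the recovery-phase
#'   steady state below the preceding stage velocity, km/h.
#' @param start_hr Optional initial HR, bpm; default is the stage-map fixed
#'   point.
#' @return An [hr_trace()] at 1 Hz.
#' @export
simulate_hr <- function(profile, schedule, seed = 1L, noise_sd = 2,
                        drift_sd = 2, drift_tau = 60,
                        recovery_drop = 3, start_hr = NULL) {
  if (nrow(schedule) == 0L) stop_invalid("schedule must be non-empty")
  profile <- as.list(profile)
  params <- attr(schedule, "params")
  total <- schedule_duration(schedule)
  n <- as.integer(ceiling(total))
  secs <- seq_len(n) - 1

  # per-second drive velocity: stage velocity in runs, stage velocity minus
  # recovery_drop in the following recovery
  v_drive <- numeric(n)
  for (k in seq_len(nrow(schedule))) {
    in_run <- secs >= schedule$run_start_s[k] & secs < schedule$run_end_s[k]
    in_rec <- secs >= schedule$run_end_s[k] & secs < schedule$recovery_end_s[k]
    v_drive[in_run] <- schedule$velocity_kmh[k]
    v_drive[in_rec] <- schedule$velocity_kmh[k] - recovery_drop
  }
  ss <- clamp(profile$hr_min + profile$hr_slope * v_drive,
              profile$hr_min, profile$hr_max)

  tau <- profile$hr_tau
  alpha <- exp(-1 / tau)

  if (is.null(start_hr)) {
    run_d <- if (!is.null(params)) params$run_duration else 30
    rec_d <- if (!is.null(params)) params$recovery_duration else 15
    inc <- if (!is.null(params)) params$increment else 0.5
    a <- alpha^run_d
    b <- alpha^rec_d
    v1 <- schedule$velocity_kmh[1]
    s_run <- clamp(profile$hr_min + profile$hr_slope * v1,
                   profile$hr_min, profile$hr_max)
    s_rec <- clamp(profile$hr_min + profile$hr_slope * (v1 - recovery_drop),
                   profile$hr_min, profile$hr_max)
    delta <- profile$hr_slope * inc
    h0 <- (s_rec * (1 - b) + b * s_run * (1 - a) - delta) / (1 - a * b)
    start_hr <- clamp(h0, profile$hr_min, profile$hr_max)
  }

  h <- numeric(n)
  h[1] <- clamp(start_hr, profile$hr_min, profile$hr_max)
  for (s in seq_len(n - 1)) {
    h[s + 1] <- ss[s] + (h[s] - ss[s]) * alpha
  }
  h <- clamp(h, profile$hr_min, profile$hr_max)

  set.seed(seed)
  if (drift_sd > 0) {
    phi <- exp(-1 / drift_tau)
    eps <- stats::rnorm(n, 0, drift_sd * sqrt(1 - phi^2))
    drift <- as.numeric(stats::filter(eps, phi, method = "recursive",
                                      init = stats::rnorm(1, 0, drift_sd)))
    h <- h + drift
  }
  obs <- clamp(h + stats::rnorm(n, 0, noise_sd), 20, profile$hr_max)
  hr_trace(obs, start_time = 0, sampling_rate = 1)
}

#' Simulate one full test session for a subject
#'
#' Builds the stage schedule from the subject's final velocity and
#' simulates the aligned accelerometer and heart-rate traces on a shared
#' session clock.
#'
#' @param profile One [draw_cohort()] row.
#' @param params Protocol parameters.
#' @param seed Integer seed; accelerometer and HR noise use derived
#'   substreams.
#' @param noise Noise settings (see [cohort_spec()]); missing entries take
#'   the defaults there.
#' @param ... Passed to [simulate_accel()] (e.g. `artifacts`, `turn_coef`).
#' @return List with elements `accel`, `hr`, `schedule`.
#' @export
simulate_session <- function(profile, params = protocol_params(), seed = 1L,
                             noise = list(), ...) {
  profile <- as.list(profile)
  noise <- utils::modifyList(
    list(axis_sd = 0.05, hr_sd = 2, window_jitter_sd = 0.05,
         hr_drift_sd = 2, hr_drift_tau = 60), noise)
  schedule <- build_schedule(profile$v_ift, params)
  accel <- simulate_accel(profile, schedule, seed = derive_seed(seed, 1),
                          noise_sd = noise$axis_sd,
                          window_jitter_sd = noise$window_jitter_sd, ...)
  hr <- simulate_hr(profile, schedule, seed = derive_seed(seed, 2),
                    noise_sd = noise$hr_sd, drift_sd = noise$hr_drift_sd,
                    drift_tau = noise$hr_drift_tau)
  list(accel = accel, hr = hr, schedule = schedule)
}

#' Simulate a full synthetic cohort
#'
#' @param spec A [cohort_spec()].
#' @param params Protocol parameters.
#' @param ... Passed to [simulate_session()] / [simulate_accel()].
#' @return List with `profiles` (the [draw_cohort()] data frame) and
#'   `sessions`, a list of per-session lists `subject_id`, `session`,
#'   `accel`, `hr`, `schedule`.
#' @export
simulate_cohort <- function(spec = cohort_spec(), params = protocol_params(), ...) {
  stopifnot(inherits(spec, "ift_cohort_spec"))
  profiles <- draw_cohort(spec, params)
  sessions <- list()
  for (i in seq_len(nrow(profiles))) {
    subj_seed <- derive_seed(spec$seed, 100000 + i)
    for (s in seq_len(spec$sessions_per_subject)) {
      sess <- simulate_session(profiles[i, ], params,
                               seed = derive_seed(subj_seed, s),
                               noise = spec$noise, ...)
      sessions[[length(sessions) + 1L]] <- c(
        list(subject_id = profiles$subject_id[i], session = s), sess
      )
    }
  }
  list(profiles = profiles, sessions = sessions)
}
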