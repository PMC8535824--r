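# Shared fixtures: hand-built subject profiles and small cohort specs so
# unit tests stay fast; full-scale defaults are exercised in
# test-acceptance.R only.

make_profile <- function(subject_id = "S01", mass = 70, hr_min = 60,
                         hr_max = 195, v_ift = 9.5, accel_slope = 1.8,
                         bounce_g = 0.4, pl_noise_scale = 1, hr_slope = 3.9,
                         hr_tau = 30, step_freq_base = 2.6) {
  list(subject_id = subject_id, mass = mass, hr_min = hr_min,
       hr_max = hr_max, v_ift = v_ift, accel_slope = accel_slope,
       bounce_g = bounce_g, pl_noise_scale = pl_noise_scale,
       hr_slope = hr_slope, hr_tau = hr_tau, step_freq_base = step_freq_base)
}

# cohort spec with every profile SD forced to zero (all subjects equal the
# mean profile)
zero_sd_spec <- function(spec) {
  spec$profiles <- lapply(spec$profiles, function(p) c(p[1], 0))
  spec
}

# noise-free variant of a spec
noise_free_spec <- function(spec) {
  spec$noise <- list(axis_sd = 0, hr_sd = 0, window_jitter_sd = 0,
                     hr_drift_sd = 0, hr_drift_tau = 60)
  spec
}

# small fast cohort: few subjects, short test
small_cohort_spec <- function(n_subjects = 3, seed = 1, v_ift = 10, ...) {
  spec <- cohort_spec(n_subjects = n_subjects, seed = seed, ...)
  spec$profiles$v_ift <- c(v_ift, 0)
  spec
}

# a window object built directly from axis samples (no simulation)
make_window <- function(x, y, z, hr = rep(150, 30), mask = NULL,
                        velocity = 10, stage = 1L, subject_id = "S01",
                        valid = TRUE) {
  if (is.null(mask)) mask <- rep(FALSE, length(x))
  structure(
    list(subject_id = subject_id, stage = stage, velocity = velocity,
         accel = data.frame(x_g = x, y_g = y, z_g = z),
         mask = mask, hr = hr, masked_frac = mean(mask), valid = valid),
    class = "ift_window"
  )
}
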