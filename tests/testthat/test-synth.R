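test_that("cohort draws are seeded, reproducible and subject-stable", {
  spec <- cohort_spec(n_subjects = 5, seed = 42)
  c1 <- draw_cohort(spec)
  c2 <- draw_cohort(spec)
  expect_identical(c1, c2)

  # adding subjects does not perturb existing ones
  spec7 <- cohort_spec(n_subjects = 7, seed = 42)
  c3 <- draw_cohort(spec7)
  expect_identical(c3[1:5, ], c1)

  spec_b <- cohort_spec(n_subjects = 5, seed = 43)
  expect_false(identical(draw_cohort(spec_b), c1))
})

test_that("zero-SD spec yields identical mean-profile subjects", {
  spec <- zero_sd_spec(cohort_spec(n_subjects = 4, seed = 1))
  co <- draw_cohort(spec)
  expect_equal(co$mass, rep(71.93, 4))
  expect_equal(co$hr_slope, rep(3.92, 4))
  expect_equal(co$accel_slope * co$mass, rep(132.46, 4))
  expect_equal(co$v_ift, rep(20, 4)) # 19.78 snapped to the 0.5 km/h grid
  expect_equal(length(unique(co$bounce_g)), 1L)
})

test_that("large-cohort slope draws average to the configured means", {
  co <- draw_cohort(cohort_spec(n_subjects = 1000, seed = 3))
  se_hr <- sd(co$hr_slope) / sqrt(nrow(co))
  expect_lt(abs(mean(co$hr_slope) - 3.92), 3 * se_hr)
  force_slopes <- co$accel_slope * co$mass
  se_f <- sd(force_slopes) / sqrt(nrow(co))
  expect_lt(abs(mean(force_slopes) - 132.46), 3 * se_f)
  expect_true(all(co$hr_min < co$hr_max))
  expect_true(all(co$v_ift >= 18.5 & co$v_ift <= 21.5))
})

test_that("invalid cohort specs are rejected", {
  expect_error(cohort_spec(n_subjects = 1), "at least 2")
  expect_error(cohort_spec(noise = list(axis_sd = -1)), "axis_sd")
  expect_error(cohort_spec(noise = list(volume = 11)), "unknown noise")
  expect_error(cohort_spec(profiles = list(mass = c(70, 10))), "missing fields")
})

test_that("accelerometer simulation is seeded and protocol-aligned", {
  prof <- make_profile()
  sch <- build_schedule(9)
  a1 <- simulate_accel(prof, sch, seed = 9)
  a2 <- simulate_accel(prof, sch, seed = 9)
  expect_identical(a1, a2)
  expect_false(identical(a1, simulate_accel(prof, sch, seed = 10)))
  expect_equal(nrow(a1), 3 * 45 * 100)
})

test_that("gravity-only signal gives unit VMU in recovery phases", {
  # no dynamics, no bounce, no noise: walking recovery carries no turns,
  # so the magnitude there is exactly 1 g
  prof <- make_profile(accel_slope = 0, bounce_g = 0)
  sch <- build_schedule(8.5)
  acc <- simulate_accel(prof, sch, seed = 1, noise_sd = 0, window_jitter_sd = 0)
  rec <- acc$time_s >= 30 & acc$time_s < 45
  v <- vmu(acc$x_g[rec], acc$y_g[rec], acc$z_g[rec])
  expect_equal(v, rep(1, sum(rec)), tolerance = 1e-12)
})

test_that("window-mean VMU is non-decreasing in stage velocity when noise-free", {
  prof <- make_profile(v_ift = 12)
  sch <- build_schedule(12)
  acc <- simulate_accel(prof, sch, seed = 2, noise_sd = 0, window_jitter_sd = 0)
  v <- vmu(acc$x_g, acc$y_g, acc$z_g)
  wm <- sapply(seq_len(nrow(sch)), function(k) {
    idx <- acc$time_s >= sch$run_start_s[k] & acc$time_s < sch$run_end_s[k]
    mean(v[idx])
  })
  expect_true(all(diff(wm) > 0))
})

test_that("HR equals the clipped steady state in the fast-kinetics limit", {
  prof <- make_profile(hr_tau = 1e-9, hr_min = 60, hr_max = 120, hr_slope = 4)
  sch <- build_schedule(10)
  hr <- simulate_hr(prof, sch, seed = 1, noise_sd = 0, drift_sd = 0)
  for (k in seq_len(nrow(sch))) {
    # drop the first run second: it integrates the preceding input
    in_run <- hr$time_s > sch$run_start_s[k] & hr$time_s < sch$run_end_s[k]
    expected <- min(max(60 + 4 * sch$velocity_kmh[k], 60), 120)
    expect_equal(hr$hr_bpm[in_run], rep(expected, sum(in_run)), tolerance = 1e-6)
  }
})

test_that("HR converges to steady state within 1% after five time constants", {
  # single long run phase at constant velocity, starting from rest
  params <- protocol_params(run_duration = 300, recovery_duration = 15,
                            stage_period = 315)
  prof <- make_profile(hr_tau = 30, hr_min = 60, hr_max = 195, hr_slope = 5)
  sch <- build_schedule(8, params)
  hr <- simulate_hr(prof, sch, seed = 1, noise_sd = 0, drift_sd = 0,
                    start_hr = 60)
  ss <- 60 + 5 * 8
  at5tau <- hr$hr_bpm[hr$time_s == 150]
  expect_lt(abs(at5tau - ss) / ss, 0.01)
  expect_gt(abs(hr$hr_bpm[hr$time_s == 10] - ss) / ss, 0.01) # not converged early
})

test_that("simulated HR never exceeds the subject maximum and dips in recovery", {
  spec <- cohort_spec(n_subjects = 4, seed = 6)
  cohort <- simulate_cohort(spec)
  for (i in seq_along(cohort$sessions)) {
    sess <- cohort$sessions[[i]]
    prof <- cohort$profiles[cohort$profiles$subject_id == sess$subject_id, ]
    expect_lte(max(sess$hr$hr_bpm), prof$hr_max)
    expect_gte(min(sess$hr$hr_bpm), 20)
  }
  # recovery dip: late-recovery HR below the preceding late-run HR
  sess <- cohort$sessions[[1]]
  sch <- sess$schedule
  k <- nrow(sch) - 1
  late_run <- mean(sess$hr$hr_bpm[sess$hr$time_s >= sch$run_end_s[k] - 5 &
                                  sess$hr$time_s < sch$run_end_s[k]])
  late_rec <- mean(sess$hr$hr_bpm[sess$hr$time_s >= sch$recovery_end_s[k] - 3 &
                                  sess$hr$time_s < sch$recovery_end_s[k]])
  expect_lt(late_rec, late_run)
})

test_that("sessions share one clock and are deterministic end to end", {
  prof <- make_profile(v_ift = 8)
  s1 <- simulate_session(prof, seed = 4)
  s2 <- simulate_session(prof, seed = 4)
  expect_identical(s1, s2)
  expect_equal(nrow(s1$accel), 4500) # 45 s at 100 Hz
  expect_equal(nrow(s1$hr), 45)
  expect_equal(s1$accel$time_s[1], s1$hr$time_s[1])
})

test_that("per-subject slopes are recovered from simulated windows", {
  # mean-profile cohort: recovery at default noise well inside 15% / 10%
  spec <- zero_sd_spec(cohort_spec(n_subjects = 3, seed = 12))
  f <- cohort_features(simulate_cohort(spec))
  anf <- subject_fits(f, "avnetforce_N")
  hr <- subject_fits(f, "hr_bpm")
  expect_true(all(abs(anf$per_subject$beta - 132.46) / 132.46 < 0.15))
  expect_true(all(abs(hr$per_subject$beta - 3.92) / 3.92 < 0.10))
})

test_that("heterogeneous-cohort recovered slopes track the configured ones", {
  spec <- cohort_spec(n_subjects = 8, seed = 21)
  cohort <- simulate_cohort(spec)
  f <- cohort_features(cohort)
  anf <- subject_fits(f, "avnetforce_N")
  conf <- cohort$profiles$accel_slope * cohort$profiles$mass
  fitted <- anf$per_subject$beta[match(cohort$profiles$subject_id,
                                       anf$per_subject$subject_id)]
  expect_gt(pearson_r(conf, fitted), 0.9)
  expect_lt(abs(coef(lm(fitted ~ conf))[2] - 1), 0.15)
})

test_that("between-subject spread of velocity-HR correlations stays low", {
  spec <- cohort_spec(n_subjects = 21, seed = 8)
  f <- cohort_features(simulate_cohort(spec))
  fits <- subject_fits(f, "hr_bpm")
  expect_lte(fits$sd_r, 0.15)
})
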