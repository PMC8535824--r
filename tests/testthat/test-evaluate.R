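test_that("pearson_r matches closed forms and the base oracle", {
  a <- 1:5
  expect_equal(pearson_r(a, a * 2 + 1), 1)
  expect_equal(pearson_r(a, -a + 10), -1)
  expect_equal(pearson_r(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5)), 0.8)
  set.seed(4)
  for (i in 1:100) {
    x <- rnorm(sample(3:50, 1))
    y <- rnorm(length(x))
    expect_equal(pearson_r(x, y), cor(x, y), tolerance = 1e-12)
  }
  expect_error(pearson_r(1:3, rep(2, 3)), "constant")
  expect_error(pearson_r(1:3, 1:4), "equal lengths")
})

test_that("correlation bands follow the 0.1/0.4/0.7/0.9 cut-offs", {
  expect_equal(classify_correlation(0.91), "very strong")
  expect_equal(classify_correlation(0.68), "moderate")
  expect_equal(classify_correlation(0.05), "negligible")
  expect_equal(classify_correlation(-0.75), "strong")
  expect_equal(classify_correlation(c(0.1, 0.4, 0.7, 0.9)),
               c("weak", "moderate", "strong", "very strong"))
  expect_error(classify_correlation(1.2), "<= 1")
})

test_that("linear_fit recovers exact affine relations", {
  a <- c(8, 9, 10, 11, 12)
  expect_equal(linear_fit(a, a), c(slope = 1, intercept = 0))
  expect_equal(linear_fit(a, 2 * a + 3), c(slope = 2, intercept = 3))
  expect_error(linear_fit(rep(1, 5), 1:5), "constant")
})

test_that("bland_altman obeys its algebraic identities", {
  z <- bland_altman(1:5, 1:5)
  expect_equal(unclass(z), list(mean_diff = 0, sd_diff = 0,
                                loa_upper = 0, loa_lower = 0))
  two <- bland_altman(c(0, 0), c(-1, 1))
  expect_equal(two$mean_diff, 0)
  expect_equal(two$sd_diff, sqrt(2))
  expect_equal(two$loa_upper, 1.96 * sqrt(2))
  set.seed(6)
  for (i in 1:100) {
    n <- sample(2:100, 1)
    actual <- rnorm(n); predicted <- rnorm(n)
    ba <- bland_altman(actual, predicted)
    expect_equal(ba$loa_upper - ba$loa_lower, 2 * 1.96 * ba$sd_diff)
    expect_equal(ba$loa_upper + ba$loa_lower, 2 * ba$mean_diff)
    expect_gte(ba$loa_upper, ba$loa_lower)
  }
})

test_that("paired_t matches t.test and honours the degenerate contracts", {
  set.seed(7)
  a <- rnorm(30, 10); b <- a + rnorm(30, 0.3)
  mine <- paired_t(a, b)
  ref <- t.test(b, a, paired = TRUE)
  expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(mine$df, unname(ref$parameter))
  expect_equal(mine$p, ref$p.value, tolerance = 1e-12)

  same <- paired_t(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(paired_t(a, a + 2), "infinite t")
})

test_that("null p-values of the paired t are uniform", {
  ps <- sapply(1:200, function(s) {
    set.seed(s)
    paired_t(rep(0, 341), rnorm(341))$p
  })
  d <- suppressWarnings(ks.test(ps, "punif"))$statistic
  expect_lt(unname(d), 0.1)
  # df is n - 1 always
  expect_equal(paired_t(rep(0, 341), rnorm(341))$df, 340L)
})

test_that("Fisher r-to-z comparison reproduces known statistics", {
  expect_equal(round_half_up(compare_correlations(0.91, 0.73, 341)$z, 2), 7.78)
  expect_equal(round_half_up(compare_correlations(0.91, 0.62, 341)$z, 2), 10.43)
  expect_equal(round_half_up(compare_correlations(0.91, 0.87, 341)$z, 2), 2.53)

  eq <- compare_correlations(0.5, 0.5, 100)
  expect_equal(eq$z, 0)
  expect_equal(eq$p, 1)

  # antisymmetry
  set.seed(9)
  for (i in 1:50) {
    r1 <- runif(1, -0.95, 0.95); r2 <- runif(1, -0.95, 0.95)
    n <- sample(4:500, 1)
    ab <- compare_correlations(r1, r2, n)
    ba <- compare_correlations(r2, r1, n)
    expect_equal(ab$z, -ba$z)
    expect_equal(ab$p, ba$p)
    expect_equal(sign(ab$z), sign(r1 - r2))
  }
  expect_error(compare_correlations(1, 0.5, 100), "< 1")
  expect_error(compare_correlations(0.5, 0.4, 3), "n")
})

test_that("subject fits summarise per-subject relationships", {
  v <- seq(8, 12, by = 0.5)
  tab <- rbind(
    data.frame(subject_id = "A", stage = seq_along(v), velocity_kmh = v,
               pl_au = 1, avnetforce_N = 1, hr_bpm = 60 + 1 * v),
    data.frame(subject_id = "B", stage = seq_along(v), velocity_kmh = v,
               pl_au = 1, avnetforce_N = 1, hr_bpm = 40 + 3 * v)
  )
  fits <- subject_fits(tab, "hr_bpm")
  expect_equal(fits$mean_beta, 2)
  expect_equal(fits$per_subject$beta, c(1, 3))
  expect_equal(fits$sd_r, 0)
  expect_equal(fits$mean_r, 1)

  # single-stage subjects are excluded with a warning
  tab1 <- rbind(tab, data.frame(subject_id = "C", stage = 1, velocity_kmh = 8,
                                pl_au = 1, avnetforce_N = 1, hr_bpm = 100))
  expect_warning(f2 <- subject_fits(tab1, "hr_bpm"), "C")
  expect_equal(nrow(f2$per_subject), 2L)
})

test_that("descriptives reproduce printed coefficient-of-variation rows", {
  # two-point vectors have mean (a+b)/2 and sd |b-a|/sqrt(2): build one
  # with the height row's mean and SD and check the CV comes out right
  d <- descriptives(c(177.5 - 8.08 / sqrt(2), 177.5 + 8.08 / sqrt(2)))
  expect_equal(d$mean, 177.5)
  expect_equal(d$sd, 8.08)
  expect_equal(round_half_up(d$cv_percent, 2), 4.55)
  cv <- function(mean, sd) round_half_up(100 * sd / mean, 2)
  expect_equal(cv(177.5, 8.08), 4.55)
  expect_equal(cv(71.93, 11.14), 15.49)
  expect_equal(cv(22.71, 2.36), 10.39)
  expect_equal(cv(59.8, 8.53), 14.26)

  set.seed(10)
  x <- rnorm(50, 100, 10)
  dd <- descriptives(x)
  expect_equal(dd$cv_percent, 100 * sd(x) / mean(x))
  expect_true(dd$min <= dd$mean && dd$mean <= dd$max)
  expect_equal(descriptives(rep(5, 4))$cv_percent, 0)
  expect_error(descriptives(c(-1, 1)), "mean is zero")
})

test_that("evaluation bundles and comparison tables are coherent", {
  set.seed(12)
  actual <- rep(seq(8, 14, 0.5), 4)
  pred <- data.frame(subject_id = "S01", stage = 1, velocity_kmh = actual,
                     predicted_kmh = actual + rnorm(length(actual), 0, 0.4),
                     fold_id = "S01", model_tag = "pl+av_net_force+hr")
  class(pred) <- c("ift_predictions", "data.frame")
  ev <- evaluate_predictions(pred)
  expect_equal(ev$n, length(actual))
  expect_equal(ev$r, pearson_r(actual, pred$predicted_kmh))
  expect_equal(ev$agreement$loa_upper - ev$agreement$loa_lower,
               2 * 1.96 * ev$agreement$sd_diff)

  uni <- list(hr = pred)
  cmp <- model_comparison_table(pred, uni)
  expect_equal(cmp$model, c("multivariate", "hr"))
  expect_equal(cmp$z_vs_multivariate[2], 0)
})
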