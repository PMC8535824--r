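# Statistical evaluation battery: correlations and magnitude bands,
# predicted-vs-actual fits, Bland-Altman agreement, paired t-test, Fisher
# r-to-z model comparison, per-subject fits, descriptive statistics.

#' Pearson correlation coefficient
#'
#' @param a,b Equal-length numeric vectors (n >= 3), neither constant.
#' @return Sample Pearson correlation.
#' @export
pearson_r <- function(a, b) {
  if (length(a) != length(b)) stop_invalid("inputs must have equal lengths")
  if (length(a) < 3L) stop_invalid("need at least 3 pairs")
  da <- a - mean(a)
  db <- b - mean(b)
  va <- sum(da^2)
  vb <- sum(db^2)
  if (va <= 0 || vb <= 0) stop_invalid("correlation undefined for constant input")
  sum(da * db) / sqrt(va * vb)
}

#' Qualitative correlation-magnitude band
#'
#' Classifies `|r|` by the conventional cut-offs 0.1 / 0.4 / 0.7 / 0.9:
#' negligible, weak, moderate, strong, very strong.
#'
#' @param r Correlation coefficient(s), `|r| <= 1`.
#' @return Character band label(s).
#' @export
#' @examples
#' classify_correlation(0.91) # "very strong"
#' classify_correlation(0.68) # "moderate"
classify_correlation <- function(r) {
  if (any(!is.finite(r)) || any(abs(r) > 1)) {
    stop_invalid("|r| must be <= 1")
  }
  cut_labels <- c("negligible", "weak", "moderate", "strong", "very strong")
  idx <- findInterval(abs(r), c(0.10, 0.40, 0.70, 0.90)) + 1L
  cut_labels[idx]
}

#' OLS fit of predicted on actual velocity
#'
#' @param actual,predicted Equal-length vectors; `actual` non-constant.
#' @return Named vector `c(slope, intercept)`.
#' @export
linear_fit <- function(actual, predicted) {
  if (length(actual) != length(predicted)) stop_invalid("inputs must have equal lengths")
  if (length(actual) < 2L) stop_invalid("need at least 2 pairs")
  if (stats::var(actual) <= 0) stop_invalid("singular fit: `actual` is constant")
  fit <- stats::lm(predicted ~ actual)
  c(slope = unname(stats::coef(fit)[2L]), intercept = unname(stats::coef(fit)[1L]))
}

#' Bland-Altman limits of agreement
#'
#' Differences are `predicted - actual`; limits of agreement are the mean
#' difference +/- 1.96 SD of the differences.
#'
#' @param actual,predicted Equal-length vectors (n >= 2).
#' @param multiplier LoA multiplier (1.96 for 95% limits).
#' @return List of class `ift_agreement`: `mean_diff`, `sd_diff`,
#'   `loa_upper`, `loa_lower` (km/h).
#' @export
bland_altman <- function(actual, predicted, multiplier = 1.96) {
  if (length(actual) != length(predicted)) stop_invalid("inputs must have equal lengths")
  if (length(actual) < 2L) stop_invalid("need at least 2 pairs")
  d <- predicted - actual
  m <- mean(d)
  s <- stats::sd(d)
  structure(
    list(mean_diff = m, sd_diff = s,
         loa_upper = m + multiplier * s, loa_lower = m - multiplier * s),
    class = "ift_agreement"
  )
}

#' Paired t-test on predicted vs actual velocity
#'
#' One-sample t on the differences with df = n - 1 and a two-sided p. If
#' the differences have zero variance: t = 0, p = 1 when their mean is
#' zero, otherwise an infinite-t error.
#'
#' @param actual,predicted Equal-length vectors (n >= 2).
#' @return List `t`, `df`, `p`.
#' @export
paired_t <- function(actual, predicted) {
  if (length(actual) != length(predicted)) stop_invalid("inputs must have equal lengths")
  n <- length(actual)
  if (n < 2L) stop_invalid("need at least 2 pairs")
  d <- predicted - actual
  s <- stats::sd(d)
  if (s <= 0) {
    if (abs(mean(d)) <= 0) return(list(t = 0, df = n - 1L, p = 1))
    stop_invalid("infinite t: constant nonzero differences")
  }
  tstat <- mean(d) / (s / sqrt(n))
  list(t = tstat, df = n - 1L, p = 2 * stats::pt(-abs(tstat), df = n - 1L))
}

#' Fisher r-to-z comparison of two correlations
#'
#' Two-sample Fisher r-to-z statistic
#' `z = (atanh(r1) - atanh(r2)) / sqrt(2 / (n - 3))` with a two-sided
#' standard-normal p, for comparing two correlation coefficients computed
#' on n paired samples.
#'
#' @param r1,r2 Correlations, `|r| < 1`.
#' @param n Sample count behind each correlation (>= 4).
#' @return List of class `ift_corr_comparison`: `r1`, `r2`, `n`, `z`, `p`.
#' @export
#' @examples
#' compare_correlations(0.91, 0.73, 341)$z # 7.78 at 2 dp
compare_correlations <- function(r1, r2, n) {
  if (!is.finite(r1) || !is.finite(r2) || abs(r1) >= 1 || abs(r2) >= 1) {
    stop_invalid("|r| must be < 1")
  }
  check_number(n, "n", lower = 4)
  z <- (atanh(r1) - atanh(r2)) / sqrt(2 / (n - 3))
  structure(
    list(r1 = r1, r2 = r2, n = n, z = z, p = 2 * stats::pnorm(-abs(z))),
    class = "ift_corr_comparison"
  )
}

#' Per-subject linear fits of a metric against velocity
#'
#' Pearson r and OLS slope of the metric on stage velocity for each
#' subject, with cohort mean and SD of both; quantifies between-subject
#' variability of the metric-velocity relationship. Subjects with fewer
#' than 2 windows or a constant velocity are excluded with a warning.
#'
#' @param table Feature table from [build_feature_table()].
#' @param metric_name Column to fit: `"pl_au"`, `"avnetforce_N"`, or
#'   `"hr_bpm"`.
#' @return List of class `ift_subject_fits`: `per_subject` (data frame
#'   `subject_id,r,beta`), `mean_r`, `sd_r`, `mean_beta`, `sd_beta`.
#' @export
subject_fits <- function(table, metric_name) {
  if (!metric_name %in% names(table)) {
    stop_invalid("no column '%s' in the feature table", metric_name)
  }
  rows <- list()
  excluded <- character()
  for (sid in unique(table$subject_id)) {
    sub <- table[table$subject_id == sid, , drop = FALSE]
    if (nrow(sub) < 2L || stats::var(sub$velocity_kmh) <= 0) {
      excluded <- c(excluded, sid)
      next
    }
    y <- sub[[metric_name]]
    beta <- unname(stats::coef(stats::lm(y ~ sub$velocity_kmh))[2L])
    r <- if (stats::var(y) <= 0) NA_real_ else pearson_r(sub$velocity_kmh, y)
    rows[[length(rows) + 1L]] <- data.frame(subject_id = sid, r = r, beta = beta)
  }
  if (length(excluded)) {
    warning(sprintf("excluded subject(s) with a single stage: %s",
                    paste(excluded, collapse = ", ")), call. = FALSE)
  }
  per <- do.call(rbind, rows)
  structure(
    list(per_subject = per,
         mean_r = mean(per$r, na.rm = TRUE), sd_r = stats::sd(per$r, na.rm = TRUE),
         mean_beta = mean(per$beta), sd_beta = stats::sd(per$beta)),
    class = "ift_subject_fits"
  )
}

#' Descriptive statistics with coefficient of variation
#'
#' @param values Non-empty numeric vector; mean must be nonzero for the CV.
#' @return List of class `ift_descriptives`: `mean`, `sd` (n - 1
#'   denominator), `min`, `max`, `cv_percent` (= 100 * sd / mean).
#' @export
#' @examples
#' descriptives(c(170, 175, 180, 185))
descriptives <- function(values) {
  if (length(values) == 0L || any(!is.finite(values))) {
    stop_invalid("values must be non-empty and finite")
  }
  m <- mean(values)
  s <- if (length(values) > 1L) stats::sd(values) else 0
  if (m == 0) stop_invalid("CV undefined: mean is zero")
  structure(
    list(mean = m, sd = s, min = min(values), max = max(values),
         cv_percent = 100 * s / m),
    class = "ift_descriptives"
  )
}

#' Evaluate a set of cross-validated predictions
#'
#' Bundles the agreement battery for one prediction set: Pearson r with
#' its magnitude band, the predicted-on-actual OLS fit, Bland-Altman
#' limits of agreement, and the paired t-test.
#'
#' @param predictions An `ift_predictions` data frame from [loso_cv()].
#' @return List of class `ift_evaluation`: `n`, `r`, `r_band`, `fit`
#'   (slope/intercept), `agreement`, `t_test`, `model_tag`.
#' @export
evaluate_predictions <- function(predictions) {
  actual <- predictions$velocity_kmh
  predicted <- predictions$predicted_kmh
  r <- pearson_r(actual, predicted)
  structure(
    list(n = nrow(predictions), r = r, r_band = classify_correlation(r),
         fit = linear_fit(actual, predicted),
         agreement = bland_altman(actual, predicted),
         t_test = paired_t(actual, predicted),
         model_tag = predictions$model_tag[1L]),
    class = "ift_evaluation"
  )
}

#' Compare the multivariate model with univariate baselines
#'
#' Fisher r-to-z comparison of the multivariate LOSO correlation against
#' each univariate baseline's, on the shared window count.
#'
#' @param multi An `ift_predictions` set from [loso_cv()].
#' @param uni_list Named list of univariate `ift_predictions` sets.
#' @return Data frame `model,r,z_vs_multivariate,p` (first row the
#'   multivariate model).
#' @export
model_comparison_table <- function(multi, uni_list) {
  n <- nrow(multi)
  r_multi <- pearson_r(multi$velocity_kmh, multi$predicted_kmh)
  rows <- data.frame(model = "multivariate", r = r_multi,
                     z_vs_multivariate = NA_real_, p = NA_real_)
  for (nm in names(uni_list)) {
    u <- uni_list[[nm]]
    r_u <- pearson_r(u$velocity_kmh, u$predicted_kmh)
    cmp <- compare_correlations(r_multi, r_u, n)
    rows <- rbind(rows, data.frame(model = nm, r = r_u,
                                   z_vs_multivariate = cmp$z, p = cmp$p))
  }
  rows
}

#' @export
print.ift_evaluation <- function(x, ...) {
  cat(sprintf("LOSO evaluation (%s), n = %d windows\n", x$model_tag, x$n))
  cat(sprintf("  Pearson r: %.3f (%s)\n", x$r, x$r_band))
  cat(sprintf("  Fit: predicted = %.2f x actual + %.2f\n",
              x$fit["slope"], x$fit["intercept"]))
  cat(sprintf("  Bland-Altman: mean diff %.2f km/h, LoA [%.2f, %.2f]\n",
              x$agreement$mean_diff, x$agreement$loa_lower, x$agreement$loa_upper))
  cat(sprintf("  Paired t: t = %.3f, df = %d, p = %.3f\n",
              x$t_test$t, x$t_test$df, x$t_test$p))
  invisible(x)
}
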