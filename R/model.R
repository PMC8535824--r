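# z-scoring, linear-kernel support-vector regression, and
# leave-one-subject-out cross-validation with univariate baselines.

.feature_columns <- c(pl = "pl_au", av_net_force = "avnetforce_N", hr = "hr_bpm")

#' SVR configuration
#'
#' The published analysis reports a linear kernel but no hyperparameters;
#' the defaults here are the conventional cost C = 1 and epsilon tube
#' 0.1 km/h (velocity targets are not normalised, only the features are).
#'
#' @param C Regularisation cost, > 0.
#' @param epsilon Epsilon-insensitive tube half-width, km/h.
#' @param features Feature subset: any of `"pl"`, `"av_net_force"`, `"hr"`.
#' @param scale_scope `"fold"` (z-score fit on each training fold, the
#'   leakage-free default) or `"global"` (one scaler on the pooled table,
#'   for parity experiments).
#' @param estimator `"svr"` (epsilon-insensitive linear SVR) or `"ols"`
#'   (ordinary least squares on the scaled features).
#' @return An object of class `ift_svr_config`.
#' @export
svr_config <- function(C = 1, epsilon = 0.1,
                       features = c("pl", "av_net_force", "hr"),
                       scale_scope = c("fold", "global"),
                       estimator = c("svr", "ols")) {
  check_number(C, "C", lower = 0, allow_equal_lower = FALSE)
  check_number(epsilon, "epsilon", lower = 0)
  if (length(features) == 0L) stop_invalid("feature subset must be non-empty")
  unknown <- setdiff(features, names(.feature_columns))
  if (length(unknown)) {
    stop_invalid("unknown feature(s): %s (use %s)",
                 paste(unknown, collapse = ", "),
                 paste(names(.feature_columns), collapse = ", "))
  }
  structure(
    list(C = C, epsilon = epsilon, features = features,
         scale_scope = match.arg(scale_scope),
         estimator = match.arg(estimator)),
    class = "ift_svr_config"
  )
}

#' Fit / apply a z-score scaler
#'
#' `fit_scaler` estimates per-feature means and SDs on training rows;
#' `apply_scaler` standardises rows with those (training-fold) parameters
#' only, so held-out rows never influence the scaling.
#'
#' @param x Numeric matrix or data frame of features (training rows for
#'   `fit_scaler`).
#' @return `fit_scaler`: list of class `ift_scaler` with `mean` and `sd`;
#'   `apply_scaler`: the scaled matrix.
#' @export
fit_scaler <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop_invalid("need at least 2 training rows to fit a scaler")
  if (any(!is.finite(x))) stop_invalid("features must be finite")
  mu <- colMeans(x)
  sdev <- apply(x, 2L, stats::sd)
  degenerate <- sdev <= 1e-12
  if (any(degenerate)) {
    stop_invalid("degenerate (constant) feature: %s",
                 paste(colnames(x)[degenerate], collapse = ", "))
  }
  structure(list(mean = mu, sd = sdev), class = "ift_scaler")
}

#' @rdname fit_scaler
#' @param scaler An `ift_scaler`.
#' @export
apply_scaler <- function(x, scaler) {
  stopifnot(inherits(scaler, "ift_scaler"))
  x <- as.matrix(x)
  sweep(sweep(x, 2L, scaler$mean, "-"), 2L, scaler$sd, "/")
}

#' Invert a z-score scaler
#' @rdname fit_scaler
#' @export
invert_scaler <- function(x, scaler) {
  stopifnot(inherits(scaler, "ift_scaler"))
  x <- as.matrix(x)
  sweep(sweep(x, 2L, scaler$sd, "*"), 2L, scaler$mean, "+")
}

#' Train an epsilon-insensitive linear SVR
#'
#' Thin wrapper around `e1071::svm` (eps-regression, linear kernel, no
#' internal scaling) exposing the primal weight vector and bias for
#' inspection. With `estimator = "ols"` an ordinary least-squares fit is
#' used instead (same interface).
#'
#' @param x Scaled feature matrix.
#' @param y Velocity targets, km/h.
#' @param config An [svr_config()].
#' @return Object of class `ift_svr`: `w` (named weights), `b` (bias), and
#'   the underlying fit.
#' @export
train_svr <- function(x, y, config = svr_config()) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop_invalid("need at least 2 rows to train")
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop_invalid("features and targets must be finite")
  }
  if (config$estimator == "ols") {
    fit <- stats::lm.fit(cbind(`(Intercept)` = 1, x), y)
    w <- fit$coefficients[-1L]
    b <- fit$coefficients[1L]
    obj <- list(fit = fit, w = w, b = unname(b), kind = "ols")
  } else {
    fit <- e1071::svm(x = x, y = y, type = "eps-regression", kernel = "linear",
                      cost = config$C, epsilon = config$epsilon, scale = FALSE)
    w <- drop(t(fit$coefs) %*% fit$SV)
    names(w) <- colnames(x)
    obj <- list(fit = fit, w = w, b = -fit$rho, kind = "svr")
  }
  class(obj) <- "ift_svr"
  obj
}

#' @export
predict.ift_svr <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  drop(newdata %*% object$w) + object$b
}

check_feature_table <- function(table, features) {
  cols <- .feature_columns[features]
  needed <- c("subject_id", "velocity_kmh", unname(cols))
  missing <- setdiff(needed, names(table))
  if (length(missing)) {
    stop_invalid("feature table is missing column(s): %s",
                 paste(missing, collapse = ", "))
  }
  cols
}

#' Leave-one-subject-out cross-validated predictions
#'
#' For each subject, a z-score scaler and a regression model are fit on
#' all other subjects' windows and applied to the held-out subject's
#' windows; the union of held-out predictions is returned, so every window
#' is predicted exactly once by a model that never saw that subject.
#'
#' @param table Feature table from [build_feature_table()].
#' @param config An [svr_config()].
#' @return Data frame of class `ift_predictions`:
#'   `subject_id,stage,velocity_kmh,predicted_kmh,fold_id,model_tag`, with
#'   per-fold fitted coefficients in attribute `"fold_models"`.
#' @export
loso_cv <- function(table, config = svr_config()) {
  stopifnot(inherits(config, "ift_svr_config"))
  cols <- check_feature_table(table, config$features)
  subjects <- unique(table$subject_id)
  if (length(subjects) < 2L) {
    stop_invalid("LOSO needs at least 2 distinct subjects (got %d)", length(subjects))
  }
  tag <- paste(config$features, collapse = "+")
  global_scaler <- if (config$scale_scope == "global") {
    fit_scaler(table[, cols, drop = FALSE])
  } else NULL

  preds <- vector("list", length(subjects))
  fold_models <- vector("list", length(subjects))
  names(fold_models) <- subjects
  for (j in seq_along(subjects)) {
    sid <- subjects[j]
    train <- table[table$subject_id != sid, , drop = FALSE]
    test <- table[table$subject_id == sid, , drop = FALSE]
    scaler <- if (is.null(global_scaler)) {
      fit_scaler(train[, cols, drop = FALSE])
    } else global_scaler
    model <- train_svr(apply_scaler(train[, cols, drop = FALSE], scaler),
                       train$velocity_kmh, config)
    yhat <- predict(model, apply_scaler(test[, cols, drop = FALSE], scaler))
    preds[[j]] <- data.frame(
      subject_id = test$subject_id, stage = test$stage,
      velocity_kmh = test$velocity_kmh, predicted_kmh = as.numeric(yhat),
      fold_id = sid, model_tag = tag
    )
    fold_models[[j]] <- list(w = model$w, b = model$b,
                             scaler_mean = scaler$mean, scaler_sd = scaler$sd)
  }
  out <- do.call(rbind, preds)
  rownames(out) <- NULL
  attr(out, "fold_models") <- fold_models
  class(out) <- c("ift_predictions", "data.frame")
  out
}

#' Univariate LOSO baseline
#'
#' Identical machinery to [loso_cv()] with a single-feature subset.
#'
#' @param table Feature table.
#' @param feature_name One of `"pl"`, `"av_net_force"`, `"hr"`.
#' @param config An [svr_config()]; its feature subset is replaced.
#' @return An `ift_predictions` data frame.
#' @export
univariate_loso <- function(table, feature_name, config = svr_config()) {
  if (length(feature_name) != 1L || !feature_name %in% names(.feature_columns)) {
    stop_invalid("unknown feature '%s' (use %s)", paste(feature_name, collapse = ","),
                 paste(names(.feature_columns), collapse = ", "))
  }
  config$features <- feature_name
  loso_cv(table, config)
}
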