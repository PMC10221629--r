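#' Fit the ridge-regression fatigue model
#'
#' Solves the ridge normal equations analytically,
#' \deqn{(X^\top X + \alpha I)\beta = X^\top y,}
#' on centered (and, by default, z-scored) features with an unpenalized
#' intercept recovered from the training means. At `alpha = 0` this reduces
#' to ordinary least squares; as `alpha` grows all coefficients shrink
#' toward zero. The stored model predicts on the original feature scale
#' whatever scaling convention was used for the fit.
#'
#' @param data A data frame holding the response and feature columns.
#' @param response Name of the response column (default `"fss"`).
#' @param features Character vector of feature column names. Default: the
#'   three spectral features used for the fatigue score (channel-7 centroid
#'   frequency and entropy, channel-10 entropy).
#' @param alpha Regularization parameter, >= 0 (default 0.1).
#' @param standardize Z-score the feature columns before solving (default
#'   `TRUE`). When `FALSE` the features are only centered, so the intercept
#'   stays unpenalized.
#' @param standardize_response Z-score the response as well (default: same
#'   as `standardize`). Coefficients are then in response-SD units per
#'   feature-SD, directly comparable across features.
#'
#' @return An object of class `fatigue_model`: coefficients on the fitting
#'   scale (`beta`, `beta0`), on the original scale (`beta_raw`,
#'   `beta0_raw`), the scaling parameters, `alpha`, `feature_names`, and the
#'   training data summary.
#' @export
#' @examples
#' study <- apply_exclusions(load_study())
#' fit <- ridge_fit(study, alpha = 0.1)
#' fit
#' tidy(fit)
ridge_fit <- function(data,
                      response = "fss",
                      features = c("cf_ch7", "pse_ch7", "pse_ch10"),
                      alpha = 0.1,
                      standardize = TRUE,
                      standardize_response = standardize) {
  missing_cols <- setdiff(c(response, features), names(data))
  if (length(missing_cols)) {
    abort(paste("Missing columns:", paste(missing_cols, collapse = ", ")))
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0) {
    abort("`alpha` must be a single value >= 0.")
  }
  X <- as.matrix(data[, features, drop = FALSE])
  y <- data[[response]]
  if (anyNA(X) || anyNA(y)) abort("Missing values in the design matrix.")
  n <- nrow(X)
  p <- ncol(X)
  x_center <- colMeans(X)
  x_scale <- if (standardize) apply(X, 2, sd) else rep(1, p)
  if (any(x_scale == 0)) abort("A feature column is constant; cannot z-score.")
  y_center <- mean(y)
  y_scale <- if (standardize_response) sd(y) else 1
  if (y_scale == 0) abort("The response is constant.")
  Xs <- scale(X, center = x_center, scale = x_scale)
  ys <- (y - y_center) / y_scale
  A <- crossprod(Xs) + diag(alpha, p)
  beta <- tryCatch(
    drop(solve(A, crossprod(Xs, ys))),
    error = function(e) {
      abort(paste0(
        "The normal-equation system is singular at alpha = ", alpha,
        "; use alpha > 0."
      ))
    }
  )
  names(beta) <- features
  beta_raw <- beta * y_scale / x_scale
  beta0_raw <- y_center - sum(beta_raw * x_center)
  model <- structure(
    list(
      beta = beta, beta0 = 0,
      beta_raw = beta_raw, beta0_raw = beta0_raw,
      alpha = alpha, feature_names = features, response = response,
      standardize = standardize, standardize_response = standardize_response,
      x_center = x_center, x_scale = x_scale,
      y_center = y_center, y_scale = y_scale,
      n = n
    ),
    class = "fatigue_model"
  )
  model$fitted <- predict(model, data)
  model$r_insample <- if (sd(model$fitted) > 0) cor(model$fitted, y) else NA_real_
  model
}

#' @export
print.fatigue_model <- function(x, ...) {
  conv <- if (x$standardize) {
    if (x$standardize_response) "z-scored X and y" else "z-scored X, raw y"
  } else "raw scale (centered)"
  cat(sprintf("<fatigue_model> ridge, alpha = %g, n = %d, %s\n",
              x$alpha, x$n, conv))
  coefs <- c("(Intercept)" = x$beta0, x$beta)
  print(round(coefs, 4))
  cat(sprintf("in-sample r(predicted, actual) = %.3f\n", x$r_insample))
  invisible(x)
}

#' Predict fatigue scores from a fitted model
#'
#' Evaluates \eqn{\hat y = \beta_0 + \sum_j \beta_j x_j} on the model's
#' fitting scale and maps the result back to original response units, so
#' predictions are always on the FSS scale regardless of the scaling
#' convention used in [ridge_fit()].
#'
#' @param object A `fatigue_model`.
#' @param newdata A data frame containing the model's feature columns, or a
#'   numeric matrix/vector in the model's feature order.
#' @param ... Unused.
#' @return Numeric vector of predicted scores.
#' @export
predict.fatigue_model <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) {
    missing_cols <- setdiff(object$feature_names, names(newdata))
    if (length(missing_cols)) {
      abort(paste("`newdata` lacks feature columns:",
                  paste(missing_cols, collapse = ", ")))
    }
    X <- as.matrix(newdata[, object$feature_names, drop = FALSE])
  } else {
    X <- rbind(newdata)
    if (ncol(X) != length(object$feature_names)) {
      abort(sprintf("Expected %d feature values, got %d.",
                    length(object$feature_names), ncol(X)))
    }
  }
  drop(object$beta0_raw + X %*% object$beta_raw)
}

#' @rdname ridge_fit
#' @param x A `fatigue_model`.
#' @param ... Unused.
#' @export
tidy.fatigue_model <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", x$feature_names),
    estimate = unname(c(x$beta0, x$beta)),
    estimate_raw = unname(c(x$beta0_raw, x$beta_raw))
  )
}

#' @rdname ridge_fit
#' @export
glance.fatigue_model <- function(x, ...) {
  tibble::tibble(
    alpha = x$alpha,
    n = x$n,
    p = length(x$beta),
    r_insample = x$r_insample,
    standardized = x$standardize,
    standardized_response = x$standardize_response
  )
}

#' Serialize a fatigue model to JSON
#'
#' @param model A `fatigue_model`.
#' @param path Output file path.
#' @return `path`, invisibly. `read_fatigue_model()` reconstructs the model.
#' @export
write_fatigue_model <- function(model, path) {
  stopifnot(inherits(model, "fatigue_model"))
  keep <- c("beta", "beta0", "beta_raw", "beta0_raw", "alpha",
            "feature_names", "response", "standardize",
            "standardize_response", "x_center", "x_scale",
            "y_center", "y_scale", "n")
  jsonlite::write_json(model[keep], path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fatigue_model
#' @export
read_fatigue_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("beta", "beta_raw", "x_center", "x_scale")) {
    obj[[f]] <- setNames(as.numeric(obj[[f]]), obj$feature_names)
  }
  structure(obj, class = "fatigue_model")
}

cv_folds <- function(n, k, seed) {
  if (k < 2) abort("`k` must be >= 2.")
  if (k > n) abort("`k` cannot exceed the number of rows.")
  set.seed(as.integer(seed))
  sample(rep(seq_len(k), length.out = n))
}

cv_metric <- function(err, metric) {
  switch(metric,
         mae = mean(abs(err)),
         rmse = sqrt(mean(err^2)),
         mse = mean(err^2),
         abort("`metric` must be one of mse, mae, rmse."))
}

#' K-fold cross-validated error of the ridge model
#'
#' Rows are shuffled with `seed` and split into `k` near-equal folds. For
#' each fold the model is refit on the remaining folds — scaling parameters
#' recomputed on the training folds only — and evaluated on the held-out
#' fold. The mean of the `k` fold errors is returned.
#'
#' @inheritParams ridge_fit
#' @param k Number of folds (default 5).
#' @param metric `"mse"` (default), `"mae"` or `"rmse"`.
#' @param seed Integer seed controlling the fold assignment; required.
#'
#' @return The mean validation error (a single number) with attribute
#'   `"fold_errors"`.
#' @export
#' @examples
#' study <- apply_exclusions(load_study())
#' kfold_cv(study, alpha = 0.1, seed = 1)
kfold_cv <- function(data, response = "fss",
                     features = c("cf_ch7", "pse_ch7", "pse_ch10"),
                     alpha = 0.1, k = 5,
                     metric = c("mse", "mae", "rmse"),
                     seed,
                     standardize = TRUE,
                     standardize_response = standardize) {
  if (missing(seed)) abort("`seed` is required for the fold shuffle.")
  metric <- match.arg(metric)
  fold <- cv_folds(nrow(data), k, seed)
  errs <- vapply(seq_len(k), function(f) {
    fit <- ridge_fit(data[fold != f, , drop = FALSE], response, features,
                     alpha, standardize, standardize_response)
    pred <- predict(fit, data[fold == f, , drop = FALSE])
    cv_metric(pred - data[[response]][fold == f], metric)
  }, numeric(1))
  structure(mean(errs), fold_errors = errs)
}

#' Out-of-fold predictions from k-fold cross-validation
#'
#' Same partitioning as [kfold_cv()], but returns each row's prediction from
#' the model fit that excluded it, e.g. to correlate cross-validated
#' predictions with the actual scores.
#'
#' @inheritParams kfold_cv
#' @return A tibble with columns `actual`, `predicted`, `fold`, in row order
#'   of `data`.
#' @export
cv_predictions <- function(data, response = "fss",
                           features = c("cf_ch7", "pse_ch7", "pse_ch10"),
                           alpha = 0.1, k = 5, seed,
                           standardize = TRUE,
                           standardize_response = standardize) {
  if (missing(seed)) abort("`seed` is required for the fold shuffle.")
  fold <- cv_folds(nrow(data), k, seed)
  pred <- numeric(nrow(data))
  for (f in seq_len(k)) {
    fit <- ridge_fit(data[fold != f, , drop = FALSE], response, features,
                     alpha, standardize, standardize_response)
    pred[fold == f] <- predict(fit, data[fold == f, , drop = FALSE])
  }
  tibble::tibble(actual = data[[response]], predicted = pred, fold = fold)
}

#' Select the ridge regularization parameter by cross-validation
#'
#' Evaluates each candidate `alpha` by k-fold cross-validated mean squared
#' error (the same folds for every candidate) and returns the minimizer;
#' ties break toward the smaller `alpha`.
#'
#' @inheritParams kfold_cv
#' @param grid Numeric vector of candidate `alpha` values, all >= 0.
#' @return The selected `alpha`, with attribute `"cv_mse"` (named vector of
#'   the grid's scores).
#' @export
select_alpha <- function(data, response = "fss",
                         features = c("cf_ch7", "pse_ch7", "pse_ch10"),
                         grid = c(0.001, 0.01, 0.1, 1, 10),
                         k = 5, seed,
                         standardize = TRUE,
                         standardize_response = standardize) {
  if (missing(seed)) abort("`seed` is required for the fold shuffle.")
  if (length(grid) < 1 || any(grid < 0)) {
    abort("`grid` must be a nonempty vector of values >= 0.")
  }
  grid <- sort(unique(grid))
  scores <- vapply(grid, function(a) {
    as.numeric(kfold_cv(data, response, features, alpha = a, k = k,
                        metric = "mse", seed = seed,
                        standardize = standardize,
                        standardize_response = standardize_response))
  }, numeric(1))
  structure(grid[which.min(scores)], cv_mse = setNames(scores, grid))
}
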