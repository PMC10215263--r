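#' Random train/test split of a jump dataset
#'
#' @param ds data frame containing the features and `l_meter`.
#' @param train_frac fraction of rows assigned to the training set
#'   (default 0.8; 286 rows yield 229/57).
#' @param seed integer seed.
#' @return list with `train` and `test` data frames (disjoint, exhaustive).
#' @export
split_dataset <- function(ds, train_frac = 0.8, seed = 1) {
  if (!nrow(ds)) stop_sljump("sljump_data_error", "empty dataset")
  if ("l_meter" %in% names(ds)) {
    rng <- range(ds$l_meter, na.rm = TRUE)
    if (rng[1] < 0.5 || rng[2] > 3.5)
      warning("l_meter outside the plausible SLJ range (", signif(rng[1], 3),
              "-", signif(rng[2], 3), " m)")
  }
  n <- nrow(ds)
  n_train <- round(train_frac * n)
  idx <- withr::with_seed(seed, sample.int(n, n_train))
  if (n_train == n) warning("train_frac = ", train_frac, " leaves an empty test set")
  list(train = ds[sort(idx), , drop = FALSE],
       test = ds[setdiff(seq_len(n), idx), , drop = FALSE])
}

#' Fit z-score normalization parameters on the training set
#'
#' @param train_X numeric matrix/data frame of training features.
#' @return object of class `normalization_params` with per-feature `mean`
#'   and `sd` (sample SD, n-1 denominator); zero-variance features are
#'   dropped with a warning.
#' @export
fit_normalization <- function(train_X) {
  X <- as.matrix(train_X)
  if (!nrow(X)) stop_sljump("sljump_data_error", "empty training set")
  mu <- colMeans(X)
  sigma <- apply(X, 2, sd)
  keep <- sigma > 0
  if (any(!keep))
    warning("dropping zero-variance feature(s): ",
            paste(colnames(X)[!keep], collapse = ", "))
  structure(list(mean = mu[keep], sd = sigma[keep],
                 features = colnames(X)[keep]),
            class = "normalization_params")
}

#' Apply z-score normalization with training-set parameters
#'
#' @param X matrix/data frame to normalize (e.g. the test set).
#' @param params a `normalization_params` from [fit_normalization()].
#' @return normalized matrix restricted to the retained features.
#' @export
apply_normalization <- function(X, params) {
  X <- as.matrix(X)[, params$features, drop = FALSE]
  scale(X, center = params$mean, scale = params$sd)[, , drop = FALSE]
}

#' Lasso feature reduction
#'
#' L1-penalized linear regression on the (already z-scored) training
#' features; features whose coefficient is exactly zero at the given
#' penalty are dropped.  `alpha` is the per-observation-scaled L1 penalty
#' weight (the `1/(2n) RSS + alpha * ||beta||_1` gaussian objective).
#'
#' @param train_X normalized feature matrix.
#' @param train_y response (m).
#' @param alpha penalty weight, default 0.1.
#' @return list with `selected` (feature names), `coefficients` (named,
#'   nonzero), `alpha`.
#' @export
lasso_select <- function(train_X, train_y, alpha = 0.1) {
  X <- as.matrix(train_X)
  fit <- glmnet::glmnet(X, train_y, alpha = 1, lambda = alpha,
                        standardize = FALSE)
  beta <- as.numeric(coef(fit))[-1]
  names(beta) <- colnames(X)
  nz <- beta[beta != 0]
  if (!length(nz))
    stop_sljump("sljump_selection_error",
                "Lasso at alpha = %g removed every feature; use a smaller alpha", alpha)
  list(selected = names(nz), coefficients = nz, alpha = alpha)
}

#' Standard regression error metrics
#'
#' @param y observed values.
#' @param y_hat predictions.
#' @return named list `RMSE`, `MSE`, `MAE`, `R2` (with
#'   `R2 = 1 - SS_res / SS_tot`).
#' @export
regression_metrics <- function(y, y_hat) {
  if (length(y) != length(y_hat))
    stop_sljump("sljump_contract_error", "y and y_hat lengths differ")
  e <- y - y_hat
  mse <- mean(e^2)
  list(RMSE = sqrt(mse), MSE = mse, MAE = mean(abs(e)),
       R2 = 1 - sum(e^2) / sum((y - mean(y))^2))
}
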