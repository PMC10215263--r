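#' Bland-Altman limits of agreement from summary statistics
#'
#' `UL = bias + 1.96 sd`, `LL = bias - 1.96 sd`; 95% confidence intervals
#' use `SE_bias = sd / sqrt(n)` for the bias and the classical
#' limit-of-agreement approximation `SE_limit = sqrt(3) sd / sqrt(n)` for
#' the limits.
#'
#' @param bias mean difference (m).
#' @param sd_diff SD of the differences (m).
#' @param n number of pairs.
#' @param t_value t quantile for the CIs; default `qt(0.975, n - 1)`.
#' @return list with `bias`, `sd_diff`, `UL`, `LL`, `CI_bias`, `CI_UL`,
#'   `CI_LL`, `SE_bias`, `n`, `t_value`.
#' @export
bland_altman_limits <- function(bias, sd_diff, n, t_value = NULL) {
  t_value <- t_value %||% qt(0.975, n - 1)
  UL <- bias + 1.96 * sd_diff
  LL <- bias - 1.96 * sd_diff
  se_b <- sd_diff / sqrt(n)
  se_l <- sqrt(3) * sd_diff / sqrt(n)
  list(bias = bias, sd_diff = sd_diff, UL = UL, LL = LL,
       CI_bias = c(bias - t_value * se_b, bias + t_value * se_b),
       CI_UL = c(UL - t_value * se_l, UL + t_value * se_l),
       CI_LL = c(LL - t_value * se_l, LL + t_value * se_l),
       SE_bias = se_b, n = n, t_value = t_value)
}

#' Bland-Altman agreement analysis
#'
#' Differences are oriented `reference - estimate`.  Besides the bias and
#' 95% limits of agreement with their confidence intervals, the
#' regression of differences on pair means (slope, intercept, R^2) is
#' returned for the difference-versus-mean trend.
#'
#' @param y_ref reference values (m).
#' @param y_est estimated values (m).
#' @param t_value optional t quantile override (e.g. a printed 2.00);
#'   default `qt(0.975, n - 1)`.
#' @return object of class `bland_altman` (see [bland_altman_limits()]
#'   plus `regression` and the raw `differences` and `means`).
#' @export
bland_altman <- function(y_ref, y_est, t_value = NULL) {
  if (length(y_ref) != length(y_est))
    stop_sljump("sljump_contract_error", "y_ref and y_est lengths differ")
  n <- length(y_ref)
  if (n < 3)
    stop_sljump("sljump_statistics_error", "Bland-Altman needs at least 3 pairs")
  d <- y_ref - y_est
  m <- (y_ref + y_est) / 2
  out <- bland_altman_limits(mean(d), sd(d), n, t_value)
  reg <- lm(d ~ m)
  out$regression <- list(slope = unname(coef(reg)[2]),
                         intercept = unname(coef(reg)[1]),
                         R2 = suppressWarnings(summary(reg)$r.squared))
  out$differences <- d
  out$means <- m
  structure(out, class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(paste0("<bland_altman> n=%d  bias=%.3f m [%.3f, %.3f]  ",
                     "UL=%.3f [%.3f, %.3f]  LL=%.3f [%.3f, %.3f]\n"),
              x$n, x$bias, x$CI_bias[1], x$CI_bias[2],
              x$UL, x$CI_UL[1], x$CI_UL[2], x$LL, x$CI_LL[1], x$CI_LL[2]))
  invisible(x)
}

#' Kendall's tau heteroscedasticity screen
#'
#' Rank correlation between the pair means and the absolute differences
#' (ties handled by tau-b); `|tau| < 0.1` is read as homoscedastic error.
#' The alternative convention (reference vs. signed difference) is
#' available via `convention = "signed"`.
#'
#' @param y_ref,y_est paired measurements.
#' @param convention `"absolute"` (default) or `"signed"`.
#' @return Kendall's tau.
#' @export
kendall_tau_hetero <- function(y_ref, y_est,
                               convention = c("absolute", "signed")) {
  convention <- match.arg(convention)
  if (length(y_ref) < 3)
    stop_sljump("sljump_statistics_error", "need at least 3 pairs")
  d <- y_ref - y_est
  a <- switch(convention, absolute = (y_ref + y_est) / 2, signed = y_ref)
  b <- switch(convention, absolute = abs(d), signed = d)
  if (sd(a) == 0 || sd(b) == 0)
    stop_sljump("sljump_statistics_error", "tau undefined for constant inputs")
  cor(a, b, method = "kendall")
}

#' Accuracy, precision and bias of an estimator
#'
#' Accuracy = RMSE of reference vs. estimate; precision = SD of the
#' differences; bias = mean difference (reference - estimate).
#'
#' @param y_ref,y_est paired measurements (m).
#' @return named list `accuracy`, `precision`, `bias` (m).
#' @export
accuracy_precision_bias <- function(y_ref, y_est) {
  if (length(y_ref) != length(y_est))
    stop_sljump("sljump_contract_error", "y_ref and y_est lengths differ")
  d <- y_ref - y_est
  list(accuracy = sqrt(mean(d^2)), precision = sd(d), bias = mean(d))
}

#' Permutation feature importance
#'
#' For each feature column, `reps` independent permutations are applied
#' while the other columns are left untouched; the importance is the mean
#' ratio `MSE_i / MSE_0` between the permuted and intact model errors
#' (computed on the training set by convention).
#'
#' @param model an `slj_model` (or anything with a matching `predict`).
#' @param X feature matrix with the model's columns.
#' @param y observed response.
#' @param reps permutations per feature.
#' @param seed integer seed.
#' @return object of class `pfi_result`: data frame `importance`
#'   (`feature`, `ratio`), plus `mse_0`, `reps`, `seed`.
#' @export
permutation_feature_importance <- function(model, X, y, reps = 10, seed = 1) {
  X <- as.matrix(X)
  mse_0 <- mean((y - predict(model, X))^2)
  if (mse_0 <= 0) mse_0 <- .Machine$double.eps
  ratios <- withr::with_seed(seed, {
    vapply(seq_len(ncol(X)), function(j) {
      mean(vapply(seq_len(reps), function(r) {
        Xp <- X
        Xp[, j] <- X[sample.int(nrow(X)), j]
        mean((y - predict(model, Xp))^2) / mse_0
      }, numeric(1)))
    }, numeric(1))
  })
  structure(list(importance = data.frame(feature = colnames(X), ratio = ratios),
                 mse_0 = mse_0, reps = reps, seed = seed),
            class = "pfi_result")
}

#' @export
print.pfi_result <- function(x, ...) {
  ord <- order(x$importance$ratio, decreasing = TRUE)
  cat("<pfi_result> MSE ratios (permuted / intact), descending:\n")
  print(x$importance[ord, ], row.names = FALSE)
  invisible(x)
}

#' Bland-Altman plot
#'
#' Difference-versus-mean scatter with bias, 95% limits of agreement,
#' their confidence bands and the difference-on-mean regression line.
#'
#' @param ba a [bland_altman()] result.
#' @param title plot title.
#' @return a ggplot object.
#' @export
plot_bland_altman <- function(ba, title = "Bland-Altman") {
  df <- data.frame(mean = ba$means, diff = ba$differences)
  bands <- data.frame(y = c(ba$CI_bias, ba$CI_UL, ba$CI_LL),
                      grp = rep(c("bias", "UL", "LL"), each = 2))
  ggplot2::ggplot(df, ggplot2::aes(x = mean, y = diff)) +
    ggplot2::geom_rect(data = data.frame(ymin = c(ba$CI_bias[1], ba$CI_UL[1], ba$CI_LL[1]),
                                         ymax = c(ba$CI_bias[2], ba$CI_UL[2], ba$CI_LL[2])),
                       ggplot2::aes(ymin = ymin, ymax = ymax),
                       xmin = -Inf, xmax = Inf, fill = "grey85",
                       inherit.aes = FALSE) +
    ggplot2::geom_hline(yintercept = c(ba$bias, ba$UL, ba$LL),
                        linetype = c("solid", "dashed", "dashed")) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "black", linewidth = 0.4) +
    ggplot2::labs(title = title, x = "mean of reference and estimate (m)",
                  y = "reference - estimate (m)") +
    ggplot2::theme_minimal()
}
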