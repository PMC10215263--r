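# Exact Gaussian process regression with the kernel families and explicit
# basis functions used by the model pipeline.  n is a few hundred at most,
# so the O(n^3) Cholesky route is appropriate.

gpr_kernels <- c("rational_quadratic", "exponential", "matern52", "matern32",
                 "squared_exponential")

kernel_matrix <- function(D, kernel, length_scale, rq_alpha = 1) {
  r <- D / length_scale
  switch(kernel,
         rational_quadratic = (1 + r^2 / (2 * rq_alpha))^(-rq_alpha),
         exponential = exp(-r),
         matern52 = (1 + sqrt(5) * r + 5 * r^2 / 3) * exp(-sqrt(5) * r),
         matern32 = (1 + sqrt(3) * r) * exp(-sqrt(3) * r),
         squared_exponential = exp(-0.5 * r^2),
         stop_sljump("sljump_contract_error", "unknown kernel '%s'", kernel))
}

basis_matrix <- function(X, basis) {
  switch(basis,
         zero = matrix(0, nrow(X), 0),
         constant = matrix(1, nrow(X), 1),
         linear = cbind(1, X),
         stop_sljump("sljump_contract_error", "unknown basis '%s'", basis))
}

pdist <- function(A, B) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, `+`) - 2 * A %*% t(B)
  sqrt(pmax(d2, 0))
}

#' Fit a Gaussian process regression model
#'
#' Exact GP regression with observation-noise standard deviation `sigma`,
#' an explicit mean basis (`"zero"`, `"constant"` or `"linear"`, fitted by
#' generalized least squares), and one of the rational-quadratic,
#' exponential, Matern 3/2, Matern 5/2 or squared-exponential kernels.
#' The kernel length scale defaults to the median pairwise training
#' distance; the signal SD defaults to the SD of the basis residuals.
#'
#' @param X numeric training matrix (n x p).
#' @param y numeric response.
#' @param kernel one of
#'   `"rational_quadratic"`, `"exponential"`, `"matern52"`, `"matern32"`,
#'   `"squared_exponential"`.
#' @param sigma observation-noise SD (response units).
#' @param basis explicit mean basis.
#' @param length_scale kernel length scale; `NULL` = median heuristic.
#' @param signal_sd kernel signal SD; `NULL` = SD of basis residuals.
#' @param rq_alpha rational-quadratic shape parameter.
#' @return object of class `slj_gpr`.
#' @export
gpr_fit <- function(X, y, kernel = "squared_exponential", sigma = 0.1,
                    basis = "constant", length_scale = NULL,
                    signal_sd = NULL, rq_alpha = 1) {
  X <- as.matrix(X)
  D <- pdist(X, X)
  if (is.null(length_scale)) {
    ls <- median(D[upper.tri(D)])
    length_scale <- if (is.finite(ls) && ls > 0) ls else 1
  }
  H <- basis_matrix(X, basis)
  if (is.null(signal_sd)) {
    # prior variance must cover what the mean function does not explain;
    # with a zero basis that includes the offset of y itself
    signal_sd <- if (ncol(H))
      max(sd(stats::lm.fit(H, y)$residuals), 1e-3)
    else max(sqrt(mean(y^2)), 1e-3)
  }
  K <- signal_sd^2 * kernel_matrix(D, kernel, length_scale, rq_alpha)
  Ky <- K + diag(max(sigma, 1e-6)^2, nrow(X))
  L <- chol(Ky + diag(1e-10 * signal_sd^2, nrow(X)))
  solve_K <- function(b) backsolve(L, forwardsolve(t(L), b))
  beta <- numeric(0)
  if (ncol(H)) {
    KiH <- solve_K(H)
    A <- crossprod(H, KiH)
    beta <- solve(A + diag(1e-10, ncol(H)), crossprod(KiH, y))
    resid <- y - H %*% beta
  } else resid <- y
  alpha_vec <- solve_K(resid)
  structure(list(X = X, kernel = kernel, sigma = sigma, basis = basis,
                 length_scale = length_scale, signal_sd = signal_sd,
                 rq_alpha = rq_alpha, beta = beta, alpha = alpha_vec, L = L),
            class = "slj_gpr")
}

#' @export
predict.slj_gpr <- function(object, newdata, ...) {
  Xs <- as.matrix(newdata)
  Ks <- object$signal_sd^2 *
    kernel_matrix(pdist(Xs, object$X), object$kernel,
                  object$length_scale, object$rq_alpha)
  mu <- as.numeric(Ks %*% object$alpha)
  Hs <- basis_matrix(Xs, object$basis)
  if (ncol(Hs)) mu <- mu + as.numeric(Hs %*% object$beta)
  mu
}

# Posterior mean and SD (basis-uncertainty term omitted; used by the
# Bayesian-optimization surrogate).
gpr_posterior <- function(object, newdata) {
  Xs <- as.matrix(newdata)
  Ks <- object$signal_sd^2 *
    kernel_matrix(pdist(Xs, object$X), object$kernel,
                  object$length_scale, object$rq_alpha)
  mu <- as.numeric(Ks %*% object$alpha)
  Hs <- basis_matrix(Xs, object$basis)
  if (ncol(Hs)) mu <- mu + as.numeric(Hs %*% object$beta)
  V <- forwardsolve(t(object$L), t(Ks))
  s2 <- pmax(object$signal_sd^2 - colSums(V^2), 0)
  list(mean = mu, sd = sqrt(s2))
}
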