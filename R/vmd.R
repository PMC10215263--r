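#' Variational mode decomposition
#'
#' Decomposes a real signal into `K` band-limited intrinsic mode functions
#' by the standard ADMM scheme in the frequency domain (mirror-extended
#' signal, Wiener-filter mode updates, center-of-gravity frequency
#' updates).
#'
#' @param signal numeric vector.
#' @param K number of modes.
#' @param alpha bandwidth penalty (dimensionless), default 2000.
#' @param tau dual ascent step (0 = no noise-slack update).
#' @param tol convergence threshold on the relative mode update.
#' @param max_iter iteration cap.
#' @param init center-frequency initialization: `"zero"` or `"uniform"`.
#' @param dc_mode lock the first mode at DC.
#' @param fs sampling rate (samples/s) used to express frequencies in Hz.
#' @return list with `omega` (central frequencies, Hz, one per mode,
#'   unsorted), `modes` (n x K matrix of reconstructed modes), `iterations`,
#'   and `converged`.
#' @export
vmd <- function(signal, K = 3, alpha = 2000, tau = 0, tol = 1e-7,
                max_iter = 500, init = c("zero", "uniform"), dc_mode = FALSE,
                fs = 1) {
  init <- match.arg(init)
  x <- as.numeric(signal)
  T0 <- length(x)
  half <- floor(T0 / 2)
  f <- c(rev(x[seq_len(half)]), x, rev(x[seq(half + 1, T0)]))
  T <- length(f)
  if (T %% 2 == 1) { f <- c(f, f[T]); T <- T + 1 }
  freqs <- ((seq_len(T) - 1) / T) - 0.5          # fftshifted normalized freqs
  f_hat <- fft(f)
  f_hat <- c(f_hat[(T / 2 + 1):T], f_hat[1:(T / 2)])   # fftshift
  f_hat_plus <- f_hat
  f_hat_plus[1:(T / 2)] <- 0
  pos <- (T / 2 + 1):T
  omega <- switch(init,
                  zero = rep(0, K),
                  uniform = (0.5 / K) * (seq_len(K) - 0.5))
  if (dc_mode) omega[1] <- 0
  # only the positive-frequency half carries information (the analytic
  # signal); the compiled ADMM core operates there
  res <- vmd_admm(f_hat_plus[pos], freqs[pos], omega, alpha, tau, tol,
                  max_iter, dc_mode)
  omega <- res$omega
  it <- res$iterations
  converged <- res$converged
  u_hat <- matrix(0 + 0i, T, K)
  u_hat[pos, ] <- res$u
  if (!converged && it >= max_iter && max_iter > 1) {
    # report but do not fail: callers decide; frequencies are still usable
    attr(omega, "warning") <- sprintf("VMD did not converge in %d iterations", it)
  }
  # reconstruct modes in the original support
  modes <- matrix(0, T0, K)
  for (k in seq_len(K)) {
    full <- u_hat[, k]
    idx <- 2:(T / 2)                                   # hermitian completion:
    full[idx] <- Conj(full[T + 2 - idx])               # X(-f) = conj(X(f))
    full[1] <- Conj(full[T])
    full <- c(full[(T / 2 + 1):T], full[1:(T / 2)])    # inverse fftshift
    m <- Re(fft(full, inverse = TRUE)) / T
    modes[, k] <- m[(half + 1):(half + T0)]
  }
  list(omega = pmax(omega, 0) * fs, modes = modes, iterations = it,
       converged = converged)
}

#' VMD central-frequency features of a segmented acceleration signal
#'
#' Runs a 3-mode variational mode decomposition on the preparation-phase
#' acceleration and returns the converged central frequencies sorted
#' descending (`f1 > f2 > f3`, Hz): the high and middle frequencies track
#' wobbling/soft-tissue artifacts, the low one the jump itself.
#'
#' @param signal acceleration samples over `[t_0, t_TO]`.
#' @param fs sampling rate (samples/s).
#' @param n_modes number of modes (3).
#' @param bandwidth_penalty,tolerance,max_iter,init_mode VMD controls, see
#'   [vmd()].
#' @return named numeric vector `c(f1 =, f2 =, f3 =)` in Hz.
#' @export
vmd_features <- function(signal, fs, n_modes = 3, bandwidth_penalty = 2000,
                         tolerance = 1e-7, max_iter = 500,
                         init_mode = "zero") {
  if (length(signal) < 32)
    stop_sljump("sljump_feature_error",
                "signal too short for VMD (%d < 32 samples)", length(signal))
  res <- vmd(signal, K = n_modes, alpha = bandwidth_penalty, tol = tolerance,
             max_iter = max_iter, init = init_mode, fs = fs)
  f <- sort(res$omega, decreasing = TRUE)
  stats::setNames(f, paste0("f", seq_along(f)))
}
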