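#' Construct a gravity-removed global-frame acceleration series
#'
#' Convention: `a_V` is kinematic vertical acceleration (0 at rest, `-g` in
#' free fall); `a_AP` is the anteroposterior component with the propulsion
#' burst positive.
#'
#' @param timestamps sample times (s).
#' @param a_V,a_AP component series (m/s^2).
#' @param g gravity used for the removal (m/s^2).
#' @param sampling_rate samples/s.
#' @param clipped logical, carried over from the source recording.
#' @return object of class `global_acceleration`.
#' @export
global_acceleration <- function(timestamps, a_V, a_AP, g = SLJ_G,
                                sampling_rate = NULL, clipped = FALSE) {
  n <- length(timestamps)
  stopifnot(length(a_V) == n, length(a_AP) == n)
  if (is.null(sampling_rate)) sampling_rate <- 1 / median(diff(timestamps))
  structure(list(timestamps = as.numeric(timestamps),
                 a_V = as.numeric(a_V), a_AP = as.numeric(a_AP),
                 g = g, sampling_rate = sampling_rate, clipped = clipped),
            class = "global_acceleration")
}

#' @export
print.global_acceleration <- function(x, ...) {
  cat(sprintf("<global_acceleration> %d samples @ %.1f Hz, a_V in [%.2f, %.2f] m/s^2\n",
              length(x$timestamps), x$sampling_rate, min(x$a_V), max(x$a_V)))
  invisible(x)
}

#' Express a recording in the global frame with gravity removed
#'
#' A constant rotation is estimated from the mean specific-force vector in
#' the static window (tilt only; the yaw of the phone is irrelevant because
#' the movement plane is recovered from the data).  Acceleration is rotated
#' so one axis is vertical, gravity `(0, 0, g)` is subtracted, and the
#' in-plane horizontal component is returned as `a_AP` with its sign fixed
#' so the forward (propulsion) velocity excursion is positive.
#'
#' @param rec a calibrated [imu_recording()].
#' @param static_window numeric length-2 interval (s) known to be static.
#' @param g gravity (m/s^2), default 9.81.
#' @param tol relative tolerance on the static specific-force magnitude;
#'   a deviation from `g` beyond it raises an orientation error.
#' @return a [global_acceleration()].
#' @export
to_global_frame <- function(rec, static_window, g = SLJ_G, tol = 0.05) {
  idx <- window_idx(rec$timestamps, static_window)
  if (length(idx) < 2)
    stop_sljump("sljump_orientation_error", "static window contains < 2 samples")
  m <- colMeans(rec$acc[idx, , drop = FALSE])
  if (abs(sqrt(sum(m^2)) - g) > tol * g)
    stop_sljump("sljump_orientation_error",
                "static specific force (%.3f m/s^2) differs from g by more than %.0f%%",
                sqrt(sum(m^2)), 100 * tol)
  R <- rotation_between(m, c(0, 0, 1))
  f_glob <- t(R %*% t(rec$acc))            # specific force in global frame
  a_V <- f_glob[, 3] - g
  h <- f_glob[, 1:2, drop = FALSE]         # horizontal kinematic = horizontal specific force
  # Movement plane: principal horizontal direction over the whole recording.
  C <- crossprod(sweep(h, 2, colMeans(h))) # 2x2 second-moment of centered horizontal acc
  dir <- eigen(C, symmetric = TRUE)$vectors[, 1]
  a_AP <- as.numeric(h %*% dir)
  cv <- cumtrapz1(rec$timestamps, a_AP)    # horizontal velocity along dir
  if (abs(min(cv)) > abs(max(cv))) a_AP <- -a_AP
  global_acceleration(rec$timestamps, a_V, a_AP, g = g,
                      sampling_rate = rec$sampling_rate,
                      clipped = isTRUE(rec$clipped))
}

#' Export a global-frame series as delimited text
#' @param gacc a [global_acceleration()].
#' @param path output file (columns `time`, `a_V`, `a_AP`).
#' @export
write_global_acceleration <- function(gacc, path) {
  utils::write.table(
    data.frame(time = gacc$timestamps, a_V = gacc$a_V, a_AP = gacc$a_AP),
    path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
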