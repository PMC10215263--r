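#' Detect the jump onset
#'
#' The onset `t_0` is the sample occurring `backshift` (default 30 ms)
#' before the first sample after the static window whose vertical
#' acceleration deviates from the static mean by more than `k` (default 8)
#' times the static-phase standard deviation.
#'
#' @param gacc a [global_acceleration()].
#' @param static_window length-2 interval (s) used for the baseline
#'   statistics (default `c(0.5, 2.5)`).
#' @param k threshold multiplier.
#' @param backshift back-shift applied to the first deviating sample (s).
#' @return onset time `t_0` (s), clamped to the recording start.
#' @export
detect_onset <- function(gacc, static_window = c(0.5, 2.5), k = 8,
                         backshift = 0.030) {
  idx <- window_idx(gacc$timestamps, static_window)
  if (length(idx) < 2)
    stop_sljump("sljump_segmentation_error", "static window contains < 2 samples")
  mu <- mean(gacc$a_V[idx]); sigma <- sd(gacc$a_V[idx])
  thr <- k * sigma
  after <- seq(max(idx) + 1L, length(gacc$timestamps))
  dev <- abs(gacc$a_V[after] - mu)
  hit <- which(dev > thr)
  if (!length(hit))
    stop_sljump("sljump_no_jump_error",
                "no sample deviates by more than %g x static SD: no jump detected", k)
  t_first <- gacc$timestamps[after[hit[1]]]
  max(t_first - backshift, gacc$timestamps[1])
}

#' Detect take-off
#'
#' Take-off `t_TO` is the first sample after `t_0` with `a_V <= -g`.  A
#' crossing occurring well before the vertical-velocity peak indicates a
#' corrupted (e.g. clipped) signal and is rejected.
#'
#' @param gacc a [global_acceleration()].
#' @param t_0 onset time (s).
#' @param check_velocity_peak reject crossings occurring before the
#'   vertical-velocity maximum (default `TRUE`).
#' @return take-off time `t_TO` (s).
#' @export
detect_takeoff <- function(gacc, t_0, check_velocity_peak = TRUE) {
  after <- which(gacc$timestamps > t_0)
  cross <- after[gacc$a_V[after] <= -gacc$g]
  if (!length(cross))
    stop_sljump("sljump_no_takeoff_error",
                "a_V never reaches -g after onset: no take-off detected")
  i_to <- cross[1]
  if (check_velocity_peak) {
    seg <- which(gacc$timestamps >= t_0 & gacc$timestamps <= gacc$timestamps[i_to])
    if (length(seg) >= 2) {
      v <- cumtrapz1(gacc$timestamps[seg], gacc$a_V[seg])
      if (v[length(v)] <= 0 || v[length(v)] < 0.6 * max(v))
        stop_sljump("sljump_invalid_jump_error",
                    "a_V <= -g reached before the vertical-velocity peak; jump flagged as invalid")
    }
  }
  gacc$timestamps[i_to]
}

#' Integrate velocity over the preparation phase
#'
#' Cumulative trapezoidal integral of `a_V` and `a_AP` on `[t_0, t_TO]`
#' with zero initial condition; the interval is kept to a minimum to limit
#' integration drift.
#'
#' @param gacc a [global_acceleration()].
#' @param t_0,t_TO onset and take-off times (s).
#' @return object of class `velocity_series` with fields `timestamps`,
#'   `v_V`, `v_AP` (m/s).
#' @export
integrate_velocity <- function(gacc, t_0, t_TO) {
  if (!(t_0 < t_TO))
    stop_sljump("sljump_segmentation_error", "t_0 must precede t_TO")
  idx <- which(gacc$timestamps >= t_0 & gacc$timestamps <= t_TO)
  if (length(idx) < 10)
    stop_sljump("sljump_segmentation_error",
                "integration interval has only %d samples (< 10)", length(idx))
  t <- gacc$timestamps[idx]
  structure(list(timestamps = t,
                 v_V = cumtrapz1(t, gacc$a_V[idx]),
                 v_AP = cumtrapz1(t, gacc$a_AP[idx]),
                 idx = idx),
            class = "velocity_series")
}

#' Mass-normalized mechanical power series
#'
#' Default definition `P_V = (a_V + g) v_V` (force per unit mass times
#' velocity, gravity included) and `P_AP = a_AP v_AP`; the gravity-free
#' variant `P_V = a_V v_V` is available via `include_gravity = FALSE`.
#'
#' @param gacc a [global_acceleration()].
#' @param vel a `velocity_series` from [integrate_velocity()].
#' @param include_gravity include the gravitational term in `P_V`.
#' @return object of class `power_series` with fields `timestamps`, `P_V`,
#'   `P_AP` (W/kg).
#' @export
compute_power <- function(gacc, vel, include_gravity = TRUE) {
  idx <- vel$idx
  a_V <- gacc$a_V[idx]; a_AP <- gacc$a_AP[idx]
  P_V <- if (include_gravity) (a_V + gacc$g) * vel$v_V else a_V * vel$v_V
  structure(list(timestamps = vel$timestamps,
                 P_V = P_V, P_AP = a_AP * vel$v_AP),
            class = "power_series")
}

#' Locate the jump sub-phase landmarks and signal extrema
#'
#' Landmarks: `t_UL` = minimum of `a_V` on `[t_0, t_UB]` (end of
#' unloading), `t_UB` = minimum of `v_V` (end of eccentric yielding),
#' `t_BP` = first upward zero-crossing of `v_V` after `t_UB` (end of
#' eccentric braking; linearly interpolated, snapped to the nearest
#' sample).  Also returns per-component extrema times of acceleration,
#' velocity and power over `[t_0, t_TO]`.
#'
#' @param gacc a [global_acceleration()].
#' @param vel a `velocity_series`.
#' @param power a `power_series`.
#' @return object of class `jump_events`.
#' @export
detect_phase_events <- function(gacc, vel, power) {
  t <- vel$timestamps
  t_0 <- t[1]; t_TO <- t[length(t)]
  i_UB <- which.min(vel$v_V)
  t_UB <- t[i_UB]
  a_V <- gacc$a_V[vel$idx]; a_AP <- gacc$a_AP[vel$idx]
  i_UL <- which.min(a_V[seq_len(i_UB)])
  t_UL <- t[i_UL]
  # first sign change of v_V from negative to non-negative after t_UB
  v <- vel$v_V
  cross <- NULL
  if (i_UB < length(v)) {
    for (i in seq(i_UB, length(v) - 1L)) {
      if (v[i] < 0 && v[i + 1] >= 0) { cross <- i; break }
    }
  }
  if (is.null(cross))
    stop_sljump("sljump_segmentation_error",
                "vertical velocity never crosses zero after t_UB")
  tz <- if (v[cross + 1] == 0) t[cross + 1] else
    t[cross] + (0 - v[cross]) / (v[cross + 1] - v[cross]) * (t[cross + 1] - t[cross])
  t_BP <- t[cross + which.min(abs(t[c(cross, cross + 1)] - tz)) - 1L]  # snap to nearest sample
  ext <- function(x) list(t_min = t[which.min(x)], t_max = t[which.max(x)])
  ev <- list(t_0 = t_0, t_UL = t_UL, t_UB = t_UB, t_BP = t_BP, t_TO = t_TO,
             a_V = ext(a_V), a_AP = ext(a_AP),
             v_V = ext(vel$v_V), v_AP = ext(vel$v_AP),
             P_V = ext(power$P_V), P_AP = ext(power$P_AP))
  check_event_order(ev)
  structure(ev, class = "jump_events")
}

check_event_order <- function(ev) {
  pairs <- list(c("t_0", "t_UL"), c("t_UL", "t_UB"), c("t_UB", "t_BP"), c("t_BP", "t_TO"))
  strict <- c(TRUE, FALSE, FALSE, TRUE)
  for (i in seq_along(pairs)) {
    a <- ev[[pairs[[i]][1]]]; b <- ev[[pairs[[i]][2]]]
    ok <- if (strict[i]) a < b else a <= b
    if (!ok)
      stop_sljump("sljump_segmentation_error",
                  "event ordering violated: %s (%.4f s) !%s %s (%.4f s)",
                  pairs[[i]][1], a, if (strict[i]) "<" else "<=", pairs[[i]][2], b)
  }
  invisible(TRUE)
}

#' @export
print.jump_events <- function(x, ...) {
  cat(sprintf("<jump_events> t_0=%.3f t_UL=%.3f t_UB=%.3f t_BP=%.3f t_TO=%.3f (s)\n",
              x$t_0, x$t_UL, x$t_UB, x$t_BP, x$t_TO))
  invisible(x)
}

#' Export jump events as an annotation table
#'
#' @param events a `jump_events` object.
#' @param gacc the [global_acceleration()] the events refer to (used for
#'   0-based sample indices).
#' @param jump_id identifier column value.
#' @return data frame with columns `jump_id`, `event`, `time_s`,
#'   `sample_index` (0-based).
#' @export
events_table <- function(events, gacc, jump_id = "jump") {
  nm <- c("t_0", "t_UL", "t_UB", "t_BP", "t_TO")
  tms <- unlist(events[nm])
  data.frame(jump_id = jump_id, event = nm, time_s = as.numeric(tms),
             sample_index = vapply(tms, function(tt)
               which.min(abs(gacc$timestamps - tt)) - 1L, integer(1)),
             row.names = NULL)
}
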