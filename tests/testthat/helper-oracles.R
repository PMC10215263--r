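# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths (straight-line loops, brute-force numerics).

# Numerically integrated point-mass projectile: launch with (v_h, v_v) from
# height 0, gravity g; returns range, apex height and flight duration at
# landing (z back to 0).  Fine fixed-step RK4 with linear crossing
# interpolation.
oracle_projectile <- function(v_v, v_h, g = 9.81, dt = 1e-5) {
  t <- seq(dt, 3 * v_v / g, by = dt)
  z <- v_v * t - 0.5 * g * t^2            # exact stepping of z'' = -g on a grid
  i <- which(z <= 0)[1]                   # first grid point at/below ground
  frac <- z[i - 1] / (z[i - 1] - z[i])
  t_land <- t[i - 1] + frac * dt
  list(range = v_h * t_land, apex = max(z), duration = t_land)
}

# Straight-line reimplementation of the 48 biomechanical/power features,
# written independently of biomechanical_features() (plain loops over the
# sample arrays).
oracle_biomech <- function(t, a_V, a_AP, v_V, v_AP, P_V, P_AP, ev) {
  dt <- stats::median(diff(t))
  one <- function(a, v, P) {
    n <- length(t)
    i_amin <- 1; i_amax <- 1; i_vmin <- 1; i_pmin <- 1; i_pmax <- 1
    for (i in seq_len(n)) {
      if (a[i] < a[i_amin]) i_amin <- i
      if (a[i] > a[i_amax]) i_amax <- i
      if (v[i] < v[i_vmin]) i_vmin <- i
      if (P[i] < P[i_pmin]) i_pmin <- i
      if (P[i] > P[i_pmax]) i_pmax <- i
    }
    D <- 0; M <- 0
    for (i in seq_len(n)) {
      if (a[i] > 0) D <- D + dt
      if (P[i] > 0) M <- M + dt
    }
    i_UB <- which.min(abs(t - ev$t_UB))
    j <- NA
    for (i in seq_len(n)) if (a[i] > 0 && t[i] < t[n]) j <- i
    q <- NA_real_
    if (!is.na(j) && j > i_UB) {
      area <- 0
      for (i in i_UB:(j - 1))
        area <- area + (a[i] + a[i + 1]) / 2 * (t[i + 1] - t[i])
      q <- area / (D * a[i_amax])
    }
    i_BP <- which.min(abs(t - ev$t_BP))
    ucnt <- 0; usum <- 0; zcnt <- 0; zsum <- 0
    for (i in seq_len(n)) {
      if (t[i] >= ev$t_BP && t[i] <= ev$t_TO) { ucnt <- ucnt + 1; usum <- usum + P[i] }
      if (t[i] <= ev$t_BP) { zcnt <- zcnt + 1; zsum <- zsum + P[i] }
    }
    list(b = a[i_amin], e = a[i_amax], C = t[i_amax] - t[i_amin],
         da = a[i_amax] - a[i_amin], dv = max(v) - min(v), D = D,
         F = t[n] - t[i_amax], J = ev$t_BP - t[i_vmin], k = a[i_BP],
         l = P[i_pmin], n = P[i_pmax], M = M, O = t[n] - t[i_pmax],
         p = (a[i_amax] - a[i_amin]) / (t[i_amax] - t[i_amin]),
         q = q, r = a[i_amin] / a[i_amax], u = usum / ucnt, nu = v[i_vmin],
         W = t[i_pmax] - t[i_pmin], z = zsum / zcnt,
         t_pmin = t[i_pmin], t_pmax = t[i_pmax])
  }
  V <- one(a_V, v_V, P_V)
  AP <- one(a_AP, v_AP, P_AP)
  pre <- which(t <= ev$t_BP)
  i_V <- -Inf
  for (i in pre[-length(pre)])
    i_V <- max(i_V, (a_V[i + 1] - a_V[i]) / (t[i + 1] - t[i]))
  list(V = V, AP = AP,
       A_V = ev$t_UB - ev$t_0, G_V = ev$t_TO - ev$t_0, i_V = i_V,
       Q_V = ev$t_TO - ev$t_BP, L_AP = AP$t_pmax - AP$t_pmin, R_AP = AP$M,
       H = ev$t_BP - ev$t_UL)
}

# Static recording helper: axis `up` carries +g, with optional affine
# corruption and noise.
make_static_rec <- function(up = 3, duration = 10, fs = 500, g = 9.81,
                            offset = c(0, 0, 0), scale = c(1, 1, 1),
                            noise = 0.03, gyro_bias = NULL, gyro_noise = 0.1,
                            seed = 1) {
  withr::with_seed(seed, {
    tt <- seq(0, duration, by = 1 / fs)
    truth <- matrix(0, length(tt), 3)
    truth[, up] <- g
    meas <- sweep(truth %*% diag(scale), 2, offset, `+`)
    if (noise > 0) meas <- meas + matrix(rnorm(3 * length(tt), 0, noise), ncol = 3)
    gyro <- NULL
    if (!is.null(gyro_bias)) {
      gyro <- matrix(rnorm(3 * length(tt), 0, gyro_noise), ncol = 3)
      gyro <- sweep(gyro, 2, gyro_bias, `+`)
    }
    imu_recording(tt, meas, gyro)
  })
}

# Segment one simulated jump with the live pipeline and return everything.
segment_jump <- function(aj, static_window = c(0.5, 2.5)) {
  g <- to_global_frame(aj$recording, static_window)
  t0 <- detect_onset(g, static_window)
  tTO <- detect_takeoff(g, t0)
  vel <- integrate_velocity(g, t0, tTO)
  pw <- compute_power(g, vel)
  ev <- detect_phase_events(g, vel, pw)
  list(gacc = g, t_0 = t0, t_TO = tTO, vel = vel, power = pw, events = ev)
}
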