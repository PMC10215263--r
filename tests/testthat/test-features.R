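test_that("ballistic formulas match a numerically integrated projectile", {
  bf <- ballistic_features(2.0, 2.0)
  expect_equal(bf$alpha, 45)

  bf <- ballistic_features(2.0, 3.0)
  orac <- oracle_projectile(2.0, 3.0)
  expect_equal(bf$b_jump, orac$range, tolerance = 1e-3)
  expect_equal(bf$h_jump, orac$apex, tolerance = 1e-3)
  expect_equal(bf$t_flight, orac$duration, tolerance = 1e-3)
  expect_equal(bf$b_jump, 1.2232, tolerance = 1e-3)
  expect_equal(bf$t_flight, 0.4077, tolerance = 1e-3)
  expect_equal(bf$h_jump, 0.2039, tolerance = 1e-3)

  # limit: v_AP -> 0+ gives alpha -> 90, b_jump -> 0
  bf <- ballistic_features(2.0, 1e-9)
  expect_equal(bf$alpha, 90, tolerance = 1e-6)
  expect_lt(bf$b_jump, 1e-8)

  expect_error(ballistic_features(-1, 2), class = "sljump_invalid_jump_error")
})

test_that("ballistic formulas track the projectile oracle over random pairs", {
  set.seed(101)
  for (i in 1:50) {
    v_v <- runif(1, 1.0, 3.5); v_h <- runif(1, 1.0, 5.0)
    bf <- ballistic_features(v_v, v_h)
    orac <- oracle_projectile(v_v, v_h)
    expect_lt(abs(bf$b_jump - orac$range) / orac$range, 1e-3)
    expect_lt(abs(bf$h_jump - orac$apex) / orac$apex, 1e-3)
    expect_lt(abs(bf$t_flight - orac$duration) / orac$duration, 1e-3)
  }
})

test_that("VMD recovers known tone frequencies and the DC mode", {
  fs <- 500
  t <- seq(0, 2, by = 1 / fs)
  x <- sin(2 * pi * 5 * t) + 0.8 * sin(2 * pi * 40 * t) + 0.6 * sin(2 * pi * 120 * t)
  f <- vmd_features(x, fs)
  expect_equal(unname(f), c(120, 40, 5), tolerance = 0.1)

  # the extracted modes reconstruct the band-limited signal
  recon <- rowSums(vmd(x, K = 3, fs = fs)$modes)
  expect_lt(sqrt(mean((recon - x)^2)) / sd(x), 0.05)

  f1 <- vmd_features(sin(2 * pi * 10 * t), fs)
  expect_equal(unname(f1[["f3"]]), 10, tolerance = 0.1 * 10)

  fc <- vmd_features(rep(2, 256), fs)
  expect_lt(fc[["f3"]], 0.5)

  expect_error(vmd_features(rnorm(10), fs), class = "sljump_feature_error")
})

test_that("triangular and rectangular acceleration templates give the hand-computed features", {
  # triangular a_V pulse: min -2 at t = 0.1, max +4 at t = 0.3
  dt <- 1 / 500
  t <- seq(0, 0.6, by = dt)
  a <- numeric(length(t))
  ramp <- function(x, x0, x1, y0, y1) y0 + (x - x0) / (x1 - x0) * (y1 - y0)
  a[t <= 0.1] <- ramp(t[t <= 0.1], 0, 0.1, 0, -2)
  sel <- t > 0.1 & t <= 0.3
  a[sel] <- ramp(t[sel], 0.1, 0.3, -2, 4)
  sel <- t > 0.3 & t <= 0.45
  a[sel] <- ramp(t[sel], 0.3, 0.45, 4, 0)
  g <- global_acceleration(t, a, a)
  vel <- integrate_velocity(g, 0, max(t))
  pw <- compute_power(g, vel)
  ev <- detect_phase_events(g, vel, pw)
  feats <- biomechanical_features(g, vel, pw, ev)
  expect_equal(feats$da_V, 6)
  expect_equal(feats$C_V, 0.2, tolerance = dt)
  expect_equal(feats$p_V, 30, tolerance = 0.5)
  expect_equal(feats$r_V, -0.5, tolerance = 1e-6)
  expect_equal(feats$b_V, -2)
  expect_equal(feats$e_V, 4)

  # rectangular positive pulse: shape factor q = 1 over its bounding box
  a2 <- numeric(length(t))
  a2[t <= 0.12] <- ramp(t[t <= 0.12], 0, 0.12, 0, -1.5)
  a2[t > 0.12 & t <= 0.2] <- ramp(t[t > 0.12 & t <= 0.2], 0.12, 0.2, -1.5, 0)
  a2[t > 0.2 & t < 0.5] <- 3                     # rectangle, height e, width D
  g2 <- global_acceleration(t, a2, a2)
  vel2 <- integrate_velocity(g2, 0, max(t))
  pw2 <- compute_power(g2, vel2)
  ev2 <- detect_phase_events(g2, vel2, pw2)
  feats2 <- biomechanical_features(g2, vel2, pw2, ev2)
  expect_equal(feats2$q_V, 1, tolerance = 0.02)
})

test_that("live features equal an independent straight-line reimplementation", {
  for (s in c(5, 21)) {
    aj <- simulate_jump(jump_scenario(v_takeoff = 4.1 + s / 50, seed = s))
    seg <- segment_jump(aj)
    feats <- biomechanical_features(seg$gacc, seg$vel, seg$power, seg$events)
    expect_true(all(vapply(feats, is.finite, logical(1))))
    t <- seg$vel$timestamps
    o <- oracle_biomech(t, seg$gacc$a_V[seg$vel$idx], seg$gacc$a_AP[seg$vel$idx],
                        seg$vel$v_V, seg$vel$v_AP, seg$power$P_V, seg$power$P_AP,
                        seg$events)
    tol <- 1e-9
    expect_equal(feats$b_V, o$V$b, tolerance = tol)
    expect_equal(feats$b_AP, o$AP$b, tolerance = tol)
    expect_equal(feats$e_V, o$V$e, tolerance = tol)
    expect_equal(feats$C_V, o$V$C, tolerance = tol)
    expect_equal(feats$da_V, o$V$da, tolerance = tol)
    expect_equal(feats$dv_AP, o$AP$dv, tolerance = tol)
    expect_equal(feats$D_V, o$V$D, tolerance = tol)
    expect_equal(feats$F_V, o$V$F, tolerance = tol)
    expect_equal(feats$G_V, o$G_V, tolerance = tol)
    expect_equal(feats$H_V, o$H, tolerance = tol)
    expect_equal(feats$i_V, o$i_V, tolerance = tol)
    expect_equal(feats$J_AP, o$AP$J, tolerance = tol)
    expect_equal(feats$k_V, o$V$k, tolerance = tol)
    expect_equal(feats$l_V, o$V$l, tolerance = tol)
    expect_equal(feats$l_AP_pow, o$AP$l, tolerance = tol)
    expect_equal(feats$L_AP, o$L_AP, tolerance = tol)
    expect_equal(feats$M_V, o$V$M, tolerance = tol)
    expect_equal(feats$n_V, o$V$n, tolerance = tol)
    expect_equal(feats$O_AP, o$AP$O, tolerance = tol)
    expect_equal(feats$p_V, o$V$p, tolerance = tol)
    expect_equal(feats$q_V, o$V$q, tolerance = tol)
    expect_equal(feats$Q_V, o$Q_V, tolerance = tol)
    expect_equal(feats$r_AP, o$AP$r, tolerance = tol)
    expect_equal(feats$R_AP, o$R_AP, tolerance = tol)
    expect_equal(feats$u_V, o$V$u, tolerance = tol)
    expect_equal(feats$nu_V, o$V$nu, tolerance = tol)
    expect_equal(feats$W_AP, o$AP$W, tolerance = tol)
    expect_equal(feats$z_V, o$V$z, tolerance = tol)
    expect_equal(feats$A_V, o$A_V, tolerance = tol)
  }
})

test_that("time features are shift-invariant and amplitude features scale-equivariant", {
  aj <- simulate_jump(jump_scenario(seed = 61))
  seg <- segment_jump(aj)
  f1 <- biomechanical_features(seg$gacc, seg$vel, seg$power, seg$events)

  shift <- 12.5
  # anchor on grid samples so float re-rounding cannot move the window
  t0g <- seg$vel$timestamps[1]
  tTOg <- seg$vel$timestamps[length(seg$vel$timestamps)]
  g2 <- global_acceleration(seg$gacc$timestamps + shift, seg$gacc$a_V, seg$gacc$a_AP)
  vel2 <- integrate_velocity(g2, t0g + shift, tTOg + shift)
  pw2 <- compute_power(g2, vel2)
  ev2 <- detect_phase_events(g2, vel2, pw2)
  f2 <- biomechanical_features(g2, vel2, pw2, ev2)
  for (nm in c("A_V", "C_V", "D_V", "F_V", "G_V", "H_V", "J_V", "Q_V",
               "M_AP", "O_AP", "W_V", "L_AP"))
    expect_equal(f2[[nm]], f1[[nm]], tolerance = 1e-9, label = nm)

  # doubling the acceleration doubles the amplitude features
  k <- 2
  g3 <- global_acceleration(seg$gacc$timestamps, k * seg$gacc$a_V, k * seg$gacc$a_AP)
  vel3 <- integrate_velocity(g3, seg$t_0, seg$t_TO)
  pw3 <- compute_power(g3, vel3, include_gravity = FALSE)
  ev3 <- detect_phase_events(g3, vel3, pw3)
  f3 <- biomechanical_features(g3, vel3, pw3, ev3)
  for (nm in c("b_V", "e_V", "da_V", "b_AP", "e_AP", "da_AP", "k_V"))
    expect_equal(f3[[nm]], k * f1[[nm]], tolerance = 1e-9, label = nm)
  expect_equal(f3$dv_V, k * f1$dv_V, tolerance = 1e-9)
})

test_that("b_jump grows monotonically with the programmed take-off speed", {
  speeds <- seq(3.6, 5.2, length.out = 8)
  est <- vapply(seq_along(speeds), function(i) {
    aj <- simulate_jump(jump_scenario(v_takeoff = speeds[i], noise_acc = 0,
                                      noise_gyro = 0, seed = 70))
    seg <- segment_jump(aj)
    ballistic_features(seg$vel$v_V[length(seg$vel$v_V)],
                       seg$vel$v_AP[length(seg$vel$v_AP)])$b_jump
  }, numeric(1))
  expect_equal(cor(est, speeds, method = "spearman"), 1)
})

test_that("feature vectors assemble to 61 entries and flag incomplete jumps", {
  aj <- simulate_jump(jump_scenario(seed = 81))
  res <- process_jump(aj$recording, anthropometrics(1.75, 68, 23),
                      l_meter = aj$truth$l_meter)
  expect_false(res$excluded)
  expect_equal(ncol(res$features), 62)            # 61 features + l_meter
  expect_identical(names(res$features)[1:61], feature_names())
  expect_false(anyNA(res$features))

  # a flagged-missing biomechanical part marks the record excluded
  bio <- biomechanical_features(res$gacc, res$velocity, res$power, res$events)
  bio$q_V <- NA_real_
  attr(bio, "flagged") <- "q_V"
  fv <- assemble_feature_vector(
    anthropometrics(1.75, 68, 23),
    ballistic_features(2.2, 3.4),
    bio,
    c(f1 = 20, f2 = 5, f3 = 1), c(f1 = 18, f2 = 4, f3 = 1), 1.9)
  expect_true(isTRUE(attr(fv, "excluded")))
})

test_that("feature tables round-trip through the delimited format with units sidecar", {
  coh <- simulate_cohort(6, seed = 99)
  p <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(coh$features, p)
  expect_true(file.exists(paste0(p, ".meta")))
  back <- read_feature_table(p)
  expect_equal(dim(back), dim(coh$features))
  expect_equal(back$b_jump, coh$features$b_jump, tolerance = 1e-6)
})
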