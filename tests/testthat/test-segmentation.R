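make_gacc <- function(t, a_V, a_AP = NULL) {
  global_acceleration(t, a_V, a_AP %||% numeric(length(t)))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("onset detection applies the 8 x SD rule with the 30 ms back-shift", {
  t <- seq(0, 5, by = 1 / 500)
  a <- withr::with_seed(1, rnorm(length(t), 0, 0.05))
  a[t >= 3.0] <- a[t >= 3.0] + 2
  t0 <- detect_onset(make_gacc(t, a), c(0.5, 2.5))
  expect_equal(t0, 2.970, tolerance = 0.003)

  # pure noise: no jump
  a2 <- withr::with_seed(2, rnorm(length(t), 0, 0.05))
  expect_error(detect_onset(make_gacc(t, a2), c(0.5, 2.5)),
               class = "sljump_no_jump_error")

  # simulated jump: within 40 ms of the programmed movement start
  aj <- simulate_jump(jump_scenario(seed = 3))
  g <- to_global_frame(aj$recording, c(0.5, 2.5))
  expect_lt(abs(detect_onset(g, c(0.5, 2.5)) - aj$truth$events$t_0), 0.040)
})

test_that("take-off is the first frame with a_V <= -g", {
  t <- seq(0, 4, by = 1 / 500)
  a <- rep(1, length(t))
  a[1500:length(t)] <- -9.81
  g <- make_gacc(t, a)
  expect_equal(detect_takeoff(g, t[200], check_velocity_peak = FALSE), t[1500])
  expect_error(detect_takeoff(make_gacc(t, rep(1, length(t))), t[200]),
               class = "sljump_no_takeoff_error")
})

test_that("velocity integration matches closed forms and is linear", {
  t <- seq(0, 1, by = 1 / 500)
  g1 <- make_gacc(t, rep(1, length(t)))
  vel <- integrate_velocity(g1, 0, 1)
  expect_equal(vel$v_V[length(vel$v_V)], 1.0, tolerance = 1e-12)
  expect_equal(vel$v_V[1], 0)

  g2 <- make_gacc(t, sin(2 * pi * t))
  vel2 <- integrate_velocity(g2, 0, 1)
  expect_lt(abs(vel2$v_V[length(vel2$v_V)]), (1 / 500)^2 * 50)

  # linearity: integral of (a+b) = integral a + integral b (to round-off)
  a <- withr::with_seed(7, rnorm(length(t)))
  b <- withr::with_seed(8, rnorm(length(t)))
  va <- integrate_velocity(make_gacc(t, a), 0, 1)$v_V
  vb <- integrate_velocity(make_gacc(t, b), 0, 1)$v_V
  vab <- integrate_velocity(make_gacc(t, a + b), 0, 1)$v_V
  expect_equal(vab, va + vb, tolerance = 1e-12)

  expect_error(integrate_velocity(g1, 0, 0.01), class = "sljump_segmentation_error")

  # simulator ground truth: take-off velocity within 0.05 m/s (noise 0.05)
  aj <- simulate_jump(jump_scenario(v_takeoff = 4.2, angle_deg = 33, seed = 9))
  seg <- segment_jump(aj)
  expect_lt(abs(seg$vel$v_V[length(seg$vel$v_V)] - aj$truth$v_V_TO), 0.05)
})

test_that("power series follow the (a_V + g) v_V definition", {
  t <- seq(0, 1, by = 1 / 500)
  g0 <- make_gacc(t, rep(0, length(t)))
  vel <- integrate_velocity(g0, 0, 1)
  pw <- compute_power(g0, vel)
  expect_equal(pw$P_V, rep(0, length(t)) + 9.81 * vel$v_V)  # v = 0 throughout
  expect_true(all(pw$P_V == 0))

  # hand case: a_V = 0, v_V = 1 -> P_V = g
  vel$v_V <- rep(1, length(t)); vel$v_AP <- rep(0.5, length(t))
  pw <- compute_power(g0, vel)
  expect_equal(pw$P_V, rep(9.81, length(t)))
  expect_equal(pw$P_AP, rep(0, length(t)))

  # random series equal the sample-by-sample product oracle, both variants
  a <- withr::with_seed(3, rnorm(length(t)))
  ga <- make_gacc(t, a, withr::with_seed(4, rnorm(length(t))))
  vel <- integrate_velocity(ga, 0, 1)
  pw <- compute_power(ga, vel)
  expect_equal(pw$P_V, (a + 9.81) * vel$v_V, tolerance = 1e-12)
  pw2 <- compute_power(ga, vel, include_gravity = FALSE)
  expect_equal(pw2$P_V, a * vel$v_V, tolerance = 1e-12)
})

test_that("phase events land on the template landmarks and enforce ordering", {
  # analytic template: a_V dip with minimum at exactly t = 0.20 s
  t <- seq(0, 1.2, by = 1 / 500)
  a <- -3 * sin(pi * pmin(t, 0.4) / 0.4)^2
  a[t > 0.4] <- 8 * sin(pi * pmin(t[t > 0.4] - 0.4, 0.4) / 0.4)^2
  g <- make_gacc(t, a)
  vel <- integrate_velocity(g, 0, max(t))
  pw <- compute_power(g, vel)
  ev <- detect_phase_events(g, vel, pw)
  expect_equal(ev$t_UL, 0.20, tolerance = 1 / 500)
  # v_V crosses zero where the positive lobe has re-integrated the dip
  vz <- t[max(which(vel$v_V < 0))]
  expect_equal(ev$t_BP, vz, tolerance = 1.01 / 500)
  expect_true(ev$t_0 < ev$t_UL && ev$t_UL <= ev$t_UB &&
                ev$t_UB <= ev$t_BP && ev$t_BP < ev$t_TO)

  # monotone negative velocity: no crossing -> segmentation error
  g2 <- make_gacc(t, rep(-0.5, length(t)))
  vel2 <- integrate_velocity(g2, 0, max(t))
  pw2 <- compute_power(g2, vel2)
  expect_error(detect_phase_events(g2, vel2, pw2),
               class = "sljump_segmentation_error")
})

test_that("noise-free simulator landmarks match ground truth within a sample", {
  dt <- 1 / 500
  for (s in 1:12) {
    scn <- withr::with_seed(s, jump_scenario(
      v_takeoff = runif(1, 3.8, 5.0), angle_deg = runif(1, 25, 40),
      dip_velocity = runif(1, 0.6, 1.2), tilt_deg = runif(1, -10, 10),
      noise_acc = 0, noise_gyro = 0, seed = s))
    aj <- simulate_jump(scn)
    seg <- segment_jump(aj)
    tr <- aj$truth$events
    expect_lt(abs(seg$t_0 - tr$t_0), 0.030 + dt)
    expect_lt(abs(seg$events$t_UL - tr$t_UL), dt + 1e-9)
    expect_lt(abs(seg$events$t_UB - tr$t_UB), dt + 1e-9)
    expect_lt(abs(seg$events$t_BP - tr$t_BP), dt + 1e-9)
    expect_lt(abs(seg$t_TO - tr$t_TO), dt + 1e-9)
  }
})

test_that("phase ordering holds across 1000 random noisy scenarios", {
  ok <- vapply(1:1000, function(s) {
    aj <- simulate_jump(withr::with_seed(1000 + s, jump_scenario(
      v_takeoff = runif(1, 3.6, 5.2), angle_deg = runif(1, 20, 45),
      dip_velocity = runif(1, 0.5, 1.4), tilt_deg = runif(1, -15, 15),
      yaw_deg = runif(1, -180, 180), seed = 1000 + s)))
    ev <- segment_jump(aj)$events
    ev$t_0 < ev$t_UL && ev$t_UL <= ev$t_UB &&
      ev$t_UB <= ev$t_BP && ev$t_BP < ev$t_TO
  }, logical(1))
  expect_true(all(ok))
})

test_that("events export as a 0-based annotation table", {
  aj <- simulate_jump(jump_scenario(seed = 77))
  seg <- segment_jump(aj)
  tab <- events_table(seg$events, seg$gacc, jump_id = "j77")
  expect_equal(nrow(tab), 5)
  expect_equal(tab$event, c("t_0", "t_UL", "t_UB", "t_BP", "t_TO"))
  expect_true(all(tab$sample_index >= 0))
  expect_equal(seg$gacc$timestamps[tab$sample_index + 1], tab$time_s,
               tolerance = 1 / 500)
})
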