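test_that("read_recording parses Phyphox-style files and estimates the rate", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Time (s),X,Y,Z",
               "0,0.1,0.2,9.8", "0.002,0.1,0.2,9.8",
               "0.004,0.1,0.2,9.8", "0.006,0.1,0.2,9.8"), p)
  rec <- read_recording(p)
  expect_equal(n_samples(rec), 4)
  expect_equal(rec$sampling_rate, 500, tolerance = 1e-6)
  expect_equal(unname(rec$acc[1, ]), c(0.1, 0.2, 9.8))
})

test_that("write-then-read round-trips a simulated recording on the shared grid", {
  aj <- simulate_jump(jump_scenario(seed = 12))
  ap <- withr::local_tempfile(fileext = ".csv")
  gp <- withr::local_tempfile(fileext = ".csv")
  write_recording(aj$recording, ap, gp)
  rec2 <- read_recording(ap, gp)
  expect_equal(rec2$timestamps, aj$recording$timestamps, tolerance = 1e-12)
  expect_equal(rec2$acc, aj$recording$acc, tolerance = 1e-12)
  expect_equal(rec2$gyro, aj$recording$gyro, tolerance = 1e-12)
})

test_that("malformed sensor files raise format/data errors", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Time (s),X,Y,Z", "0.006,1,2,3", "0.004,1,2,3", "0.002,1,2,3"), p)
  expect_error(read_recording(p), class = "sljump_data_error")
  p2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Time (s),A,B,C", "0,1,2,3"), p2)
  expect_error(read_recording(p2), class = "sljump_format_error")
})

test_that("gyro bias estimation matches the static mean and its sampling error", {
  tt <- seq(0, 2, by = 1 / 500)
  acc <- matrix(rep(c(0, 0, 9.81), each = length(tt)), ncol = 3)
  gyro <- matrix(rep(c(0.3, -0.1, 0.05), each = length(tt)), ncol = 3)
  cal <- estimate_gyro_bias(imu_recording(tt, acc, gyro))
  expect_equal(unname(cal$bias), c(0.3, -0.1, 0.05))

  # white noise: bias within 4 sigma / sqrt(n) of zero per axis
  n <- 30000; sdg <- 0.5
  rec <- withr::with_seed(4, {
    tt <- seq(0, by = 1 / 500, length.out = n)
    imu_recording(tt, matrix(rep(c(0, 0, 9.81), each = n), ncol = 3),
                  matrix(rnorm(3 * n, 0, sdg), ncol = 3))
  })
  cal <- estimate_gyro_bias(rec)
  expect_true(all(abs(cal$bias) < 4 * sdg / sqrt(n)))

  # injected bias recovered; motion raises a calibration error
  rec <- make_static_rec(gyro_bias = c(1.2, 0, 0), seed = 5)
  expect_equal(estimate_gyro_bias(rec)$bias[[1]], 1.2, tolerance = 0.05)
  moving <- imu_recording(tt <- seq(0, 2, by = 1 / 500),
                          matrix(rep(c(0, 0, 9.81), each = length(tt)), ncol = 3),
                          cbind(40 * sin(2 * pi * tt), 0, 0))
  expect_error(estimate_gyro_bias(moving), class = "sljump_calibration_error")
})

test_that("accelerometer calibration recovers offset and scale; ideal sensor maps to identity", {
  ideal <- calibrate_accelerometer(make_static_rec(1, seed = 1),
                                   make_static_rec(2, seed = 2),
                                   make_static_rec(3, seed = 3))
  expect_equal(ideal$offset, c(0, 0, 0), tolerance = 5e-3)
  expect_equal(ideal$sensitivity, diag(3), tolerance = 5e-3)

  off <- c(0.2, -0.1, 0.3); scl <- c(1.01, 0.99, 1.02)
  cal <- calibrate_accelerometer(
    make_static_rec(1, offset = off, scale = scl, seed = 11),
    make_static_rec(2, offset = off, scale = scl, seed = 12),
    make_static_rec(3, offset = off, scale = scl, seed = 13))
  # three orientations identify the model up to a one-dimensional trade-off;
  # scales recover to < 1%, offsets to < 0.5% of g
  expect_equal(diag(cal$sensitivity), scl, tolerance = 0.01)
  expect_true(all(abs(cal$offset - off) < 0.05))

  # applying the estimated calibration puts the gravity-aligned axis at g
  rec <- apply_calibration(make_static_rec(1, offset = off, scale = scl, seed = 14), cal)
  expect_equal(mean(rec$acc[, 1]), 9.81, tolerance = 0.005 * 9.81)
})

test_that("rank-deficient calibration designs are rejected", {
  expect_error(
    calibrate_accelerometer(make_static_rec(1, seed = 1),
                            make_static_rec(1, seed = 2),
                            make_static_rec(3, seed = 3)),
    class = "sljump_calibration_error")
})

test_that("apply_calibration is identity for identity calibration and subtracts offsets", {
  rec <- make_static_rec(3, seed = 21)
  out <- apply_calibration(rec, accel_calibration())
  expect_equal(out$acc, rec$acc)
  out <- apply_calibration(rec, accel_calibration(offset = c(1, 2, 3)))
  expect_equal(out$acc, sweep(rec$acc, 2, c(1, 2, 3)))
})

test_that("corrupt-then-calibrate-then-apply returns the identity (no noise)", {
  off <- c(0.12, -0.4, 0.2); scl <- c(1.02, 0.97, 1.01)
  recs <- lapply(1:3, function(k)
    make_static_rec(k, offset = off, scale = scl, noise = 0, seed = k))
  cal <- calibrate_accelerometer(recs[[1]], recs[[2]], recs[[3]])
  for (k in 1:3) {
    out <- apply_calibration(recs[[k]], cal)
    truth <- matrix(0, n_samples(out), 3); truth[, k] <- 9.81
    expect_equal(unname(out$acc), truth, tolerance = 1e-8)
  }
})

test_that("to_global_frame zeroes statics, corrects tilt and preserves free fall", {
  # level phone at rest
  rec <- make_static_rec(3, duration = 4, seed = 31)
  g <- to_global_frame(rec, c(0.5, 2.5))
  expect_lt(abs(mean(g$a_V)), 0.01)
  expect_lt(abs(mean(g$a_AP)), 0.01)

  # pitched 20 degrees, at rest: tilt corrected
  aj <- simulate_jump(jump_scenario(v_takeoff = 0, tilt_deg = 20, tail = 2, seed = 32))
  g <- to_global_frame(aj$recording, c(0.5, 2.5))
  expect_lt(abs(mean(g$a_V)), 0.01)

  # free-fall segment reads -g throughout
  aj <- simulate_jump(jump_scenario(noise_acc = 0, noise_gyro = 0, seed = 33))
  g <- to_global_frame(aj$recording, c(0.5, 2.5))
  tr <- aj$truth$events
  inflight <- g$timestamps > tr$t_TO + 0.01 & g$timestamps < tr$t_land - 0.01
  expect_equal(g$a_V[inflight], rep(-9.81, sum(inflight)), tolerance = 1e-6)

  # static specific force far from g is rejected
  bad <- make_static_rec(3, scale = c(1, 1, 1.2), seed = 34)
  expect_error(to_global_frame(bad, c(0.5, 2.5)), class = "sljump_orientation_error")
})

test_that("to_global_frame is invariant to yaw and the pipeline round-trips the simulator", {
  # yaw invariance is a property of the geometry: check it noise-free
  base <- jump_scenario(noise_acc = 0, noise_gyro = 0, tilt_deg = 8,
                        yaw_deg = 0, seed = 41)
  rot <- jump_scenario(noise_acc = 0, noise_gyro = 0, tilt_deg = 8,
                       yaw_deg = 117, seed = 41)
  g1 <- to_global_frame(simulate_jump(base)$recording, c(0.5, 2.5))
  g2 <- to_global_frame(simulate_jump(rot)$recording, c(0.5, 2.5))
  expect_equal(g1$a_V, g2$a_V, tolerance = 1e-8)
  expect_equal(abs(g1$a_AP), abs(g2$a_AP), tolerance = 1e-6)

  # round-trip: corrupt (tilt, offset, scale, bias) -> calibrate ->
  # to_global_frame recovers the ground-truth series
  off <- c(0.15, -0.1, 0.2); scl <- c(1.015, 0.99, 1.01)
  cal <- calibrate_accelerometer(
    make_static_rec(1, offset = off, scale = scl, noise = 0.03, seed = 141),
    make_static_rec(2, offset = off, scale = scl, noise = 0.03, seed = 142),
    make_static_rec(3, offset = off, scale = scl, noise = 0.03, seed = 143))
  scn <- jump_scenario(noise_acc = 0.05, tilt_deg = 6, yaw_deg = 30,
                       acc_offset = off, acc_scale = scl,
                       gyro_bias = c(1.2, -0.4, 0.7), seed = 42)
  aj <- simulate_jump(scn)
  rec <- apply_calibration(aj$recording, cal)
  g <- to_global_frame(rec, c(0.5, 2.5))
  keep <- g$timestamps <= aj$truth$events$t_TO
  expect_lt(sqrt(mean((g$a_V[keep] - aj$truth$a_V[keep])^2)), 0.1)
  expect_lt(sqrt(mean((g$a_AP[keep] - aj$truth$a_AP[keep])^2)), 0.1)
})

test_that("calibration files round-trip through the key-value format", {
  acc <- accel_calibration(c(0.1, 0.2, -0.3), diag(c(1.01, 0.99, 1.02)))
  gyr <- structure(list(bias = c(1.2, -0.4, 0.7)), class = "gyro_calibration")
  p <- withr::local_tempfile(fileext = ".txt")
  write_calibration(acc, gyr, p)
  back <- read_calibration(p)
  expect_equal(back$acc_cal$offset, acc$offset)
  expect_equal(back$acc_cal$sensitivity, acc$sensitivity)
  expect_equal(back$gyro_cal$bias, gyr$bias)
})
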