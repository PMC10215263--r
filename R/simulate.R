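#' Define a synthetic standing-long-jump scenario
#'
#' All the knobs of the physics-based jump generator: anthropometrics,
#' programmed take-off velocity and angle, preparation sub-phase durations,
#' sensor corruption (tilt, yaw, offsets, scale and cross-axis error, gyro
#' bias, additive noise, full-scale clipping) and the reference-length
#' noise model.  The defaults emulate a trained young adult jumping ~1.8 m
#' while holding a phone at the hip, recorded at 500 samples/s with full
#' scales of 8 g and 500 deg/s.
#'
#' @param stature,mass,age anthropometrics (m, kg, years).
#' @param v_takeoff take-off speed magnitude (m/s); 0 produces a
#'   zero-motion (static) recording.
#' @param angle_deg take-off velocity angle above horizontal (deg).
#' @param dip_velocity peak downward speed of the countermovement (m/s).
#' @param static,unloading,yielding,braking,propulsion,landing,tail phase
#'   durations (s); flight duration follows from ballistics.
#' @param sampling_rate samples/s.
#' @param full_scale_acc,full_scale_gyro sensor full scales (m/s^2, deg/s).
#' @param noise_acc,noise_gyro additive white-noise SDs (m/s^2, deg/s).
#' @param tilt_deg,yaw_deg sensor attitude relative to the global frame.
#' @param acc_offset length-3 accelerometer offset (m/s^2).
#' @param acc_scale length-3 diagonal sensitivity.
#' @param cross_axis scalar symmetric cross-axis sensitivity term.
#' @param gyro_bias length-3 gyroscope bias (deg/s).
#' @param landing_amp landing-transient peak (m/s^2, kinematic vertical).
#' @param sigma_len SD of the technique/landing noise added to the
#'   ballistic range when drawing the reference length (m).
#' @param landing_offset_frac stature-proportional landing reach added to
#'   the reference length.
#' @param g gravity (m/s^2).
#' @param clip apply full-scale clipping (otherwise an infeasible scenario
#'   raises an error).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return list of class `jump_scenario`.
#' @export
jump_scenario <- function(stature = 1.80, mass = 70.9, age = 21.4,
                          v_takeoff = 4.37, angle_deg = 32,
                          dip_velocity = 0.9,
                          static = 3.0, unloading = 0.20, yielding = 0.25,
                          braking = 0.12, propulsion = 0.18,
                          landing = 0.08, tail = 0.8,
                          sampling_rate = 500,
                          full_scale_acc = 8 * SLJ_G, full_scale_gyro = 500,
                          noise_acc = 0.05, noise_gyro = 0.1,
                          tilt_deg = 5, yaw_deg = 0,
                          acc_offset = c(0, 0, 0), acc_scale = c(1, 1, 1),
                          cross_axis = 0, gyro_bias = c(0, 0, 0),
                          landing_amp = 4 * SLJ_G,
                          sigma_len = 0.08, landing_offset_frac = 0.05,
                          g = SLJ_G, clip = TRUE, seed = NULL) {
  scn <- as.list(environment())
  durs <- c(static, unloading, yielding, braking, propulsion, landing, tail)
  if (any(durs <= 0))
    stop_sljump("sljump_scenario_error", "phase durations must be positive")
  if (v_takeoff < 0 || angle_deg <= 0 || angle_deg >= 90)
    stop_sljump("sljump_scenario_error", "take-off angle must lie in (0, 90) deg")
  structure(scn, class = "jump_scenario")
}

# Continuous-time preparation-phase templates (gravity-removed, global frame).
# a_V: static 0; half raised-cosine dip to -A1 over `unloading`, back to 0
# over `yielding`; positive lobe rising to A2 over `braking` and decaying
# over `propulsion`; -g plateau in flight; landing transient; 0 tail.
template_a_V <- function(tt, scn, A1, A2, t0, t_UL, t_UB, t_TO, t_land, t_land_end, g) {
  a <- numeric(length(tt))
  i <- tt >= t0 & tt < t_UL
  a[i] <- -A1 * sin2_rise(tt[i] - t0, scn$unloading)
  i <- tt >= t_UL & tt < t_UB
  a[i] <- -A1 * sin2_fall(tt[i] - t_UL, scn$yielding)
  i <- tt >= t_UB & tt < t_UB + scn$braking
  a[i] <- A2 * sin2_rise(tt[i] - t_UB, scn$braking)
  i <- tt >= t_UB + scn$braking & tt < t_TO
  a[i] <- A2 * sin2_fall(tt[i] - t_UB - scn$braking, scn$propulsion)
  i <- tt >= t_TO & tt < t_land
  a[i] <- -g
  i <- tt >= t_land & tt < t_land_end
  a[i] <- scn$landing_amp * sin(pi * (tt[i] - t_land) / scn$landing)^2 - g *
    sin2_fall(tt[i] - t_land, scn$landing)
  a
}

template_a_AP <- function(tt, scn, B, t_UB, t_TO, t_land, t_land_end) {
  a <- numeric(length(tt))
  L <- scn$braking + scn$propulsion
  i <- tt >= t_UB & tt < t_TO
  a[i] <- B * sin(pi * (tt[i] - t_UB) / L)^2
  i <- tt >= t_land & tt < t_land_end
  a[i] <- -0.5 * scn$landing_amp * sin(pi * (tt[i] - t_land) / scn$landing)^2
  a
}

#' Simulate one annotated smartphone SLJ recording
#'
#' Builds smooth raised-cosine acceleration templates whose integrals equal
#' the programmed take-off velocities, adds the free-fall plateau and a
#' landing transient, re-adds gravity, rotates into a tilted/yawed sensor
#' frame, applies the scenario's calibration corruptions, noise and
#' full-scale clipping, and returns the raw recording together with exact
#' ground-truth annotations.
#'
#' @param scn a [jump_scenario()].
#' @return list of class `annotated_jump` with elements `recording` (an
#'   [imu_recording()]), `truth` (events, gravity-removed series, take-off
#'   velocities, ballistic range, reference length `l_meter`, scenario) —
#'   annotations are exact by construction.
#' @export
simulate_jump <- function(scn) {
  run <- function() simulate_jump_impl(scn)
  if (!is.null(scn$seed)) withr::with_seed(scn$seed, run()) else run()
}

simulate_jump_impl <- function(scn) {
  g <- scn$g
  dt <- 1 / scn$sampling_rate
  v_V <- scn$v_takeoff * sin(scn$angle_deg * pi / 180)
  v_AP <- scn$v_takeoff * cos(scn$angle_deg * pi / 180)
  moving <- scn$v_takeoff > 0
  t0 <- scn$static
  t_UL <- t0 + scn$unloading
  t_UB <- t_UL + scn$yielding
  t_TO <- t_UB + scn$braking + scn$propulsion
  t_flight <- if (moving) 2 * v_V / g else 0
  t_land <- t_TO + t_flight
  t_land_end <- t_land + scn$landing
  total <- if (moving) t_land_end + scn$tail else scn$static + scn$tail
  tt <- seq(0, total, by = dt)
  if (moving) {
    A1 <- 2 * scn$dip_velocity / (scn$unloading + scn$yielding)
    A2 <- 2 * (v_V + scn$dip_velocity) / (scn$braking + scn$propulsion)
    a_V <- template_a_V(tt, scn, A1, A2, t0, t_UL, t_UB, t_TO, t_land, t_land_end, g)
    B <- 2 * v_AP / (scn$braking + scn$propulsion)
    a_AP <- template_a_AP(tt, scn, B, t_UB, t_TO, t_land, t_land_end)
    # t_BP: cumulative integral of a_V from t_UB reaches +dip_velocity
    f_rise <- function(x) A2 * int_sin2_rise(x, scn$braking) - scn$dip_velocity
    t_BP <- if (f_rise(scn$braking) >= 0) {
      t_UB + stats::uniroot(f_rise, c(0, scn$braking), tol = 1e-12)$root
    } else {
      f_fall <- function(x) A2 * (scn$braking / 2 + int_sin2_fall(x, scn$propulsion)) -
        scn$dip_velocity
      t_UB + scn$braking + stats::uniroot(f_fall, c(0, scn$propulsion), tol = 1e-12)$root
    }
  } else {
    a_V <- numeric(length(tt)); a_AP <- numeric(length(tt))
    A1 <- A2 <- 0; t_BP <- NA_real_
  }
  # global frame: x = AP (jump direction), z = up; specific force = a + (0,0,g)
  f_glob <- cbind(a_AP, 0, a_V + g)
  R <- rot_axis(3, scn$yaw_deg) %*% rot_axis(2, scn$tilt_deg)  # sensor-to-global
  f_sens <- f_glob %*% R                                       # rows: R^T f
  S <- diag(scn$acc_scale)
  S[1, 2] <- S[2, 1] <- scn$cross_axis
  S[1, 3] <- S[3, 1] <- scn$cross_axis
  S[2, 3] <- S[3, 2] <- scn$cross_axis
  meas <- f_sens %*% t(S)
  meas <- sweep(meas, 2, scn$acc_offset, `+`)
  if (scn$noise_acc > 0)
    meas <- meas + matrix(rnorm(length(meas), 0, scn$noise_acc), ncol = 3)
  clipped <- any(abs(meas) > scn$full_scale_acc)
  if (clipped && !scn$clip)
    stop_sljump("sljump_scenario_error",
                "scenario exceeds the accelerometer full scale with clipping disabled")
  if (clipped)
    meas <- pmin(pmax(meas, -scn$full_scale_acc), scn$full_scale_acc)
  wobble <- if (moving) 5 * sin(2 * pi * 2 * tt) * (tt >= t0 & tt <= t_land_end)
  else numeric(length(tt))
  gyro <- cbind(wobble, wobble / 2, numeric(length(tt)))
  gyro <- sweep(gyro, 2, scn$gyro_bias, `+`)
  if (scn$noise_gyro > 0)
    gyro <- gyro + matrix(rnorm(length(gyro), 0, scn$noise_gyro), ncol = 3)
  rec <- imu_recording(tt, meas, gyro, sampling_rate = scn$sampling_rate,
                       full_scale_acc = scn$full_scale_acc,
                       full_scale_gyro = scn$full_scale_gyro,
                       label = "simulated SLJ")
  b_jump <- if (moving) 2 * v_V * v_AP / g else 0
  l_meter <- if (moving)
    b_jump + scn$landing_offset_frac * scn$stature + rnorm(1, 0, scn$sigma_len)
  else NA_real_
  truth <- list(
    events = if (moving) list(t_0 = t0, t_UL = t_UL, t_UB = t_UB,
                              t_BP = t_BP, t_TO = t_TO, t_land = t_land) else NULL,
    a_V = a_V, a_AP = a_AP, timestamps = tt,
    v_V_TO = if (moving) v_V else 0, v_AP_TO = if (moving) v_AP else 0,
    b_jump = b_jump, l_meter = l_meter, clipped = clipped,
    scenario = scn)
  structure(list(recording = rec, truth = truth), class = "annotated_jump")
}

rtrunc <- function(n, mean, sd, lo, hi) pmin(pmax(rnorm(n, mean, sd), lo), hi)

#' Population configuration for cohort simulation
#'
#' Defaults are tuned so simulated reference lengths have mean ~1.83 m and
#' SD ~0.30 m in a trained young-adult population (stature 1.80 +- 0.10 m,
#' mass 70.9 +- 10.3 kg, age 21.4 +- 5.1 y), with take-off speed mildly
#' coupled to stature so anthropometrics carry genuine predictive signal.
#'
#' @param v_mean,v_sd_between,v_sd_within take-off speed population mean
#'   and between-/within-participant SDs (m/s).
#' @param v_stature_slope coupling of participant mean speed to stature
#'   (m/s per m).
#' @param angle_mean,angle_sd take-off angle distribution (deg).
#' @param sigma_len reference-length noise SD (m).
#' @param jumps_per_participant trials per participant.
#' @param noise_acc accelerometer noise SD (m/s^2).
#' @return list of population parameters.
#' @export
cohort_population <- function(v_mean = 4.35, v_sd_between = 0.30,
                              v_sd_within = 0.15, v_stature_slope = 1.0,
                              angle_mean = 32, angle_sd = 4,
                              sigma_len = 0.08, jumps_per_participant = 3,
                              noise_acc = 0.05) {
  as.list(environment())
}

#' Simulate a cohort and run the real feature pipeline on it
#'
#' Draws participants and jumps from the population configuration,
#' simulates each recording, runs the full ingest / segmentation / feature
#' pipeline, and returns the resulting feature dataset together with the
#' ground-truth annotations.  Jumps the pipeline flags (clipping, failed
#' detection) are excluded, mirroring the data-cleaning rule.
#'
#' @param n number of jumps.
#' @param population a [cohort_population()].
#' @param seed integer seed.
#' @return list with `features` (data frame: `jump_id`, `participant_id`,
#'   61 features, `l_meter`), `annotations` (per-jump ground truth),
#'   `excluded` (ids and reasons).
#' @export
simulate_cohort <- function(n, population = cohort_population(), seed = 1) {
  withr::with_seed(seed, simulate_cohort_impl(n, population))
}

simulate_cohort_impl <- function(n, pop) {
  n_part <- ceiling(n / pop$jumps_per_participant)
  part <- data.frame(
    id = seq_len(n_part),
    stature = rtrunc(n_part, 1.80, 0.10, 1.50, 2.10),
    mass = rtrunc(n_part, 70.9, 10.3, 45, 110),
    age = rtrunc(n_part, 21.4, 5.1, 16, 45))
  part$v_mean <- pop$v_mean + pop$v_stature_slope * (part$stature - 1.80) +
    rnorm(n_part, 0, pop$v_sd_between)
  rows <- vector("list", n)
  annot <- vector("list", n)
  excluded <- list()
  for (j in seq_len(n)) {
    p <- ((j - 1) %% n_part) + 1
    scn <- jump_scenario(
      stature = part$stature[p], mass = part$mass[p], age = part$age[p],
      v_takeoff = max(3.0, part$v_mean[p] + rnorm(1, 0, pop$v_sd_within)),
      angle_deg = rtrunc(1, pop$angle_mean, pop$angle_sd, 15, 55),
      dip_velocity = rtrunc(1, 0.9, 0.15, 0.4, 1.6),
      unloading = rtrunc(1, 0.20, 0.03, 0.10, 0.35),
      yielding = rtrunc(1, 0.25, 0.04, 0.12, 0.40),
      braking = rtrunc(1, 0.12, 0.02, 0.06, 0.20),
      propulsion = rtrunc(1, 0.18, 0.03, 0.10, 0.30),
      tilt_deg = rtrunc(1, 5, 3, -20, 20),
      yaw_deg = runif(1, -180, 180),
      acc_offset = rnorm(3, 0, 0.02),
      acc_scale = 1 + rnorm(3, 0, 0.005),
      cross_axis = rnorm(1, 0, 0.001),
      gyro_bias = rnorm(3, 0, 0.5),
      noise_acc = pop$noise_acc,
      sigma_len = pop$sigma_len,
      seed = NULL)
    aj <- simulate_jump(scn)
    res <- process_jump(aj$recording,
                        anthropometrics(scn$stature, scn$mass, scn$age),
                        l_meter = aj$truth$l_meter)
    annot[[j]] <- data.frame(jump_id = j, participant_id = part$id[p],
                             t_0 = aj$truth$events$t_0, t_TO = aj$truth$events$t_TO,
                             v_V_TO = aj$truth$v_V_TO, v_AP_TO = aj$truth$v_AP_TO,
                             b_jump_true = aj$truth$b_jump,
                             l_meter = aj$truth$l_meter)
    if (res$excluded) {
      excluded[[length(excluded) + 1]] <- data.frame(jump_id = j, reason = res$reason)
      next
    }
    row <- res$features
    row <- cbind(data.frame(jump_id = j, participant_id = part$id[p]), row)
    rows[[j]] <- row
  }
  list(features = do.call(rbind, rows[!vapply(rows, is.null, logical(1))]),
       annotations = do.call(rbind, annot),
       excluded = if (length(excluded)) do.call(rbind, excluded) else NULL)
}

#' Write a fixed-seed fixture set
#'
#' Writes, under `dir`: three accelerometer-calibration static recordings
#' (`calib_x/y/z.csv`), one gyro-bias static recording (+ gyro file), six
#' jump recordings (including one clipped and one without a jump), an
#' expected-feature table for the valid jumps computed by the live
#' pipeline, and a small cohort feature table.  All seeds fixed, so two
#' runs write identical files.
#'
#' @param dir writable directory.
#' @return invisibly, the files written.
#' @export
make_fixtures <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character()
  wr <- function(rec, name, gyro = FALSE) {
    ap <- file.path(dir, paste0(name, "_acc.csv"))
    gp <- if (gyro) file.path(dir, paste0(name, "_gyro.csv")) else NULL
    write_recording(rec, ap, gp)
    files <<- c(files, ap, gp)
  }
  # calibration statics: axis k aligned with gravity, mild corruption
  off <- c(0.15, -0.08, 0.22); scl <- c(1.01, 0.99, 1.02)
  for (k in 1:3) {
    rec <- withr::with_seed(100 + k, {
      tt <- seq(0, 10, by = 1 / 500)
      truth <- matrix(0, length(tt), 3); truth[, k] <- SLJ_G
      meas <- sweep(truth %*% diag(scl), 2, off, `+`) +
        matrix(rnorm(3 * length(tt), 0, 0.03), ncol = 3)
      imu_recording(tt, meas, label = paste0("calib_", c("x", "y", "z")[k]))
    })
    wr(rec, paste0("calib_", c("x", "y", "z")[k]))
  }
  # gyro-bias static
  rec <- withr::with_seed(110, {
    tt <- seq(0, 10, by = 1 / 500)
    acc <- cbind(0, 0, SLJ_G)[rep(1, length(tt)), ] +
      matrix(rnorm(3 * length(tt), 0, 0.03), ncol = 3)
    gyro <- matrix(rnorm(3 * length(tt), 0, 0.1), ncol = 3)
    gyro <- sweep(gyro, 2, c(1.2, -0.4, 0.7), `+`)
    imu_recording(tt, acc, gyro, label = "gyro_static")
  })
  wr(rec, "gyro_static", gyro = TRUE)
  # six jumps: 4 valid, 1 clipped, 1 static (no jump)
  specs <- list(
    list(seed = 201, v = 4.4), list(seed = 202, v = 4.0),
    list(seed = 203, v = 4.8), list(seed = 204, v = 4.37),
    list(seed = 205, v = 4.4, landing_amp = 12 * SLJ_G),  # clips at 8 g
    list(seed = 206, v = 0))
  feats <- list()
  for (i in seq_along(specs)) {
    s <- specs[[i]]
    scn <- jump_scenario(v_takeoff = s$v,
                         landing_amp = s$landing_amp %||% (4 * SLJ_G),
                         seed = s$seed)
    aj <- simulate_jump(scn)
    wr(aj$recording, paste0("jump", i), gyro = TRUE)
    if (s$v > 0 && !aj$truth$clipped) {
      res <- process_jump(aj$recording, anthropometrics(1.8, 70.9, 21.4),
                          l_meter = aj$truth$l_meter)
      if (!res$excluded)
        feats[[length(feats) + 1]] <- cbind(data.frame(jump_id = i), res$features)
    }
  }
  fp <- file.path(dir, "expected_features.csv")
  write_feature_table(do.call(rbind, feats), fp)
  files <- c(files, fp, paste0(fp, ".meta"))
  coh <- simulate_cohort(12, seed = 42)
  cp <- file.path(dir, "cohort_features.csv")
  write_feature_table(coh$features, cp)
  files <- c(files, cp, paste0(cp, ".meta"))
  invisible(files)
}
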