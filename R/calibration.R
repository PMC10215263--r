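#' Estimate gyroscope static bias
#'
#' Per-axis mean of the gyroscope channels over a static trial (nominally
#' 60 s with the phone still on a flat surface).
#'
#' @param static an [imu_recording()] with a gyroscope stream.
#' @param sd_threshold per-axis motion threshold (deg/s); a standard
#'   deviation above it raises a calibration error.
#' @return object of class `gyro_calibration` with field `bias` (deg/s).
#' @export
estimate_gyro_bias <- function(static, sd_threshold = 5) {
  if (is.null(static$gyro))
    stop_sljump("sljump_calibration_error", "recording has no gyroscope stream")
  sds <- apply(static$gyro, 2, sd)
  if (any(sds > sd_threshold))
    stop_sljump("sljump_calibration_error",
                "motion detected in static trial (gyro SD = %s deg/s)",
                paste(signif(sds, 3), collapse = ", "))
  structure(list(bias = colMeans(static$gyro)), class = "gyro_calibration")
}

#' Construct an accelerometer calibration
#'
#' Affine measurement model `a_meas = sensitivity %*% a_true + offset`;
#' [apply_calibration()] inverts it.
#'
#' @param offset 3-vector (m/s^2).
#' @param sensitivity invertible 3x3 matrix (dimensionless).
#' @return object of class `accel_calibration`.
#' @export
accel_calibration <- function(offset = c(0, 0, 0), sensitivity = diag(3)) {
  sensitivity <- as.matrix(sensitivity)
  if (abs(det(sensitivity)) < 1e-8)
    stop_sljump("sljump_calibration_error", "sensitivity matrix is singular")
  structure(list(offset = as.numeric(offset), sensitivity = sensitivity),
            class = "accel_calibration")
}

#' Estimate accelerometer offset and cross-axis sensitivity
#'
#' Fits the affine model `a_meas = S a_true + o` to three 60 s static
#' acquisitions, recording `k` holding sensor axis `k` aligned with the
#' (upward) reaction to gravity so that the true specific force is
#' `g * e_k`.  Three orientations identify 8 of the 9 parameters of a
#' symmetric-sensitivity + offset model; the remaining direction (a uniform
#' all-ones sensitivity perturbation trading against a common offset shift)
#' is fixed by the minimum-norm solution about the ideal sensor
#' (S = I, o = 0).
#'
#' @param static_x,static_y,static_z static [imu_recording()]s with axis
#'   x / y / z gravity-aligned respectively.
#' @param g gravity (m/s^2).
#' @param sd_threshold motion threshold on per-axis accelerometer SD (m/s^2).
#' @return an [accel_calibration()].
#' @export
calibrate_accelerometer <- function(static_x, static_y, static_z,
                                    g = SLJ_G, sd_threshold = 1) {
  recs <- list(static_x, static_y, static_z)
  means <- vapply(recs, function(r) {
    if (any(apply(r$acc, 2, sd) > sd_threshold))
      stop_sljump("sljump_calibration_error", "motion detected in static acquisition")
    colMeans(r$acc)
  }, numeric(3))                       # 3 x 3: column k = mean of recording k
  # Rank check: the three mean vectors must point along distinct axes.
  if (abs(det(means)) < 0.1 * g^3)
    stop_sljump("sljump_calibration_error",
                "static orientations are not linearly independent (rank-deficient design)")
  # Parameters theta = (S11,S22,S33,S12,S13,S23,o1',o2',o3') with offsets
  # expressed in g units (o' = o/g) so the min-norm resolution of the
  # one-dimensional null space balances sensitivity and offset errors.
  # Recording k, axis i: means[i,k]/g = S[i,k] + o'_i.
  A <- matrix(0, 9, 9); b <- numeric(9)
  Sidx <- function(i, j) {             # index of S[i,j] in theta (symmetric)
    if (i == j) i else 3 + c("12" = 1, "13" = 2, "23" = 3)[paste0(min(i, j), max(i, j))]
  }
  row <- 0
  for (k in 1:3) for (i in 1:3) {
    row <- row + 1
    A[row, Sidx(i, k)] <- 1
    A[row, 6 + i] <- 1
    b[row] <- means[i, k] / g
  }
  theta0 <- c(1, 1, 1, 0, 0, 0, 0, 0, 0)
  # Minimum-norm correction about the ideal sensor via the pseudo-inverse.
  d <- b - A %*% theta0
  theta <- theta0 + as.numeric(pracma::pinv(A) %*% d)
  S <- matrix(0, 3, 3)
  S[1, 1] <- theta[1]; S[2, 2] <- theta[2]; S[3, 3] <- theta[3]
  S[1, 2] <- S[2, 1] <- theta[4]
  S[1, 3] <- S[3, 1] <- theta[5]
  S[2, 3] <- S[3, 2] <- theta[6]
  accel_calibration(offset = g * theta[7:9], sensitivity = S)
}

#' Apply sensor calibrations to a recording
#'
#' Accelerometer samples become `S^-1 (a - o)`; gyroscope samples have the
#' static bias subtracted.
#'
#' @param rec an [imu_recording()].
#' @param acc_cal an [accel_calibration()], or `NULL` to leave acc untouched.
#' @param gyro_cal a `gyro_calibration` from [estimate_gyro_bias()], or `NULL`.
#' @return the calibrated [imu_recording()].
#' @export
apply_calibration <- function(rec, acc_cal = NULL, gyro_cal = NULL) {
  acc <- rec$acc
  if (!is.null(acc_cal)) {
    Sinv <- solve(acc_cal$sensitivity)
    acc <- t(Sinv %*% (t(acc) - acc_cal$offset))
    colnames(acc) <- c("x", "y", "z")
  }
  gyro <- rec$gyro
  if (!is.null(gyro) && !is.null(gyro_cal))
    gyro <- sweep(gyro, 2, gyro_cal$bias)
  out <- rec
  out$acc <- acc
  out$gyro <- gyro
  out
}

#' Persist a calibration pair as a key-value text file
#' @param acc_cal an [accel_calibration()] (or `NULL`).
#' @param gyro_cal a `gyro_calibration` (or `NULL`).
#' @param path output file.
#' @export
write_calibration <- function(acc_cal, gyro_cal, path) {
  lines <- character()
  if (!is.null(acc_cal)) {
    lines <- c(lines,
               paste0("acc_offset: ", paste(format(acc_cal$offset, digits = 12), collapse = " ")),
               paste0("acc_sensitivity: ",
                      paste(format(as.numeric(acc_cal$sensitivity), digits = 12), collapse = " ")))
  }
  if (!is.null(gyro_cal))
    lines <- c(lines, paste0("gyro_bias: ", paste(format(gyro_cal$bias, digits = 12), collapse = " ")))
  writeLines(lines, path)
  invisible(path)
}

#' Read a calibration file written by [write_calibration()]
#' @param path input file.
#' @return list with elements `acc_cal` and `gyro_cal` (either may be `NULL`).
#' @export
read_calibration <- function(path) {
  lines <- readLines(path)
  get <- function(key) {
    hit <- grep(paste0("^", key, ": "), lines, value = TRUE)
    if (!length(hit)) return(NULL)
    as.numeric(strsplit(trimws(sub(paste0("^", key, ": "), "", hit[1])), " +")[[1]])
  }
  off <- get("acc_offset"); sens <- get("acc_sensitivity"); bias <- get("gyro_bias")
  list(acc_cal = if (!is.null(off)) accel_calibration(off, matrix(sens, 3, 3)) else NULL,
       gyro_cal = if (!is.null(bias)) structure(list(bias = bias), class = "gyro_calibration") else NULL)
}
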