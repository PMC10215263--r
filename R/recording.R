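#' Construct an IMU recording
#'
#' Container for synchronous tri-axial accelerometer (specific force, m/s^2,
#' sensor frame) and gyroscope (deg/s, sensor frame) streams from a
#' smartphone, with device metadata.
#'
#' @param timestamps numeric vector of sample times (s), strictly increasing.
#' @param acc n x 3 matrix of specific force (m/s^2).
#' @param gyro n x 3 matrix of angular rate (deg/s), or `NULL` if absent.
#' @param sampling_rate nominal rate (samples/s); estimated from timestamps
#'   when `NULL`.
#' @param full_scale_acc accelerometer full scale (m/s^2), default 8 g.
#' @param full_scale_gyro gyroscope full scale (deg/s), default 500.
#' @param label free-text label.
#' @return object of class `imu_recording`.
#' @export
imu_recording <- function(timestamps, acc, gyro = NULL,
                          sampling_rate = NULL,
                          full_scale_acc = 8 * SLJ_G,
                          full_scale_gyro = 500,
                          label = "") {
  timestamps <- as.numeric(timestamps)
  acc <- as.matrix(acc)
  if (ncol(acc) != 3L) stop_sljump("sljump_format_error", "acc must have 3 columns")
  n <- length(timestamps)
  if (nrow(acc) != n)
    stop_sljump("sljump_data_error", "acc length (%d) != timestamps length (%d)", nrow(acc), n)
  if (n >= 2 && any(diff(timestamps) <= 0))
    stop_sljump("sljump_data_error", "timestamps must be strictly increasing")
  if (!is.null(gyro)) {
    gyro <- as.matrix(gyro)
    if (ncol(gyro) != 3L || nrow(gyro) != n)
      stop_sljump("sljump_data_error", "gyro must be an n x 3 matrix matching timestamps")
  }
  if (is.null(sampling_rate)) {
    sampling_rate <- if (n >= 2) 1 / median(diff(timestamps)) else NA_real_
  }
  colnames(acc) <- c("x", "y", "z")
  if (!is.null(gyro)) colnames(gyro) <- c("x", "y", "z")
  structure(
    list(timestamps = timestamps, acc = acc, gyro = gyro,
         sampling_rate = sampling_rate,
         full_scale_acc = full_scale_acc, full_scale_gyro = full_scale_gyro,
         label = label,
         clipped = any(abs(acc) >= full_scale_acc - 1e-9)),
    class = "imu_recording")
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf("<imu_recording> %s: %d samples @ %.1f Hz, %.2f s%s%s\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              length(x$timestamps), x$sampling_rate,
              diff(range(x$timestamps)),
              if (is.null(x$gyro)) ", no gyro" else "",
              if (isTRUE(x$clipped)) ", CLIPPED" else ""))
  invisible(x)
}

#' Number of samples in a recording
#' @param rec an `imu_recording`.
#' @export
n_samples <- function(rec) length(rec$timestamps)

default_column_map <- function() {
  list(time = c("Time (s)", "time", "t"),
       x = c("X", "x", "Acceleration x (m/s^2)", "Gyroscope x (rad/s)"),
       y = c("Y", "y", "Acceleration y (m/s^2)", "Gyroscope y (rad/s)"),
       z = c("Z", "z", "Acceleration z (m/s^2)", "Gyroscope z (rad/s)"))
}

read_sensor_file <- function(path, column_map, sep) {
  df <- utils::read.delim(path, sep = sep, header = TRUE, check.names = FALSE)
  pick <- function(keys, what) {
    hit <- intersect(keys, names(df))
    if (!length(hit))
      stop_sljump("sljump_format_error",
                  "%s: no column matching '%s' (found: %s)",
                  path, what, paste(names(df), collapse = ", "))
    as.numeric(df[[hit[1]]])
  }
  out <- list(time = pick(column_map$time, "time"),
              x = pick(column_map$x, "x"),
              y = pick(column_map$y, "y"),
              z = pick(column_map$z, "z"))
  if (any(diff(out$time) <= 0))
    stop_sljump("sljump_data_error", "%s: time column is not strictly increasing", path)
  out
}

#' Read a Phyphox-style smartphone IMU export
#'
#' Reads one delimited-text file per sensor (header row; columns time, x, y,
#' z) and aligns the gyroscope onto the accelerometer time base by linear
#' interpolation when the sensor clocks differ.  Gaps longer than 5 nominal
#' sample intervals are filled linearly with a warning.
#'
#' @param acc_path path to the accelerometer export.
#' @param gyro_path path to the gyroscope export, or `NULL`.
#' @param sampling_rate,full_scale_acc,full_scale_gyro,label device metadata
#'   (see [imu_recording()]).
#' @param column_map named list of accepted header names for `time`, `x`,
#'   `y`, `z`.
#' @param sep field separator (default `","`).
#' @return an [imu_recording()].
#' @export
read_recording <- function(acc_path, gyro_path = NULL,
                           sampling_rate = NULL,
                           full_scale_acc = 8 * SLJ_G,
                           full_scale_gyro = 500,
                           label = basename(acc_path),
                           column_map = default_column_map(),
                           sep = ",") {
  a <- read_sensor_file(acc_path, column_map, sep)
  dt <- median(diff(a$time))
  if (any(diff(a$time) > 5 * dt)) {
    warning("gap > 5 sample intervals in ", acc_path, "; linear fill applied")
    # resample onto a regular grid spanning the recording
    grid <- seq(a$time[1], a$time[length(a$time)], by = dt)
    a <- list(time = grid,
              x = approx(a$time, a$x, grid)$y,
              y = approx(a$time, a$y, grid)$y,
              z = approx(a$time, a$z, grid)$y)
  }
  gyro <- NULL
  if (!is.null(gyro_path)) {
    g <- read_sensor_file(gyro_path, column_map, sep)
    gyro <- cbind(x = approx(g$time, g$x, a$time, rule = 2)$y,
                  y = approx(g$time, g$y, a$time, rule = 2)$y,
                  z = approx(g$time, g$z, a$time, rule = 2)$y)
  }
  imu_recording(a$time, cbind(x = a$x, y = a$y, z = a$z), gyro,
                sampling_rate = sampling_rate,
                full_scale_acc = full_scale_acc,
                full_scale_gyro = full_scale_gyro, label = label)
}

#' Write a recording as Phyphox-style delimited text
#'
#' @param rec an [imu_recording()].
#' @param acc_path,gyro_path output paths (gyro file written only when the
#'   recording has a gyroscope stream and `gyro_path` is given).
#' @return invisibly, the paths written.
#' @export
write_recording <- function(rec, acc_path, gyro_path = NULL) {
  fmt <- function(t, m) {
    # %.17g keeps the doubles bit-exact through the text round-trip
    df <- data.frame(sprintf("%.17g", t), sprintf("%.17g", m[, 1]),
                     sprintf("%.17g", m[, 2]), sprintf("%.17g", m[, 3]))
    names(df) <- c("Time (s)", "X", "Y", "Z")
    df
  }
  utils::write.table(fmt(rec$timestamps, rec$acc), acc_path, sep = ",",
                     row.names = FALSE, quote = FALSE)
  paths <- acc_path
  if (!is.null(gyro_path) && !is.null(rec$gyro)) {
    utils::write.table(fmt(rec$timestamps, rec$gyro), gyro_path, sep = ",",
                       row.names = FALSE, quote = FALSE)
    paths <- c(paths, gyro_path)
  }
  invisible(paths)
}

# Indices of samples falling inside a closed time interval.
window_idx <- function(timestamps, window) {
  which(timestamps >= window[1] & timestamps <= window[2])
}
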