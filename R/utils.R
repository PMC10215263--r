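`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rotation matrix about a coordinate axis
#'
#' @param axis 1, 2 or 3 (x, y, z).
#' @param angle_deg rotation angle in degrees.
#' @return 3x3 rotation matrix.
#' @keywords internal
rot_axis <- function(axis, angle_deg) {
  th <- angle_deg * pi / 180
  c_ <- cos(th); s_ <- sin(th)
  R <- diag(3)
  i <- setdiff(1:3, axis)
  R[i[1], i[1]] <- c_; R[i[2], i[2]] <- c_
  R[i[1], i[2]] <- -s_; R[i[2], i[1]] <- s_
  R
}

# Minimal rotation taking unit vector u onto unit vector v (Rodrigues).
rotation_between <- function(u, v) {
  u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
  w <- c(u[2] * v[3] - u[3] * v[2],
         u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  s <- sqrt(sum(w^2)); c_ <- sum(u * v)
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    # antipodal: rotate pi about any axis orthogonal to u
    a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    w <- a - sum(a * u) * u; w <- w / sqrt(sum(w^2))
    K <- matrix(c(0, -w[3], w[2], w[3], 0, -w[1], -w[2], w[1], 0), 3, 3, byrow = TRUE)
    return(diag(3) + 2 * K %*% K)
  }
  K <- matrix(c(0, -w[3], w[2], w[3], 0, -w[1], -w[2], w[1], 0), 3, 3, byrow = TRUE)
  diag(3) + K + K %*% K * ((1 - c_) / s^2)
}

# Cumulative trapezoidal integral with zero initial condition.
cumtrapz1 <- function(t, y) as.numeric(pracma::cumtrapz(t, y))

# Raised-cosine (sin^2) half-lobe helpers used by the simulator: value of
# A * sin(pi * x / (2 * d))^2 rises from 0 at x = 0 to A at x = d.
sin2_rise <- function(x, d) sin(pi * x / (2 * d))^2
sin2_fall <- function(x, d) cos(pi * x / (2 * d))^2

# Analytic integral of sin(pi x / (2 d))^2 from 0 to x.
int_sin2_rise <- function(x, d) x / 2 - d / (2 * pi) * sin(pi * x / d)
# Analytic integral of cos(pi x / (2 d))^2 from 0 to x.
int_sin2_fall <- function(x, d) x / 2 + d / (2 * pi) * sin(pi * x / d)

stop_sljump <- function(class, msg, ...) {
  stop(structure(class = c(class, "sljump_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}
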