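#' Canonical feature order
#'
#' The 61 feature identifiers, grouped as 3 anthropometric, 4 ballistic,
#' 48 biomechanical/power, and 6 VMD time-frequency features.  `l_AP_pow`
#' is the anteroposterior negative peak power (named to avoid a case-only
#' collision with the power-peaks delta time `L_AP`); `nu_V`/`nu_AP` are
#' the minimum negative velocities.
#'
#' @return character vector of length 61.
#' @export
feature_names <- function() {
  c("h_anthro", "w_anthro", "y_anthro",
    "alpha", "b_jump", "h_jump", "t_flight",
    "A_V", "b_V", "b_AP", "C_V", "C_AP", "da_V", "da_AP", "dv_V", "dv_AP",
    "D_V", "D_AP", "e_V", "e_AP", "F_V", "F_AP", "G_V", "H_V", "H_AP",
    "i_V", "J_V", "J_AP", "k_V", "k_AP", "l_V", "l_AP_pow", "L_AP",
    "M_V", "M_AP", "n_V", "n_AP", "O_V", "O_AP", "p_V", "p_AP",
    "q_V", "q_AP", "Q_V", "r_V", "r_AP", "R_AP",
    "u_V", "u_AP", "nu_V", "nu_AP", "W_V", "W_AP", "z_V", "z_AP",
    "f1_V", "f2_V", "f3_V", "f1_AP", "f2_AP", "f3_AP")
}

#' Anthropometric descriptors
#' @param stature stature (m).
#' @param mass body mass (kg).
#' @param age age (years).
#' @return named list `h_anthro`, `w_anthro`, `y_anthro`.
#' @export
anthropometrics <- function(stature, mass, age) {
  if (any(c(stature, mass, age) <= 0))
    stop_sljump("sljump_data_error", "anthropometrics must be strictly positive")
  list(h_anthro = stature, w_anthro = mass, y_anthro = age)
}

#' Ballistic (projectile) features from the take-off velocities
#'
#' Under the ballistic hypothesis the sensor origin follows a parabola, so
#' the SLJ length, height and flight time follow in closed form from the
#' take-off velocity components: `b_jump = 2 v_V v_AP / g`,
#' `h_jump = v_V^2 / (2 g)`, `t_flight = 2 v_V / g`, and the take-off
#' angle `alpha = atan(v_V / v_AP)` in degrees.
#'
#' @param v_V_TO,v_AP_TO vertical / anteroposterior take-off velocity (m/s).
#' @param g gravity (m/s^2).
#' @return named list `alpha` (deg), `b_jump` (m), `h_jump` (m),
#'   `t_flight` (s).
#' @export
ballistic_features <- function(v_V_TO, v_AP_TO, g = SLJ_G) {
  if (v_V_TO <= 0 || v_AP_TO < 0)
    stop_sljump("sljump_invalid_jump_error",
                "take-off velocities must be positive (got v_V=%.3f, v_AP=%.3f)",
                v_V_TO, v_AP_TO)
  list(alpha = atan2(v_V_TO, v_AP_TO) * 180 / pi,
       b_jump = 2 * v_V_TO * v_AP_TO / g,
       h_jump = v_V_TO^2 / (2 * g),
       t_flight = 2 * v_V_TO / g)
}

# Per-component biomechanical features over [t_0, t_TO].
component_features <- function(t, a, v, P, ext_a, ext_v, ext_P,
                               t_UB, t_BP, t_TO) {
  dt <- median(diff(t))
  b <- min(a); e <- max(a)
  C <- ext_a$t_max - ext_a$t_min
  D <- sum(a > 0) * dt
  i_BP <- which.min(abs(t - t_BP))
  pos_idx <- which(a > 0 & t < t_TO)
  q <- NA_real_
  if (length(pos_idx) && e != 0 && D > 0) {
    j <- max(pos_idx)
    i_UB <- which.min(abs(t - t_UB))
    if (j > i_UB) {
      area <- pracma::trapz(t[i_UB:j], a[i_UB:j])
      q <- area / (D * e)
    }
  }
  con <- t >= t_BP & t <= t_TO
  ecc <- t <= t_BP
  list(b = b,
       C = C,
       da = e - b,
       dv = max(v) - min(v),
       D = D,
       e = e,
       F = t_TO - ext_a$t_max,
       H = NA_real_,                      # filled by caller (needs t_UL)
       J = t_BP - ext_v$t_min,
       k = a[i_BP],
       l = min(P),
       n = max(P),
       M = sum(P > 0) * dt,
       O = t_TO - ext_P$t_max,
       p = if (C != 0) (e - b) / C else NA_real_,
       q = q,
       r = if (e != 0) b / e else NA_real_,
       u = mean(P[con]),
       nu = min(v),
       W = ext_P$t_max - ext_P$t_min,
       z = mean(P[ecc]))
}

#' Biomechanical and power features of a segmented jump
#'
#' Computes the 48 preparation-phase features (42 jump-related + 6 power)
#' on `[t_0, t_TO]`: starred features for both the vertical and
#' anteroposterior components, plus the six single-component features
#' `A_V` (unweighting duration, `[t_0, t_UB]`), `G_V` (ground contact),
#' `i_V` (max slope of `a_V` up to `t_BP`), `Q_V` (braking end to
#' take-off), `L_AP` and `R_AP`.
#'
#' @param gacc a [global_acceleration()].
#' @param vel a `velocity_series`.
#' @param power a `power_series`.
#' @param events a `jump_events`.
#' @param unweighting_end landmark ending the unweighting-duration feature
#'   `A_V`: `"t_UB"` (as printed in the feature table) or `"t_UL"`.
#' @return named list of 48 features; features with zero denominators are
#'   `NA` and flagged via the `"flagged"` attribute.
#' @export
biomechanical_features <- function(gacc, vel, power, events,
                                   unweighting_end = c("t_UB", "t_UL")) {
  unweighting_end <- match.arg(unweighting_end)
  t <- vel$timestamps
  a_V <- gacc$a_V[vel$idx]; a_AP <- gacc$a_AP[vel$idx]
  fV <- component_features(t, a_V, vel$v_V, power$P_V,
                           events$a_V, events$v_V, events$P_V,
                           events$t_UB, events$t_BP, events$t_TO)
  fAP <- component_features(t, a_AP, vel$v_AP, power$P_AP,
                            events$a_AP, events$v_AP, events$P_AP,
                            events$t_UB, events$t_BP, events$t_TO)
  fV$H <- events$t_BP - events$t_UL
  fAP$H <- events$t_BP - events$t_UL
  pre_BP <- t <= events$t_BP
  slope <- diff(a_V[pre_BP]) / diff(t[pre_BP])
  out <- list(
    A_V = events[[unweighting_end]] - events$t_0,
    b_V = fV$b, b_AP = fAP$b,
    C_V = fV$C, C_AP = fAP$C,
    da_V = fV$da, da_AP = fAP$da,
    dv_V = fV$dv, dv_AP = fAP$dv,
    D_V = fV$D, D_AP = fAP$D,
    e_V = fV$e, e_AP = fAP$e,
    F_V = fV$F, F_AP = fAP$F,
    G_V = events$t_TO - events$t_0,
    H_V = fV$H, H_AP = fAP$H,
    i_V = max(slope),
    J_V = fV$J, J_AP = fAP$J,
    k_V = fV$k, k_AP = fAP$k,
    l_V = fV$l, l_AP_pow = fAP$l,
    L_AP = events$P_AP$t_max - events$P_AP$t_min,
    M_V = fV$M, M_AP = fAP$M,
    n_V = fV$n, n_AP = fAP$n,
    O_V = fV$O, O_AP = fAP$O,
    p_V = fV$p, p_AP = fAP$p,
    q_V = fV$q, q_AP = fAP$q,
    Q_V = events$t_TO - events$t_BP,
    r_V = fV$r, r_AP = fAP$r,
    R_AP = fAP$M,
    u_V = fV$u, u_AP = fAP$u,
    nu_V = fV$nu, nu_AP = fAP$nu,
    W_V = fV$W, W_AP = fAP$W,
    z_V = fV$z, z_AP = fAP$z)
  missing <- names(out)[vapply(out, function(x) !is.finite(x), logical(1))]
  if (length(missing)) attr(out, "flagged") <- missing
  out
}

#' Assemble the full 61-entry feature vector for one jump
#'
#' @param anthro output of [anthropometrics()].
#' @param ballistic output of [ballistic_features()].
#' @param biomech output of [biomechanical_features()].
#' @param vmd_V,vmd_AP outputs of [vmd_features()] for the vertical and
#'   anteroposterior acceleration.
#' @param l_meter reference jump length (m), the dependent variable.
#' @return one-row data frame with the 61 features in [feature_names()]
#'   order plus `l_meter`; carries attribute `excluded = TRUE` when any
#'   feature is flagged missing (mirroring the data-cleaning rule).
#' @export
assemble_feature_vector <- function(anthro, ballistic, biomech,
                                    vmd_V, vmd_AP, l_meter = NA_real_) {
  vals <- c(anthro[c("h_anthro", "w_anthro", "y_anthro")],
            ballistic[c("alpha", "b_jump", "h_jump", "t_flight")],
            biomech,
            list(f1_V = vmd_V[["f1"]], f2_V = vmd_V[["f2"]], f3_V = vmd_V[["f3"]],
                 f1_AP = vmd_AP[["f1"]], f2_AP = vmd_AP[["f2"]], f3_AP = vmd_AP[["f3"]]))
  stopifnot(identical(sort(names(vals)), sort(feature_names())))
  df <- as.data.frame(vals)[, feature_names()]
  df$l_meter <- l_meter
  if (anyNA(df[, feature_names()]) || !is.null(attr(biomech, "flagged")))
    attr(df, "excluded") <- TRUE
  df
}

#' Write / read a feature table as delimited text
#'
#' @param features data frame of feature rows.
#' @param path output path; a `<path>.meta` sidecar records the column
#'   units.
#' @export
write_feature_table <- function(features, path) {
  out <- features
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) sprintf("%.17g", x))
  utils::write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE)
  units <- c(h_anthro = "m", w_anthro = "kg", y_anthro = "y", alpha = "deg",
             b_jump = "m", h_jump = "m", t_flight = "s", l_meter = "m")
  meta <- vapply(names(features), function(nm) {
    if (nm %in% names(units)) units[[nm]]
    else if (grepl("^f[123]_", nm)) "Hz"
    else if (grepl("^(A|C|D|F|G|H|J|L|M|O|Q|R|W)_", nm)) "s"
    else if (grepl("^(b|e|k|da)_", nm)) "m/s2"
    else if (grepl("^(dv|nu)_", nm)) "m/s"
    else if (grepl("^(l|n|u|z)_", nm)) "W/kg"
    else "a.u."
  }, character(1))
  writeLines(paste0(names(features), ": ", meta), paste0(path, ".meta"))
  invisible(path)
}

#' @rdname write_feature_table
#' @param path path of a table written by [write_feature_table()].
#' @export
read_feature_table <- function(path) {
  utils::read.delim(path, sep = ",", header = TRUE, check.names = FALSE)
}
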