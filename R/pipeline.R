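#' Run the full single-jump pipeline on a raw recording
#'
#' Convenience wrapper chaining [to_global_frame()], [detect_onset()],
#' [detect_takeoff()], [integrate_velocity()], [compute_power()],
#' [detect_phase_events()], the feature extractors and
#' [assemble_feature_vector()].  Recordings that clip, contain no jump, or
#' fail segmentation are returned flagged as excluded with a reason,
#' mirroring the dataset cleaning rule.
#'
#' @param rec a calibrated [imu_recording()].
#' @param anthro an [anthropometrics()] list.
#' @param l_meter reference jump length (m) or `NA`.
#' @param static_window static interval used for orientation and onset
#'   statistics (s).
#' @param g gravity (m/s^2).
#' @param include_gravity_in_power see [compute_power()].
#' @return list with `features` (one-row data frame or `NULL`), `events`,
#'   `gacc`, `velocity`, `power`, `excluded` (logical) and `reason`.
#' @export
process_jump <- function(rec, anthro, l_meter = NA_real_,
                         static_window = c(0.5, 2.5), g = SLJ_G,
                         include_gravity_in_power = TRUE) {
  excluded <- function(reason)
    list(features = NULL, events = NULL, gacc = NULL, velocity = NULL,
         power = NULL, excluded = TRUE, reason = reason)
  if (isTRUE(rec$clipped)) return(excluded("full-scale clipping"))
  out <- tryCatch({
    gacc <- to_global_frame(rec, static_window, g = g)
    t_0 <- detect_onset(gacc, static_window)
    t_TO <- detect_takeoff(gacc, t_0)
    vel <- integrate_velocity(gacc, t_0, t_TO)
    pw <- compute_power(gacc, vel, include_gravity = include_gravity_in_power)
    ev <- detect_phase_events(gacc, vel, pw)
    bal <- ballistic_features(vel$v_V[length(vel$v_V)],
                              vel$v_AP[length(vel$v_AP)], g = g)
    bio <- biomechanical_features(gacc, vel, pw, ev)
    fs <- gacc$sampling_rate
    fv <- assemble_feature_vector(
      anthro, bal, bio,
      vmd_features(gacc$a_V[vel$idx], fs),
      vmd_features(gacc$a_AP[vel$idx], fs),
      l_meter = l_meter)
    list(features = fv, events = ev, gacc = gacc, velocity = vel, power = pw,
         excluded = isTRUE(attr(fv, "excluded")),
         reason = if (isTRUE(attr(fv, "excluded"))) "flagged-missing feature" else NA_character_)
  }, sljump_error = function(e) excluded(conditionMessage(e)))
  out
}
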