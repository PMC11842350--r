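# From raw trial to cycle-normalized quantities.
#
# One processed trial holds everything the calibration and load estimation
# need on a common 201-point cycle axis: iMVC-normalized excitations, the
# filtered lumbosacral angle and its derivatives, the hand force, and the
# inverse-dynamics moment.

#' Process one lifting trial
#'
#' Filters the motion channels (6 Hz zero-phase low-pass), segments the lift
#' cycle from the box kinematics, extracts iMVC-normalized EMG envelopes
#' (or uses stored clean envelopes), computes the inverse-dynamics moment,
#' and time-normalizes everything to `n_points` samples across the cycle.
#'
#' @param trial A `lift_trial` (see [forward_simulate()]).
#' @param subj The trial subject's [subject()] record.
#' @param seg_cfg A [segmentation_config()].
#' @param env_cfg An [envelope_config()].
#' @param gravity m/s^2.
#' @return A `processed_trial` list with `cycle`, `excitations`
#'   (n_points x 6), `theta`, `theta_dot`, `theta_ddot`, `load_force`,
#'   `m_id`, `rom` (rad) and trial identifiers.
#' @export
process_trial <- function(trial, subj, seg_cfg = segmentation_config(),
                          env_cfg = envelope_config(), gravity = GRAVITY) {
  if (!inherits(trial, "lift_trial"))
    stop("`trial` must be a lift_trial", call. = FALSE)
  motion <- lowpass_motion(trial$motion)
  height <- lift_ts(ts_channel(motion, "box_height"), motion$fs, motion$t0)
  velocity <- lift_ts(ts_channel(motion, "box_velocity"), motion$fs,
                      motion$t0)
  cycle <- segment_lift(height, velocity, seg_cfg)

  angle <- lift_ts(ts_channel(motion, "angle"), motion$fs, motion$t0,
                   "angle")
  load <- lift_ts(ts_channel(motion, "load_force"), motion$fs, motion$t0,
                  "load_force")
  m_id_full <- inverse_dynamics_moment(angle, subj, load, gravity)

  env <- if (trial$emg_is_envelope) trial$emg else
    emg_envelope(trial$emg, env_cfg)
  env <- normalize_envelope(env, trial$imvc_peaks[colnames(env$values)])

  np <- env_cfg$n_points
  theta <- time_normalize(angle, cycle, np)
  theta_dot <- time_normalize(ts_derivative(angle), cycle, np)
  theta_ddot <- time_normalize(ts_derivative(ts_derivative(angle)), cycle,
                               np)
  structure(list(
    subject_id = trial$subject_id, li_level = trial$li_level,
    repetition = trial$repetition, cycle = cycle,
    excitations = time_normalize(env, cycle, np),
    theta = theta, theta_dot = theta_dot, theta_ddot = theta_ddot,
    load_force = time_normalize(load, cycle, np),
    m_id = time_normalize(m_id_full, cycle, np),
    rom = diff(range(theta)),
    duration = cycle$end_time - cycle$start_time),
    class = "processed_trial")
}

#' @export
print.processed_trial <- function(x, ...) {
  cat(sprintf(
    "<processed_trial> subject %s L%d rep %d | cycle %.2f s | ROM %.1f deg | peak M_id %.1f N m\n",
    x$subject_id, x$li_level, x$repetition, x$duration,
    x$rom * 180 / pi, max(abs(x$m_id))))
  invisible(x)
}

#' EMG-driven joint loads for a processed trial
#'
#' @param model The subject's (calibrated) [trunk_model()].
#' @param ptrial A [process_trial()] result.
#' @param normalized Also attach body-normalized loads.
#' @return A [joint_load_series()] over the cycle fraction.
#' @export
estimate_trial_loads <- function(model, ptrial, normalized = TRUE) {
  loads <- estimate_joint_loads(model, ptrial$excitations, ptrial$theta,
                                ptrial$theta_dot, ptrial$theta_ddot,
                                ptrial$load_force)
  if (normalized) loads <- normalize_loads(loads, model$subject)
  loads
}

#' Per-trial summary of peaks and range of motion
#'
#' Peaks are taken within the lift cycle only; left/right homologous EMG
#' channels are averaged after peak extraction.
#'
#' @param ptrial A [process_trial()] result.
#' @param loads The trial's normalized [joint_load_series()].
#' @return One-row data.frame: identifiers, `rom_deg`, peak normalized
#'   envelope per muscle, `peak_moment_norm` (N m/kg), `peak_compression_bw`
#'   and `peak_shear_bw` (multiples of body weight).
#' @export
summarize_trial <- function(ptrial, loads) {
  if (is.null(loads$compression_bw))
    stop("`loads` must be normalized (see normalize_loads)", call. = FALSE)
  env_peaks <- apply(ptrial$excitations, 2, max)
  muscles <- unique(sub("_[lr]$", "", colnames(ptrial$excitations)))
  lr_mean <- vapply(muscles, function(m) {
    idx <- grep(paste0("^", m, "_[lr]$"), names(env_peaks))
    mean(env_peaks[idx])
  }, numeric(1))
  out <- data.frame(subject_id = ptrial$subject_id,
                    li_level = ptrial$li_level,
                    repetition = ptrial$repetition,
                    rom_deg = ptrial$rom * 180 / pi,
                    peak_moment_norm = max(loads$moment_norm),
                    peak_compression_bw = max(loads$compression_bw),
                    peak_shear_bw = max(abs(loads$shear_bw)),
                    stringsAsFactors = FALSE)
  for (m in muscles) out[[paste0("peak_emg_", m)]] <- lr_mean[[m]]
  out
}
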