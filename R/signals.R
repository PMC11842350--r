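# Signal conditioning and lift-cycle handling.
#
# The processing chain mirrors standard occupational-biomechanics practice:
# motion/force channels are zero-phase low-pass filtered at 6 Hz; lift cycles
# are bounded by a 0.025 m/s vertical box-velocity threshold; raw sEMG is
# band-pass filtered 20-400 Hz, full-wave rectified, low-pass filtered at
# 5 Hz, normalized to the mean of three iMVC peaks, and time-normalized to
# 201 samples per lift cycle.

#' Default segmentation and envelope settings
#'
#' @param velocity_threshold Vertical velocity threshold in m/s marking lift
#'   start/end (default 0.025).
#' @return A list of settings.
#' @export
segmentation_config <- function(velocity_threshold = 0.025) {
  if (!is.finite(velocity_threshold) || velocity_threshold <= 0)
    stop("`velocity_threshold` must be > 0", call. = FALSE)
  list(velocity_threshold = velocity_threshold, axis = "vertical")
}

#' @rdname segmentation_config
#' @param bandpass Two band edges in Hz for the raw sEMG band-pass.
#' @param lowpass Envelope low-pass cutoff in Hz.
#' @param order Butterworth design order for both filters.
#' @param n_points Number of samples after time normalization.
#' @export
envelope_config <- function(bandpass = c(20, 400), lowpass = 5, order = 4L,
                            n_points = 201L) {
  if (n_points < 2L) stop("`n_points` must be >= 2", call. = FALSE)
  list(bandpass = bandpass, lowpass = lowpass, order = order,
       n_points = as.integer(n_points))
}

#' Zero-phase 6 Hz low-pass for motion and force channels
#'
#' @param series A [lift_ts()] of kinematic or force channels.
#' @param cutoff_hz Cutoff in Hz (default 6).
#' @return The filtered series.
#' @export
lowpass_motion <- function(series, cutoff_hz = 6) {
  stopifnot_ts(series)
  if (series$fs <= 2 * cutoff_hz)
    stop("sampling frequency too low for the motion low-pass", call. = FALSE)
  butter_filtfilt(series, cutoff_hz, order = 4L, type = "low")
}

#' Segment one lift cycle from box kinematics
#'
#' The lift starts at the first sample where the vertical box velocity rises
#' above the threshold and ends at the first sample after the displacement
#' maximum where the velocity falls back below it (or at the last sample if
#' it never does).
#'
#' @param box_height `lift_ts` of vertical box position, m.
#' @param box_velocity Optional `lift_ts` of vertical box velocity, m/s;
#'   differentiated from `box_height` when omitted.
#' @param cfg A [segmentation_config()].
#' @return A `lift_cycle` list with `start_index`, `end_index`, `start_time`,
#'   `end_time`.
#' @examples
#' t <- seq(0, 2, by = 1 / 340)
#' h <- lift_ts(pmin(t, 1)^2 * 0.5, fs = 340)
#' segment_lift(h)
#' @export
segment_lift <- function(box_height, box_velocity = NULL,
                         cfg = segmentation_config()) {
  stopifnot_ts(box_height, "box_height")
  if (is.null(box_velocity)) box_velocity <- ts_derivative(box_height)
  stopifnot_ts(box_velocity, "box_velocity")
  if (n_samples(box_height) != n_samples(box_velocity))
    stop("height and velocity series must be aligned", call. = FALSE)
  h <- ts_channel(box_height)
  v <- ts_channel(box_velocity)
  if (any(!is.finite(h)) || any(!is.finite(v)))
    stop("invalid series: non-finite samples", call. = FALSE)
  thr <- cfg$velocity_threshold

  above <- which(v > thr)
  if (length(above) == 0L)
    stop("no lift detected: vertical velocity never exceeds the threshold",
         call. = FALSE)
  start <- above[1L]
  imax <- which.max(h)
  after <- which(v < thr & seq_along(v) > imax)
  end <- if (length(after)) after[1L] else length(v)
  if (end <= start)
    stop("no lift detected: degenerate cycle bounds", call. = FALSE)
  tt <- ts_time(box_height)
  structure(list(start_index = start, end_index = end,
                 start_time = tt[start], end_time = tt[end]),
            class = "lift_cycle")
}

#' @export
print.lift_cycle <- function(x, ...) {
  cat(sprintf("<lift_cycle> samples %d..%d (%.3f s to %.3f s, %.3f s long)\n",
              x$start_index, x$end_index, x$start_time, x$end_time,
              x$end_time - x$start_time))
  invisible(x)
}

#' Linear envelope of raw surface EMG
#'
#' Band-pass (default 20-400 Hz), full-wave rectification, then low-pass
#' (default 5 Hz), all zero-phase Butterworth. Small negative values produced
#' by the final filter are clipped at zero.
#'
#' @param raw `lift_ts` of raw EMG, one column per channel.
#' @param cfg An [envelope_config()].
#' @return `lift_ts` of non-negative envelopes.
#' @export
emg_envelope <- function(raw, cfg = envelope_config()) {
  stopifnot_ts(raw, "raw")
  if (raw$fs <= 2 * max(cfg$bandpass))
    stop(sprintf("sampling frequency %g Hz too low for a %g Hz band edge",
                 raw$fs, max(cfg$bandpass)), call. = FALSE)
  bp <- butter_filtfilt(raw, cfg$bandpass, order = cfg$order, type = "pass")
  rect <- lift_ts(abs(bp$values), bp$fs, bp$t0, colnames(bp$values))
  env <- butter_filtfilt(rect, cfg$lowpass, order = cfg$order, type = "low")
  env$values[env$values < 0] <- 0
  env
}

#' Normalize an envelope to iMVC reference peaks
#'
#' Divides each channel by the mean of its three iMVC peak values, yielding
#' a dimensionless activation-like signal.
#'
#' @param env `lift_ts` of envelopes.
#' @param imvc_peaks Numeric vector of peaks (recycled across channels), or a
#'   list with one vector of peaks per channel.
#' @return Normalized `lift_ts`.
#' @export
normalize_envelope <- function(env, imvc_peaks) {
  stopifnot_ts(env, "env")
  nc <- ncol(env$values)
  peaks <- if (is.list(imvc_peaks)) imvc_peaks else
    rep(list(as.numeric(imvc_peaks)), nc)
  if (length(peaks) != nc)
    stop("need one iMVC peak set per channel", call. = FALSE)
  out <- env$values
  for (j in seq_len(nc)) {
    p <- as.numeric(peaks[[j]])
    if (any(!is.finite(p)) || any(p <= 0))
      stop("invalid iMVC: peaks must be positive and finite", call. = FALSE)
    out[, j] <- out[, j] / mean(p)
  }
  lift_ts(out, env$fs, env$t0, colnames(env$values))
}

#' Time-normalize a series over a lift cycle
#'
#' Resamples each channel onto `n_points` equally spaced time points spanning
#' the cycle, using shape-preserving piecewise-cubic (monotone Hermite)
#' interpolation; linear and constant segments are reproduced exactly.
#'
#' @param series A `lift_ts` (any sampling rate; the cycle is located by
#'   time, so motion-rate and EMG-rate streams can share a cycle).
#' @param cycle A `lift_cycle`, or `NULL` to use the full series.
#' @param n_points Output length (default 201).
#' @return A matrix of `n_points` rows (one column per channel); single
#'   channels are returned as a vector.
#' @export
time_normalize <- function(series, cycle = NULL, n_points = 201L) {
  stopifnot_ts(series)
  if (n_points < 2L) stop("`n_points` must be >= 2", call. = FALSE)
  tt <- ts_time(series)
  if (is.null(cycle)) {
    t0 <- tt[1L]; t1 <- tt[length(tt)]
  } else {
    t0 <- cycle$start_time; t1 <- cycle$end_time
  }
  keep <- which(tt >= t0 - 1e-9 & tt <= t1 + 1e-9)
  if (length(keep) < 2L)
    stop("degenerate cycle: fewer than 2 samples inside it", call. = FALSE)
  grid <- seq(t0, t1, length.out = n_points)
  grid <- pmin(pmax(grid, tt[keep[1L]]), tt[keep[length(keep)]])
  out <- matrix(NA_real_, n_points, ncol(series$values),
                dimnames = list(NULL, colnames(series$values)))
  for (j in seq_len(ncol(out))) {
    f <- splinefun(tt[keep], series$values[keep, j], method = "monoH.FC")
    out[, j] <- f(grid)
  }
  if (ncol(out) == 1L) as.numeric(out) else out
}
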