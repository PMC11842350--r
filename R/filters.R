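# Zero-phase Butterworth filtering.
#
# Filter design comes from signal::butter; application is a forward-backward
# pass of a direct-form II transposed IIR (compiled) with odd reflective
# padding and steady-state initial conditions, so constants and slowly
# varying offsets pass without edge transients.

# Steady-state filter state for a unit-step input (companion-matrix solve).
lfilter_zi <- function(b, a) {
  m <- length(a)
  if (m < 2L) return(numeric(0))
  A <- matrix(0, m - 1L, m - 1L)
  A[1L, ] <- -a[-1L] / a[1L]
  if (m > 2L) A[cbind(2:(m - 1L), 1:(m - 2L))] <- 1
  IminusA <- diag(m - 1L) - t(A)
  B <- b[-1L] - a[-1L] * b[1L]
  as.numeric(solve(IminusA, B))
}

apply_iir <- function(b, a, x, zi) {
  iir_filter_cpp(b, a, x, zi * x[1L])
}

# Forward-backward filtering of one numeric vector with odd (point-mirror)
# end padding. padlen defaults to 3x the number of coefficients, as is
# conventional for zero-phase IIR application.
filtfilt_vec <- function(b, a, x, padlen = 3L * max(length(a), length(b))) {
  n <- length(x)
  p <- min(padlen, n - 1L)
  if (p < 1L) stop("series too short for zero-phase filtering", call. = FALSE)
  zi <- lfilter_zi(b, a)
  head_pad <- 2 * x[1L] - x[(p + 1L):2L]
  tail_pad <- 2 * x[n] - x[(n - 1L):(n - p)]
  ext <- c(head_pad, x, tail_pad)
  y <- apply_iir(b, a, ext, zi)
  y <- rev(apply_iir(b, a, rev(y), zi))
  y[(p + 1L):(p + n)]
}

butter_coefs <- function(order, cutoff_hz, fs, type) {
  w <- cutoff_hz / (fs / 2)
  if (any(w <= 0) || any(w >= 1))
    stop(sprintf("cutoff %s Hz infeasible at fs = %g Hz",
                 paste(cutoff_hz, collapse = "-"), fs), call. = FALSE)
  bf <- signal::butter(order, w, type = type)
  list(b = bf$b / bf$a[1L], a = bf$a / bf$a[1L])
}

#' Zero-phase Butterworth filter for a time series
#'
#' Applies a Butterworth filter forward and backward (zero phase lag, squared
#' magnitude response) to every channel. End effects are suppressed with odd
#' reflective padding and steady-state initial conditions.
#'
#' @param x A [lift_ts()].
#' @param cutoff_hz Cutoff frequency in Hz (length 2 for `type = "pass"`).
#' @param order Filter order handed to the design routine (default 4).
#' @param type `"low"`, `"high"` or `"pass"`.
#' @return A filtered `lift_ts` of identical geometry.
#' @examples
#' ts <- lift_ts(rnorm(500), fs = 340)
#' sm <- butter_filtfilt(ts, 6)
#' @export
butter_filtfilt <- function(x, cutoff_hz, order = 4L, type = "low") {
  stopifnot_ts(x)
  if (any(!is.finite(x$values)))
    stop("series contains non-finite values", call. = FALSE)
  co <- butter_coefs(order, cutoff_hz, x$fs, type)
  padlen <- 3L * max(length(co$a), length(co$b))
  if (n_samples(x) <= padlen + 1L)
    stop("series shorter than the filter warm-up length", call. = FALSE)
  out <- x$values
  for (j in seq_len(ncol(out)))
    out[, j] <- filtfilt_vec(co$b, co$a, out[, j], padlen)
  lift_ts(out, x$fs, x$t0, colnames(x$values))
}
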