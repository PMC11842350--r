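#' Uniformly sampled multichannel time series
#'
#' Light-weight container used throughout the package for kinematic, force
#' and EMG recordings: a numeric matrix (samples x channels) plus a sampling
#' frequency. Time stamps are implicit (`t0 + (0:(n-1))/fs`).
#'
#' @param values Numeric vector or matrix, samples in rows. A vector is
#'   treated as a single channel.
#' @param fs Sampling frequency in Hz (> 0).
#' @param t0 Time of the first sample in seconds (default 0).
#' @param channels Optional channel names; defaults to existing column names
#'   or `"ch1"`, `"ch2"`, ...
#' @return An object of class `lift_ts`.
#' @examples
#' ts <- lift_ts(sin(2 * pi * 1 * seq(0, 1, by = 1 / 100)), fs = 100)
#' n_samples(ts)
#' @export
lift_ts <- function(values, fs, t0 = 0, channels = NULL) {
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a single positive number", call. = FALSE)
  if (is.null(dim(values))) values <- matrix(as.numeric(values), ncol = 1L)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(channels)) {
    channels <- colnames(values)
    if (is.null(channels)) channels <- paste0("ch", seq_len(ncol(values)))
  }
  if (length(channels) != ncol(values))
    stop("`channels` length must match the number of columns", call. = FALSE)
  colnames(values) <- channels
  structure(list(values = values, fs = as.numeric(fs), t0 = as.numeric(t0)),
            class = "lift_ts")
}

#' @rdname lift_ts
#' @param x A `lift_ts` object.
#' @export
n_samples <- function(x) nrow(x$values)

#' @rdname lift_ts
#' @export
ts_time <- function(x) x$t0 + (seq_len(n_samples(x)) - 1L) / x$fs

#' @rdname lift_ts
#' @param channel Channel name or index.
#' @export
ts_channel <- function(x, channel = 1L) as.numeric(x$values[, channel])

#' @export
print.lift_ts <- function(x, ...) {
  cat(sprintf("<lift_ts> %d samples x %d channel(s) @ %g Hz (%.3f s)\n",
              n_samples(x), ncol(x$values), x$fs, n_samples(x) / x$fs))
  cat("  channels:", paste(colnames(x$values), collapse = ", "), "\n")
  invisible(x)
}

stopifnot_ts <- function(x, arg = "series") {
  if (!inherits(x, "lift_ts"))
    stop(sprintf("`%s` must be a lift_ts object", arg), call. = FALSE)
  invisible(x)
}

#' Numerical derivative of a time series
#'
#' Central differences in the interior, one-sided at the endpoints.
#'
#' @param x A `lift_ts`.
#' @return A `lift_ts` with the same sampling grid.
#' @export
ts_derivative <- function(x) {
  stopifnot_ts(x)
  v <- x$values
  n <- nrow(v)
  if (n < 2L) stop("need at least 2 samples to differentiate", call. = FALSE)
  d <- v
  d[1L, ] <- (v[2L, ] - v[1L, ]) * x$fs
  d[n, ] <- (v[n, ] - v[n - 1L, ]) * x$fs
  if (n > 2L)
    d[2:(n - 1L), ] <- (v[3:n, , drop = FALSE] -
                          v[1:(n - 2L), , drop = FALSE]) * (x$fs / 2)
  lift_ts(d, x$fs, x$t0, colnames(v))
}
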