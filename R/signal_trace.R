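# Core signal container and minimal preprocessing.

#' Continuous signal trace
#'
#' A uniformly sampled single-channel signal with its sampling rate and
#' channel metadata. All event times produced by the package are seconds
#' from the start of the trace (`start_time` offsets the absolute time
#' axis); sample indices are 0-based and intervals half-open.
#'
#' @param samples Numeric vector of samples (arbitrary units or z-units).
#' @param rate Sampling rate in Hz (> 0).
#' @param start_time Start time of the first sample, seconds.
#' @param channel_id Channel label.
#' @return An object of class `signal_trace`.
#' @export
signal_trace <- function(samples, rate, start_time = 0, channel_id = "chan") {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop("trace must contain at least one sample")
  if (!all(is.finite(samples))) stop("trace samples must be finite")
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("rate must be a single positive number (Hz)")
  structure(
    list(samples = samples, rate = rate, start_time = as.numeric(start_time),
         channel_id = as.character(channel_id)),
    class = "signal_trace")
}

#' @export
print.signal_trace <- function(x, ...) {
  cat(sprintf("<signal_trace> channel '%s': %d samples @ %g Hz (%.2f s), t0 = %g s\n",
              x$channel_id, length(x$samples), x$rate,
              length(x$samples) / x$rate, x$start_time))
  invisible(x)
}

#' @export
length.signal_trace <- function(x) length(x$samples)

#' Trace duration in seconds
#' @param trace A [signal_trace()].
#' @return Duration in seconds.
#' @export
trace_duration <- function(trace) length(trace$samples) / trace$rate

# Time axis of a trace (seconds, relative to recording start).
trace_times <- function(trace) {
  trace$start_time + (seq_along(trace$samples) - 1L) / trace$rate
}

#' Minimal standard preprocessing of a continuous trace
#'
#' Demeans, linearly detrends, band-pass filters (0.5--150 Hz, zero-phase
#' two-pass Butterworth of order 3, applied as a high-pass followed by a
#' low-pass), and z-normalizes over the whole trace. This is the minimal
#' preprocessing applied to every simulated recording before detection, so
#' that detection thresholds are always derived from a unit-variance trace.
#'
#' @param trace A [signal_trace()] of at least 2 s.
#' @param band Pass band in Hz.
#' @param order Butterworth order per pass.
#' @return Preprocessed [signal_trace()], mean 0 and SD 1.
#' @export
preprocess_minimal <- function(trace, band = c(0.5, 150), order = 3L) {
  stopifnot(inherits(trace, "signal_trace"))
  n <- length(trace$samples)
  if (n < 2 * trace$rate) stop("trace must be at least 2 s long")
  x <- trace$samples
  if (stats::sd(x) == 0) stop("degenerate (constant) trace: z-normalization undefined")
  x <- x - mean(x)
  tt <- seq_len(n) - (n + 1) / 2
  x <- x - sum(x * tt) / sum(tt * tt) * tt
  nyq <- trace$rate / 2
  # generous pad for the low high-pass corner: ~3 periods of the corner freq
  pad_hp <- min(n - 1L, ceiling(3 * trace$rate / band[1L]))
  x <- zero_phase_filter(signal::butter(order, band[1L] / nyq, "high"), x, pad_hp)
  if (band[2L] < nyq)
    x <- zero_phase_filter(signal::butter(order, band[2L] / nyq, "low"), x)
  x <- (x - mean(x)) / stats::sd(x)
  signal_trace(x, trace$rate, trace$start_time, trace$channel_id)
}
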