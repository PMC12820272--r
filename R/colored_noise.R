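# 1/f^chi colored-noise generation and exponent-matched surrogates.

# Raw colored noise: white Gaussian noise whose discrete Fourier amplitudes
# are shaped by f^(chi/2); the DC bin is zeroed. Exact power-law spectrum
# in expectation, circularly continuous.
colored_noise_raw <- function(exponent, n, rate, seed = NULL) {
  w <- with_seed(seed, stats::rnorm(n))
  W <- stats::fft(w)
  f <- c(0, seq_len(n - 1L)) * rate / n
  hi <- f > rate / 2
  f[hi] <- rate - f[hi]
  amp <- ifelse(f > 0, f^(exponent / 2), 0)
  Re(stats::fft(W * amp, inverse = TRUE)) / n
}

#' Generate 1/f^chi colored noise
#'
#' White Gaussian noise is spectrally shaped so its power spectral density
#' follows `f^exponent` (the exponent is in slope form, so it is <= 0:
#' 0 is white, -1 pink, -2 brown noise). The trace is then passed through
#' [preprocess_minimal()] (demean, detrend, 0.5--150 Hz band-pass,
#' z-normalize), matching how simulated recordings are treated before
#' event detection.
#'
#' @param exponent Spectral exponent chi, in `[-6, 0]`.
#' @param duration Duration in seconds (>= 2).
#' @param rate Sampling rate in Hz.
#' @param seed Integer seed; the same seed reproduces the trace exactly.
#' @param preprocess Apply [preprocess_minimal()] (default TRUE).
#' @param channel_id Channel label.
#' @return A [signal_trace()].
#' @export
generate_colored_noise <- function(exponent, duration, rate = 1000,
                                   seed = NULL, preprocess = TRUE,
                                   channel_id = "sim") {
  if (!is.finite(exponent)) stop("exponent must be finite")
  if (exponent > 0 || exponent < -6)
    stop("exponent must lie in [-6, 0] (slope form)")
  if (duration < 2) stop("duration too short: need at least 2 s")
  n <- round(duration * rate)
  x <- colored_noise_raw(exponent, n, rate, seed)
  tr <- signal_trace(x, rate, 0, channel_id)
  if (preprocess) preprocess_minimal(tr) else tr
}

#' Surrogate plan: per-segment spectral exponents
#'
#' Describes an exponent-matched surrogate recording as an ordered list of
#' spectral exponents, one per fixed-length segment.
#'
#' @param segment_exponents Numeric vector of exponents (slope form, <= 0).
#' @param segment_length Segment length in seconds (> 0).
#' @param rate Sampling rate in Hz.
#' @param seed Integer base seed; segment `i` uses an independent
#'   sub-stream derived from `seed + i - 1`.
#' @return An object of class `surrogate_plan`.
#' @export
surrogate_plan <- function(segment_exponents, segment_length, rate = 1000,
                           seed = NULL) {
  if (length(segment_exponents) < 1L) stop("empty plan")
  if (segment_length <= 0) stop("segment_length must be positive")
  if (any(!is.finite(segment_exponents)) || any(segment_exponents > 1e-9))
    stop("segment exponents must be finite and <= 0 (slope form)")
  structure(list(segment_exponents = as.numeric(segment_exponents),
                 segment_length = segment_length, rate = rate, seed = seed),
            class = "surrogate_plan")
}

#' @export
print.surrogate_plan <- function(x, ...) {
  cat(sprintf("<surrogate_plan> %d x %g s segments @ %g Hz, chi in [%.2f, %.2f]\n",
              length(x$segment_exponents), x$segment_length, x$rate,
              min(x$segment_exponents), max(x$segment_exponents)))
  invisible(x)
}

#' Build an exponent-matched surrogate recording
#'
#' Simulates one colored-noise segment per plan entry (independent random
#' sub-streams: segment `i` is seeded by `seed + i - 1`, so editing one
#' segment's exponent leaves all other segments untouched), z-normalizes
#' each segment, and concatenates. The surrogate contains no oscillatory
#' activity beyond what colored noise itself produces.
#'
#' Preprocessing scope: with `preprocess = "segment"` (default for segments
#' of >= 2 s) each segment is fully preprocessed before concatenation, which
#' keeps segments exactly independent; `"whole"` (default for sub-2 s
#' segments, e.g. 1 s task-matched surrogates) concatenates raw z-scored
#' segments and band-passes the concatenated trace once.
#'
#' @param plan A [surrogate_plan()].
#' @param preprocess `"segment"`, `"whole"`, or `"auto"` (default).
#' @param channel_id Channel label.
#' @return A [signal_trace()] of length `n_segments * segment_length * rate`.
#' @export
build_matched_surrogate <- function(plan, preprocess = c("auto", "segment", "whole"),
                                    channel_id = "surrogate") {
  stopifnot(inherits(plan, "surrogate_plan"))
  preprocess <- match.arg(preprocess)
  if (preprocess == "auto")
    preprocess <- if (plan$segment_length >= 2) "segment" else "whole"
  nseg <- round(plan$segment_length * plan$rate)
  segs <- lapply(seq_along(plan$segment_exponents), function(i) {
    chi <- min(0, max(-6, plan$segment_exponents[i]))
    sd_i <- if (is.null(plan$seed)) NULL else child_seed(plan$seed, i - 1L)
    x <- colored_noise_raw(chi, nseg, plan$rate, sd_i)
    if (preprocess == "segment") {
      preprocess_minimal(signal_trace(x, plan$rate))$samples
    } else {
      (x - mean(x)) / stats::sd(x)
    }
  })
  x <- unlist(segs, use.names = FALSE)
  tr <- signal_trace(x, plan$rate, 0, channel_id)
  if (preprocess == "whole") tr <- preprocess_minimal(tr)
  tr
}

#' Estimate a surrogate plan from a recording
#'
#' Splits the recording into non-overlapping segments, fits the aperiodic
#' exponent of each segment with [fit_aperiodic()] on a [compute_psd()]
#' spectrum, and returns the matching [surrogate_plan()]. Estimated
#' exponents are clamped to the generator's valid range `[-6, 0]`.
#'
#' @param trace A [signal_trace()] at least two segments long.
#' @param segment_length Segment length in seconds (default 30).
#' @param fit_range Frequency range for the aperiodic fit, Hz.
#' @param seed Seed stored in the plan for surrogate synthesis.
#' @param welch_length Welch sub-segment length (s) for per-segment PSDs;
#'   defaults to `segment_length / 4` for segments of at least 8 s
#'   (within-segment averaging reduces estimator variance), else
#'   `segment_length`.
#' @return A [surrogate_plan()] with one exponent per segment.
#' @export
match_plan_from_recording <- function(trace, segment_length = 30,
                                      fit_range = c(20, 45), seed = NULL,
                                      welch_length = NULL) {
  stopifnot(inherits(trace, "signal_trace"))
  if (is.null(welch_length))
    welch_length <- if (segment_length >= 8) segment_length / 4 else segment_length
  nseg <- floor(trace_duration(trace) / segment_length)
  if (nseg < 2L) stop("trace shorter than two segments")
  spm <- round(segment_length * trace$rate)
  chis <- vapply(seq_len(nseg), function(i) {
    seg <- signal_trace(trace$samples[((i - 1L) * spm + 1L):(i * spm)],
                        trace$rate)
    ps <- compute_psd(seg, segment_length = welch_length)
    fit_aperiodic(ps, fit_range)$exponent
  }, 0)
  surrogate_plan(pmin(0, pmax(-6, chis)), segment_length, trace$rate, seed)
}

#' Read / write a surrogate plan as delimited text
#' @param path File path.
#' @return For the reader a [surrogate_plan()]; for the writer `path`.
#' @export
read_plan <- function(path) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  surrogate_plan(df$exponent,
                 segment_length = df$segment_length[1L],
                 rate = df$rate[1L],
                 seed = if (is.na(df$seed[1L])) NULL else df$seed[1L])
}

#' @rdname read_plan
#' @param plan A [surrogate_plan()].
#' @export
write_plan <- function(plan, path) {
  write.table(data.frame(segment_index = seq_along(plan$segment_exponents),
                         exponent = plan$segment_exponents,
                         segment_length = plan$segment_length,
                         rate = plan$rate,
                         seed = plan$seed %||% NA),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
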