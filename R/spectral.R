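# PSD estimation and aperiodic (1/f) parameterization.

#' Welch power spectrum with quarter-octave smoothing
#'
#' Hanning-tapered Welch average over overlapping segments, evaluated on a
#' 1 Hz grid from `fmin` to `fmax`. The native-resolution log10-power is
#' smoothed along log2-frequency with a Gaussian kernel of FWHM
#' `smooth_octaves` while being resampled onto the output grid, which
#' realizes the quarter-octave frequency smoothing.
#'
#' @param trace A [signal_trace()] at least `segment_length` long.
#' @param segment_length Welch segment length in seconds (default 30).
#' @param overlap Fractional overlap between segments (default 0.7).
#' @param fmin,fmax Output grid bounds in Hz (1 Hz steps).
#' @param smooth_octaves Gaussian FWHM of the log-frequency smoothing in
#'   octaves; 0 disables smoothing (nearest native bins are averaged).
#' @return An object of class `power_spectrum` with fields `freqs`
#'   (Hz), `power` (linear units), `segment_length`, `overlap`,
#'   `n_segments`.
#' @export
compute_psd <- function(trace, segment_length = 30, overlap = 0.7,
                        fmin = 2, fmax = 128, smooth_octaves = 0.25) {
  stopifnot(inherits(trace, "signal_trace"))
  rate <- trace$rate
  nseg <- round(segment_length * rate)
  n <- length(trace$samples)
  if (n < nseg) stop("trace shorter than one segment")
  step <- max(1L, round(nseg * (1 - overlap)))
  starts <- seq(1L, n - nseg + 1L, by = step)
  win <- 0.5 - 0.5 * cos(2 * pi * seq(0, nseg - 1) / (nseg - 1))
  wnorm <- sum(win^2)
  nfreq <- floor(nseg / 2)
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- trace$samples[s:(s + nseg - 1L)]
    seg <- (seg - mean(seg)) * win
    sp <- Mod(stats::fft(seg)[2:(nfreq + 1L)])^2
    acc <- acc + sp
  }
  pxx <- acc / length(starts) * 2 / (rate * wnorm)
  f_native <- seq_len(nfreq) * rate / nseg
  f_out <- seq(fmin, min(fmax, floor(max(f_native))), by = 1)
  keep <- f_native > 0 & pxx > 0
  lf <- log2(f_native[keep])
  lp <- log10(pxx[keep])
  if (smooth_octaves > 0) {
    sdo <- smooth_octaves / (2 * sqrt(2 * log(2)))
    p_out <- vapply(f_out, function(f0) {
      d <- lf - log2(f0)
      sel <- abs(d) <= 4 * sdo
      if (!any(sel)) sel <- which.min(abs(d))
      w <- exp(-0.5 * (d[sel] / sdo)^2)
      10^(sum(w * lp[sel]) / sum(w))
    }, 0)
  } else {
    p_out <- vapply(f_out, function(f0) {
      i <- which.min(abs(f_native - f0))
      pxx[i]
    }, 0)
  }
  structure(list(freqs = f_out, power = p_out,
                 segment_length = segment_length, overlap = overlap,
                 n_segments = length(starts)),
            class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("<power_spectrum> %d bins, %g-%g Hz (%d x %g s segments, %.0f%% overlap)\n",
              length(x$freqs), min(x$freqs), max(x$freqs),
              x$n_segments, x$segment_length, 100 * x$overlap))
  invisible(x)
}

#' Aperiodic (1/f) fit of a power spectrum
#'
#' Ordinary least-squares fit of `log10(power)` on `log10(frequency)` over
#' `fit_range`. The slope is the spectral exponent in slope form (negative
#' for 1/f-type spectra); equivalent to fixed-mode aperiodic spectral
#' parameterization with no oscillatory peaks.
#'
#' @param spectrum A [compute_psd()] result, or any list with `freqs` and
#'   `power`.
#' @param fit_range Frequency range `(lo, hi)` in Hz (default 20--45).
#' @return An object of class `spectral_fit` with fields `exponent`,
#'   `offset` (log10-power intercept), `fit_range`, `r_squared`, `n_bins`.
#' @export
fit_aperiodic <- function(spectrum, fit_range = c(20, 45)) {
  if (fit_range[1L] >= fit_range[2L]) stop("fit_range must be increasing")
  sel <- spectrum$freqs >= fit_range[1L] & spectrum$freqs <= fit_range[2L]
  if (sum(sel) < 5L) stop("need at least 5 frequency bins inside fit_range")
  p <- spectrum$power[sel]
  if (any(p <= 0)) stop("non-positive power inside fit_range: log undefined")
  x <- log10(spectrum$freqs[sel])
  y <- log10(p)
  xc <- x - mean(x)
  slope <- sum(xc * y) / sum(xc^2)
  intercept <- mean(y) - slope * mean(x)
  res <- y - (intercept + slope * x)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sum(res^2) / sst else 1
  structure(list(exponent = slope, offset = intercept,
                 fit_range = fit_range, r_squared = r2, n_bins = sum(sel)),
            class = "spectral_fit")
}

#' @export
print.spectral_fit <- function(x, ...) {
  cat(sprintf("<spectral_fit> chi = %.3f, offset = %.3f, R^2 = %.4f (%g-%g Hz, %d bins)\n",
              x$exponent, x$offset, x$r_squared,
              x$fit_range[1L], x$fit_range[2L], x$n_bins))
  invisible(x)
}

#' Time-resolved spectral exponent
#'
#' Slides a window along the trace and fits the aperiodic exponent of each
#' windowed segment. Window positions step by `step` seconds (e.g. 30 s
#' windows with 3 s steps give 90% overlap; 1 s windows with 0.1 s steps
#' match trial-resolved analyses).
#'
#' @param trace A [signal_trace()] at least `window` long.
#' @param window Window length in seconds.
#' @param step Step between window starts in seconds (> 0).
#' @param fit_range Frequency range for the aperiodic fit, Hz.
#' @param r2_flag Segments with fit `r_squared` below this are flagged
#'   (column `flagged`), not dropped.
#' @param welch_length Welch sub-segment length (s) used for the PSD of
#'   each window; defaults to `window / 4` (Welch averaging within the
#'   window reduces per-window estimator variance) for windows of at
#'   least 8 s and to `window` itself for shorter windows.
#' @return A `data.frame` of class `exponent_series` with columns `time`
#'   (window centers, s), `exponent`, `r_squared`, `flagged`; attributes
#'   `window` and `step`.
#' @export
time_resolved_exponent <- function(trace, window = 30, step = 3,
                                   fit_range = c(20, 45), r2_flag = 0.5,
                                   welch_length = NULL) {
  stopifnot(inherits(trace, "signal_trace"))
  if (step <= 0) stop("step must be positive")
  if (is.null(welch_length))
    welch_length <- if (window >= 8) window / 4 else window
  n <- length(trace$samples)
  wsmp <- round(window * trace$rate)
  if (n < wsmp) stop("trace shorter than one window")
  starts <- seq(1L, n - wsmp + 1L, by = max(1L, round(step * trace$rate)))
  fits <- lapply(starts, function(s) {
    seg <- signal_trace(trace$samples[s:(s + wsmp - 1L)], trace$rate)
    ps <- compute_psd(seg, segment_length = welch_length)
    fit_aperiodic(ps, fit_range)
  })
  out <- data.frame(
    time = trace$start_time + (starts - 1L) / trace$rate + window / 2,
    exponent = vapply(fits, function(f) f$exponent, 0),
    r_squared = vapply(fits, function(f) f$r_squared, 0))
  out$flagged <- out$r_squared < r2_flag
  attr(out, "window") <- window
  attr(out, "step") <- step
  class(out) <- c("exponent_series", "data.frame")
  out
}

#' Read / write an exponent series as delimited text
#' @param path File path.
#' @return For the reader an `exponent_series`; for the writer `path`.
#' @export
read_exponent_series <- function(path) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  out <- data.frame(time = df$time_s, exponent = df$exponent,
                    r_squared = df$r_squared)
  out$flagged <- out$r_squared < 0.5
  class(out) <- c("exponent_series", "data.frame")
  out
}

#' @rdname read_exponent_series
#' @param series An `exponent_series`.
#' @export
write_exponent_series <- function(series, path) {
  write.table(data.frame(time_s = series$time, exponent = series$exponent,
                         r_squared = series$r_squared),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
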