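# Detector parameterizations: the five published ripple detectors.

#' Detector configuration
#'
#' Full parameterization of the shared detection engine
#' (band-pass -> envelope -> transform -> threshold -> duration ->
#' event criteria -> merge -> IED exclusion -> trough alignment).
#' Use [detector_preset()] for the five published parameterizations.
#'
#' @param band Pass band `(lo, hi)` in Hz.
#' @param filter_family `"butterworth"`, `"fir"` (band-pass), or
#'   `"fir_sequential"` (high-pass at `band[1]` then low-pass at `band[2]`).
#' @param filter_order Filter order (per pass). For FIR high-pass an odd
#'   order is incremented by one, as in MATLAB's `fir1`.
#' @param envelope Envelope extraction; only `"hilbert_abs"` is used by the
#'   presets.
#' @param smoothing List describing envelope smoothing: `list(type =
#'   "lowpass", hz = )`, `list(type = "moving_average", width = )` seconds,
#'   `list(type = "kaiser_lowpass", hz = , order = , beta = )`, or
#'   `list(type = "none")`.
#' @param normalize `"zscore"` (threshold in SD units above the mean) or
#'   `"none"`.
#' @param threshold_rule One of `list(type = "sd_range", lo = , hi = )`
#'   (detect above `lo`, envelope peak must stay within `[lo, hi]`),
#'   `list(type = "sd_min", x = )`, `list(type = "percentile", p = )`, or
#'   `list(type = "rms_frac", frac = )` (threshold at `frac` times the
#'   envelope RMS).
#' @param duration Event duration bounds `(min, max)` in seconds measured
#'   at the threshold crossing (`Inf` for no upper bound).
#' @param merge_gap Events closer than this (end-to-start, s) are merged;
#'   `NA` disables merging.
#' @param amplitude_clip Clip the envelope at mean + this many SD before
#'   computing threshold statistics (`NA` disables).
#' @param square_envelope Square the envelope before smoothing/thresholding.
#' @param frequency_min Reject events whose within-event mean frequency
#'   (trough-count based) is at or below this (Hz); `NA` disables.
#' @param max_peak_diff Reject events whose successive peak-to-peak
#'   amplitudes of the band-passed signal (in its own SD units) differ by
#'   this much or more; `NA` disables.
#' @param ied_exclusion Half-width (s) of the exclusion window around
#'   detected interictal discharges; `NA` disables.
#' @param detector_id Identifier recorded in event tables.
#' @return An object of class `detector_config`.
#' @export
detector_config <- function(band, filter_family = "butterworth",
                            filter_order = 3L, envelope = "hilbert_abs",
                            smoothing = list(type = "none"),
                            normalize = "zscore",
                            threshold_rule = list(type = "sd_min", x = 2),
                            duration = c(0.025, 0.2), merge_gap = NA,
                            amplitude_clip = NA, square_envelope = FALSE,
                            frequency_min = NA, max_peak_diff = NA,
                            ied_exclusion = NA, detector_id = "custom") {
  if (band[1L] >= band[2L]) stop("band must be increasing")
  if (duration[1L] >= duration[2L]) stop("duration min must be below max")
  structure(list(band = band, filter_family = filter_family,
                 filter_order = as.integer(filter_order),
                 envelope = envelope, smoothing = smoothing,
                 normalize = normalize, threshold_rule = threshold_rule,
                 duration = duration, merge_gap = merge_gap,
                 amplitude_clip = amplitude_clip,
                 square_envelope = square_envelope,
                 frequency_min = frequency_min,
                 max_peak_diff = max_peak_diff,
                 ied_exclusion = ied_exclusion,
                 detector_id = detector_id),
            class = "detector_config")
}

#' @export
print.detector_config <- function(x, ...) {
  dur_hi <- if (is.finite(x$duration[2L])) sprintf("%.0f ms", 1000 * x$duration[2L]) else "Inf"
  cat(sprintf("<detector_config> '%s': %g-%g Hz %s(%d), %s, dur %.0f ms-%s, merge %s, IED %s\n",
              x$detector_id, x$band[1L], x$band[2L], x$filter_family,
              x$filter_order, x$threshold_rule$type,
              1000 * x$duration[1L], dur_hi,
              if (is.na(x$merge_gap)) "-" else sprintf("%.0f ms", 1000 * x$merge_gap),
              if (is.na(x$ied_exclusion)) "-" else sprintf("+/-%g s", x$ied_exclusion)))
  invisible(x)
}

#' Published ripple-detector presets
#'
#' The five detection algorithms benchmarked by the package:
#' \describe{
#'   \item{1}{80--120 Hz Butterworth, Hilbert envelope, 10 Hz low-pass
#'     smoothing, z-normalized; 2--4 SD amplitude window for 25--200 ms;
#'     mean frequency > 80 Hz; successive peak-to-peak amplitude
#'     differential < 2; merge within 500 ms; IED exclusion +/- 2.5 s.}
#'   \item{2}{80 Hz FIR high-pass then 100 Hz FIR low-pass (order 3),
#'     Hilbert envelope with 20 ms moving-average smoothing, z-normalized;
#'     threshold at the 99th percentile of the envelope; 38--100 ms; IED
#'     exclusion +/- 1.5 s.}
#'   \item{3}{80--120 Hz Butterworth order 2 two-pass, Hilbert envelope,
#'     unsmoothed; > mean + 2 SD for at least 25 ms; merge within 15 ms.}
#'   \item{4}{70--180 Hz FIR order 5 two-pass, Hilbert envelope; extreme
#'     values clipped at 4 SD, squared, 40 Hz Kaiser low-pass smoothed;
#'     threshold statistics from the clipped-squared-smoothed series
#'     applied to the unclipped squared smoothed envelope at mean + 4 SD;
#'     20--200 ms; merge within 30 ms; artifact exclusion +/- 50 ms.}
#'   \item{5}{As detector 1 but 20--200 ms duration, merge within 100 ms,
#'     IED exclusion +/- 1 s, and no peak-to-peak differential criterion.}
#' }
#'
#' @param id Detector number, 1--5.
#' @return A [detector_config()].
#' @export
detector_preset <- function(id) {
  if (!id %in% 1:5) stop("unknown detector id: ", id)
  switch(as.character(id),
    "1" = detector_config(
      band = c(80, 120), filter_family = "butterworth", filter_order = 3L,
      smoothing = list(type = "lowpass", hz = 10), normalize = "zscore",
      threshold_rule = list(type = "sd_range", lo = 2, hi = 4),
      duration = c(0.025, 0.2), merge_gap = 0.5,
      frequency_min = 80, max_peak_diff = 2, ied_exclusion = 2.5,
      detector_id = "1"),
    "2" = detector_config(
      band = c(80, 100), filter_family = "fir_sequential", filter_order = 3L,
      smoothing = list(type = "moving_average", width = 0.02),
      normalize = "zscore",
      threshold_rule = list(type = "percentile", p = 0.99),
      duration = c(0.038, 0.1), merge_gap = NA, ied_exclusion = 1.5,
      detector_id = "2"),
    "3" = detector_config(
      band = c(80, 120), filter_family = "butterworth", filter_order = 2L,
      smoothing = list(type = "none"), normalize = "none",
      threshold_rule = list(type = "sd_min", x = 2),
      duration = c(0.025, Inf), merge_gap = 0.015,
      detector_id = "3"),
    "4" = detector_config(
      band = c(70, 180), filter_family = "fir", filter_order = 5L,
      smoothing = list(type = "kaiser_lowpass", hz = 40, order = 40L, beta = 5),
      normalize = "zscore",
      threshold_rule = list(type = "sd_min", x = 4),
      duration = c(0.02, 0.2), merge_gap = 0.03,
      amplitude_clip = 4, square_envelope = TRUE, ied_exclusion = 0.05,
      detector_id = "4"),
    "5" = detector_config(
      band = c(80, 120), filter_family = "butterworth", filter_order = 3L,
      smoothing = list(type = "lowpass", hz = 10), normalize = "zscore",
      threshold_rule = list(type = "sd_range", lo = 2, hi = 4),
      duration = c(0.02, 0.2), merge_gap = 0.1,
      frequency_min = 80, ied_exclusion = 1,
      detector_id = "5"))
}
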