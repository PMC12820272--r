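# Shared detection engine: band-pass -> envelope -> transform -> threshold
# -> duration -> event criteria -> merge -> IED exclusion -> trough alignment.

empty_events <- function() {
  data.frame(channel = character(0), detector = character(0),
             trough_s = numeric(0), start_s = numeric(0), end_s = numeric(0),
             peak_z = numeric(0), freq_hz = numeric(0),
             stringsAsFactors = FALSE)
}

band_filter <- function(x, rate, config) {
  nyq <- rate / 2
  if (config$filter_family == "butterworth") {
    flt <- signal::butter(config$filter_order, config$band / nyq, "pass")
    zero_phase_filter(flt, x)
  } else if (config$filter_family == "fir_sequential") {
    ord <- config$filter_order
    hp_ord <- if (ord %% 2L == 1L) ord + 1L else ord  # fir1 needs even for high-pass
    hp <- suppressWarnings(signal::fir1(hp_ord, config$band[1L] / nyq, "high"))
    lp <- signal::fir1(ord, config$band[2L] / nyq, "low")
    zero_phase_filter(lp, zero_phase_filter(hp, x))
  } else {
    flt <- signal::fir1(config$filter_order, config$band / nyq, "pass")
    zero_phase_filter(flt, x)
  }
}

smooth_envelope <- function(env, rate, smoothing) {
  switch(smoothing$type,
    none = env,
    lowpass = zero_phase_filter(
      signal::butter(3, smoothing$hz / (rate / 2), "low"), env),
    moving_average = moving_average(env, round(smoothing$width * rate)),
    kaiser_lowpass = {
      ord <- smoothing$order %||% 40L
      w <- signal::kaiser(ord + 1L, smoothing$beta %||% 5)
      flt <- signal::fir1(ord, smoothing$hz / (rate / 2), "low", window = w)
      zero_phase_filter(flt, env)
    },
    stop("unknown smoothing type: ", smoothing$type))
}

# Mean within-event oscillation frequency: (trough count - 1) / duration,
# troughs being local minima of the band-passed signal inside the event.
event_frequency <- function(xb_seg, duration) {
  n <- length(local_minima(xb_seg))
  (n - 1) / duration
}

# Largest absolute difference between successive peak-to-peak amplitudes of
# the band-passed signal inside the event (signal in its own SD units).
event_peak_diff <- function(xbz_seg) {
  d <- diff(sign(diff(xbz_seg)))
  ext <- which(d != 0) + 1L
  if (length(ext) < 3L) return(0)
  p2p <- abs(diff(xbz_seg[ext]))
  if (length(p2p) < 2L) return(0)
  max(abs(diff(p2p)))
}

#' Detect candidate ripple events
#'
#' Runs the configured detection pipeline on a (preprocessed) continuous
#' trace. All threshold statistics (mean, SD, percentiles) are computed
#' over the entire recording, so state- or segment-wise differences in
#' background amplitude directly bias where events are found.
#'
#' @param trace A [signal_trace()], at least 10 s, rate >= twice the upper
#'   band edge. Normally the output of [preprocess_minimal()].
#' @param config A [detector_config()], e.g. from [detector_preset()].
#' @param ieds Optional precomputed IED event table from [detect_ieds()];
#'   computed on the fly when the config requests IED exclusion and `ieds`
#'   is `NULL`.
#' @return Event `data.frame` with columns `channel`, `detector`,
#'   `trough_s`, `start_s`, `end_s`, `peak_z`, `freq_hz`, sorted by
#'   `trough_s`.
#' @export
detect_ripples <- function(trace, config, ieds = NULL) {
  stopifnot(inherits(trace, "signal_trace"), inherits(config, "detector_config"))
  rate <- trace$rate
  if (length(trace$samples) < 10 * rate)
    stop("trace too short: need at least 10 s for stable threshold statistics")
  if (rate < 2 * config$band[2L])
    stop("sampling rate too low for the requested band (aliasing)")
  if (stats::sd(trace$samples) == 0) stop("degenerate (constant) trace")

  xb <- band_filter(trace$samples, rate, config)
  env <- hilbert_envelope(xb)

  env_stats_src <- env
  if (!is.na(config$amplitude_clip)) {
    clip_at <- mean(env) + config$amplitude_clip * stats::sd(env)
    env_stats_src <- pmin(env, clip_at)
  }
  env_det <- env
  if (isTRUE(config$square_envelope)) {
    env_stats_src <- env_stats_src^2
    env_det <- env_det^2
  }
  env_stats_src <- smooth_envelope(env_stats_src, rate, config$smoothing)
  env_det <- if (is.na(config$amplitude_clip) && !isTRUE(config$square_envelope))
    env_stats_src else smooth_envelope(env_det, rate, config$smoothing)

  mu <- mean(env_stats_src)
  sigma <- stats::sd(env_stats_src)
  if (sigma == 0) stop("degenerate envelope")
  z <- (env_det - mu) / sigma

  rule <- config$threshold_rule
  thr <- switch(rule$type,
    sd_range = rule$lo,
    sd_min = rule$x,
    percentile = as.numeric(stats::quantile(z, rule$p)),
    rms_frac = (rule$frac * sqrt(mean(env_det^2)) - mu) / sigma,
    stop("unknown threshold rule: ", rule$type))

  cr <- runs_above(z > thr)
  if (!nrow(cr)) return(empty_events())
  durs <- (cr[, 2L] - cr[, 1L] + 1L) / rate
  cr <- cr[durs >= config$duration[1L] & durs <= config$duration[2L], , drop = FALSE]
  if (!nrow(cr)) return(empty_events())

  xbz <- xb / stats::sd(xb)
  keep <- logical(nrow(cr))
  peak_z <- numeric(nrow(cr))
  freq <- numeric(nrow(cr))
  for (i in seq_len(nrow(cr))) {
    s <- cr[i, 1L]; e <- cr[i, 2L]
    zseg <- z[s:e]
    peak_z[i] <- max(zseg)
    dur_i <- (e - s + 1L) / rate
    freq[i] <- event_frequency(xb[s:e], dur_i)
    ok <- TRUE
    if (rule$type == "sd_range") ok <- peak_z[i] <= rule$hi
    if (ok && !is.na(config$frequency_min))
      ok <- freq[i] > config$frequency_min
    if (ok && !is.na(config$max_peak_diff))
      ok <- event_peak_diff(xbz[s:e]) < config$max_peak_diff
    keep[i] <- ok
  }
  cr <- cr[keep, , drop = FALSE]
  if (!nrow(cr)) return(empty_events())
  peak_z <- peak_z[keep]; freq <- freq[keep]

  t0 <- trace$start_time
  ev <- data.frame(channel = trace$channel_id, detector = config$detector_id,
                   trough_s = t0 + (cr[, 1L] + cr[, 2L] - 2L) / 2 / rate,
                   start_s = t0 + (cr[, 1L] - 1L) / rate,
                   end_s = t0 + cr[, 2L] / rate,
                   peak_z = peak_z, freq_hz = freq,
                   stringsAsFactors = FALSE)

  if (!is.na(config$merge_gap)) ev <- merge_events(ev, config$merge_gap)

  if (!is.na(config$ied_exclusion)) {
    if (is.null(ieds)) ieds <- detect_ieds(trace)
    ev <- exclude_near_ieds(ev, ieds, config$ied_exclusion)
  }
  if (!nrow(ev)) return(ev)
  align_to_trough(ev, trace)
}

#' Merge events closer than a gap
#'
#' Events whose end-to-start separation is at most `gap` seconds are fused
#' into a single event spanning their union. The merged event keeps the
#' maximum `peak_z` and inherits `trough_s` and `freq_hz` from the
#' constituent with that peak. Idempotent.
#'
#' @param events Event `data.frame`, sorted by `start_s`.
#' @param gap Merge gap in seconds.
#' @return Merged event `data.frame`.
#' @export
merge_events <- function(events, gap) {
  if (nrow(events) < 2L) return(events)
  events <- events[order(events$start_s), , drop = FALSE]
  grp <- cumsum(c(1L, as.integer(events$start_s[-1L] -
                                   cummax_end(events$end_s)[-nrow(events)] > gap)))
  out <- do.call(rbind, lapply(split(events, grp), function(g) {
    best <- which.max(g$peak_z)
    data.frame(channel = g$channel[1L], detector = g$detector[1L],
               trough_s = g$trough_s[best], start_s = min(g$start_s),
               end_s = max(g$end_s), peak_z = g$peak_z[best],
               freq_hz = g$freq_hz[best], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$trough_s), , drop = FALSE]
}

cummax_end <- function(end_s) cummax(end_s)

#' Detect interictal epileptiform discharge (IED) candidates
#'
#' Band-pass 25--80 Hz, Hilbert envelope, z-normalized; events exceed 2 SD
#' for 20--100 ms and are discarded when the z-scored envelope of the raw
#' (broadband) signal does not also exceed 2 SD inside the event. Events
#' in close temporal proximity (1 s) are concatenated.
#'
#' @param trace A [signal_trace()] (preprocessed broadband signal).
#' @param band Detection band in Hz.
#' @param threshold Envelope threshold in SD units.
#' @param duration Duration bounds in seconds.
#' @param raw_threshold Broadband-envelope confirmation threshold (SD).
#' @param concat_gap Concatenation window in seconds.
#' @return Event `data.frame` (detector `"IED"`).
#' @export
detect_ieds <- function(trace, band = c(25, 80), threshold = 2,
                        duration = c(0.02, 0.1), raw_threshold = 2,
                        concat_gap = 1) {
  stopifnot(inherits(trace, "signal_trace"))
  rate <- trace$rate
  if (stats::sd(trace$samples) == 0) stop("degenerate (constant) trace")
  xb <- zero_phase_filter(signal::butter(3, band / (rate / 2), "pass"),
                          trace$samples)
  env <- hilbert_envelope(xb)
  z <- (env - mean(env)) / stats::sd(env)
  renv <- hilbert_envelope(trace$samples)
  rz <- (renv - mean(renv)) / stats::sd(renv)
  cr <- runs_above(z > threshold)
  if (!nrow(cr)) return(empty_events())
  durs <- (cr[, 2L] - cr[, 1L] + 1L) / rate
  cr <- cr[durs >= duration[1L] & durs <= duration[2L], , drop = FALSE]
  if (!nrow(cr)) return(empty_events())
  keep <- vapply(seq_len(nrow(cr)), function(i)
    max(rz[cr[i, 1L]:cr[i, 2L]]) > raw_threshold, TRUE)
  cr <- cr[keep, , drop = FALSE]
  if (!nrow(cr)) return(empty_events())
  t0 <- trace$start_time
  pk <- vapply(seq_len(nrow(cr)), function(i) {
    s <- cr[i, 1L]; e <- cr[i, 2L]
    s + which.max(z[s:e]) - 1L
  }, 0L)
  ev <- data.frame(channel = trace$channel_id, detector = "IED",
                   trough_s = t0 + (pk - 1L) / rate,
                   start_s = t0 + (cr[, 1L] - 1L) / rate,
                   end_s = t0 + cr[, 2L] / rate,
                   peak_z = vapply(seq_len(nrow(cr)), function(i)
                     max(z[cr[i, 1L]:cr[i, 2L]]), 0),
                   freq_hz = NA_real_, stringsAsFactors = FALSE)
  merge_events(ev, concat_gap)
}

#' Discard ripples near interictal discharges
#'
#' Removes every candidate ripple whose trough lies within `window`
#' seconds of a detected IED (measured against the IED's span expanded by
#' the window on both sides).
#'
#' @param ripples,ieds Event tables (sorted).
#' @param window Exclusion half-width in seconds.
#' @return Filtered ripple table.
#' @export
exclude_near_ieds <- function(ripples, ieds, window) {
  if (!nrow(ripples) || is.null(ieds) || !nrow(ieds)) return(ripples)
  bad <- rep(FALSE, nrow(ripples))
  for (i in seq_len(nrow(ieds))) {
    bad <- bad | (ripples$trough_s >= ieds$start_s[i] - window &
                  ripples$trough_s <= ieds$end_s[i] + window)
  }
  out <- ripples[!bad, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Align events to the nearest broadband trough
#'
#' Sets each event's `trough_s` to the time of the local minimum of the
#' broadband trace nearest to the within-event envelope maximum (located
#' here by the event's recorded trough/peak position). Ties break toward
#' the earlier time; the search widens by 10 ms beyond the event bounds
#' when the event interior contains no strict local minimum. Idempotent.
#'
#' @param events Event `data.frame`.
#' @param trace Broadband [signal_trace()].
#' @return Event table with updated `trough_s`, sorted by `trough_s`.
#' @export
align_to_trough <- function(events, trace) {
  if (!nrow(events)) return(events)
  x <- trace$samples
  rate <- trace$rate
  t0 <- trace$start_time
  n <- length(x)
  for (i in seq_len(nrow(events))) {
    s <- max(1L, round((events$start_s[i] - t0) * rate) + 1L)
    e <- min(n, round((events$end_s[i] - t0) * rate))
    if (e - s < 2L) next
    ref <- round((events$trough_s[i] - t0) * rate) + 1L
    mins <- local_minima(x[s:e]) + s - 1L
    if (!length(mins)) {
      w <- round(0.01 * rate)
      s2 <- max(1L, s - w); e2 <- min(n, e + w)
      mins <- local_minima(x[s2:e2]) + s2 - 1L
    }
    if (!length(mins)) next
    d <- abs(mins - ref)
    events$trough_s[i] <- t0 + (mins[which.min(d)] - 1L) / rate
  }
  events[order(events$trough_s), , drop = FALSE]
}

#' Event-locked broadband average
#'
#' Cuts broadband snippets around each event trough, z-normalizes each
#' snippet to its own baseline window, and averages. Events too close to
#' the trace edges are skipped and counted.
#'
#' @param events Event `data.frame` with `trough_s`.
#' @param trace Broadband [signal_trace()].
#' @param window Half-width of the snippet in seconds (default 2.5).
#' @param baseline Baseline window relative to the trough, seconds
#'   (default `c(-2.5, -2)`).
#' @return List of class `event_average`: `lag` (s), `average`,
#'   `n_used`, `n_skipped`.
#' @export
event_locked_average <- function(events, trace, window = 2.5,
                                 baseline = c(-2.5, -2)) {
  stopifnot(inherits(trace, "signal_trace"))
  rate <- trace$rate
  t0 <- trace$start_time
  n <- length(trace$samples)
  w <- round(window * rate)
  lag <- (-w:w) / rate
  bsel <- lag >= baseline[1L] & lag <= baseline[2L]
  acc <- numeric(2L * w + 1L)
  used <- 0L; skipped <- 0L
  for (i in seq_len(nrow(events))) {
    c0 <- round((events$trough_s[i] - t0) * rate) + 1L
    if (c0 - w < 1L || c0 + w > n) { skipped <- skipped + 1L; next }
    snip <- trace$samples[(c0 - w):(c0 + w)]
    bm <- mean(snip[bsel]); bs <- stats::sd(snip[bsel])
    if (!is.finite(bs) || bs == 0) { skipped <- skipped + 1L; next }
    acc <- acc + (snip - bm) / bs
    used <- used + 1L
  }
  if (used == 0L) stop("no eligible events fully inside the trace")
  structure(list(lag = lag, average = acc / used,
                 n_used = used, n_skipped = skipped),
            class = "event_average")
}

#' @export
print.event_average <- function(x, ...) {
  cat(sprintf("<event_average> %d events averaged (%d skipped), lag %g..%g s\n",
              x$n_used, x$n_skipped, min(x$lag), max(x$lag)))
  invisible(x)
}

#' Read / write event tables as delimited text
#' @param path File path.
#' @return For the reader an event `data.frame`; for the writer `path`.
#' @export
read_events <- function(path) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  names(df) <- c("channel", "detector", "trough_s", "start_s", "end_s",
                 "peak_z", "freq_hz")[seq_len(ncol(df))]
  df$channel <- as.character(df$channel)
  df$detector <- as.character(df$detector)
  df
}

#' @rdname read_events
#' @param events Event `data.frame`.
#' @export
write_events <- function(events, path) {
  write.table(events, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
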