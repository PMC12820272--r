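# Noise-floor analytics: detector sensitivity sweeps, density-by-exponent
# profiles, and percent-within-noise-floor estimation.

#' Detector noise-sensitivity sweep
#'
#' Simulates colored-noise traces over a grid of spectral exponents and
#' counts the events each detector reports, although the traces contain no
#' oscillations. Every detection is by construction a false positive, so
#' the resulting density curve is the detector's noise profile.
#'
#' Each (exponent, iteration) cell uses an independently seeded trace
#' derived from `seed`. Detectors share the trace and the IED detection
#' within a cell.
#'
#' @param detectors Integer vector of detector ids (1--5) or a list of
#'   [detector_config()] objects.
#' @param exponents Exponent grid (default -4 to 0 in 0.1 steps).
#' @param duration Trace duration per cell in seconds (default 600; the
#'   full-scale setting is 3600).
#' @param iterations Simulated traces per exponent (default 10; the
#'   full-scale setting is 100).
#' @param rate Sampling rate in Hz.
#' @param seed Integer base seed (mandatory for reproducibility).
#' @param verbose Print progress.
#' @return An object of class `sweep_result`: `exponent_grid`, `density`
#'   (matrix exponent x detector, Hz), `density_sd`, `counts` (array
#'   exponent x detector x iteration), `iterations`, `trace_duration`,
#'   `detector_ids`, `seed`.
#' @export
run_sweep <- function(detectors = 1:5, exponents = seq(-4, 0, by = 0.1),
                      duration = 600, iterations = 10, rate = 1000,
                      seed = 1L, verbose = FALSE) {
  if (length(detectors) == 0L) stop("empty detector set")
  if (iterations < 1L) stop("iterations must be >= 1")
  configs <- lapply(detectors, function(d)
    if (inherits(d, "detector_config")) d else detector_preset(d))
  ids <- vapply(configs, function(cfg) cfg$detector_id, "")
  need_ied <- any(vapply(configs, function(cfg) !is.na(cfg$ied_exclusion), TRUE))
  ne <- length(exponents); nd <- length(configs)
  counts <- array(0, dim = c(ne, nd, iterations),
                  dimnames = list(NULL, ids, NULL))
  for (i in seq_len(ne)) {
    for (j in seq_len(iterations)) {
      cell_seed <- child_seed(seed, (i - 1L) * iterations + (j - 1L))
      tr <- generate_colored_noise(exponents[i], duration, rate, cell_seed)
      ieds <- if (need_ied) detect_ieds(tr) else NULL
      for (k in seq_len(nd))
        counts[i, k, j] <- nrow(detect_ripples(tr, configs[[k]], ieds))
    }
    if (verbose)
      message(sprintf("chi = %5.2f: mean counts %s", exponents[i],
                      paste(round(rowMeans(matrix(counts[i, , ], nrow = nd)), 1),
                            collapse = " / ")))
  }
  density <- apply(counts, c(1, 2), mean) / duration
  density_sd <- apply(counts, c(1, 2), stats::sd) / duration
  structure(list(exponent_grid = exponents, density = density,
                 density_sd = density_sd, counts = counts,
                 iterations = iterations, trace_duration = duration,
                 detector_ids = ids, seed = seed),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %d exponents x %d detectors x %d iterations (%g s traces)\n",
              length(x$exponent_grid), length(x$detector_ids), x$iterations,
              x$trace_duration))
  pk <- peak_exponent(x)
  cat("  density argmax: ",
      paste(sprintf("det %s: %.1f", names(pk), pk), collapse = ", "), "\n")
  invisible(x)
}

#' Exponent of maximal noise-floor density per detector
#'
#' Argmax of the mean density curve over the exponent grid; ties break
#' toward the more negative exponent.
#'
#' @param result A [run_sweep()] result.
#' @return Named numeric vector, one exponent per detector.
#' @export
peak_exponent <- function(result) {
  out <- vapply(seq_along(result$detector_ids), function(k) {
    result$exponent_grid[which.max(result$density[, k])]
  }, 0)
  names(out) <- result$detector_ids
  out
}

#' Effect size of the exponent on noise-floor density
#'
#' One-way repeated-measures ANOVA across the exponent grid with
#' iterations as subjects; returns the partial eta squared
#' `SS_effect / (SS_effect + SS_error)` per detector.
#'
#' @param result A [run_sweep()] result with at least 2 iterations.
#' @return Named numeric vector of partial eta squared values.
#' @export
sweep_effect_size <- function(result) {
  if (result$iterations < 2L) stop("need at least 2 iterations")
  if (length(result$exponent_grid) < 2L) stop("need at least 2 grid levels")
  out <- vapply(seq_along(result$detector_ids), function(k) {
    m <- t(result$counts[, k, ]) / result$trace_duration  # iterations x exponents
    rm_anova(m)$eta_sq_partial
  }, 0)
  names(out) <- result$detector_ids
  out
}

#' Write a sweep result as a delimited table
#' @param result A [run_sweep()] result.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_sweep <- function(result, path) {
  df <- data.frame(exponent = rep(result$exponent_grid,
                                  times = length(result$detector_ids)),
                   detector = rep(result$detector_ids,
                                  each = length(result$exponent_grid)),
                   density = as.vector(result$density),
                   density_sd = as.vector(result$density_sd))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Event density binned by spectral exponent
#'
#' Assigns each event to the exponent bin of the segment containing its
#' trough (segments from a non-overlapping [time_resolved_exponent()]
#' series, span `time +/- step/2`) and divides by the total time spent in
#' each bin.
#'
#' @param events Event `data.frame`.
#' @param series An `exponent_series` whose `step` equals its `window`
#'   (non-overlapping segments).
#' @param bins Bin edges (default -8 to 0 in 0.1 steps).
#' @param source Label recorded on the profile (`"experimental"` or
#'   `"surrogate"`).
#' @param grouping Optional group label.
#' @return `data.frame` of class `density_profile` with columns `bin_lo`,
#'   `bin_hi`, `n_events`, `time_s`, `density`.
#' @export
density_by_exponent <- function(events, series, bins = seq(-8, 0, by = 0.1),
                                source = "experimental", grouping = "all") {
  step <- attr(series, "step") %||% diff(series$time[1:2])
  seg_lo <- series$time - step / 2
  seg_hi <- series$time + step / 2
  if (nrow(events)) {
    seg_of <- vapply(events$trough_s, function(t) {
      i <- which(t >= seg_lo & t < seg_hi)
      if (!length(i)) NA_integer_ else i[1L]
    }, 0L)
    if (anyNA(seg_of)) stop("event outside the exponent series span")
  } else seg_of <- integer(0)
  nb <- length(bins) - 1L
  bin_of_seg <- findInterval(series$exponent, bins, rightmost.closed = TRUE)
  time_in_bin <- vapply(seq_len(nb), function(b)
    step * sum(bin_of_seg == b), 0)
  n_in_bin <- vapply(seq_len(nb), function(b)
    sum(bin_of_seg[seg_of] == b), 0)
  out <- data.frame(bin_lo = bins[-length(bins)], bin_hi = bins[-1L],
                    n_events = n_in_bin, time_s = time_in_bin,
                    density = ifelse(time_in_bin > 0, n_in_bin / time_in_bin, 0))
  attr(out, "source") <- source
  attr(out, "grouping") <- grouping
  class(out) <- c("density_profile", "data.frame")
  out
}

#' Exponent range of the detection noise floor
#'
#' Bounds of the exponent bins in which the surrogate profile has nonzero
#' density. Experimental events falling into segments with exponents
#' inside this range are attributable to the noise floor.
#'
#' @param surr_profile A [density_by_exponent()] profile of surrogate
#'   detections.
#' @return `c(lo, hi)`: lower edge of the first and upper edge of the last
#'   nonzero bin.
#' @export
floor_range <- function(surr_profile) {
  nz <- which(surr_profile$n_events > 0)
  if (!length(nz)) stop("all-zero surrogate profile: no noise floor detected")
  c(surr_profile$bin_lo[nz[1L]], surr_profile$bin_hi[nz[length(nz)]])
}

#' Percent of detections within the noise floor
#'
#' Compares event counts on experimental and exponent-matched surrogate
#' recordings covering the same time base. The percentage within the
#' noise floor is `100 * min(1, n_surrogate / n_experimental)` per group;
#' the uncapped ratio and the raw counts are always reported. Groups with
#' no experimental events yield `NA`.
#'
#' @param exp_events,surr_events Event tables from the experimental and
#'   surrogate recordings.
#' @param schedule Optional [state_schedule()]; events are grouped by the
#'   state containing their trough. Without it a single `"all"` group is
#'   used.
#' @return `data.frame` of class `floor_estimate` with columns `group`,
#'   `n_experimental`, `n_surrogate`, `ratio`, `percent_within_floor`.
#' @export
estimate_floor <- function(exp_events, surr_events, schedule = NULL) {
  if (is.null(schedule)) {
    groups <- "all"
    ge <- rep("all", nrow(exp_events))
    gs <- rep("all", nrow(surr_events))
  } else {
    groups <- unique(schedule$label)
    ge <- schedule_label_at(schedule, exp_events$trough_s)
    gs <- schedule_label_at(schedule, surr_events$trough_s)
  }
  out <- do.call(rbind, lapply(groups, function(g) {
    ne <- sum(ge == g, na.rm = TRUE)
    ns <- sum(gs == g, na.rm = TRUE)
    ratio <- if (ne > 0) ns / ne else NA_real_
    data.frame(group = g, n_experimental = ne, n_surrogate = ns,
               ratio = ratio,
               percent_within_floor = if (ne > 0) 100 * min(1, ratio) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("floor_estimate", "data.frame")
  out
}
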