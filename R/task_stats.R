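# Trial-locked density analysis and pseudo-population statistics.

#' Trial table
#'
#' @param onset,offset Epoch bounds in seconds (half-open).
#' @param condition Condition label per epoch (e.g. ITI_1, task, ITI_2).
#' @return `data.frame` of class `trial_table`.
#' @export
trial_table <- function(onset, offset, condition) {
  df <- data.frame(onset = as.numeric(onset), offset = as.numeric(offset),
                   condition = as.character(condition),
                   stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("trial table must contain at least one trial")
  if (any(df$offset <= df$onset)) stop("trial offset must exceed onset")
  if (is.unsorted(df$onset)) stop("trial onsets must be increasing")
  class(df) <- c("trial_table", "data.frame")
  df
}

#' Read / write a trial table as delimited text
#' @param path File path.
#' @return For the reader a [trial_table()]; for the writer `path`.
#' @export
read_trials <- function(path) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  trial_table(df[[1L]], df[[2L]], df[[3L]])
}

#' @rdname read_trials
#' @param trials A [trial_table()].
#' @export
write_trials <- function(trials, path) {
  write.table(data.frame(onset_s = trials$onset, offset_s = trials$offset,
                         condition = trials$condition),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Trial-locked event density timecourse
#'
#' Event density (events/s) in a sliding window at each time point
#' relative to trial onset, averaged across trials that extend to that
#' time point.
#'
#' @param events Event `data.frame`.
#' @param trials A [trial_table()] (each row is one lockable epoch).
#' @param window Moving-window length in seconds (default 1).
#' @param step Step in seconds (default 0.1).
#' @return `data.frame` of class `density_timecourse` with columns `time`
#'   (s relative to onset, window centers) and `density` (Hz); attributes
#'   `window`, `step`, `n_trials`.
#' @export
density_timecourse <- function(events, trials, window = 1, step = 0.1) {
  if (window <= 0 || step <= 0) stop("window and step must be positive")
  spans <- trials$offset - trials$onset
  if (window > max(spans)) stop("window longer than the longest trial")
  grid <- seq(0, max(spans), by = step)
  dens <- vapply(grid, function(t) {
    active <- which(spans >= t)
    if (!length(active)) return(NA_real_)
    cnt <- vapply(active, function(i) {
      lo <- trials$onset[i] + t - window / 2
      hi <- trials$onset[i] + t + window / 2
      sum(events$trough_s >= lo & events$trough_s < hi)
    }, 0)
    mean(cnt) / window
  }, 0)
  out <- data.frame(time = grid, density = dens)
  attr(out, "window") <- window
  attr(out, "step") <- step
  attr(out, "n_trials") <- nrow(trials)
  class(out) <- c("density_timecourse", "data.frame")
  out
}

#' Mean event density per condition
#'
#' Events inside each condition's epochs divided by the condition's total
#' time, per channel.
#'
#' @param events Event `data.frame` (with a `channel` column).
#' @param trials A [trial_table()].
#' @return `data.frame` with columns `channel`, `condition`, `n_events`,
#'   `time_s`, `density`.
#' @export
epoch_density <- function(events, trials) {
  conds <- unique(trials$condition)
  chans <- if (nrow(events)) unique(events$channel) else "chan"
  out <- do.call(rbind, lapply(chans, function(ch) {
    ev <- events[events$channel == ch, , drop = FALSE]
    do.call(rbind, lapply(conds, function(co) {
      sel <- trials$condition == co
      tt <- sum(trials$offset[sel] - trials$onset[sel])
      if (tt <= 0) stop("zero total time for condition ", co)
      cnt <- sum(vapply(which(sel), function(i)
        sum(ev$trough_s >= trials$onset[i] & ev$trough_s < trials$offset[i]), 0))
      data.frame(channel = ch, condition = co, n_events = cnt,
                 time_s = tt, density = cnt / tt, stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' One-way repeated-measures ANOVA
#'
#' Within-subject one-way ANOVA on a subjects x conditions matrix (for
#' pseudo-population tests the unit of observation is the channel). Fitted
#' with [stats::aov()] using an `Error(subject)` stratum; the partial eta
#' squared is `SS_condition / (SS_condition + SS_error)`. An optional
#' Greenhouse-Geisser correction adjusts the degrees of freedom of the
#' p-value.
#'
#' @param values Numeric matrix or data.frame, subjects in rows,
#'   conditions in columns (>= 3 subjects, >= 2 conditions, no missing
#'   cells).
#' @param gg Apply the Greenhouse-Geisser sphericity correction
#'   (default FALSE).
#' @return List of class `rm_anova`: `F`, `df1`, `df2`, `p`,
#'   `eta_sq_partial`, `ss_condition`, `ss_error`, `gg_epsilon`.
#' @export
rm_anova <- function(values, gg = FALSE) {
  m <- as.matrix(values)
  if (anyNA(m)) stop("missing cells")
  n <- nrow(m); k <- ncol(m)
  if (k < 2L) stop("need at least 2 conditions")
  if (n < 2L) stop("need at least 2 subjects")
  df <- data.frame(y = as.vector(m),
                   subject = factor(rep(seq_len(n), times = k)),
                   condition = factor(rep(seq_len(k), each = n)))
  fit <- stats::aov(y ~ condition + Error(subject), data = df)
  s <- summary(fit)
  tab <- s[["Error: Within"]][[1L]]
  rownames(tab) <- trimws(rownames(tab))
  ss_cond <- tab["condition", "Sum Sq"]
  ss_err <- tab["Residuals", "Sum Sq"]
  df1 <- tab["condition", "Df"]
  df2 <- tab["Residuals", "Df"]
  # treat roundoff-scale sums of squares as exact zeros
  tol <- 1e-12 * max(sum(m^2), .Machine$double.xmin)
  if (ss_cond < tol) ss_cond <- 0
  if (ss_err < tol) ss_err <- 0
  if (ss_err == 0) {
    f <- if (ss_cond == 0) 0 else Inf
  } else f <- (ss_cond / df1) / (ss_err / df2)
  eta <- if (ss_cond + ss_err == 0) 0 else ss_cond / (ss_cond + ss_err)
  eps <- NA_real_
  if (gg) {
    S <- stats::cov(m)
    J <- diag(k) - 1 / k
    Sc <- J %*% S %*% J
    eps <- sum(diag(Sc))^2 / ((k - 1) * sum(Sc * Sc))
    eps <- min(1, max(1 / (k - 1), eps))
  }
  d1 <- if (gg) eps * df1 else df1
  d2 <- if (gg) eps * df2 else df2
  p <- if (!is.finite(f)) 0 else if (f == 0) 1 else stats::pf(f, d1, d2, lower.tail = FALSE)
  structure(list(F = f, df1 = df1, df2 = df2, p = p,
                 eta_sq_partial = eta, ss_condition = ss_cond,
                 ss_error = ss_err, gg_epsilon = eps),
            class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("RM-ANOVA: F(%g, %g) = %.3f, p = %.4g, partial eta^2 = %.3f\n",
              x$df1, x$df2, x$F, x$p, x$eta_sq_partial))
  invisible(x)
}

#' Spearman rank correlation
#'
#' Tie-corrected Spearman correlation with a two-sided p-value
#' (t-approximation), via [stats::cor.test()].
#'
#' @param x,y Numeric vectors of equal length >= 4.
#' @return List: `rho`, `p`, `n`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 4L) stop("need at least 4 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant input")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Partial correlation controlling for a confounder
#'
#' Pearson correlation of the residuals of `x` and `y` after regressing
#' each on `control`; the p-value uses a t-test with `n - 3` degrees of
#' freedom.
#'
#' @param x,y Numeric vectors of equal length >= 5.
#' @param control Confounding variable (vector or matrix of columns).
#' @return List: `r`, `p`, `df`, `n`.
#' @export
partial_correlation <- function(x, y, control) {
  control <- as.matrix(control)
  n <- length(x)
  if (length(y) != n || nrow(control) != n) stop("inputs must have equal length")
  if (n < 5L) stop("need at least 5 observations")
  if (any(apply(control, 2, stats::sd) == 0)) stop("constant control variable")
  X <- cbind(1, control)
  rx <- stats::lm.fit(X, x)$residuals
  ry <- stats::lm.fit(X, y)$residuals
  # a variable fully explained by the control leaves only roundoff residuals
  if (stats::sd(rx) < 1e-10 * stats::sd(x) ||
      stats::sd(ry) < 1e-10 * stats::sd(y)) {
    return(list(r = 0, p = 1, df = n - 2L - ncol(control), n = n))
  }
  r <- stats::cor(rx, ry)
  df <- n - 2L - ncol(control)
  tval <- r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(-abs(tval), df)
  list(r = r, p = p, df = df, n = n)
}

#' Compare two correlation coefficients (Fisher z)
#'
#' Two-sided test of the difference between two independent correlations
#' via the Fisher z-transform.
#'
#' @param r1,r2 Correlation coefficients (|r| < 1).
#' @param n1,n2 Sample sizes (>= 4).
#' @return List: `z`, `p`.
#' @export
compare_correlations <- function(r1, n1, r2, n2) {
  if (abs(r1) >= 1 || abs(r2) >= 1) stop("correlations must satisfy |r| < 1")
  if (n1 < 4L || n2 < 4L) stop("need n >= 4 in both samples")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}
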