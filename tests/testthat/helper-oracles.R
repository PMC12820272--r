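# Independent oracles used to validate the implementation. These share no
# code with the package paths they check.

# Log-log periodogram slope via octave-binned raw periodogram + lm.
# Independent of compute_psd/fit_aperiodic (raw FFT, log-spaced binning).
oracle_loglog_slope <- function(trace, frange = c(1, 150), bins_per_octave = 6) {
  x <- trace$samples
  n <- length(x)
  sp <- Mod(stats::fft(x - mean(x))[2:(floor(n / 2) + 1)])^2
  f <- seq_len(floor(n / 2)) * trace$rate / n
  sel <- f >= frange[1] & f <= frange[2]
  f <- f[sel]; sp <- sp[sel]
  edges <- 2^seq(log2(frange[1]), log2(frange[2]),
                 by = 1 / bins_per_octave)
  bin <- findInterval(f, edges, rightmost.closed = TRUE)
  bf <- tapply(f, bin, mean)
  bp <- tapply(sp, bin, mean)
  ok <- bp > 0
  unname(coef(lm(log10(bp[ok]) ~ log10(bf[ok])))[2])
}

# Band power of a trace around f0 (+/- half_bw Hz) from the raw periodogram.
oracle_band_power <- function(samples, rate, f0, half_bw = 2) {
  n <- length(samples)
  sp <- Mod(stats::fft(samples - mean(samples))[2:(floor(n / 2) + 1)])^2
  f <- seq_len(floor(n / 2)) * rate / n
  sum(sp[f >= f0 - half_bw & f <= f0 + half_bw])
}

# Brute-force one-way repeated-measures sums of squares (textbook loops).
oracle_rm_ss <- function(m) {
  n <- nrow(m); k <- ncol(m)
  gm <- mean(m)
  ss_cond <- 0
  for (j in 1:k) ss_cond <- ss_cond + n * (mean(m[, j]) - gm)^2
  ss_subj <- 0
  for (i in 1:n) ss_subj <- ss_subj + k * (mean(m[i, ]) - gm)^2
  ss_tot <- sum((m - gm)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  list(ss_cond = ss_cond, ss_subj = ss_subj, ss_err = ss_err,
       F = (ss_cond / (k - 1)) / (ss_err / ((n - 1) * (k - 1))),
       eta = ss_cond / (ss_cond + ss_err))
}

# Spearman rho from explicit average ranks + Pearson product-moment formula.
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# First-order partial correlation from the pairwise-correlation recursion.
oracle_partial_r <- function(x, y, z) {
  rxy <- cor(x, y); rxz <- cor(x, z); ryz <- cor(y, z)
  (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
}

# Ripple-band (80-120 Hz) envelope of a raw vector: independent minimal
# band-pass + analytic amplitude used to check injections and detections.
oracle_ripple_envelope <- function(samples, rate) {
  n <- length(samples)
  X <- stats::fft(samples)
  f <- c(0, seq_len(n - 1)) * rate / n
  f[f > rate / 2] <- rate - f[f > rate / 2]
  H <- as.numeric(f >= 80 & f <= 120)
  xb <- Re(stats::fft(X * H, inverse = TRUE) / n)
  Xb <- stats::fft(xb)
  h <- numeric(n); h[1] <- 1
  if (n %% 2 == 0) { h[n/2 + 1] <- 1; h[2:(n/2)] <- 2 } else h[2:((n+1)/2)] <- 2
  Mod(stats::fft(Xb * h, inverse = TRUE) / n)
}

# Evaluate expr under a fixed seed without touching the global stream.
with_test_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
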