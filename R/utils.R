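# Internal numerical helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Analytic-signal amplitude (Hilbert envelope)
#'
#' Computes the magnitude of the analytic signal via the frequency-domain
#' Hilbert transform.
#'
#' @param x Numeric vector.
#' @return Numeric vector of the same length: instantaneous amplitude.
#' @export
hilbert_envelope <- function(x) {
  n <- length(x)
  if (n < 2L) return(abs(x))
  X <- stats::fft(x)
  h <- numeric(n)
  h[1L] <- 1
  if (n %% 2L == 0L) {
    h[n / 2L + 1L] <- 1
    h[2L:(n / 2L)] <- 2
  } else {
    h[2L:((n + 1L) / 2L)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

#' Zero-phase (two-pass) filtering with reflection padding
#'
#' Applies `flt` forward and backward so the net response is zero-phase with
#' the squared magnitude of the one-pass filter. The input is extended at
#' both ends by odd reflection before filtering, which suppresses the edge
#' transients that plain two-pass filtering produces on signals dominated by
#' low-frequency power (steep 1/f noise); the padding is discarded.
#'
#' @param flt A filter as returned by [signal::butter()] or an `Ma`
#'   coefficient vector from [signal::fir1()].
#' @param x Numeric vector to filter.
#' @param padlen Reflection pad length in samples (capped at `length(x) - 1`).
#' @return Filtered vector, same length as `x`.
#' @export
zero_phase_filter <- function(flt, x, padlen = 3000L) {
  if (is.numeric(flt)) {
    b <- flt; a <- 1
  } else {
    b <- flt$b; a <- flt$a
  }
  n <- length(x)
  L <- min(n - 1L, as.integer(padlen))
  if (L > 0L) {
    pre <- 2 * x[1L] - x[(L + 1L):2L]
    post <- 2 * x[n] - x[(n - 1L):(n - L)]
    xe <- c(pre, x, post)
  } else xe <- x
  y <- rev(apply_filter(b, a, xe))
  y <- rev(apply_filter(b, a, y))
  if (L > 0L) y[(L + 1L):(L + n)] else y
}

# One causal filter pass (zero initial conditions), direct form.
apply_filter <- function(b, a, x) {
  nb <- length(b)
  if (nb > 1L) {
    y <- stats::filter(c(rep(0, nb - 1L), x), b, method = "convolution",
                       sides = 1L)
    y <- y[nb:(nb + length(x) - 1L)]
  } else y <- b * x
  if (length(a) > 1L)
    y <- stats::filter(y, -a[-1L] / a[1L], method = "recursive") / a[1L]
  as.numeric(y)
}

# One-pass FIR smoothing by centered moving average (NA edges -> nearest
# valid value).
moving_average <- function(x, k) {
  k <- max(1L, as.integer(k))
  y <- as.numeric(stats::filter(x, rep(1 / k, k), sides = 2))
  if (anyNA(y)) {
    idx <- which(!is.na(y))
    y[seq_len(idx[1L] - 1L)] <- y[idx[1L]]
    y[seq((idx[length(idx)] + 1L), length.out = length(y) - idx[length(idx)])] <-
      y[idx[length(idx)]]
  }
  y
}

# Runs of TRUE in a logical vector as an integer matrix [start, end]
# (inclusive sample indices).
runs_above <- function(above) {
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

# Indices of strict local minima of x.
local_minima <- function(x) {
  if (length(x) < 3L) return(integer(0))
  which(diff(sign(diff(x))) > 0) + 1L
}

# Derive a bounded child seed from a base seed and stream index.
child_seed <- function(seed, stream) {
  as.integer((as.double(seed) + 99991 * as.double(stream)) %% 2147483587) + 1L
}
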