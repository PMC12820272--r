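# Synthetic-recording fixture generator: state-dependent exponent dynamics
# with optional injected ripple bursts and IED-like transients.

#' Fixture specification
#'
#' Describes a synthetic recording whose aperiodic background follows a
#' state schedule (one spectral exponent per state), optionally with
#' injected band-limited ripple bursts and sharp IED-like transients for
#' exercising detector plumbing. Surrogate benchmarking itself never
#' injects events; injections exist so true positives can be planted at
#' known times in tests.
#'
#' @param schedule A [state_schedule()].
#' @param exponent_by_state Named numeric vector mapping each schedule
#'   label to a spectral exponent (slope form, <= 0).
#' @param injected_ripples Optional `data.frame(time, frequency, duration,
#'   amplitude)`: burst center time (s), carrier frequency (70--180 Hz),
#'   duration (0.02--0.2 s), amplitude in SD units of the background.
#' @param injected_ieds Optional `data.frame(time, amplitude)`: sharp
#'   transient center time (s) and amplitude in background-SD units.
#' @param rate Sampling rate in Hz (default 1000).
#' @param seed Integer seed.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(schedule, exponent_by_state, injected_ripples = NULL,
                         injected_ieds = NULL, rate = 1000, seed = 1L) {
  stopifnot(inherits(schedule, "state_schedule"))
  missing_states <- setdiff(unique(schedule$label), names(exponent_by_state))
  if (length(missing_states))
    stop("no exponent given for state(s): ", paste(missing_states, collapse = ", "))
  if (!is.null(injected_ripples)) {
    injected_ripples <- as.data.frame(injected_ripples)
    if (any(injected_ripples$frequency < 70 | injected_ripples$frequency > 180))
      stop("injected ripple frequency must lie within 70-180 Hz")
    if (any(injected_ripples$duration < 0.02 | injected_ripples$duration > 0.2))
      stop("injected ripple duration must lie within 0.02-0.2 s")
  }
  if (!is.null(injected_ieds)) injected_ieds <- as.data.frame(injected_ieds)
  structure(list(schedule = schedule, exponent_by_state = exponent_by_state,
                 injected_ripples = injected_ripples,
                 injected_ieds = injected_ieds, rate = rate,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

# Ricker (mexican-hat) wavelet; sigma in seconds. Its energy concentrates
# near 1/(2*pi*sigma) Hz, so sigma ~ 5 ms lands in the 25-80 Hz IED band.
ricker_wave <- function(t, sigma) {
  a <- (t / sigma)^2
  (1 - a) * exp(-a / 2)
}

#' Generate a synthetic recording from a fixture specification
#'
#' The aperiodic background is built per schedule epoch as colored noise
#' with the state's exponent (independent sub-streams per epoch),
#' z-normalized per epoch and concatenated. Injected ripples are additive
#' Hann-enveloped sinusoids; injected IEDs are Ricker-wavelet transients
#' (sigma 5 ms). The whole trace is then passed through
#' [preprocess_minimal()].
#'
#' @param spec A [fixture_spec()].
#' @param channel_id Channel label.
#' @return A list with elements `trace` (a [signal_trace()]) and
#'   `schedule` (the input [state_schedule()]).
#' @export
generate_fixture <- function(spec, channel_id = "fixture") {
  stopifnot(inherits(spec, "fixture_spec"))
  sched <- spec$schedule
  rate <- spec$rate
  t0 <- sched$start[1L]
  segs <- lapply(seq_len(nrow(sched)), function(i) {
    nseg <- round((sched$end[i] - sched$start[i]) * rate)
    chi <- spec$exponent_by_state[[sched$label[i]]]
    x <- colored_noise_raw(min(0, max(-6, chi)), nseg, rate,
                           child_seed(spec$seed, i - 1L))
    (x - mean(x)) / stats::sd(x)
  })
  x <- unlist(segs, use.names = FALSE)
  tt <- t0 + (seq_along(x) - 1L) / rate
  if (!is.null(spec$injected_ripples)) {
    for (i in seq_len(nrow(spec$injected_ripples))) {
      rp <- spec$injected_ripples[i, ]
      sel <- which(tt >= rp$time - rp$duration / 2 & tt < rp$time + rp$duration / 2)
      if (!length(sel)) next
      ph <- seq_along(sel) / length(sel)
      hann <- 0.5 - 0.5 * cos(2 * pi * ph)
      x[sel] <- x[sel] + rp$amplitude * hann *
        sin(2 * pi * rp$frequency * (tt[sel] - rp$time))
    }
  }
  if (!is.null(spec$injected_ieds)) {
    for (i in seq_len(nrow(spec$injected_ieds))) {
      ie <- spec$injected_ieds[i, ]
      sel <- which(abs(tt - ie$time) <= 0.04)
      if (!length(sel)) next
      x[sel] <- x[sel] + ie$amplitude * ricker_wave(tt[sel] - ie$time, 0.005)
    }
  }
  tr <- preprocess_minimal(signal_trace(x, rate, t0, channel_id))
  list(trace = tr, schedule = sched)
}
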