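# Core trace type, minimal preprocessing, file round trips, fixtures.

test_that("preprocessing z-normalizes and band-limits the trace", {
  set.seed(11)
  tr <- signal_trace(rnorm(60000), 1000)
  out <- preprocess_minimal(tr)
  expect_lt(abs(mean(out$samples)), 1e-10)
  expect_equal(sd(out$samples), 1, tolerance = 1e-9)

  # out-of-band attenuation, measured as the transfer gain at 200 Hz
  # relative to the (untouched) 100 Hz passband on the same white noise.
  # The z-normalization rescales both bands identically, so the gain
  # ratio isolates the filter; an order-3 two-pass Butterworth at 150 Hz
  # attenuates 200 Hz by ~16 dB.
  g200 <- oracle_band_power(out$samples, 1000, 200) /
    oracle_band_power(tr$samples, 1000, 200)
  g100 <- oracle_band_power(out$samples, 1000, 100) /
    oracle_band_power(tr$samples, 1000, 100)
  atten_db <- 10 * log10(g200 / g100)
  expect_lt(atten_db, -15)

  expect_error(preprocess_minimal(signal_trace(rep(0, 5000), 1000)),
               "degenerate")
})

test_that("repeated preprocessing only re-attenuates the band corners", {
  # A second pass only re-applies the Butterworth corner attenuation, so
  # in-band content is preserved: compare the two traces away from the
  # temporal edges and outside the corner octaves (2-80 Hz).
  tr <- generate_colored_noise(-2, 30, 1000, seed = 5)
  twice <- preprocess_minimal(tr)
  core <- seq(round(0.05 * 30000), round(0.95 * 30000))
  # the second z-normalization rescales globally (low-frequency corner power
  # is removed again), so in-band shape preservation means a *constant*
  # gain across the pass band
  ratios <- vapply(c(5, 20, 60), function(f0)
    oracle_band_power(twice$samples[core], 1000, f0) /
      oracle_band_power(tr$samples[core], 1000, f0), 0)
  expect_lt(max(ratios) / min(ratios), 1.05)
  # and white noise (negligible mass at the corners) is near-unchanged
  wh <- generate_colored_noise(0, 30, 1000, seed = 6)
  wh2 <- preprocess_minimal(wh)
  rel_rms <- sqrt(mean((wh2$samples[core] - wh$samples[core])^2)) /
    sqrt(mean(wh$samples[core]^2))
  expect_lt(rel_rms, 0.2)
})

test_that("raw-float and delimited traces round-trip", {
  set.seed(13)
  tr <- signal_trace(rnorm(5000), 500, channel_id = "ch7")
  p <- file.path(tempdir(), "trace.bin")
  write_trace(tr, p, "raw-float")
  back <- read_trace(p, "raw-float")
  expect_identical(back$samples, tr$samples)
  expect_equal(back$rate, 500)
  expect_equal(back$channel_id, "ch7")

  pd <- file.path(tempdir(), "trace.txt")
  write_trace(tr, pd, "delimited")
  backd <- read_trace(pd, "delimited", rate = 500)
  expect_equal(backd$samples, tr$samples, tolerance = 1e-12)
  expect_error(read_trace(pd, "delimited"), "rate")
})

test_that("EDF files round-trip with two channels", {
  set.seed(14)
  tr1 <- signal_trace(rnorm(3000), 1000, channel_id = "HPC")
  tr2 <- signal_trace(rnorm(3000) * 5, 1000, channel_id = "PFC")
  p <- file.path(tempdir(), "pair.edf")
  write_trace(list(tr1, tr2), p, "edf")
  back <- read_trace(p, "edf")
  expect_length(back, 2)
  expect_equal(back[[1]]$channel_id, "HPC")
  expect_equal(back[[2]]$channel_id, "PFC")
  expect_equal(back[[1]]$rate, 1000)
  # 16-bit quantization tolerance
  expect_lt(max(abs(back[[1]]$samples - tr1$samples)), diff(range(tr1$samples)) / 60000)
  expect_lt(max(abs(back[[2]]$samples - tr2$samples)), diff(range(tr2$samples)) / 60000)
})

test_that("state schedules validate and round-trip", {
  sch <- state_schedule(c(0, 120), c(120, 240), c("wake", "SWS"))
  p <- file.path(tempdir(), "sched.tsv")
  write_schedule(sch, p)
  back <- read_schedule(p)
  expect_equal(back$label, c("wake", "SWS"))
  expect_error(state_schedule(c(0, 100), c(120, 240), c("a", "b")), "overlap")
  expect_error(state_schedule(0, 0, "a"), "exceed")
})

test_that("fixtures are deterministic and recover the per-state exponents", {
  sch <- state_schedule(c(0, 120), c(120, 240), c("wake", "SWS"))
  spec <- fixture_spec(sch, c(wake = -2, SWS = -3), seed = 21)
  fx1 <- generate_fixture(spec)
  fx2 <- generate_fixture(spec)
  expect_identical(fx1$trace$samples, fx2$trace$samples)

  for (i in 1:2) {
    seg <- signal_trace(fx1$trace$samples[((i - 1) * 120000 + 1):(i * 120000)],
                        1000)
    fit <- fit_aperiodic(compute_psd(seg))
    expected <- c(-2, -3)[i]
    expect_lt(abs(fit$exponent - expected), 0.15)
  }
})

test_that("injected ripples surface in the ripple-band envelope", {
  sch <- state_schedule(0, 30, "SWS")
  spec <- fixture_spec(sch, c(SWS = -3),
                       injected_ripples = data.frame(
                         time = 10, frequency = 90, duration = 0.1,
                         amplitude = 5),
                       seed = 31)
  fx <- generate_fixture(spec)
  env <- oracle_ripple_envelope(fx$trace$samples, 1000)
  z <- (env - mean(env)) / sd(env)
  near <- z[9900:10100]
  expect_gt(max(near), 2)
  # and the envelope peak is at the injection, not elsewhere
  expect_lt(abs(which.max(env) - 10000), 100)
})

test_that("fixture specs validate injection bounds", {
  sch <- state_schedule(0, 30, "wake")
  expect_error(fixture_spec(sch, c(wake = -2),
                            injected_ripples = data.frame(
                              time = 5, frequency = 50, duration = 0.1,
                              amplitude = 3)), "70-180")
  expect_error(fixture_spec(sch, c(wake = -2),
                            injected_ripples = data.frame(
                              time = 5, frequency = 90, duration = 0.5,
                              amplitude = 3)), "duration")
  expect_error(fixture_spec(sch, c(other = -2)), "no exponent")
})
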