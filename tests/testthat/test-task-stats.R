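# Trial-locked densities and the pseudo-population statistics.

ev_at <- function(troughs, channel = "c") {
  data.frame(channel = rep(channel, length(troughs)),
             detector = rep("1", length(troughs)), trough_s = troughs,
             start_s = troughs - 0.01, end_s = troughs + 0.01,
             peak_z = rep(3, length(troughs)),
             freq_hz = rep(90, length(troughs)))
}

test_that("trial-locked density places mass where the events are", {
  trials <- trial_table(onset = seq(0, 90, by = 10),
                        offset = seq(2, 92, by = 10), condition = "task")
  ev <- ev_at(trials$onset + 0.5)
  tc <- density_timecourse(ev, trials, window = 1, step = 0.1)
  expect_equal(tc$density[which.min(abs(tc$time - 0.5))], 1)
  expect_equal(tc$density[which.min(abs(tc$time - 1.9))], 0)

  none <- density_timecourse(ev_at(numeric(0)), trials)
  expect_true(all(none$density == 0))
  expect_error(density_timecourse(ev, trials, window = 5), "longer")
})

test_that("epoch densities are events over condition time", {
  trials <- trial_table(onset = c(0, 100), offset = c(100, 200),
                        condition = c("task", "ITI"))
  ed <- epoch_density(ev_at(runif(10, 1, 99)), trials)
  expect_equal(ed$density[ed$condition == "task"], 0.1)
  expect_equal(ed$density[ed$condition == "ITI"], 0)

  unif <- epoch_density(ev_at(seq(0.5, 199.5, by = 1)), trials)
  expect_equal(unif$density[1], unif$density[2], tolerance = 0.05)
})

test_that("repeated-measures ANOVA matches the textbook decomposition", {
  m <- matrix(c(3, 5, 4,
                7, 9, 8), nrow = 3)  # 3 subjects x 2 conditions
  m <- m + matrix(c(0, 1, -1, 0.5, 2, -0.5), nrow = 3)
  res <- rm_anova(m)
  ora <- oracle_rm_ss(m)
  expect_equal(res$F, ora$F, tolerance = 1e-10)
  expect_equal(res$ss_condition, ora$ss_cond, tolerance = 1e-10)
  expect_equal(res$ss_error, ora$ss_err, tolerance = 1e-10)
  expect_equal(res$eta_sq_partial, ora$eta, tolerance = 1e-10)

  same <- matrix(rep(c(1, 2, 3), 2), nrow = 3)
  rs <- rm_anova(same)
  expect_equal(rs$F, 0)
  expect_equal(rs$eta_sq_partial, 0)
  expect_equal(rs$p, 1)

  expect_error(rm_anova(matrix(c(1, NA, 2, 3), 2)), "missing")

  gg <- rm_anova(matrix(rnorm(24), 8, 3), gg = TRUE)
  expect_true(gg$gg_epsilon >= 0.5 && gg$gg_epsilon <= 1)
})

test_that("RM-ANOVA p-values are uniform under the null", {
  set.seed(1234)
  n <- 8; k <- 3
  ps <- replicate(1000, {
    m <- matrix(rnorm(n * k), n, k) + rnorm(n)  # subject offsets only
    m <- t(apply(m, 1, sample))                 # permute labels within subject
    rm_anova(m)$p
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("Spearman correlation matches the explicit rank formula", {
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  y <- c(2, 7, 1, 8, 0.5, 6)
  res <- spearman_cor(x, y)
  expect_equal(res$rho, oracle_spearman(x, y), tolerance = 1e-12)

  mono <- spearman_cor(1:6, c(2, 3, 5, 8, 13, 21))
  expect_equal(mono$rho, 1)
  expect_equal(spearman_cor(1:6, rev(1:6))$rho, -1)
  expect_error(spearman_cor(rep(1, 6), 1:6), "constant")
  # ties are handled with average ranks
  xt <- c(1, 2, 2, 3, 4, 5); yt <- c(1, 1, 2, 3, 5, 4)
  expect_equal(spearman_cor(xt, yt)$rho, oracle_spearman(xt, yt),
               tolerance = 1e-12)
})

test_that("partial correlation matches the pairwise recursion", {
  set.seed(77)
  z <- rnorm(8)
  x <- 0.5 * z + rnorm(8)
  y <- -0.3 * z + rnorm(8)
  res <- partial_correlation(x, y, z)
  expect_equal(res$r, oracle_partial_r(x, y, z), tolerance = 1e-12)
  expect_equal(res$df, 5)

  # y identical to the control: nothing left to correlate
  expect_lt(abs(partial_correlation(x, z, z)$r), 1e-9)

  # control unrelated to both: partial ~ plain r
  set.seed(78)
  x2 <- rnorm(200); y2 <- x2 + rnorm(200); z2 <- rnorm(200)
  expect_equal(partial_correlation(x2, y2, z2)$r, cor(x2, y2),
               tolerance = 0.05)
  expect_error(partial_correlation(x, y, rep(1, 8)), "constant")
})

test_that("correlation comparison behaves like a Fisher z test", {
  expect_equal(compare_correlations(0.4, 50, 0.4, 80)$p, 1)
  expect_lt(compare_correlations(0.9, 100, 0.1, 100)$p, 0.001)
  a <- compare_correlations(0.6, 40, 0.2, 60)
  b <- compare_correlations(0.2, 60, 0.6, 40)
  expect_equal(a$p, b$p)
  expect_error(compare_correlations(1, 10, 0.5, 10), "\\|r\\|")
})

test_that("trial tables validate and round-trip", {
  tt <- trial_table(c(0, 6), c(3, 9), c("ITI_1", "task"))
  p <- file.path(tempdir(), "trials.tsv")
  write_trials(tt, p)
  expect_equal(read_trials(p)$condition, tt$condition)
  expect_error(trial_table(c(5, 0), c(6, 1), c("a", "b")), "increasing")
  expect_error(trial_table(1, 1, "a"), "exceed")
})
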