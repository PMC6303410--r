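make_trace <- function(time, flavin, whi5 = rep(0, length(time)),
                       id = "cell", condition = "test") {
  structure(list(cell_id = id, time = time, flavin = flavin, whi5 = whi5,
                 condition = condition,
                 sampling_interval = stats::median(diff(time)),
                 ground_truth = NULL),
            class = "ymc_cell_trace")
}

test_that("short tracks are excluded by a strict 4.5-hour rule", {
  mk <- function(dur) make_trace(seq(0, dur, 10), rnorm(dur / 10 + 1))
  coh <- structure(list(mk(180), mk(270), mk(600)), class = "ymc_cohort")
  out <- exclude_short_tracks(coh)
  expect_identical(vapply(unclass(out), `[[`, logical(1), "excluded"),
                   c(TRUE, FALSE, FALSE))
  # identity on an all-long cohort, and an empty cohort is not an error
  coh2 <- structure(list(mk(300), mk(500)), class = "ymc_cohort")
  expect_false(any(vapply(unclass(exclude_short_tracks(coh2)), `[[`,
                          logical(1), "excluded")))
  empty <- exclude_short_tracks(structure(list(), class = "ymc_cohort"))
  expect_length(empty, 0)
})

test_that("order-7 detrending annihilates degree-7 polynomials", {
  t <- seq(0, 1000, 10)
  set.seed(1)
  cf <- rnorm(8)
  x <- rowSums(outer(t / 1000, 0:7, `^`) * rep(cf, each = length(t)))
  expect_lt(max(abs(detrend(x, t))), 1e-8 * max(abs(x)))
  expect_lt(max(abs(detrend(rep(3.5, length(t)), t))), 1e-10)
  expect_error(detrend(rnorm(8), 1:8, order = 7), "too short")
})

test_that("detrending removes linear drift from an oscillation", {
  t <- seq(0, 1000, 10)
  slope <- 0.01
  x <- sin(2 * pi * t / 130) + slope * t
  d <- detrend(x, t)
  fit <- stats::lm(d ~ t)
  expect_lt(abs(stats::coef(fit)[2]), 1e-3 * slope)
  expect_lt(abs(mean(d)), 1e-10)
})

test_that("normalization divides by the maximum and is idempotent", {
  x <- c(1, -2, 4, 0.5)
  n1 <- normalize_trace(x)
  expect_equal(max(n1), 1)
  expect_equal(n1, x / 4)
  expect_equal(normalize_trace(n1), n1)
  expect_error(normalize_trace(rep(0, 10)), "degenerate")
})

test_that("detrend-then-normalize differs from normalize-then-detrend", {
  t <- seq(0, 1000, 10)
  x <- 5 + sin(2 * pi * t / 130) + 0.02 * t + 1e-5 * t^2
  a <- smooth_trace(normalize_trace(detrend(x, t)))
  b <- smooth_trace(detrend(normalize_trace(x), t))
  expect_gt(max(abs(a - b)), 1e-3)
})

test_that("Savitzky-Golay passes low-order polynomials and damps noise", {
  t <- seq_len(101)
  quad <- 3 + 0.5 * t - 0.01 * t^2
  expect_equal(smooth_trace(quad, 5, 2), quad, tolerance = 1e-8)
  set.seed(2)
  noise <- rnorm(500)
  expect_lt(stats::var(smooth_trace(noise, 5, 2)), stats::var(noise))
  expect_error(smooth_trace(noise, 4, 3), "odd")
  expect_error(smooth_trace(noise, 5, 5), "polyorder")
  expect_error(smooth_trace(rnorm(3), 5, 2), "exceeds")
})

test_that("extrema detection handles monotone and periodic signals", {
  t <- seq(0, 650, 10)
  none <- detect_extrema(seq_along(t) * 1.0, t)
  expect_length(none$peak_times, 0)
  expect_length(none$trough_times, 0)
  # noiseless raised-cosine train through the full chain
  reg <- ymc_regime(regime_name = "clean", mc_period_mean = 130,
                    mc_period_sd = 0, noise_sd = 0, amplitude_cv = 0,
                    separation_jitter_sd = 0, n_cells = 5, seed = 2)
  coh <- simulate(reg)
  gt <- ground_truth(coh)
  for (tr in unclass(coh)) {
    pt <- process_trace(tr)
    g <- gt[[tr$cell_id]]
    expect_equal(length(pt$peak_times), length(g$flavin_peak_times))
    expect_equal(length(pt$trough_times), length(g$trough_times))
    expect_true(all(abs(pt$peak_times - g$flavin_peak_times) <= 10))
    expect_true(all(abs(pt$trough_times - g$trough_times) <= 10))
    # detected extrema strictly alternate
    ev <- rbind(cbind(pt$peak_times, 1), cbind(pt$trough_times, -1))
    ev <- ev[order(ev[, 1]), ]
    expect_true(all(diff(ev[, 2]) != 0))
  }
})

test_that("detection at default noise matches ground truth for >=95% of peaks", {
  coh <- simulate(ymc_regime("ynb_025x", n_cells = 60, seed = 11))
  gt <- ground_truth(coh)
  matched <- 0; total <- 0; spurious <- 0; detected <- 0
  for (tr in unclass(coh)) {
    pt <- process_trace(tr)
    g <- gt[[tr$cell_id]]
    tol <- 2 * tr$sampling_interval
    total <- total + length(g$flavin_peak_times)
    matched <- matched + sum(vapply(g$flavin_peak_times, function(x)
      any(abs(x - pt$peak_times) <= tol), logical(1)))
    detected <- detected + length(pt$peak_times)
    spurious <- spurious + sum(vapply(pt$peak_times, function(x)
      !any(abs(x - g$flavin_peak_times) <= tol), logical(1)))
  }
  expect_gte(matched / total, 0.95)
  expect_lte(spurious / detected, 0.05)
})

test_that("mild noise rarely changes the detected peak count", {
  t <- seq(0, 1200, 10)
  clean <- 0.5 * (1 - cos(2 * pi * t / 130))
  base <- length(detect_extrema(smooth_trace(normalize_trace(clean)),
                                t)$peak_times)
  set.seed(33)
  changed <- vapply(1:200, function(i) {
    x <- clean + rnorm(length(t), 0, 0.05)
    n <- length(detect_extrema(smooth_trace(normalize_trace(x)),
                               t)$peak_times)
    n != base
  }, logical(1))
  expect_lte(mean(changed), 0.02)
})

test_that("autocorrelation recovers a pure sine period and flags noise", {
  t <- seq(0, 1300, 10)
  res <- autocorr_period(sin(2 * pi * t / 130), t, max_lag = 300)
  expect_true(res$reliable)
  expect_lte(abs(res$period - 130), 10)
  expect_error(autocorr_period(rnorm(20), seq(0, 190, 10), max_lag = 300),
               "too short")
  set.seed(42)
  unreliable <- vapply(1:100, function(i)
    !autocorr_period(rnorm(131), t, max_lag = 300)$reliable, logical(1))
  expect_gte(mean(unreliable), 0.95)
})

test_that("autocorrelation period recovery works cohort-wide", {
  reg <- ymc_regime(regime_name = "acf", mc_period_mean = 150,
                    mc_period_sd = 15, n_cells = 60, seed = 6)
  est <- vapply(unclass(simulate(reg)), function(tr) {
    a <- autocorr_period(detrend(tr$flavin, tr$time), tr$time,
                         max_lag = 400)
    if (a$reliable) a$period else NA_real_
  }, numeric(1))
  expect_lt(abs(mean(est, na.rm = TRUE) - 150) / 150, 0.10)
})

test_that("sick-cell censoring resumes five time points after onset", {
  reg <- ymc_regime(regime_name = "sick", mc_period_mean = 130,
                    n_cells = 1, seed = 3)
  tr <- unclass(simulate(reg))[[1]]
  cen <- censor_sick_cell(tr, 500)
  expect_equal(cen$censor_start, 500 + 5 * 10)
  pt <- process_trace(cen)
  expect_true(all(pt$peak_times >= 550))
  expect_true(all(pt$trough_times >= 550))
  expect_error(censor_sick_cell(tr, 1e6), "outside")
  # without censoring, processing is unchanged
  expect_equal(process_trace(tr), process_trace(tr))
  expect_gt(length(process_trace(tr)$peak_times), length(pt$peak_times))
})

test_that("the division one before sick onset is dropped from CDC statistics", {
  reg <- ymc_regime(regime_name = "sick2", mc_period_mean = 130,
                    separation_jitter_sd = 0, stall_prob = 0, n_cells = 1,
                    seed = 3)
  tr <- unclass(simulate(reg))[[1]]
  sep <- tr$ground_truth$separation_times
  onset <- sep[4] + 20
  cen <- censor_sick_cell(tr, onset)
  coh <- structure(list(cen), class = "ymc_cohort")
  fit <- ymc_coupling(coh, whi5 = FALSE)
  used <- fit$cells[[tr$cell_id]]$separations
  expect_false(sep[4] %in% used)
  expect_true(all(setdiff(sep, sep[4]) %in% used))
})
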