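test_that("regime validation rejects invalid parameters", {
  expect_error(ymc_regime(mc_period_mean = -5), "mc_period_mean")
  expect_error(ymc_regime(stall_prob = 1.5), "stall_prob")
  expect_error(ymc_regime(n_cells = 0), "n_cells")
  expect_error(ymc_regime(noise_sd = -0.1), "noise_sd")
  expect_error(ymc_regime(duration = 50), "duration")
  expect_error(ymc_regime(coupling_mode = "decoupled"), "cdc_period_mean")
  expect_error(ymc_regime(preset = "nope"), "available presets")
})

test_that("presets cover the experimental conditions with their sampling", {
  ps <- ymc_presets()
  expect_setequal(names(ps), c("ynb_1x", "ynb_025x", "ynb_005x",
                               "urea_10mM", "rapamycin", "atp5d", "cyt1d"))
  expect_equal(ps$ynb_1x$sampling_interval, 5)
  expect_equal(ps$ynb_025x$sampling_interval, 10)
  expect_equal(ps$rapamycin$coupling_mode, "decoupled")
  # rapamycin periods: MC 191.73 min ~ 1.4x and CDC ~ 2.9x the 1X YNB value
  expect_equal(ps$rapamycin$mc_period_mean, 191.73)
  expect_equal(ps$rapamycin$cdc_period_mean, 2.9 * 136, tolerance = 1e-6)
})

test_that("a noiseless fixed-period oscillator has equally spaced peaks", {
  reg <- ymc_regime(regime_name = "det", mc_period_mean = 130,
                    mc_period_sd = 0, noise_sd = 0, amplitude_cv = 0,
                    duration = 650, sampling_interval = 10, n_cells = 1,
                    seed = 4)
  tr <- simulate_cell(reg, 1)
  pk <- tr$ground_truth$flavin_peak_times
  expect_length(pk, 5)
  expect_true(all(abs(diff(pk) - 130) <= 5))
})

test_that("gated mode without jitter or stalls puts every separation on a trough", {
  reg <- ymc_regime(regime_name = "g", mc_period_mean = 130,
                    separation_jitter_sd = 0, stall_prob = 0, n_cells = 5,
                    seed = 9)
  coh <- simulate(reg)
  for (g in ground_truth(coh)) {
    expect_true(all(vapply(g$separation_times, function(s)
      min(abs(s - g$trough_times)), numeric(1)) < 1e-9))
    expect_true(all(g$cycles_per_cdc == 1L))
  }
})

test_that("simulation is seed-deterministic and cell substreams are independent", {
  reg <- ymc_regime("ynb_1x", n_cells = 3, seed = 21)
  a <- simulate(reg)
  b <- simulate(reg)
  expect_identical(a, b)
  # different cells start at different phases
  t1 <- simulate_cell(reg, 1)
  t2 <- simulate_cell(reg, 2)
  expect_false(isTRUE(all.equal(t1$ground_truth$trough_times[1],
                                t2$ground_truth$trough_times[1])))
  # a singleton cohort reproduces generate-one-cell output
  single <- simulate(reg, nsim = 1)
  expect_equal(unclass(single)[[1]], t1)
})

test_that("ground-truth peaks and troughs strictly alternate in every cell", {
  for (p in c("ynb_1x", "rapamycin")) {
    coh <- simulate(ymc_regime(p, n_cells = 10, seed = 3))
    for (g in ground_truth(coh)) {
      ev <- rbind(cbind(g$flavin_peak_times, 1),
                  cbind(g$trough_times, -1))
      ev <- ev[order(ev[, 1]), ]
      expect_true(all(diff(ev[, 2]) != 0))
      expect_true(!is.unsorted(g$separation_times, strictly = TRUE))
    }
  }
})

test_that("empirical cycle durations recover the configured period law", {
  reg <- ymc_regime(regime_name = "law", mc_period_mean = 136,
                    mc_period_sd = 34, n_cells = 80, seed = 13)
  durs <- unlist(lapply(ground_truth(simulate(reg)), function(g)
    diff(g$trough_times)))
  expect_gt(length(durs), 500)
  se <- stats::sd(durs) / sqrt(length(durs))
  expect_lt(abs(mean(durs) - 136), 3 * se + 0.5)
})

test_that("separations stay within three jitter sds of a trough", {
  coh <- simulate(ymc_regime("ynb_025x", n_cells = 100, seed = 8))
  off <- unlist(lapply(ground_truth(coh), function(g) {
    if (length(g$separation_times) == 0) return(NULL)
    vapply(g$separation_times, function(s) min(abs(s - g$trough_times)),
           numeric(1))
  }))
  expect_gte(mean(off <= 3 * 10), 0.99)
})

test_that("initial Whi5 pulse phases are uniform across the cohort", {
  reg <- ymc_regime(regime_name = "unif", mc_period_mean = 130,
                    mc_period_sd = 0, separation_jitter_sd = 0,
                    stall_prob = 0, whi5_flavin_lag_sd = 0, n_cells = 200,
                    seed = 17)
  first <- vapply(ground_truth(simulate(reg)), function(g)
    g$whi5_peak_times[1], numeric(1))
  phase <- (first %% 130) / 130
  expect_gt(stats::ks.test(phase, "punif")$p.value, 0.01)
})

test_that("decoupled cohorts contain multi-cycle divisions", {
  coh <- simulate(ymc_regime("rapamycin", n_cells = 40, seed = 5))
  cyc <- unlist(lapply(ground_truth(coh), `[[`, "cycles_per_cdc"))
  expect_true(any(cyc > 1))
  arrested <- vapply(ground_truth(coh), `[[`, logical(1), "arrested")
  expect_true(any(vapply(ground_truth(coh), function(g)
    length(g$separation_times) == 0, logical(1))[arrested]))
})
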