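test_that("localization score is the top-k minus rest difference", {
  f <- matrix(10, 10, 10)
  f[1:5] <- 100
  expect_equal(whi5_localization_score(f), 90)
  expect_equal(whi5_localization_score(matrix(7, 8, 8)), 0)
  f2 <- matrix(1:100, 10, 10)
  expect_equal(whi5_localization_score(f2), mean(96:100) - mean(1:95))
  expect_equal(whi5_localization_score(f2), oracle_whi5_score(1:100))
  expect_error(whi5_localization_score(matrix(1, 2, 2)), "more than 5")
})

test_that("localization score is shift-invariant and scales linearly", {
  set.seed(7)
  for (i in 1:20) {
    px <- matrix(rnorm(49, 50, 20), 7, 7)
    s <- whi5_localization_score(px)
    expect_equal(whi5_localization_score(px + 13.7), s)
    expect_equal(whi5_localization_score(px * 2.5), 2.5 * s)
    expect_equal(s, oracle_whi5_score(as.numeric(px)))
  }
})

test_that("rendered mask stacks recover the source Whi5 channel", {
  reg <- ymc_regime(regime_name = "mask", mc_period_mean = 130,
                    duration = 400, n_cells = 1, seed = 5)
  tr <- unclass(simulate(reg))[[1]]
  rnd <- render_mask_images(tr, noise_sd = 0)
  sc <- score_mask_stack(rnd)
  expect_equal(sc, pmax(tr$whi5, 0), tolerance = 1e-10)
  # with pixel noise the trace still tracks the channel closely
  rndn <- render_mask_images(tr, noise_sd = 0.05, seed = 2)
  expect_gt(stats::cor(score_mask_stack(rndn), tr$whi5), 0.9)
  # a non-default nuclear pixel count still recovers the channel
  rnd7 <- render_mask_images(tr, n_nuclear = 7, noise_sd = 0)
  expect_equal(score_mask_stack(rnd7), pmax(tr$whi5, 0), tolerance = 1e-10)
  expect_error(render_mask_images(tr, mask = matrix(c(TRUE, rep(FALSE, 224)),
                                                    15, 15)),
               "at least 6")
})

test_that("mask stacks round-trip through multi-page TIFF", {
  reg <- ymc_regime(regime_name = "tif", mc_period_mean = 130,
                    duration = 200, n_cells = 1, seed = 5)
  tr <- unclass(simulate(reg))[[1]]
  rnd <- render_mask_images(tr, noise_sd = 0)
  tf <- tempfile(fileext = ".tif"); mf <- tempfile(fileext = ".tif")
  p <- write_mask_stack(rnd, tf, mask_path = mf)
  back <- read_mask_stack(tf, mf, max_intensity = attr(p, "max_intensity"))
  expect_equal(dim(back$stack), dim(rnd$stack))
  expect_equal(back$mask, rnd$mask)
  expect_lt(max(abs(back$stack - rnd$stack)), attr(p, "max_intensity") / 2^15)
})

test_that("event lists validate ordering and convert to intervals", {
  expect_error(ymc_events("c1", c(100, 90)), "strictly increasing")
  ev <- ymc_events("c1", c(100, 230, 360))
  expect_equal(cdc_periods(ev), c(130, 130))
  expect_equal(cdc_periods(c(500)), numeric(0))
  iv <- cdc_intervals(ev)
  expect_equal(unname(iv[, 1]), c(100, 230))
  expect_equal(nrow(cdc_intervals(c(10))), 0)
})

test_that("events round-trip through JSON", {
  evs <- list(a = ymc_events("a", c(10, 150, 300)),
              b = ymc_events("b", numeric(0)))
  f <- tempfile(fileext = ".json")
  write_events(evs, f)
  back <- read_events(f)
  expect_equal(back$a$separation_times, c(10, 150, 300))
  expect_equal(back$b$separation_times, numeric(0))
  expect_equal(back$a$source, "file")
})

test_that("the Whi5 peak of each division is its in-interval score maximum", {
  t <- seq(0, 130, 10)
  score <- exp(-0.5 * ((t - 60) / 10)^2)
  expect_equal(whi5_peak_per_cdc(score, t, cbind(0, 130)), 60)
  # two pulses: the taller one wins
  t2 <- seq(0, 200, 10)
  s2 <- 3 * exp(-0.5 * ((t2 - 50) / 8)^2) + 5 * exp(-0.5 * ((t2 - 150) / 8)^2)
  expect_equal(whi5_peak_per_cdc(s2, t2, cbind(0, 200)), 150)
  # flat intervals carry no peak
  expect_true(is.na(whi5_peak_per_cdc(rep(1, length(t)), t, cbind(0, 130))))
  expect_error(whi5_peak_per_cdc(score, t, rbind(c(0, 100), c(50, 130))),
               "non-overlapping")
})

test_that("detected Whi5 peaks match ground truth across a cohort", {
  coh <- simulate(ymc_regime("ynb_025x", n_cells = 50, seed = 19))
  gt <- ground_truth(coh)
  hit <- 0; total <- 0
  for (tr in unclass(coh)) {
    g <- gt[[tr$cell_id]]
    if (length(g$whi5_peak_times) == 0) next
    iv <- cdc_intervals(g$separation_times)
    wp <- whi5_peak_per_cdc(tr$whi5, tr$time, iv)
    stopifnot(length(wp) == length(g$whi5_peak_times))
    ok <- abs(wp - g$whi5_peak_times) <= tr$sampling_interval
    hit <- hit + sum(ok, na.rm = TRUE)
    total <- total + length(ok)
  }
  expect_gte(hit / total, 0.95)
})

test_that("mean division period follows the gated generator law", {
  reg <- ymc_regime(regime_name = "cdclaw", mc_period_mean = 130,
                    n_cells = 100, seed = 23)
  gt <- ground_truth(simulate(reg))
  tcdc <- unlist(lapply(gt, function(g) diff(g$separation_times)))
  cyc <- unlist(lapply(gt, `[[`, "cycles_per_cdc"))
  se <- stats::sd(tcdc) / sqrt(length(tcdc))
  expect_lt(abs(mean(tcdc) - 130 * mean(cyc)), 3 * se + 1)
})
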