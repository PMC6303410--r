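#' @importFrom stats rnorm runif
NULL

# Truncated-normal draw by rejection; lower bound guards against nonpositive
# cycle durations. sd = 0 degenerates to the mean.
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (n == 0L) return(numeric(0))
  if (sd == 0) return(rep(mean, n))
  out <- numeric(n)
  need <- seq_len(n)
  for (i in 1:100) {
    out[need] <- stats::rnorm(length(need), mean, sd)
    need <- which(out < lower | out > upper)
    if (length(need) == 0L) break
  }
  if (length(need) > 0L) out[need] <- pmin(pmax(mean, lower), upper)
  out
}

# Deterministic per-cell substream: cohorts are reproducible and
# order-independent because each cell re-seeds from (seed, cell_index).
cell_seed <- function(seed, cell_index) {
  as.integer((as.numeric(seed) + 104729 * as.numeric(cell_index)) %%
               2147483647)
}

#' Simulate one single-cell trace
#'
#' Generates one cell from the coupled-oscillator model. The flavin channel
#' is
#' \deqn{F(t) = e^{-\beta t}\,[b + d(t) + A_k\, w(\phi(t))] + \epsilon(t),}
#' where the phase \eqn{\phi} advances through successive cycles whose
#' durations are drawn per cycle from the configured truncated-normal period
#' distribution, \eqn{w(\phi) = (1 - \cos 2\pi\phi)/2} is a raised-cosine
#' waveform (one trough at each cycle boundary, one peak mid-cycle),
#' \eqn{A_k} varies per cycle, \eqn{d} is a slow polynomial drift,
#' \eqn{\beta} the photobleaching rate and \eqn{\epsilon} i.i.d. Gaussian
#' noise. Each cell starts at an independent uniform random phase, so
#' cohorts are unsynchronized.
#'
#' Division events (mother-daughter nuclear separations) are placed
#' according to the coupling mode (see [ymc_regime()]); the Whi5 channel
#' carries one localization pulse per division cycle whose peak precedes
#' the flavin peak of that cycle by a lag drawn from the configured
#' distribution (truncated so the pulse stays inside its division interval).
#' Ground truth (true peak, trough, separation and Whi5 peak times, and
#' cycles per division) is attached to the trace.
#'
#' @param reg A [ymc_regime()].
#' @param cell_index 1-based index selecting the cell's random substream.
#' @return A `ymc_cell_trace`: list with `cell_id`, `time`, `flavin`,
#'   `whi5`, `condition`, `sampling_interval` and `ground_truth`.
#' @examples
#' tr <- simulate_cell(ymc_regime("ynb_1x", n_cells = 1, seed = 7), 1)
#' length(tr$ground_truth$separation_times)
#' @export
simulate_cell <- function(reg, cell_index = 1L) {
  validate_ymc_regime(reg)
  if (reg$noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (reg$duration < reg$mc_period_mean)
    stop("'duration' must cover at least one mean metabolic-cycle period")
  set.seed(cell_seed(reg$seed, cell_index))
  dt <- reg$sampling_interval
  time <- seq(0, reg$duration, by = dt)

  ## metabolic oscillator: cycle boundaries are troughs, peaks mid-cycle
  u0 <- stats::runif(1)
  n_cyc <- ceiling(reg$duration / (0.3 * reg$mc_period_mean)) + 3L
  durs <- rnorm_trunc(n_cyc, reg$mc_period_mean, reg$mc_period_sd,
                      lower = 0.3 * reg$mc_period_mean)
  bounds <- -u0 * durs[1] + cumsum(c(0, durs))
  while (bounds[length(bounds)] < reg$duration + reg$mc_period_mean) {
    extra <- rnorm_trunc(3L, reg$mc_period_mean, reg$mc_period_sd,
                         lower = 0.3 * reg$mc_period_mean)
    durs <- c(durs, extra)
    bounds <- -u0 * durs[1] + cumsum(c(0, durs))
  }
  amps <- reg$mc_amplitude *
    rnorm_trunc(length(durs), 1, reg$amplitude_cv, lower = 0.2)
  cyc <- findInterval(time, bounds)          # cycle index per sample
  phi <- (time - bounds[cyc]) / durs[cyc]
  wave <- 0.5 * (1 - cos(2 * pi * phi))
  s <- time / reg$duration
  drift <- reg$mc_amplitude *
    rowSums(outer(s, seq_along(reg$drift_coeffs), `^`) *
              rep(reg$drift_coeffs, each = length(s)))
  bleach <- exp(-reg$bleach_rate * time)
  flavin <- bleach * (reg$baseline + drift + amps[cyc] * wave) +
    stats::rnorm(length(time), 0, reg$noise_sd * reg$mc_amplitude)

  troughs_all <- bounds
  peaks_all <- bounds[-length(bounds)] + durs / 2
  in_span <- function(x) x[x >= 0 & x <= reg$duration]
  true_troughs <- in_span(troughs_all)
  true_peaks <- in_span(peaks_all)

  ## division events
  interior <- which(troughs_all > 0 & troughs_all < reg$duration)
  arrested <- stats::runif(1) < reg$arrest_prob
  sep_idx <- integer(0)
  if (!arrested && length(interior) >= 2L) {
    if (reg$coupling_mode == "gated_1to1") {
      i <- interior[1]
      repeat {
        sep_idx <- c(sep_idx, i)
        step <- 1L + (stats::runif(1) < reg$stall_prob)
        i <- i + step
        if (i > interior[length(interior)]) break
      }
    } else {
      t0 <- stats::runif(1, 0, reg$cdc_period_mean)
      ev <- t0
      while (ev[length(ev)] < reg$duration) {
        ev <- c(ev, ev[length(ev)] +
                  rnorm_trunc(1, reg$cdc_period_mean, reg$cdc_period_sd,
                              lower = 0.3 * reg$cdc_period_mean))
      }
      ev <- ev[ev < reg$duration]
      # divisions still complete near a trough: snap to the nearest one
      idx <- vapply(ev, function(e) interior[which.min(abs(troughs_all[interior] - e))],
                    integer(1))
      sep_idx <- sort(unique(idx))
    }
  }
  sep <- numeric(0)
  cycles_per_cdc <- integer(0)
  if (length(sep_idx) > 0L) {
    jit <- stats::rnorm(length(sep_idx), 0, reg$separation_jitter_sd)
    sep <- troughs_all[sep_idx] + jit
    keep <- c(TRUE, diff(sep) > 0)
    sep <- sep[keep]
    sep_idx <- sep_idx[keep]
    sep <- pmin(pmax(sep, 0), reg$duration)
    cycles_per_cdc <- diff(sep_idx)
  }

  ## Whi5 pulses: one per complete division interval, anchored to the first
  ## flavin peak of the interval; lag truncated so the pulse stays inside.
  whi5_peaks <- numeric(0)
  if (length(sep) >= 2L) {
    for (j in seq_len(length(sep) - 1L)) {
      a <- sep[j]; b <- sep[j + 1L]
      anchors <- peaks_all[peaks_all >= a & peaks_all < b]
      if (length(anchors) == 0L) next
      anchor <- anchors[1]
      lag <- rnorm_trunc(1, reg$whi5_flavin_lag_mean, reg$whi5_flavin_lag_sd,
                         lower = a - anchor + dt, upper = b - anchor - dt)
      whi5_peaks <- c(whi5_peaks, anchor + lag)
    }
  }
  whi5 <- stats::rnorm(length(time), 0, reg$whi5_noise_sd)
  for (p in whi5_peaks)
    whi5 <- whi5 + exp(-0.5 * ((time - p) / reg$whi5_pulse_sd)^2)

  structure(list(
    cell_id = sprintf("%s_cell%03d", reg$regime_name, cell_index),
    time = time, flavin = flavin, whi5 = whi5,
    condition = reg$regime_name, sampling_interval = dt,
    ground_truth = list(
      flavin_peak_times = true_peaks,
      trough_times = true_troughs,
      separation_times = sep,
      whi5_peak_times = whi5_peaks,
      cycles_per_cdc = as.integer(cycles_per_cdc),
      arrested = arrested)),
    class = "ymc_cell_trace")
}

#' Simulate a cohort of unsynchronized cells
#'
#' `simulate()` on a [ymc_regime()] generates `reg$n_cells` independent
#' cells (or `nsim` if given). Each cell draws from its own substream
#' derived from the regime seed and the cell index, so cohorts are
#' reproducible and any subset of cells is identical to the same cells
#' generated alone.
#'
#' @param object A [ymc_regime()].
#' @param nsim Number of cells; defaults to `object$n_cells`.
#' @param seed Optional seed overriding `object$seed`.
#' @param ... Unused.
#' @return A `ymc_cohort`: list of `ymc_cell_trace` with the regime attached
#'   as attribute `regime`.
#' @examples
#' coh <- simulate(ymc_regime("ynb_1x", n_cells = 2, seed = 1))
#' length(coh)
#' @export
simulate.ymc_regime <- function(object, nsim = NULL, seed = NULL, ...) {
  reg <- object
  if (!is.null(seed)) reg$seed <- as.integer(seed)
  if (!is.null(nsim)) reg$n_cells <- as.integer(nsim)
  validate_ymc_regime(reg)
  cells <- lapply(seq_len(reg$n_cells), function(i) simulate_cell(reg, i))
  new_ymc_cohort(cells, reg)
}

new_ymc_cohort <- function(cells, regime = NULL) {
  stopifnot(is.list(cells))
  structure(cells, class = "ymc_cohort", regime = regime)
}

#' @export
print.ymc_cohort <- function(x, ...) {
  reg <- attr(x, "regime")
  cond <- unique(vapply(x, `[[`, "", "condition"))
  cat("Cohort of", length(x), "cell trace(s); condition(s):",
      paste(cond, collapse = ", "), "\n")
  if (length(x) > 0) {
    d <- vapply(x, function(tr) diff(range(tr$time)), numeric(1))
    cat(sprintf("  track length %g-%g min, sampling every %g min\n",
                min(d), max(d), x[[1]]$sampling_interval))
  }
  if (!is.null(reg)) cat("  regime:", reg$regime_name, " seed:", reg$seed, "\n")
  invisible(x)
}

#' @export
`[.ymc_cohort` <- function(x, i) {
  new_ymc_cohort(unclass(x)[i], attr(x, "regime"))
}

#' Long-format table of a cohort
#'
#' @param x A `ymc_cohort`.
#' @param ... Unused.
#' @return data.frame with columns `cell_id`, `time_min`, `flavin`, `whi5`,
#'   `condition`.
#' @export
as.data.frame.ymc_cohort <- function(x, ...) {
  do.call(rbind, lapply(unclass(x), function(tr) {
    data.frame(cell_id = tr$cell_id, time_min = tr$time,
               flavin = tr$flavin, whi5 = tr$whi5,
               condition = tr$condition, stringsAsFactors = FALSE)
  }))
}

#' Ground-truth event lists of a simulated cohort
#'
#' @param cohort A `ymc_cohort` from [simulate.ymc_regime()].
#' @return Named list (by cell id) of ground-truth lists.
#' @export
ground_truth <- function(cohort) {
  stopifnot(inherits(cohort, "ymc_cohort"))
  gt <- lapply(unclass(cohort), `[[`, "ground_truth")
  names(gt) <- vapply(unclass(cohort), `[[`, "", "cell_id")
  gt
}
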