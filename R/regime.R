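#' Simulation regime for single-cell metabolic-cycle cohorts
#'
#' A `ymc_regime` bundles every parameter of the coupled-oscillator trace
#' generator: the per-cycle period distribution of the metabolic oscillator,
#' the coupling mode between the oscillator and cell-division events, the
#' Whi5 reporter lag distribution, and the measurement model (sampling
#' interval, noise, drift, photobleaching).
#'
#' Periods are drawn per cycle from a normal distribution truncated below at
#' 0.3 times the mean, so cycle durations are always positive. In
#' `"gated_1to1"` mode each nuclear-separation event is placed at a
#' metabolic-cycle trough plus Gaussian jitter, with an extra full cycle
#' inserted before a division with probability `stall_prob`. In
#' `"decoupled"` mode division times follow an independent renewal process
#' (mean `cdc_period_mean`, sd `cdc_period_sd`) and each event is snapped to
#' the nearest trough before jitter is added, reflecting that divisions
#' complete near a trough even when the two cycles run at different rates.
#'
#' @param preset Optional preset name; see [ymc_presets()]. Further arguments
#'   override preset values.
#' @param regime_name Label attached to generated traces as `condition`.
#' @param mc_period_mean,mc_period_sd Mean and cycle-to-cycle sd of the
#'   metabolic-cycle period, minutes.
#' @param mc_amplitude Oscillation amplitude, arbitrary fluorescence units.
#' @param amplitude_cv Coefficient of variation of the per-cycle amplitude.
#' @param baseline Constant fluorescence offset, same units as
#'   `mc_amplitude`.
#' @param coupling_mode `"gated_1to1"` or `"decoupled"`.
#' @param stall_prob Probability per division of one extra metabolic cycle
#'   before the division completes (gated mode only).
#' @param cdc_period_mean,cdc_period_sd Division-cycle renewal parameters,
#'   minutes (decoupled mode only).
#' @param arrest_prob Probability that a cell never divides (its oscillator
#'   keeps running); used for the rapamycin regime.
#' @param whi5_flavin_lag_mean,whi5_flavin_lag_sd Signed lag of the Whi5
#'   nuclear-localization peak relative to the flavin peak of the same
#'   division cycle, minutes (negative = Whi5 first).
#' @param separation_jitter_sd Sd of the nuclear-separation offset from its
#'   trough, minutes.
#' @param sampling_interval Imaging interval, minutes (5 or 10 in the
#'   experiments emulated here).
#' @param duration Track length, minutes.
#' @param noise_sd Measurement noise sd as a fraction of `mc_amplitude`.
#' @param drift_coeffs Polynomial drift coefficients (powers 1, 2, ... of
#'   time rescaled to `[0, 1]`), in units of `mc_amplitude`.
#' @param bleach_rate Photobleaching decay rate, per minute.
#' @param whi5_pulse_sd Width (Gaussian sd) of a Whi5 localization pulse,
#'   minutes.
#' @param whi5_noise_sd Noise sd on the Whi5 score channel, score units.
#' @param n_cells Number of cells in a cohort.
#' @param seed Integer seed; identical seed and regime give a bit-identical
#'   cohort.
#'
#' @return An object of class `ymc_regime` (a validated named list).
#' @examples
#' reg <- ymc_regime("ynb_1x", n_cells = 3, seed = 1)
#' reg$mc_period_mean
#' @seealso [simulate.ymc_regime()], [ymc_presets()]
#' @export
ymc_regime <- function(preset = NULL,
                       regime_name = "custom",
                       mc_period_mean = 136,
                       mc_period_sd = 34,
                       mc_amplitude = 1,
                       amplitude_cv = 0.15,
                       baseline = 2,
                       coupling_mode = c("gated_1to1", "decoupled"),
                       stall_prob = 0.05,
                       cdc_period_mean = NA_real_,
                       cdc_period_sd = NA_real_,
                       arrest_prob = 0,
                       whi5_flavin_lag_mean = -45.62,
                       whi5_flavin_lag_sd = 27.59,
                       separation_jitter_sd = 10,
                       sampling_interval = 10,
                       duration = 1200,
                       noise_sd = 0.1,
                       drift_coeffs = c(0.3, -0.5),
                       bleach_rate = 1e-4,
                       whi5_pulse_sd = 12,
                       whi5_noise_sd = 0.05,
                       n_cells = 150,
                       seed = 1L) {
  if (!is.null(preset)) {
    base <- ymc_presets()[[match_preset(preset)]]
    call <- as.list(match.call())[-1]
    call$preset <- NULL
    for (nm in names(call)) base[[nm]] <- eval.parent(call[[nm]])
    return(do.call(new_ymc_regime, base))
  }
  coupling_mode <- match.arg(coupling_mode)
  new_ymc_regime(
    regime_name = regime_name, mc_period_mean = mc_period_mean,
    mc_period_sd = mc_period_sd, mc_amplitude = mc_amplitude,
    amplitude_cv = amplitude_cv, baseline = baseline,
    coupling_mode = coupling_mode, stall_prob = stall_prob,
    cdc_period_mean = cdc_period_mean, cdc_period_sd = cdc_period_sd,
    arrest_prob = arrest_prob,
    whi5_flavin_lag_mean = whi5_flavin_lag_mean,
    whi5_flavin_lag_sd = whi5_flavin_lag_sd,
    separation_jitter_sd = separation_jitter_sd,
    sampling_interval = sampling_interval, duration = duration,
    noise_sd = noise_sd, drift_coeffs = drift_coeffs,
    bleach_rate = bleach_rate, whi5_pulse_sd = whi5_pulse_sd,
    whi5_noise_sd = whi5_noise_sd, n_cells = n_cells, seed = seed)
}

new_ymc_regime <- function(...) {
  reg <- list(...)
  reg$coupling_mode <- match.arg(reg$coupling_mode,
                                 c("gated_1to1", "decoupled"))
  reg$n_cells <- as.integer(reg$n_cells)
  reg$seed <- as.integer(reg$seed)
  class(reg) <- "ymc_regime"
  validate_ymc_regime(reg)
  reg
}

validate_ymc_regime <- function(reg) {
  stopifnot(is.list(reg))
  num1 <- function(field, positive = FALSE, nonneg = FALSE, na_ok = FALSE) {
    x <- reg[[field]]
    if (length(x) != 1 || !is.numeric(x))
      stop(sprintf("'%s' must be a single number", field), call. = FALSE)
    if (is.na(x)) {
      if (na_ok) return(invisible())
      stop(sprintf("'%s' must not be NA", field), call. = FALSE)
    }
    if (positive && x <= 0)
      stop(sprintf("'%s' must be > 0", field), call. = FALSE)
    if (nonneg && x < 0)
      stop(sprintf("'%s' must be >= 0", field), call. = FALSE)
    invisible()
  }
  num1("mc_period_mean", positive = TRUE)
  num1("mc_period_sd", nonneg = TRUE)
  num1("mc_amplitude", positive = TRUE)
  num1("amplitude_cv", nonneg = TRUE)
  num1("sampling_interval", positive = TRUE)
  num1("duration", positive = TRUE)
  num1("noise_sd", nonneg = TRUE)
  num1("whi5_flavin_lag_sd", nonneg = TRUE)
  num1("separation_jitter_sd", nonneg = TRUE)
  num1("bleach_rate", nonneg = TRUE)
  num1("whi5_pulse_sd", positive = TRUE)
  num1("whi5_noise_sd", nonneg = TRUE)
  if (reg$stall_prob < 0 || reg$stall_prob > 1)
    stop("'stall_prob' must lie in [0, 1]", call. = FALSE)
  if (reg$arrest_prob < 0 || reg$arrest_prob > 1)
    stop("'arrest_prob' must lie in [0, 1]", call. = FALSE)
  if (reg$n_cells < 1L)
    stop("'n_cells' must be >= 1", call. = FALSE)
  if (reg$coupling_mode == "decoupled") {
    num1("cdc_period_mean", positive = TRUE)
    num1("cdc_period_sd", nonneg = TRUE)
  }
  if (reg$duration < reg$mc_period_mean)
    stop("'duration' must cover at least one mean metabolic-cycle period",
         call. = FALSE)
  invisible(reg)
}

match_preset <- function(name) {
  presets <- names(ymc_presets())
  if (!is.character(name) || length(name) != 1 || !(name %in% presets))
    stop("unknown preset '", paste(name, collapse = ","),
         "'; available presets: ", paste(presets, collapse = ", "),
         call. = FALSE)
  name
}

#' Built-in regime presets
#'
#' Named parameter sets for the experimental conditions the simulator
#' emulates. The four nutrient regimes (`ynb_1x`, `ynb_025x`, `ynb_005x`,
#' `urea_10mM`) use trough-gated 1:1 coupling with mean metabolic periods of
#' ~136 min (1X and 0.25X YNB) and ~163 min (0.05X YNB, 10 mM urea); the 1X
#' YNB condition is sampled every 5 min and all others every 10 min, and
#' cohort sizes default to the cell counts analyzed per condition (156, 225,
#' 175 and 176 cells). The `rapamycin` preset decouples division from the
#' oscillator: mean division period 394.4 min (2.9 times the 1X YNB value),
#' mean metabolic period 191.73 min with sd 75.41 min, and a fraction of
#' cells that never divide. The respiratory-mutant presets (`atp5d`,
#' `cyt1d`) keep wild-type gating.
#'
#' @return Named list of parameter lists accepted by [ymc_regime()].
#' @examples
#' names(ymc_presets())
#' @export
ymc_presets <- function() {
  base <- list(
    mc_amplitude = 1, amplitude_cv = 0.15, baseline = 2,
    coupling_mode = "gated_1to1", stall_prob = 0.05,
    cdc_period_mean = NA_real_, cdc_period_sd = NA_real_, arrest_prob = 0,
    whi5_flavin_lag_mean = -45.62, whi5_flavin_lag_sd = 27.59,
    separation_jitter_sd = 10, duration = 1200, noise_sd = 0.1,
    drift_coeffs = c(0.3, -0.5), bleach_rate = 1e-4,
    whi5_pulse_sd = 12, whi5_noise_sd = 0.05, seed = 1L)
  mk <- function(name, ...) {
    out <- utils::modifyList(base, list(regime_name = name, ...))
    out
  }
  list(
    ynb_1x = mk("ynb_1x", mc_period_mean = 136, mc_period_sd = 34,
                sampling_interval = 5, n_cells = 156L),
    ynb_025x = mk("ynb_025x", mc_period_mean = 136, mc_period_sd = 34,
                  sampling_interval = 10, n_cells = 225L),
    ynb_005x = mk("ynb_005x", mc_period_mean = 162.80, mc_period_sd = 47.52,
                  sampling_interval = 10, n_cells = 175L),
    urea_10mM = mk("urea_10mM", mc_period_mean = 163, mc_period_sd = 48,
                   sampling_interval = 10, n_cells = 176L),
    rapamycin = mk("rapamycin", coupling_mode = "decoupled",
                   mc_period_mean = 191.73, mc_period_sd = 75.41,
                   cdc_period_mean = 394.4, cdc_period_sd = 140,
                   arrest_prob = 0.15, sampling_interval = 10,
                   duration = 2400, n_cells = 180L),
    atp5d = mk("atp5d", mc_period_mean = 136, mc_period_sd = 34,
               sampling_interval = 10, n_cells = 150L),
    cyt1d = mk("cyt1d", mc_period_mean = 136, mc_period_sd = 34,
               sampling_interval = 10, n_cells = 150L))
}

#' @export
print.ymc_regime <- function(x, ...) {
  cat("Simulation regime '", x$regime_name, "'\n", sep = "")
  cat(sprintf("  metabolic cycle: %.1f +/- %.1f min, amplitude %.2g (CV %.2f)\n",
              x$mc_period_mean, x$mc_period_sd, x$mc_amplitude,
              x$amplitude_cv))
  if (x$coupling_mode == "gated_1to1") {
    cat(sprintf("  coupling: trough-gated 1:1, stall prob %.2f, jitter sd %.1f min\n",
                x$stall_prob, x$separation_jitter_sd))
  } else {
    cat(sprintf("  coupling: decoupled, CDC %.1f +/- %.1f min, arrest prob %.2f\n",
                x$cdc_period_mean, x$cdc_period_sd, x$arrest_prob))
  }
  cat(sprintf("  Whi5 lag: %.2f +/- %.2f min\n",
              x$whi5_flavin_lag_mean, x$whi5_flavin_lag_sd))
  cat(sprintf("  sampling every %g min for %g min; noise sd %.2f x amplitude\n",
              x$sampling_interval, x$duration, x$noise_sd))
  cat(sprintf("  cells: %d, seed %d\n", x$n_cells, x$seed))
  invisible(x)
}

#' Read or write a regime as YAML
#'
#' The resolved regime (every field, including the seed) is serialized so a
#' cohort can be regenerated exactly from the file.
#'
#' @param reg A [ymc_regime()] object.
#' @param path File path.
#' @return `write_regime` returns `path` invisibly; `read_regime` returns a
#'   `ymc_regime`.
#' @export
write_regime <- function(reg, path) {
  stopifnot(inherits(reg, "ymc_regime"))
  yaml::write_yaml(unclass(reg), path)
  invisible(path)
}

#' @rdname write_regime
#' @export
read_regime <- function(path) {
  reg <- yaml::read_yaml(path)
  reg$drift_coeffs <- as.numeric(unlist(reg$drift_coeffs))
  for (f in setdiff(names(reg), c("regime_name", "coupling_mode",
                                  "drift_coeffs", "n_cells", "seed")))
    reg[[f]] <- as.numeric(reg[[f]])
  do.call(new_ymc_regime, reg)
}
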