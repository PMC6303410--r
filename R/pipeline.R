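#' Simulate a cohort and write its files
#'
#' Writes the long-format trace table (`cohort.tsv`), ground-truth event
#' lists (`ground_truth.json`), nuclear-separation events
#' (`events.json`) and the fully resolved regime (`regime.yaml`, including
#' the seed) into `outdir`. Runs are deterministic: the same regime and
#' seed give byte-identical files.
#'
#' @param regime A [ymc_regime()] or a preset name (see [ymc_presets()]).
#' @param outdir Output directory (created if needed).
#' @param seed,n_cells Optional overrides of the regime fields.
#' @return Named list of written paths, invisibly.
#' @export
run_simulate <- function(regime, outdir, seed = NULL, n_cells = NULL) {
  if (is.character(regime))
    regime <- ymc_regime(preset = match_preset(regime))
  stopifnot(inherits(regime, "ymc_regime"))
  if (!is.null(seed)) regime$seed <- as.integer(seed)
  if (!is.null(n_cells)) regime$n_cells <- as.integer(n_cells)
  validate_ymc_regime(regime)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create output directory ", outdir)
  coh <- simulate(regime)
  paths <- list(
    cohort = file.path(outdir, "cohort.tsv"),
    ground_truth = file.path(outdir, "ground_truth.json"),
    events = file.path(outdir, "events.json"),
    regime = file.path(outdir, "regime.yaml"))
  write_cohort(coh, paths$cohort)
  write_ground_truth(coh, paths$ground_truth)
  evs <- lapply(unclass(coh), function(tr)
    list(cell_id = tr$cell_id,
         separation_times = tr$ground_truth$separation_times))
  names(evs) <- vapply(unclass(coh), `[[`, "", "cell_id")
  write_events(evs, paths$events)
  write_regime(regime, paths$regime)
  invisible(paths)
}

#' Analyze a cohort table and write statistics
#'
#' Reads a cohort table and an event-list JSON, runs the coupling fit and
#' writes per-cell period and division tables (`periods.tsv`,
#' `divisions.tsv`), detected extrema (`extrema.json`), the cohort summary
#' (`summary.json`) and a small run log (`run_log.json`, with exclusion
#' counts).
#'
#' @param cohort_file Path to a cohort table (see [write_cohort()]).
#' @param events_file Path to an events JSON (see [write_events()]).
#' @param outdir Output directory.
#' @param control A [ymc_control()].
#' @return The `ymc_coupling` fit, invisibly.
#' @export
run_analyze <- function(cohort_file, events_file, outdir,
                        control = ymc_control()) {
  coh <- read_cohort(cohort_file)
  events <- read_events(events_file)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  fit <- ymc_coupling(coh, events = events, control = control)
  utils::write.table(fit$periods, file.path(outdir, "periods.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(fit$divisions, file.path(outdir, "divisions.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  write_extrema(fit, file.path(outdir, "extrema.json"))
  summ <- lapply(fit$summary, function(s) {
    list(n_cells = s$n_cells, n_divisions = s$n_divisions,
         frac_single_cycle = s$frac_single_cycle,
         statistics = s$table)
  })
  jsonlite::write_json(
    list(conditions = summ,
         n_cells = fit$n_cells, n_excluded = fit$n_excluded,
         n_analyzed = fit$n_cells - fit$n_excluded,
         n_divisions = nrow(fit$divisions),
         n_delta_p_skipped = fit$n_delta_p_skipped),
    file.path(outdir, "summary.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows")
  jsonlite::write_json(
    list(n_cells = fit$n_cells, n_excluded = fit$n_excluded,
         min_track_duration = control$min_track_duration,
         detrend_order = control$detrend_order,
         sg_window = control$sg_window, sg_order = control$sg_order,
         min_prominence = control$criteria$min_prominence,
         min_peak_separation = control$criteria$min_peak_separation),
    file.path(outdir, "run_log.json"), auto_unbox = TRUE, digits = NA)
  invisible(fit)
}

#' Render report figures and a text summary from analysis outputs
#'
#' Reads one or more analysis output directories (as written by
#' [run_analyze()]) and writes `report.txt` with per-condition mean and sd
#' of the periods and lags, plus PNG figures (period distributions, lag
#' histogram, return map). With two or more conditions the report includes
#' a Kolmogorov-Smirnov comparison of the cycles-per-division
#' distributions between the first two.
#'
#' @param stats_dirs Character vector of [run_analyze()] output
#'   directories.
#' @param outdir Report output directory.
#' @return Path of the report file, invisibly.
#' @export
run_report <- function(stats_dirs, outdir) {
  for (d in stats_dirs)
    if (!file.exists(file.path(d, "divisions.tsv")))
      stop("missing statistics in ", d, ": run the analysis step first")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  per <- do.call(rbind, lapply(stats_dirs, function(d)
    utils::read.delim(file.path(d, "periods.tsv"))))
  div <- do.call(rbind, lapply(stats_dirs, function(d)
    utils::read.delim(file.path(d, "divisions.tsv"))))
  lines <- c("Metabolic-cycle / division-cycle coupling report", "")
  conds <- unique(c(per$condition, div$condition))
  msd <- function(x) {
    x <- x[is.finite(x)]
    if (length(x) == 0) return("insufficient data")
    sprintf("%.2f +/- %.2f min (n=%d)", mean(x), stats::sd(x), length(x))
  }
  for (cn in conds) {
    p <- per[per$condition == cn, ]
    d <- div[div$condition == cn, ]
    lines <- c(lines, sprintf("Condition %s:", cn),
               sprintf("  T_P   %s", msd(p$value[p$type == "T_P"])),
               sprintf("  T_M   %s", msd(p$value[p$type == "T_M"])),
               sprintf("  T_CDC %s", msd(p$value[p$type == "T_CDC"])),
               sprintf("  delta_T %s", msd(d$delta_t)))
    dp <- d$delta_p[is.finite(d$delta_p)]
    lines <- c(lines, if (length(dp) > 0)
      sprintf("  delta_P %s", msd(dp)) else
        "  delta_P insufficient data")
    if (nrow(d) > 0)
      lines <- c(lines, sprintf(
        "  divisions with one metabolic cycle: %.1f%% of %d",
        100 * mean(d$n_cycles == 1), nrow(d)))
    lines <- c(lines, "")
  }
  if (length(conds) >= 2) {
    a <- div$n_cycles[div$condition == conds[1]]
    b <- div$n_cycles[div$condition == conds[2]]
    if (length(a) > 0 && length(b) > 0) {
      ks <- ks_compare(a, b)
      lines <- c(lines, sprintf(
        "KS comparison of cycles per division (%s vs %s): D = %.3f, p = %.3g",
        conds[1], conds[2], ks$D, ks$p_value), "")
    }
  }
  report <- file.path(outdir, "report.txt")
  writeLines(lines, report)
  if (nrow(div) > 0) {
    grDevices::png(file.path(outdir, "delta_t_hist.png"), 600, 450)
    graphics::hist(div$delta_t, breaks = 30, xlab = "delta_T (min)",
                   main = "Division lag to nearest trough")
    graphics::abline(v = 0, lty = 2)
    grDevices::dev.off()
  }
  if (nrow(per) > 0) {
    grDevices::png(file.path(outdir, "periods.png"), 700, 450)
    graphics::boxplot(value ~ interaction(type, condition, sep = " "),
                      data = per[per$type %in% c("T_P", "T_CDC"), ],
                      las = 2, ylab = "period (min)", main = "Periods",
                      cex.axis = 0.7)
    grDevices::dev.off()
  }
  invisible(report)
}

#' Run the whole pipeline for one or more regimes
#'
#' Convenience wrapper: simulate, analyze and report each regime under
#' `outdir/<regime_name>/`, then write the joint report to
#' `outdir/report/`.
#'
#' @param regimes List of [ymc_regime()] objects or preset names.
#' @param outdir Output root directory.
#' @param seed Optional base seed; regime `i` uses `seed + i - 1`.
#' @param control A [ymc_control()].
#' @return Named list of `ymc_coupling` fits, invisibly.
#' @export
run_pipeline <- function(regimes, outdir, seed = NULL,
                         control = ymc_control()) {
  if (!is.list(regimes) || inherits(regimes, "ymc_regime"))
    regimes <- list(regimes)
  fits <- list()
  dirs <- character(0)
  for (i in seq_along(regimes)) {
    reg <- regimes[[i]]
    if (is.character(reg)) reg <- ymc_regime(preset = match_preset(reg))
    if (!is.null(seed)) reg$seed <- as.integer(seed + i - 1L)
    d <- file.path(outdir, reg$regime_name)
    paths <- run_simulate(reg, d)
    fits[[reg$regime_name]] <-
      run_analyze(paths$cohort, paths$events, d, control)
    dirs <- c(dirs, d)
  }
  run_report(dirs, file.path(outdir, "report"))
  invisible(fits)
}
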