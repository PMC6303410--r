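#' Fit the metabolic-cycle / division-cycle coupling analysis
#'
#' Runs the full analysis on a cohort of single-cell traces: short tracks
#' are excluded, each remaining flavin trace is detrended (order-7
#' polynomial), normalized by its maximum, Savitzky-Golay smoothed and
#' scanned for peaks and troughs; division intervals are formed from
#' nuclear-separation events; and every coupling statistic is assembled:
#' peak-to-peak and trough-to-trough metabolic periods (`T_P`, `T_M`),
#' division periods (`T_CDC`), the signed lag between each separation and
#' the nearest trough (`delta_T`, also scaled by the local `T_M`), the
#' Whi5-to-flavin peak lag per division (`delta_P`), metabolic cycles per
#' division, and the period return map.
#'
#' @param cohort A `ymc_cohort` (from [simulate.ymc_regime()] or
#'   [read_cohort()]).
#' @param events Optional named list of [ymc_events()] (names = cell ids).
#'   When `NULL`, ground-truth separation times attached to simulated
#'   traces are used.
#' @param control A [ymc_control()] with the preprocessing parameters.
#' @param whi5 Use the Whi5 channel to compute per-division localization
#'   peaks and `delta_P` (default `TRUE`).
#' @return Object of class `ymc_coupling` with components
#'   \describe{
#'     \item{cells}{per-cell list: processed trace, periods, events and
#'       division-level statistics}
#'     \item{periods}{data.frame of per-cell `T_P`/`T_M`/`T_CDC` values}
#'     \item{divisions}{data.frame, one row per complete division interval:
#'       `delta_t`, `delta_t_over_tm`, `delta_p`, `n_cycles`}
#'     \item{return_pairs}{matrix of consecutive-period pairs}
#'     \item{summary}{cohort summary per condition
#'       (see [summarize_condition()])}
#'     \item{n_excluded}{number of excluded tracks}
#'   }
#' @examples
#' coh <- simulate(ymc_regime("ynb_1x", n_cells = 5, seed = 1))
#' fit <- ymc_coupling(coh)
#' coef(fit)
#' @export
ymc_coupling <- function(cohort, events = NULL, control = ymc_control(),
                         whi5 = TRUE) {
  stopifnot(inherits(cohort, "ymc_cohort"))
  cohort <- exclude_short_tracks(cohort, control$min_track_duration)
  cells <- list()
  per_rows <- list()
  div_rows <- list()
  pairs <- list()
  n_excluded <- 0L
  dp_skipped <- 0L
  for (tr in unclass(cohort)) {
    pt <- process_trace(tr, control)
    if (pt$excluded) {
      n_excluded <- n_excluded + 1L
      cells[[tr$cell_id]] <- list(processed = pt)
      next
    }
    ev <- if (!is.null(events)) {
      e <- events[[tr$cell_id]]
      if (is.null(e)) numeric(0) else e$separation_times
    } else if (!is.null(tr$ground_truth)) {
      tr$ground_truth$separation_times
    } else numeric(0)
    ev <- keep_uncensored_events(ev, tr)
    per <- periods_from_extrema(pt$peak_times, pt$trough_times)
    tcdc <- cdc_periods(ev)
    iv <- cdc_intervals(ev)
    dtab <- NULL
    if (nrow(iv) > 0L && length(pt$trough_times) > 0L) {
      sep_complete <- iv[, 2]  # separations ending a complete division
      dt_df <- delta_T(pt$trough_times, sep_complete)
      # a separation outside the detected trough span has no meaningful
      # nearest trough (its own trough is cut off by the movie edge)
      outside <- sep_complete < min(pt$trough_times) |
        sep_complete > max(pt$trough_times)
      dt_df$delta_t[outside] <- NA_real_
      dt_df$delta_t_over_tm[outside] <- NA_real_
      ncyc <- cycles_per_cdc(pt$peak_times, iv)
      dp <- rep(NA_real_, nrow(iv))
      if (whi5 && !is.null(tr$whi5)) {
        wp <- whi5_peak_per_cdc(tr$whi5, tr$time, iv)
        dpv <- suppressWarnings(delta_P(wp, pt$peak_times, iv))
        dp_skipped <- dp_skipped + attr(dpv, "n_skipped")
        # re-expand to one entry per interval for the table
        kk <- 1L
        for (j in seq_len(nrow(iv))) {
          fp_in <- pt$peak_times[pt$peak_times >= iv[j, 1] &
                                   pt$peak_times < iv[j, 2]]
          if (!is.na(wp[j]) && length(fp_in) > 0L) {
            dp[j] <- dpv[kk]
            kk <- kk + 1L
          }
        }
      }
      dtab <- data.frame(cell_id = tr$cell_id, condition = tr$condition,
                         separation = dt_df$separation,
                         delta_t = dt_df$delta_t,
                         t_m_local = dt_df$t_m_local,
                         delta_t_over_tm = dt_df$delta_t_over_tm,
                         n_cycles = as.integer(ncyc),
                         delta_p = dp, t_cdc = tcdc,
                         stringsAsFactors = FALSE)
      div_rows[[tr$cell_id]] <- dtab
    }
    mk_per <- function(type, v) if (length(v) == 0) NULL else
      data.frame(cell_id = tr$cell_id, condition = tr$condition,
                 type = type, value = v, stringsAsFactors = FALSE)
    per_rows[[tr$cell_id]] <- rbind(mk_per("T_P", per$T_P),
                                    mk_per("T_M", per$T_M),
                                    mk_per("T_CDC", tcdc))
    rp <- return_map(per$T_P)
    if (nrow(rp) > 0) pairs[[tr$cell_id]] <- rp
    cells[[tr$cell_id]] <- list(processed = pt, periods = per,
                                separations = ev, divisions = dtab)
  }
  periods <- if (length(per_rows)) do.call(rbind, per_rows) else
    data.frame(cell_id = character(0), condition = character(0),
               type = character(0), value = numeric(0))
  divisions <- if (length(div_rows)) do.call(rbind, div_rows) else
    data.frame(cell_id = character(0), condition = character(0),
               separation = numeric(0), delta_t = numeric(0),
               t_m_local = numeric(0), delta_t_over_tm = numeric(0),
               n_cycles = integer(0), delta_p = numeric(0),
               t_cdc = numeric(0))
  rownames(periods) <- NULL
  rownames(divisions) <- NULL
  conds <- unique(c(periods$condition, divisions$condition))
  summ <- lapply(conds, function(cn) {
    p <- periods[periods$condition == cn, ]
    d <- divisions[divisions$condition == cn, ]
    summarize_condition(list(
      T_P = p$value[p$type == "T_P"], T_M = p$value[p$type == "T_M"],
      T_CDC = p$value[p$type == "T_CDC"], delta_T = d$delta_t,
      delta_T_over_TM = d$delta_t_over_tm, delta_P = d$delta_p,
      cycles_per_cdc = d$n_cycles),
      n_cells = length(unique(c(p$cell_id, d$cell_id))))
  })
  names(summ) <- conds
  structure(list(cells = cells, periods = periods, divisions = divisions,
                 return_pairs = if (length(pairs)) do.call(rbind, pairs) else
                   matrix(numeric(0), ncol = 2,
                          dimnames = list(NULL, c("period_n", "period_n1"))),
                 summary = summ, control = control,
                 n_cells = length(cells), n_excluded = n_excluded,
                 n_delta_p_skipped = dp_skipped,
                 regime = attr(cohort, "regime")),
            class = "ymc_coupling")
}

# Sick-cell rule for division statistics: drop the division completed one
# division before the onset and any division spanning the onset.
keep_uncensored_events <- function(sep, trace) {
  if (is.null(trace$sick_onset) || length(sep) < 2L) return(sep)
  onset <- trace$sick_onset
  before <- which(sep <= onset)
  if (length(before) == 0L) return(sep)
  # remove the last separation at/before onset: this both drops the
  # division that ended there and merges away the interval spanning onset
  sep[-before[length(before)]]
}

#' @export
print.ymc_coupling <- function(x, ...) {
  cat("Metabolic-cycle / division-cycle coupling fit\n")
  cat(sprintf("  %d cells (%d excluded), %d complete divisions\n",
              x$n_cells, x$n_excluded, nrow(x$divisions)))
  for (cn in names(x$summary)) {
    s <- x$summary[[cn]]
    tp <- s$table[s$table$statistic == "T_P", ]
    dtr <- s$table[s$table$statistic == "delta_T", ]
    cat(sprintf("  [%s] T_P %.1f +/- %.1f min (n=%d);", cn, tp$mean, tp$sd,
                tp$n))
    cat(sprintf(" delta_T %.1f +/- %.1f min;", dtr$mean, dtr$sd))
    cat(sprintf(" single-cycle divisions %.1f%%\n",
                100 * s$frac_single_cycle))
  }
  invisible(x)
}

#' @export
summary.ymc_coupling <- function(object, ...) {
  structure(object$summary, class = "summary.ymc_coupling")
}

#' @export
print.summary.ymc_coupling <- function(x, ...) {
  for (cn in names(x)) {
    s <- x[[cn]]
    cat("Condition:", cn, sprintf("(%d cells, %d divisions)\n",
                                  s$n_cells, s$n_divisions))
    tab <- s$table
    tab[, -1] <- lapply(tab[, -1], function(v) round(v, 3))
    print(tab, row.names = FALSE)
    if (!is.na(s$frac_single_cycle))
      cat(sprintf("  divisions with exactly one metabolic cycle: %.1f%%\n",
                  100 * s$frac_single_cycle))
    cat("\n")
  }
  invisible(x)
}

#' Headline cohort statistics of a coupling fit
#'
#' @param object A `ymc_coupling` fit.
#' @param ... Unused.
#' @return Named numeric vector: mean `T_P`, `T_M`, `T_CDC`, mean and sd of
#'   `delta_T`, mean `delta_P`, mean cycles per division and the fraction
#'   of single-cycle divisions, pooled over conditions.
#' @export
coef.ymc_coupling <- function(object, ...) {
  p <- object$periods
  d <- object$divisions
  m <- function(x) if (length(x) == 0) NA_real_ else mean(x, na.rm = TRUE)
  c(mean_T_P = m(p$value[p$type == "T_P"]),
    mean_T_M = m(p$value[p$type == "T_M"]),
    mean_T_CDC = m(p$value[p$type == "T_CDC"]),
    mean_delta_T = m(d$delta_t),
    sd_delta_T = if (sum(is.finite(d$delta_t)) > 1)
      stats::sd(d$delta_t, na.rm = TRUE) else NA_real_,
    mean_delta_P = m(d$delta_p),
    mean_cycles_per_cdc = m(d$n_cycles),
    frac_single_cycle = if (nrow(d) > 0) mean(d$n_cycles == 1) else NA_real_)
}

#' Diagnostic plots of a coupling fit
#'
#' Four base-graphics panels: period distributions per condition
#' (metabolic vs division periods), the distribution of the
#' trough-to-division lag `delta_T`, the cycles-per-division histogram and
#' the period return map.
#'
#' @param x A `ymc_coupling` fit.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.ymc_coupling <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  p <- x$periods
  if (nrow(p) > 0) {
    graphics::boxplot(value ~ interaction(type, condition, sep = " "),
                      data = p[p$type %in% c("T_P", "T_CDC"), ],
                      las = 2, ylab = "period (min)", main = "Periods",
                      cex.axis = 0.7)
  }
  d <- x$divisions
  if (nrow(d) > 0) {
    graphics::hist(d$delta_t, breaks = 30,
                   main = "Division lag to nearest trough",
                   xlab = expression(Delta * T ~ "(min)"))
    graphics::abline(v = 0, lty = 2)
    tab <- table(factor(d$n_cycles, levels = 0:max(1, d$n_cycles)))
    graphics::barplot(tab, main = "Metabolic cycles per division",
                      xlab = "cycles", ylab = "divisions")
  }
  rp <- x$return_pairs
  if (nrow(rp) > 0) {
    graphics::plot(rp[, 1], rp[, 2], pch = 16,
                   col = grDevices::adjustcolor("steelblue", 0.4),
                   xlab = expression(T_P[n] ~ "(min)"),
                   ylab = expression(T_P[n + 1] ~ "(min)"),
                   main = "Period return map", ...)
    graphics::abline(0, 1, lty = 2)
  }
  invisible(x)
}
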