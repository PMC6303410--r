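#' Metabolic-cycle periods from detected extrema
#'
#' Peak-to-peak periods (`T_P`) are successive differences of peak times;
#' trough-to-trough (min-to-min) periods (`T_M`) are successive differences
#' of trough times.
#'
#' @param peak_times,trough_times Sorted extrema times, minutes.
#' @return List with numeric `T_P` and `T_M` (empty when fewer than two
#'   extrema of a type exist).
#' @examples
#' periods_from_extrema(c(50, 180, 310), c(120, 250))
#' @export
periods_from_extrema <- function(peak_times, trough_times) {
  d <- function(x) if (length(x) < 2L) numeric(0) else diff(x)
  list(T_P = d(peak_times), T_M = d(trough_times))
}

#' Lag between each division and the nearest metabolic-cycle trough
#'
#' For every nuclear-separation time the signed lag `delta_T` is the
#' separation time minus the nearest trough time (positive when the
#' separation follows the trough; exact midpoint ties resolve toward the
#' earlier trough). The lag is also returned scaled by the local
#' trough-to-trough period `T_M` of the cycle containing the separation
#' (`NA` outside the detected trough span).
#'
#' @param trough_times Sorted detected trough times, minutes (nonempty).
#' @param separation_times Nuclear-separation times, minutes.
#' @return data.frame with columns `separation`, `delta_t`, `t_m_local`,
#'   `delta_t_over_tm`.
#' @examples
#' delta_T(c(100, 230), c(105, 228))
#' @export
delta_T <- function(trough_times, separation_times) {
  if (length(trough_times) == 0L)
    stop("no troughs: delta_T is undefined")
  if (length(separation_times) == 0L)
    return(data.frame(separation = numeric(0), delta_t = numeric(0),
                      t_m_local = numeric(0), delta_t_over_tm = numeric(0)))
  tt <- sort(trough_times)
  res <- lapply(separation_times, function(s) {
    i <- which.min(abs(s - tt))  # ties.method "first" = earlier trough
    dtl <- s - tt[i]
    j <- findInterval(s, tt)
    tm <- if (j >= 1L && j < length(tt)) tt[j + 1L] - tt[j] else NA_real_
    c(s, dtl, tm)
  })
  m <- do.call(rbind, res)
  data.frame(separation = m[, 1], delta_t = m[, 2], t_m_local = m[, 3],
             delta_t_over_tm = m[, 2] / m[, 3])
}

#' Lag between the Whi5 and flavin peaks of each division cycle
#'
#' Within each division interval containing both a Whi5 localization peak
#' and a flavin peak, `delta_P` is the Whi5 peak time minus the flavin peak
#' time (negative when Whi5 precedes flavin, as it normally does). The
#' flavin peak compared against is the first one at or after the Whi5 peak
#' within the interval, or the last one in the interval when Whi5 follows
#' every flavin peak. Intervals missing either peak are skipped and
#' counted in the `n_skipped` attribute.
#'
#' @param whi5_peaks Per-interval Whi5 peak times from
#'   [whi5_peak_per_cdc()] (`NA` allowed).
#' @param flavin_peak_times Detected flavin peak times, minutes.
#' @param intervals Two-column matrix from [cdc_intervals()].
#' @return Numeric vector of signed lags with attribute `n_skipped`; empty
#'   (with a warning) when no interval has both peaks.
#' @export
delta_P <- function(whi5_peaks, flavin_peak_times, intervals) {
  if (is.null(dim(intervals)) || ncol(intervals) != 2)
    stop("'intervals' must be a two-column matrix")
  stopifnot(length(whi5_peaks) == nrow(intervals))
  out <- numeric(0)
  skipped <- 0L
  for (j in seq_len(nrow(intervals))) {
    w <- whi5_peaks[j]
    fp <- flavin_peak_times[flavin_peak_times >= intervals[j, 1] &
                              flavin_peak_times < intervals[j, 2]]
    if (is.na(w) || length(fp) == 0L) {
      skipped <- skipped + 1L
      next
    }
    after <- fp[fp >= w]
    f <- if (length(after) > 0L) after[1] else fp[length(fp)]
    out <- c(out, w - f)
  }
  if (length(out) == 0L && nrow(intervals) > 0L)
    warning("no division interval contained both a Whi5 and a flavin peak")
  attr(out, "n_skipped") <- skipped
  out
}

#' Metabolic cycles per division cycle
#'
#' Counts the flavin peaks falling inside each half-open division interval.
#' Metabolic cycles outside any division interval (before the first or
#' after the last separation, or in non-dividing cells) are excluded from
#' the counts and reported in the `excluded_peaks` attribute.
#'
#' @param flavin_peak_times Detected flavin peak times, minutes.
#' @param intervals Two-column matrix from [cdc_intervals()];
#'   non-overlapping.
#' @return Integer vector of counts (one per interval) with attribute
#'   `excluded_peaks`.
#' @examples
#' cycles_per_cdc(c(60, 190), cbind(0, 130))
#' @export
cycles_per_cdc <- function(flavin_peak_times, intervals) {
  if (is.null(dim(intervals)) || ncol(intervals) != 2)
    stop("'intervals' must be a two-column matrix")
  if (nrow(intervals) == 0L) {
    out <- integer(0)
    attr(out, "excluded_peaks") <- length(flavin_peak_times)
    return(out)
  }
  o <- order(intervals[, 1])
  iv <- intervals[o, , drop = FALSE]
  if (any(iv[, 2] <= iv[, 1]) ||
      (nrow(iv) > 1 && any(iv[-1, 1] < iv[-nrow(iv), 2])))
    stop("division intervals must be non-overlapping with start < end")
  counts <- integer(nrow(intervals))
  inside <- 0L
  for (j in seq_len(nrow(intervals))) {
    n <- sum(flavin_peak_times >= intervals[j, 1] &
               flavin_peak_times < intervals[j, 2])
    counts[j] <- n
    inside <- inside + n
  }
  attr(counts, "excluded_peaks") <- length(flavin_peak_times) - inside
  counts
}

#' Return map of consecutive metabolic-cycle periods
#'
#' Pairs each peak-to-peak period with the next one within a cell. A
#' regular oscillator gives a tight cloud on the diagonal; irregular
#' cycling (as under rapamycin) disperses it.
#'
#' @param T_P Numeric vector of consecutive periods of one cell.
#' @return Two-column matrix (`period_n`, `period_n1`); zero rows when
#'   fewer than two periods exist.
#' @examples
#' return_map(c(130, 140, 120))
#' @export
return_map <- function(T_P) {
  if (length(T_P) < 2L)
    return(matrix(numeric(0), ncol = 2,
                  dimnames = list(NULL, c("period_n", "period_n1"))))
  cbind(period_n = T_P[-length(T_P)], period_n1 = T_P[-1])
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' `D` is the supremum distance between the two empirical CDFs. The
#' p-value is exact when both samples have at most 25 observations and no
#' ties are present, and asymptotic otherwise.
#'
#' @param a,b Nonempty numeric samples.
#' @return List with `D`, `p_value`, `n_a`, `n_b` and `method`.
#' @examples
#' ks_compare(c(1, 1, 2), c(2, 2, 3))$D
#' @export
ks_compare <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L)
    stop("both samples must be nonempty")
  ties <- any(duplicated(c(a, b)))
  exact <- length(a) <= 25 && length(b) <= 25 && !ties
  kt <- suppressWarnings(stats::ks.test(a, b, exact = exact))
  list(D = unname(kt$statistic), p_value = kt$p.value,
       n_a = length(a), n_b = length(b),
       method = if (exact) "exact" else "asymptotic")
}

#' Cohort summary of coupling statistics
#'
#' Mean, sd, median, quartiles and counts for each statistic, plus the
#' fraction of division cycles containing exactly one metabolic cycle.
#'
#' @param stats Named list of numeric vectors; recognized names are `T_P`,
#'   `T_M`, `T_CDC`, `delta_T`, `delta_T_over_TM`, `delta_P` and
#'   `cycles_per_cdc`.
#' @param n_cells Number of cells contributing.
#' @return List with a `table` data.frame (one row per statistic:
#'   `n`, `mean`, `sd`, `q25`, `median`, `q75`), `n_cells`, `n_divisions`
#'   and `frac_single_cycle`.
#' @export
summarize_condition <- function(stats, n_cells = NA_integer_) {
  keys <- c("T_P", "T_M", "T_CDC", "delta_T", "delta_T_over_TM", "delta_P",
            "cycles_per_cdc")
  rows <- lapply(keys, function(k) {
    x <- as.numeric(stats[[k]])
    x <- x[is.finite(x)]
    if (length(x) == 0L)
      return(data.frame(statistic = k, n = 0L, mean = NA_real_,
                        sd = NA_real_, q25 = NA_real_, median = NA_real_,
                        q75 = NA_real_))
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    data.frame(statistic = k, n = length(x), mean = mean(x),
               sd = if (length(x) > 1) stats::sd(x) else 0,
               q25 = q[1], median = q[2], q75 = q[3])
  })
  cc <- as.numeric(stats[["cycles_per_cdc"]])
  cc <- cc[is.finite(cc)]
  list(table = do.call(rbind, rows),
       n_cells = n_cells,
       n_divisions = length(cc),
       frac_single_cycle = if (length(cc) > 0) mean(cc == 1) else NA_real_)
}
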