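#' Flag tracks shorter than a minimum duration
#'
#' Cells tracked for less than 4.5 hours (270 min) are excluded from
#' analysis; the comparison is a strict `<`, so a track of exactly the
#' minimum duration is kept.
#'
#' @param cohort A `ymc_cohort`.
#' @param min_duration Minimum track span (last time minus first time),
#'   minutes.
#' @return The cohort with an `excluded` flag and `exclusion_reason` set on
#'   each trace.
#' @examples
#' coh <- simulate(ymc_regime("ynb_1x", n_cells = 2, seed = 1))
#' coh <- exclude_short_tracks(coh)
#' sapply(unclass(coh), `[[`, "excluded")
#' @export
exclude_short_tracks <- function(cohort, min_duration = 270) {
  stopifnot(inherits(cohort, "ymc_cohort"))
  cells <- lapply(unclass(cohort), function(tr) {
    dur <- diff(range(tr$time))
    if (dur < min_duration) {
      tr$excluded <- TRUE
      tr$exclusion_reason <- sprintf("tracked %g min < %g min", dur,
                                     min_duration)
    } else {
      tr$excluded <- FALSE
      tr$exclusion_reason <- NA_character_
    }
    tr
  })
  new_ymc_cohort(cells, attr(cohort, "regime"))
}

#' Polynomial detrending
#'
#' Fits a least-squares polynomial of the given order to the signal as a
#' function of time and returns the residual. The default order 7 removes
#' slow drift and photobleaching trends while leaving oscillations with
#' several cycles per track intact. The fit uses an orthogonal polynomial
#' basis for numerical stability; the result is identical to a raw-power
#' fit.
#'
#' @param signal Numeric vector (raw fluorescence).
#' @param time Time grid, same length.
#' @param order Polynomial order (default 7).
#' @return Detrended signal (residuals; mean zero).
#' @examples
#' t <- seq(0, 1000, 10)
#' x <- sin(2 * pi * t / 130) + 0.001 * t
#' d <- detrend(x, t)
#' @export
detrend <- function(signal, time, order = 7) {
  if (length(signal) != length(time))
    stop("'signal' and 'time' must have the same length")
  if (length(signal) <= order + 1)
    stop("trace too short for polynomial detrending: need more than ",
         order + 1, " samples, got ", length(signal))
  fit <- stats::lm(signal ~ stats::poly(time, degree = order))
  as.numeric(stats::residuals(fit))
}

#' Normalize a trace by its maximum
#'
#' @param signal Numeric vector.
#' @return `signal / max(signal)`; the maximum of the result is 1.
#' @examples
#' normalize_trace(c(1, 2, 4))
#' @export
normalize_trace <- function(signal) {
  m <- max(signal)
  if (!is.finite(m) || m <= 0)
    stop("degenerate trace: maximum must be positive to normalize")
  signal / m
}

#' Savitzky-Golay smoothing
#'
#' Moving least-squares polynomial filter; polynomials of degree up to
#' `polyorder` pass through unchanged, which preserves peak heights better
#' than a moving average.
#'
#' @param signal Numeric vector.
#' @param window_length Odd window size in samples (default 5).
#' @param polyorder Polynomial order, less than `window_length` (default 2).
#' @return Smoothed signal, same length.
#' @export
smooth_trace <- function(signal, window_length = 5, polyorder = 2) {
  if (window_length %% 2 != 1)
    stop("'window_length' must be odd")
  if (polyorder >= window_length)
    stop("'polyorder' must be less than 'window_length'")
  if (window_length > length(signal))
    stop("'window_length' exceeds signal length")
  as.numeric(signal::sgolayfilt(signal, p = polyorder, n = window_length))
}

#' Peak-detection criteria
#'
#' Standardized criteria for calling metabolic-cycle extrema on a
#' preprocessed (detrended, normalized, smoothed) trace.
#'
#' @param min_prominence Minimum topographic prominence as a fraction of the
#'   signal range (default 0.1).
#' @param min_peak_separation Minimum time between accepted extrema of the
#'   same type, minutes (default 40, the shortest metabolic-cycle period
#'   reported for this organism).
#' @param min_relative_height Minimum height above the signal minimum as a
#'   fraction of the range (default 0, disabled).
#' @param edge_policy `"exclude"`: the first and last samples are never
#'   extrema.
#' @return Object of class `peak_criteria`.
#' @export
peak_criteria <- function(min_prominence = 0.1, min_peak_separation = 40,
                          min_relative_height = 0,
                          edge_policy = "exclude") {
  if (min_prominence <= 0 || min_prominence >= 1)
    stop("'min_prominence' must lie in (0, 1)")
  if (min_peak_separation < 0) stop("'min_peak_separation' must be >= 0")
  structure(list(min_prominence = min_prominence,
                 min_peak_separation = min_peak_separation,
                 min_relative_height = min_relative_height,
                 edge_policy = match.arg(edge_policy, "exclude")),
            class = "peak_criteria")
}

# Topographic prominence of candidate maxima at indices `idx` of signal x:
# extend left and right to the nearest strictly higher sample (or the edge),
# take the minimum of x on each side, prominence = x[i] - max(side minima).
prominence_of <- function(x, idx) {
  n <- length(x)
  vapply(idx, function(i) {
    lo_l <- x[i]
    j <- i - 1L
    while (j >= 1L && x[j] <= x[i]) {
      if (x[j] < lo_l) lo_l <- x[j]
      j <- j - 1L
    }
    lo_r <- x[i]
    j <- i + 1L
    while (j <= n && x[j] <= x[i]) {
      if (x[j] < lo_r) lo_r <- x[j]
      j <- j + 1L
    }
    x[i] - max(lo_l, lo_r)
  }, numeric(1))
}

# Candidate maxima + prominence/height/separation selection on one signal.
select_peaks <- function(x, time, criteria) {
  n <- length(x)
  if (n < 3L) return(numeric(0))
  # local maxima with plateau support: a run of equal values counts as one
  # candidate at its first sample, provided the signal falls on both sides
  runs <- rle(x)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  k <- length(runs$values)
  cand <- integer(0)
  if (k >= 3L) {
    j <- 2:(k - 1L)
    is_max <- runs$values[j] > runs$values[j - 1L] &
      runs$values[j] > runs$values[j + 1L]
    cand <- starts[j][is_max]
  }
  if (length(cand) == 0L) return(numeric(0))
  rng <- diff(range(x))
  if (rng == 0) return(numeric(0))
  prom <- prominence_of(x, cand)
  ok <- prom >= criteria$min_prominence * rng
  if (criteria$min_relative_height > 0)
    ok <- ok & (x[cand] >= min(x) + criteria$min_relative_height * rng)
  cand <- cand[ok]
  if (length(cand) == 0L) return(numeric(0))
  # greedy by height (ties: earlier sample), enforcing minimum separation
  ord <- order(-x[cand], cand)
  accepted <- integer(0)
  for (i in cand[ord]) {
    if (all(abs(time[i] - time[accepted]) >= criteria$min_peak_separation))
      accepted <- c(accepted, i)
  }
  sort(accepted)
}

# Enforce strict peak/trough alternation: among consecutive same-type
# extrema keep the more extreme one (ties: the earlier).
interleave_extrema <- function(x, peak_idx, trough_idx) {
  ev <- rbind(
    if (length(peak_idx)) cbind(peak_idx, 1L) else NULL,
    if (length(trough_idx)) cbind(trough_idx, -1L) else NULL)
  if (is.null(ev) || nrow(ev) == 0L)
    return(list(peaks = integer(0), troughs = integer(0)))
  ev <- ev[order(ev[, 1]), , drop = FALSE]
  keep <- rep(TRUE, nrow(ev))
  repeat {
    rows <- which(keep)
    if (length(rows) < 2L) break
    same <- which(diff(ev[rows, 2]) == 0)
    if (length(same) == 0L) break
    j <- same[1]
    a <- rows[j]; b <- rows[j + 1L]
    if (ev[a, 2] == 1L) {  # two peaks: keep the higher
      drop <- if (x[ev[b, 1]] > x[ev[a, 1]]) a else b
    } else {               # two troughs: keep the lower
      drop <- if (x[ev[b, 1]] < x[ev[a, 1]]) a else b
    }
    keep[drop] <- FALSE
  }
  ev <- ev[keep, , drop = FALSE]
  list(peaks = ev[ev[, 2] == 1L, 1], troughs = ev[ev[, 2] == -1L, 1])
}

#' Detect metabolic-cycle peaks and troughs
#'
#' Local maxima of the preprocessed signal that pass the prominence,
#' relative-height and separation criteria are returned as peaks; troughs
#' are detected symmetrically on the negated signal. Consecutive extrema of
#' the same type are then resolved by keeping the more extreme one, so the
#' returned peaks and troughs strictly alternate. Extrema are reported at
#' grid times (no subsample interpolation).
#'
#' @param signal Preprocessed signal.
#' @param time Time grid, minutes.
#' @param criteria A [peak_criteria()].
#' @return List with numeric `peak_times` and `trough_times` (possibly
#'   empty).
#' @examples
#' t <- seq(0, 650, 10)
#' x <- -cos(2 * pi * t / 130)
#' detect_extrema(x, t)
#' @export
detect_extrema <- function(signal, time, criteria = peak_criteria()) {
  stopifnot(length(signal) == length(time))
  dt <- if (length(time) > 1) stats::median(diff(time)) else NA_real_
  if (is.finite(dt) && criteria$min_peak_separation < 2 * dt)
    stop("'min_peak_separation' must be at least twice the sampling interval")
  p <- select_peaks(signal, time, criteria)
  tr <- select_peaks(-signal, time, criteria)
  res <- interleave_extrema(signal, p, tr)
  list(peak_times = time[res$peaks], trough_times = time[res$troughs])
}

#' Autocorrelation period estimate
#'
#' Computes the unbiased sample autocorrelation of a detrended trace up to
#' `max_lag` and takes the period as the lag of the first local maximum
#' after the first zero crossing. The estimate is flagged unreliable when
#' that maximum falls below `threshold` (or when no zero crossing or
#' maximum exists).
#'
#' @param signal Detrended signal.
#' @param time Time grid, minutes.
#' @param max_lag Largest lag examined, minutes; the trace must span at
#'   least twice this value.
#' @param threshold Minimum autocorrelation at the detected maximum for the
#'   estimate to be called reliable (default 0.2).
#' @return List with `period` (minutes; `NA` if none found), `reliable`
#'   (logical), `acf` and `lags`.
#' @examples
#' t <- seq(0, 1300, 10)
#' autocorr_period(sin(2 * pi * t / 130), t, max_lag = 300)$period
#' @export
autocorr_period <- function(signal, time, max_lag = 400, threshold = 0.2) {
  stopifnot(length(signal) == length(time))
  dt <- stats::median(diff(time))
  span <- diff(range(time))
  if (span < 2 * max_lag)
    stop("trace too short for autocorrelation: span ", span,
         " min < 2 x max_lag = ", 2 * max_lag, " min")
  n <- length(signal)
  x <- signal - mean(signal)
  denom <- sum(x^2) / n
  kmax <- min(n - 2L, floor(max_lag / dt))
  r <- vapply(seq_len(kmax), function(k) {
    sum(x[1:(n - k)] * x[(k + 1):n]) / (n - k) / denom
  }, numeric(1))
  lags <- seq_len(kmax) * dt
  zc <- which(r <= 0)[1]
  period <- NA_real_
  reliable <- FALSE
  if (!is.na(zc) && zc < kmax - 1L) {
    # first genuine local maximum after the zero crossing
    for (k in (zc + 1L):(kmax - 1L)) {
      if (k > 1L && r[k] > r[k - 1L] && r[k] >= r[k + 1L]) {
        period <- lags[k]
        reliable <- r[k] >= threshold
        break
      }
    }
  }
  list(period = period, reliable = reliable, acf = r, lags = lags)
}

#' Apply sick-cell censoring to a trace
#'
#' When a tracked cell turns sickly at `sick_onset`, extrema detection only
#' considers fluorescence from five time points after the onset, and the
#' division completed one division before the onset is dropped from
#' division-cycle statistics.
#'
#' @param trace A `ymc_cell_trace`.
#' @param sick_onset Onset time, minutes; must lie within the trace span.
#' @return The trace with `sick_onset` and `censor_start` (onset plus five
#'   sampling intervals) recorded.
#' @export
censor_sick_cell <- function(trace, sick_onset) {
  stopifnot(inherits(trace, "ymc_cell_trace"))
  if (sick_onset < min(trace$time) || sick_onset > max(trace$time))
    stop("'sick_onset' lies outside the trace span")
  trace$sick_onset <- sick_onset
  trace$censor_start <- sick_onset + 5 * trace$sampling_interval
  trace
}

#' Processing controls for the coupling fit
#'
#' Collects the preprocessing chain parameters: polynomial detrend order,
#' max normalization, Savitzky-Golay window and order, peak criteria,
#' minimum track duration, and the autocorrelation reliability threshold.
#'
#' @param detrend_order Polynomial order for detrending (default 7).
#' @param sg_window,sg_order Savitzky-Golay window length (samples, odd) and
#'   polynomial order.
#' @param criteria A [peak_criteria()].
#' @param min_track_duration Minimum track span, minutes (default 270).
#' @param acf_max_lag,acf_threshold Autocorrelation settings.
#' @return Object of class `ymc_control`.
#' @export
ymc_control <- function(detrend_order = 7, sg_window = 5, sg_order = 2,
                        criteria = peak_criteria(),
                        min_track_duration = 270,
                        acf_max_lag = 400, acf_threshold = 0.2) {
  structure(list(detrend_order = detrend_order, sg_window = sg_window,
                 sg_order = sg_order, criteria = criteria,
                 min_track_duration = min_track_duration,
                 acf_max_lag = acf_max_lag, acf_threshold = acf_threshold),
            class = "ymc_control")
}

#' Run the preprocessing chain on one trace
#'
#' Applies the chain in the order used for the microscopy data: polynomial
#' detrend, normalization by the maximum, Savitzky-Golay smoothing, then
#' prominence-based extrema detection. If the trace carries a sick-cell
#' censor, extrema are detected only from the censor resumption point
#' onward.
#'
#' @param trace A `ymc_cell_trace`.
#' @param control A [ymc_control()].
#' @return Object of class `ymc_processed_trace` with fields `cell_id`,
#'   `time`, `raw`, `detrended`, `smoothed`, `peak_times`, `trough_times`,
#'   `censor_start`, `excluded`, `exclusion_reason`.
#' @export
process_trace <- function(trace, control = ymc_control()) {
  stopifnot(inherits(trace, "ymc_cell_trace"))
  out <- list(cell_id = trace$cell_id, time = trace$time, raw = trace$flavin,
              condition = trace$condition,
              sampling_interval = trace$sampling_interval,
              censor_start = trace$censor_start,
              sick_onset = trace$sick_onset,
              excluded = isTRUE(trace$excluded),
              exclusion_reason = if (isTRUE(trace$excluded))
                trace$exclusion_reason else NA_character_)
  out$detrended <- rep(NA_real_, length(trace$time))
  out$smoothed <- rep(NA_real_, length(trace$time))
  out$peak_times <- numeric(0)
  out$trough_times <- numeric(0)
  class(out) <- "ymc_processed_trace"
  if (out$excluded) return(out)
  idx <- seq_along(trace$time)
  if (!is.null(trace$censor_start))
    idx <- which(trace$time >= trace$censor_start)
  if (length(idx) <= control$detrend_order + 1 ||
      length(idx) < control$sg_window) {
    out$excluded <- TRUE
    out$exclusion_reason <- "too few samples after censoring"
    return(out)
  }
  det <- detrend(trace$flavin[idx], trace$time[idx], control$detrend_order)
  nrm <- normalize_trace(det)
  smo <- smooth_trace(nrm, control$sg_window, control$sg_order)
  ext <- detect_extrema(smo, trace$time[idx], control$criteria)
  out$detrended[idx] <- det
  out$smoothed[idx] <- smo
  out$peak_times <- ext$peak_times
  out$trough_times <- ext$trough_times
  out
}

#' @export
print.ymc_processed_trace <- function(x, ...) {
  cat("Processed trace", x$cell_id, "\n")
  if (x$excluded) {
    cat("  EXCLUDED:", x$exclusion_reason, "\n")
  } else {
    cat(sprintf("  %d peaks, %d troughs over %g min\n",
                length(x$peak_times), length(x$trough_times),
                diff(range(x$time))))
  }
  invisible(x)
}
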