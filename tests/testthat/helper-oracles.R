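# Independent brute-force oracles used to cross-check the implementation.

# Naive extrema scan: tests every interior sample against the prominence,
# relative-height and separation rules, then resolves same-type runs.
oracle_extrema <- function(x, time, crit) {
  n <- length(x)
  scan_side <- function(sig) {
    if (n < 3L) return(integer(0))
    rng <- max(sig) - min(sig)
    if (rng == 0) return(integer(0))
    passing <- integer(0)
    for (i in 2:(n - 1L)) {
      # candidate = first sample of a plateau that falls away on both sides
      if (sig[i] == sig[i - 1L]) next
      j <- i - 1L
      k <- i + 1L
      while (k <= n && sig[k] == sig[i]) k <- k + 1L
      if (k > n) next
      if (!(sig[i] > sig[j] && sig[i] > sig[k])) next
      lo_l <- sig[i]
      for (j in rev(seq_len(i - 1L))) {
        if (sig[j] > sig[i]) break
        if (sig[j] < lo_l) lo_l <- sig[j]
      }
      lo_r <- sig[i]
      for (j in (i + 1L):n) {
        if (sig[j] > sig[i]) break
        if (sig[j] < lo_r) lo_r <- sig[j]
      }
      prom <- sig[i] - max(lo_l, lo_r)
      if (prom < crit$min_prominence * rng) next
      if (crit$min_relative_height > 0 &&
          sig[i] < min(sig) + crit$min_relative_height * rng) next
      passing <- c(passing, i)
    }
    # accept by descending height (ties: earlier), enforcing separation
    acc <- integer(0)
    for (i in passing[order(-sig[passing], passing)]) {
      ok <- TRUE
      for (a in acc) if (abs(time[i] - time[a]) < crit$min_peak_separation)
        ok <- FALSE
      if (ok) acc <- c(acc, i)
    }
    sort(acc)
  }
  pk <- scan_side(x)
  th <- scan_side(-x)
  typ <- c(rep(1L, length(pk)), rep(-1L, length(th)))
  idx <- c(pk, th)
  o <- order(idx)
  idx <- idx[o]; typ <- typ[o]
  changed <- TRUE
  while (changed && length(idx) >= 2L) {
    changed <- FALSE
    for (j in seq_len(length(idx) - 1L)) {
      if (typ[j] != typ[j + 1L]) next
      if (typ[j] == 1L)
        drop <- if (x[idx[j + 1L]] > x[idx[j]]) j else j + 1L
      else
        drop <- if (x[idx[j + 1L]] < x[idx[j]]) j else j + 1L
      idx <- idx[-drop]; typ <- typ[-drop]
      changed <- TRUE
      break
    }
  }
  list(peak_times = time[idx[typ == 1L]],
       trough_times = time[idx[typ == -1L]])
}

# Pooled-ECDF supremum for the two-sample KS statistic.
oracle_ks_D <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  d <- 0
  for (p in pts) {
    fa <- sum(a <= p) / length(a)
    fb <- sum(b <= p) / length(b)
    if (abs(fa - fb) > d) d <- abs(fa - fb)
  }
  d
}

# Sort-and-average top-k score.
oracle_whi5_score <- function(px, k = 5) {
  s <- sort(px, decreasing = TRUE)
  mean(s[1:k]) - mean(s[-(1:k)])
}

# Type-7 quantile by direct interpolation on the sorted sample.
oracle_quantile7 <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# All multisets of the given size drawn from `values` (as a list).
all_multisets <- function(values, size) {
  if (size == 0L) return(list(numeric(0)))
  out <- list()
  rec <- function(prefix, start) {
    if (length(prefix) == size) {
      out[[length(out) + 1L]] <<- prefix
      return()
    }
    for (i in start:length(values)) rec(c(prefix, values[i]), i)
  }
  rec(numeric(0), 1L)
  out
}
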