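#' Whi5 nuclear-localization score of one frame
#'
#' The score is the difference between the mean of the `k` brightest pixels
#' inside the cell mask and the mean of all remaining in-mask pixels. When
#' Whi5 is nuclear, a few pixels are much brighter than the cytoplasmic
#' rest and the score spikes; when Whi5 is cytoplasmic the frame is uniform
#' and the score is near zero. The score is invariant to adding a constant
#' to the frame and scales linearly with intensity. Ties among
#' equal-intensity pixels do not affect the value.
#'
#' @param frame Numeric matrix of pixel intensities.
#' @param mask Logical matrix, same dimension; `TRUE` marks in-cell pixels.
#'   Defaults to the whole frame.
#' @param k Number of brightest pixels (default 5).
#' @return Numeric score.
#' @examples
#' f <- matrix(10, 10, 10); f[1:5] <- 100
#' whi5_localization_score(f)  # 90
#' @export
whi5_localization_score <- function(frame, mask = NULL, k = 5) {
  stopifnot(is.numeric(frame))
  if (is.null(mask)) mask <- array(TRUE, dim(frame))
  px <- frame[mask]
  if (length(px) <= k)
    stop("mask must contain more than ", k, " pixels (got ", length(px), ")")
  sorted <- sort(px, decreasing = TRUE)
  mean(sorted[seq_len(k)]) - mean(sorted[-seq_len(k)])
}

#' Render a Whi5 trace as a mask-image stack
#'
#' Produces a small per-frame image stack in which a fixed set of "nuclear"
#' pixels carries elevated intensity during localization pulses, scaled so
#' that the top-`k`-pixel score of each rendered frame recovers the source
#' `whi5` channel value (exactly in the noiseless case). Outside pulses the
#' in-mask intensity is uniform background plus noise.
#'
#' @param trace A `ymc_cell_trace` with a `whi5` channel.
#' @param height,width Image size in pixels (default 15 x 15).
#' @param mask Logical matrix; default is a centered disk. Must contain at
#'   least 6 pixels.
#' @param n_nuclear Number of nuclear pixels (default 5).
#' @param k Top-pixel count of the target score statistic (default 5).
#' @param background Background intensity level.
#' @param noise_sd Pixel noise sd (0 for exact recovery).
#' @param seed Seed for the pixel noise.
#' @return List of class `ymc_mask_stack`: `stack` (height x width x frames
#'   array), `mask`, `time`, and the rendering parameters.
#' @export
render_mask_images <- function(trace, height = 15, width = 15, mask = NULL,
                               n_nuclear = 5, k = 5, background = 10,
                               noise_sd = 0, seed = 1L) {
  stopifnot(inherits(trace, "ymc_cell_trace"))
  if (is.null(mask)) {
    cx <- (height + 1) / 2; cy <- (width + 1) / 2
    r <- min(height, width) / 2 - 0.5
    mask <- outer(seq_len(height), seq_len(width),
                  function(i, j) (i - cx)^2 + (j - cy)^2 <= r^2)
  }
  stopifnot(is.logical(mask), all(dim(mask) == c(height, width)))
  npx <- sum(mask)
  if (npx < 6) stop("mask must contain at least 6 pixels")
  if (n_nuclear < 1 || n_nuclear > npx - 1)
    stop("'n_nuclear' must leave at least one cytoplasmic pixel")
  in_idx <- which(mask)
  # nuclear pixels nearest the mask centroid, for a compact "nucleus"
  rc <- arrayInd(in_idx, dim(mask))
  cen <- colMeans(rc)
  nuc <- in_idx[order((rc[, 1] - cen[1])^2 + (rc[, 2] - cen[2])^2)][
    seq_len(n_nuclear)]
  # elevation v such that the top-k score of a noiseless frame equals s
  gain <- if (n_nuclear >= k) (npx - k) / (npx - n_nuclear) else k / n_nuclear
  set.seed(seed)
  nt <- length(trace$time)
  stack <- array(0, dim = c(height, width, nt))
  for (f in seq_len(nt)) {
    img <- matrix(0, height, width)
    img[in_idx] <- background
    img[nuc] <- background + max(trace$whi5[f], 0) * gain
    if (noise_sd > 0) img[in_idx] <- img[in_idx] +
        stats::rnorm(npx, 0, noise_sd)
    stack[, , f] <- img
  }
  structure(list(stack = stack, mask = mask, time = trace$time,
                 cell_id = trace$cell_id, n_nuclear = n_nuclear, k = k,
                 background = background),
            class = "ymc_mask_stack")
}

#' Score every frame of a mask-image stack
#'
#' @param stack A `ymc_mask_stack` (or a 3-d array with a `mask`).
#' @param mask Logical matrix; taken from the stack object if omitted.
#' @param k Top-pixel count (default 5).
#' @return Numeric vector of per-frame localization scores.
#' @export
score_mask_stack <- function(stack, mask = NULL, k = 5) {
  if (inherits(stack, "ymc_mask_stack")) {
    if (is.null(mask)) mask <- stack$mask
    stack <- stack$stack
  }
  stopifnot(length(dim(stack)) == 3, !is.null(mask))
  vapply(seq_len(dim(stack)[3]), function(f)
    whi5_localization_score(stack[, , f], mask, k), numeric(1))
}

#' Nuclear-separation event list
#'
#' Ordered mother-daughter nuclear-separation times for one cell, the
#' endpoints of its division cycles.
#'
#' @param cell_id Cell label.
#' @param separation_times Strictly increasing times, minutes.
#' @param source `"ground_truth"` or `"file"`.
#' @return Object of class `ymc_events`.
#' @export
ymc_events <- function(cell_id, separation_times,
                       source = c("ground_truth", "file")) {
  separation_times <- as.numeric(separation_times)
  if (is.unsorted(separation_times, strictly = TRUE))
    stop("'separation_times' must be strictly increasing")
  structure(list(cell_id = cell_id, separation_times = separation_times,
                 source = match.arg(source)),
            class = "ymc_events")
}

#' Division-cycle intervals from an event list
#'
#' Consecutive separation pairs define half-open intervals
#' `[sep_i, sep_(i+1))`, so every frame belongs to exactly one cycle.
#'
#' @param events A [ymc_events()] or numeric vector of separation times.
#' @return Two-column matrix (`start`, `end`); zero rows when fewer than
#'   two separations exist.
#' @export
cdc_intervals <- function(events) {
  sep <- if (inherits(events, "ymc_events")) events$separation_times
         else as.numeric(events)
  if (length(sep) < 2L)
    return(matrix(numeric(0), ncol = 2,
                  dimnames = list(NULL, c("start", "end"))))
  cbind(start = sep[-length(sep)], end = sep[-1])
}

#' Division-cycle periods
#'
#' The division time is the difference between each nuclear separation and
#' the one that follows.
#'
#' @param events A [ymc_events()] or numeric separation times.
#' @return Numeric vector of periods (empty when fewer than two events).
#' @examples
#' cdc_periods(c(100, 230, 360))
#' @export
cdc_periods <- function(events) {
  sep <- if (inherits(events, "ymc_events")) events$separation_times
         else as.numeric(events)
  if (length(sep) < 2L) return(numeric(0))
  diff(sep)
}

#' Whi5 peak time within each division cycle
#'
#' The Whi5 peak of a division cycle is the time of the global maximum of
#' the localization score within that cycle's half-open interval. Intervals
#' with a flat score (no information) are reported as `NA`.
#'
#' @param score Localization-score trace.
#' @param time Time grid, minutes.
#' @param intervals Two-column matrix from [cdc_intervals()].
#' @return Numeric vector, one peak time (or `NA`) per interval.
#' @export
whi5_peak_per_cdc <- function(score, time, intervals) {
  stopifnot(length(score) == length(time))
  if (is.null(dim(intervals)) || ncol(intervals) != 2)
    stop("'intervals' must be a two-column matrix")
  if (nrow(intervals) == 0L) return(numeric(0))
  o <- order(intervals[, 1])
  iv <- intervals[o, , drop = FALSE]
  if (any(iv[, 2] <= iv[, 1]) ||
      (nrow(iv) > 1 && any(iv[-1, 1] < iv[-nrow(iv), 2])))
    stop("division intervals must be non-overlapping with start < end")
  res <- rep(NA_real_, nrow(intervals))
  for (j in seq_len(nrow(intervals))) {
    idx <- which(time >= intervals[j, 1] & time < intervals[j, 2])
    if (length(idx) == 0L) next
    s <- score[idx]
    if (diff(range(s)) == 0) next  # flat: no peak information
    res[j] <- time[idx[which.max(s)]]
  }
  res
}

#' Read or write nuclear-separation event lists as JSON
#'
#' Events are stored as an array of objects with `cell_id` and
#' `separation_times_min`.
#'
#' @param events List of [ymc_events()] (or a named list of ground-truth
#'   lists from [ground_truth()]).
#' @param path File path.
#' @return `write_events` returns `path` invisibly; `read_events` returns a
#'   named list of `ymc_events`.
#' @export
write_events <- function(events, path) {
  recs <- lapply(events, function(ev) {
    if (inherits(ev, "ymc_events"))
      list(cell_id = ev$cell_id,
           separation_times_min = ev$separation_times)
    else
      list(cell_id = ev$cell_id %||% NA_character_,
           separation_times_min = as.numeric(ev$separation_times))
  })
  # ground_truth() lists carry ids in names, not fields
  nm <- names(events)
  if (!is.null(nm))
    for (i in seq_along(recs))
      if (is.na(recs[[i]]$cell_id) || is.null(recs[[i]]$cell_id))
        recs[[i]]$cell_id <- nm[i]
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname write_events
#' @export
read_events <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- lapply(recs, function(r)
    ymc_events(r$cell_id, as.numeric(unlist(r$separation_times_min)),
               source = "file"))
  names(out) <- vapply(recs, function(r) r$cell_id, "")
  out
}
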