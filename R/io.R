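#' Read or write a cohort as a long-format delimited table
#'
#' The on-disk schema is a tab-separated table with columns `cell_id`,
#' `time_min`, `flavin`, `whi5`, `condition` (one row per cell per frame).
#'
#' @param cohort A `ymc_cohort`.
#' @param path File path (`.tsv`).
#' @return `write_cohort` returns `path` invisibly; `read_cohort` returns a
#'   `ymc_cohort` (without ground truth).
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "ymc_cohort"))
  df <- as.data.frame(cohort)
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("cell_id", "time_min", "flavin", "whi5", "condition")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0)
    stop("cohort table is missing column(s): ",
         paste(missing, collapse = ", "))
  cohort_from_table(df)
}

#' Build a cohort from a long-format table
#'
#' @param df data.frame with columns `cell_id`, `time_min`, `flavin`,
#'   `whi5`, `condition`.
#' @return A `ymc_cohort`.
#' @export
cohort_from_table <- function(df) {
  ids <- unique(df$cell_id)
  cells <- lapply(ids, function(id) {
    sub <- df[df$cell_id == id, ]
    sub <- sub[order(sub$time_min), ]
    if (any(duplicated(sub$time_min)))
      stop("duplicated time points for cell ", id)
    dt <- stats::median(diff(sub$time_min))
    structure(list(cell_id = id, time = sub$time_min, flavin = sub$flavin,
                   whi5 = sub$whi5, condition = sub$condition[1],
                   sampling_interval = dt, ground_truth = NULL),
              class = "ymc_cell_trace")
  })
  new_ymc_cohort(cells)
}

#' Write simulated ground truth as JSON
#'
#' One record per cell with the true flavin peak, trough, separation and
#' Whi5 peak times (minutes) and the true cycles-per-division counts.
#'
#' @param cohort A simulated `ymc_cohort`.
#' @param path File path (`.json`).
#' @return `path`, invisibly. `read_ground_truth` returns the named list.
#' @export
write_ground_truth <- function(cohort, path) {
  gt <- ground_truth(cohort)
  recs <- lapply(names(gt), function(id) {
    g <- gt[[id]]
    list(cell_id = id,
         flavin_peak_times_min = g$flavin_peak_times,
         trough_times_min = g$trough_times,
         separation_times_min = g$separation_times,
         whi5_peak_times_min = g$whi5_peak_times,
         cycles_per_cdc = g$cycles_per_cdc,
         arrested = g$arrested)
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- lapply(recs, function(r) {
    list(flavin_peak_times = as.numeric(unlist(r$flavin_peak_times_min)),
         trough_times = as.numeric(unlist(r$trough_times_min)),
         separation_times = as.numeric(unlist(r$separation_times_min)),
         whi5_peak_times = as.numeric(unlist(r$whi5_peak_times_min)),
         cycles_per_cdc = as.integer(unlist(r$cycles_per_cdc)),
         arrested = isTRUE(r$arrested))
  })
  names(out) <- vapply(recs, function(r) r$cell_id, "")
  out
}

#' Write detected extrema as JSON event lists
#'
#' @param fit A `ymc_coupling` fit.
#' @param path File path (`.json`).
#' @return `path`, invisibly.
#' @export
write_extrema <- function(fit, path) {
  stopifnot(inherits(fit, "ymc_coupling"))
  recs <- lapply(names(fit$cells), function(id) {
    pt <- fit$cells[[id]]$processed
    list(cell_id = id, excluded = pt$excluded,
         peak_times_min = pt$peak_times,
         trough_times_min = pt$trough_times)
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write or read a rendered mask-image stack as multi-page TIFF
#'
#' Intensities are stored as 16-bit TIFF scaled by `max_intensity`; the
#' mask is written alongside as a single-page TIFF of 0/1 values.
#'
#' @param stack A `ymc_mask_stack` from [render_mask_images()].
#' @param path Stack file path (`.tif`).
#' @param mask_path Optional mask file path.
#' @param max_intensity Intensity mapped to full scale.
#' @return `path`, invisibly. `read_mask_stack` returns a list with
#'   `stack` (array) and `mask` (logical matrix or `NULL`).
#' @export
write_mask_stack <- function(stack, path, mask_path = NULL,
                             max_intensity = NULL) {
  stopifnot(inherits(stack, "ymc_mask_stack"))
  arr <- stack$stack
  if (is.null(max_intensity)) max_intensity <- max(arr, 1e-12)
  pages <- lapply(seq_len(dim(arr)[3]), function(f)
    pmin(pmax(arr[, , f] / max_intensity, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  if (!is.null(mask_path))
    tiff::writeTIFF(matrix(as.numeric(stack$mask), nrow(stack$mask)),
                    mask_path, bits.per.sample = 8)
  attr(path, "max_intensity") <- max_intensity
  invisible(path)
}

#' @rdname write_mask_stack
#' @param max_intensity Scale used at write time.
#' @export
read_mask_stack <- function(path, mask_path = NULL, max_intensity = 1) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (f in seq_along(pages)) arr[, , f] <- pages[[f]] * max_intensity
  mask <- NULL
  if (!is.null(mask_path))
    mask <- tiff::readTIFF(mask_path) > 0.5
  list(stack = arr, mask = mask)
}
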