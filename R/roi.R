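#' @importFrom EBImage bwlabel otsu Image
NULL

# label a binary matrix into 4-connected components, drop components smaller
# than min_size, and relabel in raster order of the component centroids
# (top-to-bottom, then left-to-right)
label_components <- function(mask, min_size = 1L) {
  lab <- EBImage::bwlabel(mask * 1)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  if (max(lab) == 0L) return(lab)
  sizes <- tabulate(lab, nbins = max(lab))
  keep <- which(sizes >= min_size)
  if (length(keep) == 0L) return(matrix(0L, nrow(mask), ncol(mask)))
  cent <- t(vapply(keep, function(l) {
    idx <- which(lab == l, arr.ind = TRUE)
    colMeans(idx)
  }, numeric(2)))
  ord <- order(cent[, 1], cent[, 2])
  out <- matrix(0L, nrow(mask), ncol(mask))
  for (new in seq_along(ord)) out[lab == keep[ord[new]]] <- new
  out
}

#' Region of interest
#'
#' A spatially connected set of active pixels with its centroid. Pixel
#' coordinates are 1-based `(row, col)` with origin at the top-left.
#'
#' @param roi_id Identifier (assigned in raster order of centroids).
#' @param pixel_set Two-column integer matrix of `(row, col)` coordinates.
#' @param centroid Numeric `(row, col)` mean of the pixel set.
#' @return Object of class `roi`.
#' @export
roi <- function(roi_id, pixel_set, centroid = colMeans(pixel_set)) {
  stopifnot(is.matrix(pixel_set), ncol(pixel_set) == 2L,
            nrow(pixel_set) >= 1L)
  structure(list(roi_id = roi_id, pixel_set = pixel_set,
                 centroid = as.numeric(centroid)),
            class = "roi")
}

#' Detect active regions of interest in an image sequence
#'
#' A pixel is classified active when its temporally smoothed intensity
#' exceeds its own baseline mean by more than `z(1 - alpha)` baseline
#' standard deviations at any frame from the control addition onward.
#' Baseline statistics are estimated per pixel from the unsmoothed frames
#' acquired before `control_time` (the no-drug reference window). Active
#' pixels are grouped into 4-connected components; components smaller than
#' `min_size` are discarded and ROI ids are assigned in raster order of the
#' component centroids.
#'
#' @param stack A [time_series_stack()].
#' @param alpha One-sided significance level, default 0.01 (detection above
#'   statistical noise at p < 0.01).
#' @param min_size Minimum component size in pixels (default 9).
#' @param smooth_window Odd temporal moving-average window (default 3).
#' @param min_baseline_frames Minimum number of pre-control frames required
#'   (default 10).
#'
#' @return List of [roi()] objects (possibly empty), with the active-pixel
#'   label matrix attached as attribute `"label_mask"`.
#' @export
detect_rois <- function(stack, alpha = 0.01, min_size = 9L,
                        smooth_window = 3L, min_baseline_frames = 10L) {
  stopifnot(inherits(stack, "time_series_stack"))
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  fr <- stack$frames
  n <- dim(fr)[1]
  tt <- frame_times(n, stack$frame_interval)
  base <- which(tt < stack$protocol$control_time)
  if (length(base) < min_baseline_frames)
    stop("pre-control window has fewer than ", min_baseline_frames,
         " frames")
  post <- which(tt >= stack$protocol$control_time)

  mu <- apply(fr[base, , , drop = FALSE], c(2, 3), mean)
  sdv <- apply(fr[base, , , drop = FALSE], c(2, 3), stats::sd)
  z <- stats::qnorm(1 - alpha)

  # temporal smoothing along the first dimension
  sm <- apply(fr, c(2, 3), moving_average, window = smooth_window)
  active <- matrix(FALSE, dim(fr)[2], dim(fr)[3])
  for (f in post) {
    active <- active | (sm[f, , ] > mu + z * sdv)
  }
  lab <- label_components(active, min_size = min_size)
  rois <- lapply(seq_len(max(lab, 0L)), function(l) {
    px <- which(lab == l, arr.ind = TRUE)
    colnames(px) <- c("row", "col")
    roi(roi_id = l, pixel_set = px)
  })
  attr(rois, "label_mask") <- lab
  rois
}

#' Per-pixel-frame active flags on a stack (detection calibration)
#'
#' Returns the logical array of per-pixel, per-post-control-frame threshold
#' exceedances underlying [detect_rois()], for false-positive calibration on
#' pure-noise stacks.
#'
#' @inheritParams detect_rois
#' @return Logical array (post-control frames x height x width).
#' @export
active_pixel_flags <- function(stack, alpha = 0.01, smooth_window = 3L) {
  stopifnot(inherits(stack, "time_series_stack"))
  fr <- stack$frames
  tt <- frame_times(dim(fr)[1], stack$frame_interval)
  base <- which(tt < stack$protocol$control_time)
  post <- which(tt >= stack$protocol$control_time)
  mu <- apply(fr[base, , , drop = FALSE], c(2, 3), mean)
  sdv <- apply(fr[base, , , drop = FALSE], c(2, 3), stats::sd)
  z <- stats::qnorm(1 - alpha)
  sm <- apply(fr, c(2, 3), moving_average, window = smooth_window)
  out <- array(FALSE, dim = c(length(post), dim(fr)[2], dim(fr)[3]))
  for (i in seq_along(post)) {
    out[i, , ] <- sm[post[i], , ] > mu + z * sdv
  }
  out
}

#' Extract the mean-intensity trace of an ROI
#'
#' Per-frame mean of the raw intensity over the ROI's pixel set. The result
#' is a plain numeric vector; [normalize_trace()] turns it into an F/F0
#' trace.
#'
#' @param stack A [time_series_stack()].
#' @param roi A [roi()] whose pixels lie inside the image bounds.
#' @return Numeric vector of length equal to the frame count.
#' @export
extract_trace <- function(stack, roi) {
  stopifnot(inherits(stack, "time_series_stack"), inherits(roi, "roi"))
  d <- dim(stack$frames)
  px <- roi$pixel_set
  if (any(px[, 1] < 1L | px[, 1] > d[2] | px[, 2] < 1L | px[, 2] > d[3]))
    stop("ROI pixel outside image bounds")
  n <- d[1]
  # linear indices of the ROI pixels within one frame slice
  lin <- (px[, 2] - 1L) * d[2] + px[, 1]
  vapply(seq_len(n), function(f) {
    frame <- stack$frames[f, , ]
    mean(frame[lin])
  }, numeric(1))
}

#' Count the total number of cells in a reference frame
#'
#' Segments a dye-loaded reference frame by a global Otsu threshold followed
#' by 4-connected component labeling with the same minimum-size filter used
#' for ROI detection. The count is the denominator of the responding
#' fraction.
#'
#' @param reference_frame 2D numeric intensity matrix.
#' @param min_size Minimum object size in pixels (default 9).
#' @return Integer cell count; 0 with a warning for a blank (constant)
#'   frame.
#' @export
count_total_cells <- function(reference_frame, min_size = 9L) {
  stopifnot(is.matrix(reference_frame), length(reference_frame) > 0L)
  rng <- range(reference_frame)
  if (diff(rng) == 0) {
    warning("blank reference frame: returning 0 cells")
    return(0L)
  }
  sc <- (reference_frame - rng[1]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(sc))
  lab <- label_components(sc > th, min_size = min_size)
  max(lab, 0L)
}
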