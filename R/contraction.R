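#' Segment cells in a calcein image
#'
#' Global Otsu threshold on the intensity histogram, 4-connected component
#' labeling, removal of components smaller than `min_size` or touching the
#' image border (their area is censored by the field of view), and raster
#' relabeling.
#'
#' @param frame 2D numeric intensity matrix.
#' @param min_size Minimum object size in pixels (default 9).
#' @param exclude_border Drop border-touching objects (default TRUE).
#' @return Integer label matrix (0 = background); an empty labeling with a
#'   warning for a blank frame.
#' @export
segment_cells <- function(frame, min_size = 9L, exclude_border = TRUE) {
  stopifnot(is.matrix(frame), length(frame) > 0L)
  rng <- range(frame)
  if (diff(rng) == 0) {
    warning("blank frame: empty labeling")
    return(matrix(0L, nrow(frame), ncol(frame)))
  }
  sc <- (frame - rng[1]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(sc))
  mask <- sc > th
  if (exclude_border) {
    lab0 <- EBImage::bwlabel(mask * 1)
    lab0 <- matrix(as.integer(lab0), nrow(mask), ncol(mask))
    border_labels <- unique(c(lab0[1, ], lab0[nrow(lab0), ],
                              lab0[, 1], lab0[, ncol(lab0)]))
    border_labels <- border_labels[border_labels > 0L]
    mask[lab0 %in% border_labels] <- FALSE
  }
  label_components(mask, min_size = min_size)
}

# per-label pixel counts and centroids of a label matrix
mask_objects <- function(lab) {
  nmax <- max(lab, 0L)
  if (nmax == 0L)
    return(data.frame(label = integer(0), area = integer(0),
                      row = numeric(0), col = numeric(0)))
  areas <- tabulate(lab, nbins = nmax)
  idx <- which(lab > 0L, arr.ind = TRUE)
  l <- lab[lab > 0L]
  data.frame(label = seq_len(nmax), area = areas,
             row = as.numeric(tapply(idx[, 1], l, mean)),
             col = as.numeric(tapply(idx[, 2], l, mean)))
}

# link objects of lab_from to lab_to: maximal pixel overlap first, ties by
# nearest centroid then smaller target label; leftover objects fall back to
# nearest-centroid matching (flagged via attribute "centroid_fallback")
link_masks <- function(lab_from, lab_to) {
  from <- mask_objects(lab_from)
  to <- mask_objects(lab_to)
  link <- rep(NA_integer_, nrow(from))
  if (nrow(from) == 0L || nrow(to) == 0L) {
    attr(link, "centroid_fallback") <- integer(0)
    return(link)
  }
  both <- lab_from > 0L & lab_to > 0L
  ov <- matrix(0L, nrow(from), nrow(to))
  if (any(both)) {
    tab <- table(factor(lab_from[both], levels = from$label),
                 factor(lab_to[both], levels = to$label))
    ov <- matrix(as.integer(tab), nrow(from), nrow(to))
  }
  cd <- as.matrix(stats::dist(rbind(from[, c("row", "col")],
                                    to[, c("row", "col")])))
  cd <- cd[seq_len(nrow(from)), nrow(from) + seq_len(nrow(to)), drop = FALSE]

  taken <- rep(FALSE, nrow(to))
  # candidate links ranked: overlap desc, centroid distance asc, label asc
  cand <- expand.grid(i = seq_len(nrow(from)), j = seq_len(nrow(to)))
  cand$ov <- ov[cbind(cand$i, cand$j)]
  cand$cd <- cd[cbind(cand$i, cand$j)]
  cand <- cand[order(-cand$ov, cand$cd, cand$j), ]
  fallback <- integer(0)
  for (r in seq_len(nrow(cand))) {
    i <- cand$i[r]; j <- cand$j[r]
    if (!is.na(link[i]) || taken[j]) next
    if (cand$ov[r] == 0L) {
      # no pixel overlap left anywhere for this object: centroid fallback
      fallback <- c(fallback, i)
    }
    link[i] <- j
    taken[j] <- TRUE
  }
  attr(link, "centroid_fallback") <- fallback
  link
}

#' Track cells across the three assay states
#'
#' Links segmented objects from the pre-stimulus to the post-control to the
#' post-drug labeling by maximal pixel overlap (ties broken by nearest
#' centroid, then smaller label; objects without any overlap fall back to
#' nearest-centroid linking). Objects missing from any state form
#' incomplete tracks, which are excluded from contraction measures.
#'
#' @param masks List of 3 integer label matrices (pre-stimulus,
#'   post-control, post-drug) sharing one image shape.
#' @return `data.frame` with one row per track: `track_id`, areas `s1`,
#'   `s2`, `s3` (pixels, `NA` where absent), state centroids and logical
#'   `complete`. The number of centroid-fallback links is attached as
#'   attribute `"n_centroid_fallback"`.
#' @export
track_cells <- function(masks) {
  stopifnot(length(masks) == 3L)
  if (!all(vapply(masks, function(m) identical(dim(m), dim(masks[[1]])),
                  TRUE)))
    stop("masks must share one image shape")
  o1 <- mask_objects(masks[[1]])
  o2 <- mask_objects(masks[[2]])
  o3 <- mask_objects(masks[[3]])
  l12 <- link_masks(masks[[1]], masks[[2]])
  l23 <- link_masks(masks[[2]], masks[[3]])
  n_fallback <- length(attr(l12, "centroid_fallback")) +
    length(attr(l23, "centroid_fallback"))

  tracks <- data.frame(track_id = integer(0), s1 = numeric(0),
                       s2 = numeric(0), s3 = numeric(0),
                       row1 = numeric(0), col1 = numeric(0),
                       complete = logical(0))
  tid <- 0L
  used2 <- rep(FALSE, nrow(o2))
  for (i in seq_len(nrow(o1))) {
    tid <- tid + 1L
    j <- l12[i]
    k <- if (!is.na(j)) l23[j] else NA_integer_
    if (!is.na(j)) used2[j] <- TRUE
    tracks[tid, ] <- list(tid, o1$area[i],
                          if (!is.na(j)) o2$area[j] else NA_real_,
                          if (!is.na(k)) o3$area[k] else NA_real_,
                          o1$row[i], o1$col[i],
                          !is.na(j) && !is.na(k))
  }
  # state-2 objects never linked from state 1 still open (incomplete) tracks
  for (j in which(!used2)) {
    tid <- tid + 1L
    k <- l23[j]
    tracks[tid, ] <- list(tid, NA_real_, o2$area[j],
                          if (!is.na(k)) o3$area[k] else NA_real_,
                          o2$row[j], o2$col[j], FALSE)
  }
  attr(tracks, "n_centroid_fallback") <- n_fallback
  tracks
}

#' Per-cell contraction from a complete track
#'
#' Relative cell-surface-area change between consecutive states:
#' `delta_control = (S1 - S2) / S1` (response to the medium-only control)
#' and `delta_drug = (S2 - S3) / S2` (response to the vasoconstrictor).
#' Positive values are contraction; negative values (area increase) are
#' permitted.
#'
#' @param track One row of the [track_cells()] table (or any list with
#'   `track_id`, `s1`, `s2`, `s3`, `complete`).
#' @return List with `track_id`, `delta_control`, `delta_drug`.
#' @export
compute_contraction <- function(track) {
  if (!isTRUE(track$complete) || is.na(track$s1) || is.na(track$s2) ||
      is.na(track$s3))
    stop("track must be complete (present in all three states)")
  if (track$s1 <= 0 || track$s2 <= 0)
    stop("S1 and S2 must be positive")
  list(track_id = track$track_id,
       delta_control = (track$s1 - track$s2) / track$s1,
       delta_drug = (track$s2 - track$s3) / track$s2)
}

#' Population-level contraction analysis
#'
#' Collects the control and drug relative-area-change distributions from
#' complete tracks, summarizes them (quartiles, 10th/90th percentiles) and
#' compares them with a two-sided Mann-Whitney rank test.
#'
#' @param tracks The [track_cells()] table (only complete tracks are used),
#'   or a `data.frame` of precomputed `delta_control` / `delta_drug`.
#' @param n_bins Bins for the shared-bin histograms (default 30).
#' @return List with `delta_control`, `delta_drug` (sample vectors),
#'   `summary_control`, `summary_drug`, `p_value`, `histograms` and the
#'   number of measures `n`.
#' @export
contraction_population <- function(tracks, n_bins = 30L) {
  if (all(c("delta_control", "delta_drug") %in% names(tracks))) {
    dc <- tracks$delta_control
    dd <- tracks$delta_drug
  } else {
    complete <- tracks[tracks$complete, , drop = FALSE]
    if (nrow(complete) < 2L)
      stop("need at least 2 complete tracks")
    meas <- lapply(seq_len(nrow(complete)),
                   function(i) compute_contraction(complete[i, ]))
    dc <- vapply(meas, `[[`, 0, "delta_control")
    dd <- vapply(meas, `[[`, 0, "delta_drug")
  }
  if (length(dc) < 2L) stop("need at least 2 measures")
  p <- stats::wilcox.test(dc, dd, alternative = "two.sided",
                          exact = FALSE)$p.value
  list(delta_control = dc, delta_drug = dd,
       summary_control = summarize_distribution(dc),
       summary_drug = summarize_distribution(dd),
       p_value = p,
       histograms = build_histogram_pair(dc, dd, n_bins = n_bins),
       n = length(dc))
}
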