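#' Render a synthetic calcium-imaging stack from traces
#'
#' Places one circular cell footprint per trace on a dark background and
#' lets the pixel intensities inside each footprint follow the trace,
#' scaled to a 16-bit camera range, with additive Gaussian read noise and
#' integer quantization. Footprints must fit inside the image and may not
#' overlap. The true label mask is returned for detection-recall tests.
#'
#' @param traces List of [fluorescence_trace()] of equal length and frame
#'   interval (typically from [generate_population()]).
#' @param layout `data.frame` with one row per trace: `row`, `col` (center,
#'   1-based pixel coordinates) and `radius` (pixels).
#' @param image_shape `c(height, width)` in pixels.
#' @param seed Optional integer seed for the camera noise.
#' @param protocol A [stimulus_protocol()] recorded into the stack.
#' @param gain Camera counts per unit F/F0 inside a footprint (default 1000,
#'   so resting cells sit at 1000 counts).
#' @param background Mean background level in counts (default 100).
#' @param read_noise_sd Gaussian read noise SD in counts (default 20).
#' @param n_frames,frame_interval Recording geometry used when `traces` is
#'   empty (a pure-noise stack for false-positive calibration); ignored
#'   otherwise.
#'
#' @return List with `stack` (a [time_series_stack()]) and `masks`
#'   (integer label matrix, 0 = background, i = footprint of trace i).
#' @export
generate_calcium_stack <- function(traces, layout, image_shape, seed = NULL,
                                   protocol = stimulus_protocol(60, 120),
                                   gain = 1000, background = 100,
                                   read_noise_sd = 20, n_frames = 241L,
                                   frame_interval = 1) {
  n_cells <- length(traces)
  if (n_cells > 0) {
    stopifnot(is.data.frame(layout),
              all(c("row", "col", "radius") %in% names(layout)),
              nrow(layout) == n_cells)
    r <- layout$radius
    if (any(layout$row - r < 1 | layout$row + r > image_shape[1] |
            layout$col - r < 1 | layout$col + r > image_shape[2]))
      stop("cell footprints must fit inside the image")
    if (n_cells > 1) {
      d <- as.matrix(stats::dist(layout[, c("row", "col")]))
      sep <- outer(r, r, "+")
      diag(d) <- Inf
      if (any(d <= sep))
        stop("cell footprints may not overlap")
    }
    n_frames <- length(traces[[1]]$raw)
    fi <- traces[[1]]$frame_interval
    if (!all(vapply(traces, function(x) length(x$raw) == n_frames, TRUE)))
      stop("all traces must have equal length")
  } else {
    n_frames <- as.integer(n_frames)
    fi <- frame_interval
  }
  h <- image_shape[1]; w <- image_shape[2]
  masks <- matrix(0L, h, w)
  if (n_cells > 0) {
    rows <- matrix(seq_len(h), h, w)
    cols <- matrix(seq_len(w), h, w, byrow = TRUE)
    for (i in seq_len(n_cells)) {
      inside <- (rows - layout$row[i])^2 + (cols - layout$col[i])^2 <=
        layout$radius[i]^2
      masks[inside] <- i
    }
  }
  frames <- with_seed_if(seed, {
    arr <- array(stats::rnorm(n_frames * h * w, background, read_noise_sd),
                 dim = c(n_frames, h, w))
    for (i in seq_len(n_cells)) {
      idx <- which(masks == i)             # column-major positions in a frame
      sig <- traces[[i]]$normalized * gain
      for (f in seq_len(n_frames)) {
        frame <- arr[f, , ]
        frame[idx] <- frame[idx] + sig[f]
        arr[f, , ] <- frame
      }
    }
    arr
  })
  frames <- round(pmin(pmax(frames, 0), 65535))
  list(stack = time_series_stack(frames, fi, protocol), masks = masks)
}

# pixel-center rasterization of an axis-aligned ellipse
rasterize_ellipse <- function(h, w, row0, col0, a_row, b_col) {
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  ((rows - row0) / a_row)^2 + ((cols - col0) / b_col)^2 <= 1
}

#' Ground truth for one synthetic contracting cell
#'
#' @param cell_id Identifier.
#' @param areas Numeric vector `c(S1, S2, S3)`: prescribed surface area in
#'   pixels at the pre-stimulus, post-control and post-drug states.
#' @return Object of class `contraction_ground_truth` carrying the areas and
#'   the implied relative area changes `true_delta_control = (S1 - S2)/S1`
#'   and `true_delta_drug = (S2 - S3)/S2`.
#' @export
contraction_ground_truth <- function(cell_id, areas) {
  stopifnot(length(areas) == 3L)
  if (any(areas <= 0)) stop("all three state areas must be positive")
  structure(list(cell_id = cell_id,
                 true_areas = as.numeric(areas),
                 true_delta_control = (areas[1] - areas[2]) / areas[1],
                 true_delta_drug = (areas[2] - areas[3]) / areas[2]),
            class = "contraction_ground_truth")
}

#' Render a three-state contraction image sequence
#'
#' Renders calcein-like bright ellipses on a dark background in each of the
#' three assay states (pre-stimulus, post-control, post-drug), with each
#' ellipse scaled so its area matches the prescribed S1/S2/S3, and the
#' centroid optionally jittered between states to exercise tracking. Cells
#' are laid out on a regular grid; the generation is rejected if any ellipse
#' would touch its neighbor or the image border.
#'
#' @param ground_truths List of [contraction_ground_truth()].
#' @param image_shape `c(height, width)` pixels; enlarged automatically if
#'   `NULL` to fit the grid.
#' @param seed Optional integer seed (jitter and noise).
#' @param jitter SD in pixels of the Gaussian centroid displacement between
#'   states (default 0).
#' @param aspect Ratio of the ellipse row semi-axis to the column semi-axis.
#' @param fg,bg Foreground / background mean intensity in counts.
#' @param noise_sd Gaussian noise SD in counts.
#'
#' @return List with `frames` (list of 3 matrices), `masks` (list of 3
#'   integer label matrices; label i = cell i) and `ground_truth` (the input
#'   list).
#' @export
generate_contraction_sequence <- function(ground_truths, image_shape = NULL,
                                          seed = NULL, jitter = 0,
                                          aspect = 1.4, fg = 30000, bg = 500,
                                          noise_sd = 50) {
  n <- length(ground_truths)
  stopifnot(n >= 1)
  smax <- vapply(ground_truths, function(g) max(g$true_areas), 0)
  # grid spacing from the largest footprint plus a safety margin
  a_max <- sqrt(max(smax) * aspect / pi)
  cellpitch <- ceiling(2 * a_max + 8 + 6 * jitter)
  ncol_grid <- ceiling(sqrt(n))
  nrow_grid <- ceiling(n / ncol_grid)
  need <- c(nrow_grid, ncol_grid) * cellpitch + cellpitch %/% 2
  if (is.null(image_shape)) image_shape <- need
  if (any(image_shape < need))
    stop("image_shape too small for the requested layout: cells would touch")
  h <- image_shape[1]; w <- image_shape[2]
  centers <- cbind(
    row = cellpitch * ((seq_len(n) - 1) %/% ncol_grid) + cellpitch / 2 + 4,
    col = cellpitch * ((seq_len(n) - 1) %% ncol_grid) + cellpitch / 2 + 4)

  with_seed_if(seed, {
    frames <- vector("list", 3L)
    masks <- vector("list", 3L)
    for (state in 1:3) {
      lab <- matrix(0L, h, w)
      for (i in seq_len(n)) {
        s <- ground_truths[[i]]$true_areas[state]
        a <- sqrt(s * aspect / pi)   # row semi-axis
        b <- s / (pi * a)            # col semi-axis
        dr <- if (jitter > 0) stats::rnorm(1, 0, jitter) else 0
        dc <- if (jitter > 0) stats::rnorm(1, 0, jitter) else 0
        e <- rasterize_ellipse(h, w, centers[i, "row"] + dr,
                               centers[i, "col"] + dc, a, b)
        if (any(lab[e] != 0L))
          stop("ellipses may not touch")
        lab[e] <- i
      }
      img <- matrix(bg, h, w)
      img[lab > 0L] <- fg
      if (noise_sd > 0)
        img <- img + matrix(stats::rnorm(h * w, 0, noise_sd), h, w)
      frames[[state]] <- pmin(pmax(img, 0), 65535)
      masks[[state]] <- lab
    }
    list(frames = frames, masks = masks, ground_truth = ground_truths)
  })
}
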