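#' Per-ROI fluorescence trace with F/F0 normalization
#'
#' Holds one region of interest's raw intensity time series together with
#' its baseline intensity F0 and the normalized F/F0 trace. The baseline
#' window (the frames used to estimate F0 and the noise level) is stored as
#' an index vector.
#'
#' @param raw Numeric vector of per-frame raw intensity.
#' @param f0 Baseline intensity (> 0).
#' @param frame_interval Seconds per frame.
#' @param roi_id Identifier.
#' @param baseline_frames Integer indices of the frames forming the baseline
#'   window.
#'
#' @return Object of class `fluorescence_trace` with elements `roi_id`,
#'   `raw`, `f0`, `normalized` (= `raw / f0`), `frame_interval`,
#'   `baseline_frames`.
#' @export
fluorescence_trace <- function(raw, f0, frame_interval = 1, roi_id = NA,
                               baseline_frames = seq_along(raw)) {
  stopifnot(is.numeric(raw), length(raw) >= 2L)
  if (!is.numeric(f0) || length(f0) != 1L || f0 <= 0)
    stop("f0 must be a positive scalar")
  if (frame_interval <= 0) stop("frame_interval must be positive")
  baseline_frames <- as.integer(baseline_frames)
  if (length(baseline_frames) < 1L ||
      any(baseline_frames < 1L | baseline_frames > length(raw)))
    stop("baseline_frames out of range")
  structure(list(roi_id = roi_id, raw = as.numeric(raw), f0 = f0,
                 normalized = as.numeric(raw) / f0,
                 frame_interval = frame_interval,
                 baseline_frames = baseline_frames),
            class = "fluorescence_trace")
}

#' @export
print.fluorescence_trace <- function(x, ...) {
  cat(sprintf(
    "fluorescence_trace (roi %s): %d frames, dt = %g s, F0 = %g\n",
    as.character(x$roi_id), length(x$raw), x$frame_interval, x$f0))
  invisible(x)
}

#' Normalize a raw trace to F/F0
#'
#' F0 is the mean raw intensity over the baseline window, i.e. all frames
#' acquired strictly before the control (medium-only) addition. The
#' normalized trace F/F0 then has resting level 1 by construction and is
#' invariant to uniform intensity rescaling.
#'
#' @param raw_trace Numeric vector of per-frame raw intensity.
#' @param protocol A [stimulus_protocol()].
#' @param frame_interval Seconds per frame.
#' @param roi_id Identifier carried through to the result.
#' @param min_baseline_frames Minimum number of baseline frames required
#'   (default 5).
#'
#' @return A [fluorescence_trace()].
#' @export
normalize_trace <- function(raw_trace, protocol, frame_interval = 1,
                            roi_id = NA, min_baseline_frames = 5L) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  tt <- frame_times(length(raw_trace), frame_interval)
  base <- which(tt < protocol$control_time)
  if (length(base) < min_baseline_frames)
    stop("baseline window before control_time has fewer than ",
         min_baseline_frames, " frames")
  f0 <- mean(raw_trace[base])
  if (!is.finite(f0) || f0 <= 0)
    stop("baseline mean F0 must be positive")
  fluorescence_trace(raw = raw_trace, f0 = f0,
                     frame_interval = frame_interval, roi_id = roi_id,
                     baseline_frames = base)
}
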