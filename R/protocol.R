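#' Stimulus protocol for a recording
#'
#' Describes the timing of the two additions performed during a recording:
#' a negative control (medium only, no drug) followed by the vasoconstrictor.
#' The main-peak window is the interval after drug addition within which the
#' first calcium release of a region of interest (ROI) counts as its main
#' peak (MP).
#'
#' @param control_time Time of the control (medium-only) addition, in seconds
#'   from the start of the recording. Frames before this time form the
#'   baseline window used for F0 estimation and noise statistics.
#' @param drug_time Time of vasoconstrictor addition, in seconds. Must be
#'   strictly after `control_time`.
#' @param mp_window Length of the main-peak window after `drug_time`, in
#'   seconds (default 100).
#'
#' @return An object of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(control_time, drug_time, mp_window = 100) {
  stopifnot(is.numeric(control_time), is.numeric(drug_time),
            is.numeric(mp_window), length(control_time) == 1L,
            length(drug_time) == 1L, length(mp_window) == 1L)
  if (control_time < 0)
    stop("control_time must be >= 0")
  if (drug_time <= control_time)
    stop("drug_time must be strictly after control_time")
  if (mp_window <= 0)
    stop("mp_window must be positive")
  structure(list(control_time = control_time, drug_time = drug_time,
                 mp_window = mp_window),
            class = "stimulus_protocol")
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat(sprintf("stimulus protocol: control at %g s, drug at %g s, MP window %g s\n",
              x$control_time, x$drug_time, x$mp_window))
  invisible(x)
}

#' Time-series image stack
#'
#' Container for a recorded (or synthesized) fluorescence image sequence:
#' a time x height x width intensity array, the frame interval, and the
#' stimulus protocol. Frames are indexed from 1; frame `i` is acquired at
#' time `(i - 1) * frame_interval` seconds.
#'
#' @param frames 3D numeric array, dimensions time x height x width, all
#'   values finite and non-negative, at least 2 frames.
#' @param frame_interval Time between consecutive frames, seconds (> 0).
#' @param protocol A [stimulus_protocol()]; the protocol must end before the
#'   recording does.
#'
#' @return An object of class `time_series_stack` with elements `frames`,
#'   `frame_interval`, `protocol`.
#' @export
time_series_stack <- function(frames, frame_interval, protocol) {
  stopifnot(is.array(frames), length(dim(frames)) == 3L)
  if (dim(frames)[1] < 2L)
    stop("stack must contain at least 2 frames")
  if (!is.numeric(frame_interval) || length(frame_interval) != 1L ||
      frame_interval <= 0)
    stop("frame_interval must be a positive scalar")
  if (!all(is.finite(frames)) || any(frames < 0))
    stop("all intensities must be finite and >= 0")
  if (!inherits(protocol, "stimulus_protocol"))
    stop("protocol must be a stimulus_protocol")
  t_end <- (dim(frames)[1] - 1L) * frame_interval
  if (protocol$drug_time >= t_end)
    stop("drug_time must fall before the end of the recording")
  structure(list(frames = frames, frame_interval = frame_interval,
                 protocol = protocol),
            class = "time_series_stack")
}

#' @export
print.time_series_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("time_series_stack: %d frames of %d x %d px, dt = %g s\n",
              d[1], d[2], d[3], x$frame_interval))
  print(x$protocol)
  invisible(x)
}

#' Frame acquisition times of a stack or trace
#' @param n_frames Number of frames.
#' @param frame_interval Frame interval in seconds.
#' @return Numeric vector of times, starting at 0.
#' @keywords internal
frame_times <- function(n_frames, frame_interval) {
  (seq_len(n_frames) - 1) * frame_interval
}

# centered moving average with shrinking window at the edges; window must be
# odd so the smoothed sample stays aligned with its frame
moving_average <- function(x, window = 3L) {
  window <- as.integer(window)
  stopifnot(window >= 1L, window %% 2L == 1L)
  if (window == 1L) return(x)
  n <- length(x)
  half <- window %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# run set.seed only when the caller supplied one, restoring RNG state after
with_seed_if <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}
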