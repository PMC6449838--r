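#' Ground truth for one synthetic fluorescence trace
#'
#' Describes the calcium release events of one region of interest on the
#' normalized F/F0 scale, before sampling and noise. Each event is a
#' transient pulse with a known onset, peak time, peak amplitude, and
#' half-maximum duration, from which the half-max-referenced kinetic
#' parameters follow analytically.
#'
#' @param roi_id Identifier for the ROI.
#' @param events `data.frame` with columns `onset_time`, `peak_time`
#'   (seconds), `peak_amplitude` (F/F0 units, > baseline) and
#'   `half_max_duration` (seconds, full width at half maximum). May have
#'   zero rows. Events must be sorted by onset and each peak must follow its
#'   onset.
#' @param baseline_level Resting F/F0 level, normally 1.0.
#' @param noise_sd Standard deviation of additive Gaussian noise, F/F0 units.
#'
#' @return Object of class `trace_ground_truth`.
#' @export
trace_ground_truth <- function(roi_id, events, baseline_level = 1.0,
                               noise_sd = 0) {
  if (missing(events) || is.null(events))
    events <- data.frame(onset_time = numeric(0), peak_time = numeric(0),
                         peak_amplitude = numeric(0),
                         half_max_duration = numeric(0))
  need <- c("onset_time", "peak_time", "peak_amplitude", "half_max_duration")
  if (!all(need %in% names(events)))
    stop("events must have columns ", paste(need, collapse = ", "))
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (baseline_level <= 0) stop("baseline_level must be positive")
  if (nrow(events) > 0) {
    if (any(events$peak_time <= events$onset_time))
      stop("every event must peak strictly after its onset")
    if (is.unsorted(events$onset_time))
      stop("events must be sorted by onset_time")
    if (any(events$peak_amplitude <= baseline_level))
      stop("peak_amplitude must exceed baseline_level")
    if (any(events$half_max_duration <= 0))
      stop("half_max_duration must be positive")
  }
  structure(list(roi_id = roi_id, events = events,
                 baseline_level = baseline_level, noise_sd = noise_sd),
            class = "trace_ground_truth")
}

# evaluate one pulse (excess over baseline) at times t.
# shape "linear_exp": linear rise onset->peak, exponential fall whose
#   half-life equals the half-max decay time, so that
#   time_to_peak = rise/2, decay = half_max_duration - rise/2.
# shape "triangular": linear rise and linear fall with
#   fall = 2*half_max_duration - rise, so the width at half maximum equals
#   half_max_duration by similar triangles.
pulse_value <- function(t, onset, peak_t, amplitude_excess, fwhm, shape) {
  rise <- peak_t - onset
  v <- numeric(length(t))
  up <- t >= onset & t <= peak_t
  v[up] <- amplitude_excess * (t[up] - onset) / rise
  dn <- t > peak_t
  if (shape == "triangular") {
    fall <- 2 * fwhm - rise
    if (fall <= 0)
      stop("triangular pulse needs half_max_duration > rise/2 + something: ",
           "fall duration is non-positive")
    v[dn] <- amplitude_excess * pmax(0, 1 - (t[dn] - peak_t) / fall)
  } else {
    half_life <- fwhm - rise / 2
    if (half_life <= 0)
      stop("exponential fall needs half_max_duration > rise/2")
    v[dn] <- amplitude_excess * 2 ^ (-(t[dn] - peak_t) / half_life)
  }
  v
}

#' Sample a synthetic fluorescence trace from its ground truth
#'
#' Renders the ground-truth events as transient pulses on a flat baseline,
#' samples at the frame interval, and adds Gaussian noise. The default pulse
#' family is a linear rise to the peak followed by an exponential fall whose
#' half-life equals the half-max decay time; with this family time to peak,
#' decay and duration at the half-maximum level are known in closed form.
#'
#' @param ground_truth A [trace_ground_truth()].
#' @param duration Recording length in seconds; must cover all event peaks.
#' @param frame_interval Sampling interval in seconds (> 0).
#' @param seed Optional integer seed (noise reproducibility).
#' @param shape `"linear_exp"` (default) or `"triangular"`.
#' @param baseline_frames Optional integer vector of frames to treat as the
#'   baseline window of the returned trace; defaults to all frames strictly
#'   before the first event onset (or the whole trace when there are no
#'   events).
#'
#' @return A [fluorescence_trace()] on the F/F0 scale (`f0 = 1`), with the
#'   ground truth attached as attribute `"ground_truth"`.
#' @export
generate_trace <- function(ground_truth, duration, frame_interval = 1,
                           seed = NULL, shape = c("linear_exp", "triangular"),
                           baseline_frames = NULL) {
  stopifnot(inherits(ground_truth, "trace_ground_truth"))
  shape <- match.arg(shape)
  if (frame_interval <= 0) stop("frame_interval must be positive")
  n <- floor(duration / frame_interval) + 1L
  tt <- frame_times(n, frame_interval)
  ev <- ground_truth$events
  if (nrow(ev) > 0 &&
      (any(ev$onset_time < 0) || any(ev$peak_time > duration)))
    stop("event outside recording window")
  y <- rep(ground_truth$baseline_level, n)
  if (nrow(ev) > 0) {
    for (k in seq_len(nrow(ev))) {
      y <- y + pulse_value(tt, ev$onset_time[k], ev$peak_time[k],
                           ev$peak_amplitude[k] - ground_truth$baseline_level,
                           ev$half_max_duration[k], shape)
    }
  }
  if (ground_truth$noise_sd > 0) {
    y <- y + with_seed_if(seed, stats::rnorm(n, 0, ground_truth$noise_sd))
  }
  if (is.null(baseline_frames)) {
    baseline_frames <- if (nrow(ev) > 0) {
      which(tt < min(ev$onset_time))
    } else {
      seq_len(n)
    }
    if (length(baseline_frames) == 0L) baseline_frames <- 1L
  }
  tr <- fluorescence_trace(raw = y, f0 = 1, frame_interval = frame_interval,
                           roi_id = ground_truth$roi_id,
                           baseline_frames = baseline_frames)
  attr(tr, "ground_truth") <- ground_truth
  tr
}

#' Generate a seeded population of synthetic traces
#'
#' Draws a population of ROIs with the statistical structure the analysis
#' assumes: per-ROI event counts from a geometric family (the discrete
#' analog of an exponential count distribution), positively skewed
#' (log-normal) time-to-peak and decay, optionally a two-component
#' log-normal mixture of time-to-peak to emulate bimodal kinetics. The
#' first event of an ROI starts inside the main-peak window after drug
#' addition; later events follow at exponential gaps.
#'
#' @param n_rois Number of ROIs (>= 1).
#' @param event_count_mean Mean of the geometric event-count distribution
#'   (support 0, 1, 2, ...).
#' @param kinetics List of distribution parameters:
#'   `ttp_meanlog`, `ttp_sdlog` (log-normal time to peak, s);
#'   `decay_meanlog`, `decay_sdlog` (log-normal decay, s);
#'   `amp_meanlog`, `amp_sdlog` (log-normal peak excess over baseline, F/F0);
#'   optional `ttp_mixture = list(weights, meanlog, sdlog)` replacing the
#'   single log-normal time-to-peak by a mixture;
#'   `gap_mean` (mean exponential gap between successive events, s).
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @param protocol A [stimulus_protocol()].
#' @param duration Recording length, seconds.
#' @param frame_interval Sampling interval, seconds.
#' @param noise_sd Gaussian noise SD on the F/F0 scale.
#' @param shape Pulse shape, see [generate_trace()].
#'
#' @return List with `traces` (list of [fluorescence_trace()]) and
#'   `ground_truth` (list of [trace_ground_truth()]), plus the arguments as
#'   attribute `"config"`.
#' @export
generate_population <- function(n_rois, event_count_mean = 1,
                                kinetics = list(), seed = NULL,
                                protocol = stimulus_protocol(60, 120),
                                duration = 600, frame_interval = 1,
                                noise_sd = 0.05,
                                shape = c("linear_exp", "triangular")) {
  shape <- match.arg(shape)
  if (n_rois < 1) stop("n_rois must be >= 1")
  if (event_count_mean < 0) stop("event_count_mean must be >= 0")
  kin <- utils::modifyList(list(
    ttp_meanlog = log(10), ttp_sdlog = 0.4,
    decay_meanlog = log(20), decay_sdlog = 0.5,
    amp_meanlog = log(1.5), amp_sdlog = 0.3,
    ttp_mixture = NULL, gap_mean = 60
  ), kinetics)
  if (!is.null(kin$ttp_mixture)) {
    m <- kin$ttp_mixture
    if (length(m$weights) != length(m$meanlog) ||
        length(m$weights) != length(m$sdlog) ||
        any(m$weights < 0) || abs(sum(m$weights) - 1) > 1e-9)
      stop("invalid ttp mixture parameters")
  }
  if (any(c(kin$ttp_sdlog, kin$decay_sdlog, kin$amp_sdlog) < 0) ||
      kin$gap_mean <= 0)
    stop("invalid distribution parameters")

  draw_ttp <- function(k) {
    if (is.null(kin$ttp_mixture)) {
      stats::rlnorm(k, kin$ttp_meanlog, kin$ttp_sdlog)
    } else {
      m <- kin$ttp_mixture
      comp <- sample.int(length(m$weights), k, replace = TRUE,
                         prob = m$weights)
      stats::rlnorm(k, m$meanlog[comp], m$sdlog[comp])
    }
  }

  with_seed_if(seed, {
    counts <- stats::rgeom(n_rois, prob = 1 / (1 + event_count_mean))
    gts <- vector("list", n_rois)
    traces <- vector("list", n_rois)
    for (i in seq_len(n_rois)) {
      k <- counts[i]
      if (k > 0) {
        gaps <- if (k > 1) stats::rexp(k - 1, 1 / kin$gap_mean) else numeric(0)
        ttp <- draw_ttp(k)
        decay <- stats::rlnorm(k, kin$decay_meanlog, kin$decay_sdlog)
        amp_ex <- stats::rlnorm(k, kin$amp_meanlog, kin$amp_sdlog)
        amp <- 1 + amp_ex
        # first release placed so its half-max crossing (onset + time to
        # peak under the linear rise) lands inside the MP window
        onsets <- numeric(k)
        onsets[1] <- protocol$drug_time +
          max(0.5, stats::runif(1, 0.05, 0.90) * protocol$mp_window - ttp[1])
        if (k > 1) {
          for (j in 2:k) {
            # keep successive pulses resolvable: the previous pulse must
            # fall below half of the smaller neighboring peak before the
            # next one starts
            sep <- if (shape == "linear_exp") {
              decay[j - 1] *
                log2(max(2, amp_ex[j - 1] /
                              (0.4 * min(amp_ex[j - 1], amp_ex[j]))))
            } else {
              2 * decay[j - 1]   # triangular fall length
            }
            onsets[j] <- onsets[j - 1] + 2 * ttp[j - 1] +
              max(gaps[j - 1], sep + 5)
          }
        }
        peak_t <- onsets + 2 * ttp      # linear rise: time-to-peak = rise/2
        fwhm <- ttp + decay
        keep <- peak_t + 2 * decay < duration
        ev <- data.frame(onset_time = onsets, peak_time = peak_t,
                         peak_amplitude = amp,
                         half_max_duration = fwhm)[keep, , drop = FALSE]
      } else {
        ev <- NULL
      }
      gts[[i]] <- trace_ground_truth(roi_id = i, events = ev,
                                     baseline_level = 1, noise_sd = noise_sd)
      traces[[i]] <- generate_trace(
        gts[[i]], duration = duration, frame_interval = frame_interval,
        shape = shape,
        baseline_frames = which(frame_times(
          floor(duration / frame_interval) + 1L,
          frame_interval) < protocol$control_time))
    }
    out <- list(traces = traces, ground_truth = gts)
    attr(out, "config") <- list(n_rois = n_rois,
                                event_count_mean = event_count_mean,
                                kinetics = kin, seed = seed,
                                protocol = protocol, duration = duration,
                                frame_interval = frame_interval,
                                noise_sd = noise_sd, shape = shape)
    out
  })
}
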