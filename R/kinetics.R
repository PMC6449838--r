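#' Detect calcium release events in a normalized trace
#'
#' Events are local maxima of the temporally smoothed F/F0 trace that rise
#' above statistical noise: the detection threshold is
#' `1 + z(1 - alpha) * cv` where `cv` is the coefficient of variation of the
#' normalized trace over its baseline window. Two maxima separated by a dip
#' below the half-maximum level are distinct events; maxima whose
#' intervening valley stays above half-max are merged into the larger one.
#' A retained event must additionally rise above its preceding valley by at
#' least `z(1 - alpha) * cv` (a prominence requirement, so that noise
#' ripples riding on the slowly decaying tail of an earlier event do not
#' count as new releases). Peak positions are refined on the unsmoothed
#' trace so kinetic measurements are not biased by the smoothing filter.
#'
#' @param trace A [fluorescence_trace()].
#' @param alpha One-sided significance level of the noise threshold
#'   (default 0.01).
#' @param smooth_window Odd moving-average window in frames (default 3).
#'
#' @return `data.frame` with one row per event, sorted by peak time:
#'   `roi_id`, `onset_index`, `peak_index`, `onset_s`, `peak_s`,
#'   `peak_value` (F/F0 at the peak), `label` (initially `"UNCLASSIFIED"`).
#'   Empty (zero-row) when no event exceeds the threshold.
#' @export
detect_events <- function(trace, alpha = 0.01, smooth_window = 3L) {
  stopifnot(inherits(trace, "fluorescence_trace"))
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  y <- trace$normalized
  n <- length(y)
  fi <- trace$frame_interval
  sm <- moving_average(y, smooth_window)
  base <- trace$baseline_frames
  cv <- stats::sd(y[base]) / mean(y[base])
  if (!is.finite(cv)) cv <- 0
  # numerical floor keeps exact-arithmetic ripple on noiseless traces from
  # registering as signal
  tol <- 1e-9
  thr <- 1 + stats::qnorm(1 - alpha) * cv + tol

  empty <- data.frame(roi_id = character(0), onset_index = integer(0),
                      peak_index = integer(0), onset_s = numeric(0),
                      peak_s = numeric(0), peak_value = numeric(0),
                      label = character(0), stringsAsFactors = FALSE)
  if (n < 3L) return(empty)
  i <- 2:(n - 1L)
  cand <- i[sm[i] >= sm[i - 1L] & sm[i] > sm[i + 1L] & sm[i] > thr]
  if (length(cand) == 0L) return(empty)

  # merge smoothed maxima not separated by a dip below the lower one's
  # half-max (evaluated on the smoothed trace, like the threshold)
  peaks_sm <- sort(unique(cand))
  repeat {
    if (length(peaks_sm) < 2L) break
    merged <- FALSE
    for (k in seq_len(length(peaks_sm) - 1L)) {
      p1 <- peaks_sm[k]; p2 <- peaks_sm[k + 1L]
      valley <- min(sm[p1:p2])
      half_lower <- (1 + min(sm[p1], sm[p2])) / 2
      if (valley > half_lower) {
        keep <- if (sm[p1] >= sm[p2]) p1 else p2
        peaks_sm <- sort(unique(c(peaks_sm[-c(k, k + 1L)], keep)))
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }

  # prominence filter: an event must rise out of its local background by
  # more than the noise threshold, not merely sit above the absolute level
  # (rejects noise ripples riding on the decaying tail of an earlier event)
  rise_min <- stats::qnorm(1 - alpha) * cv + tol
  kept <- integer(0)
  prev <- 1L
  for (p in peaks_sm) {
    valley_prev <- min(sm[prev:p])
    if (sm[p] - valley_prev >= rise_min) {
      kept <- c(kept, p)
      prev <- p
    }
  }
  peaks_sm <- kept
  if (length(peaks_sm) == 0L) return(empty)

  # refine surviving peaks onto the raw trace for unbiased kinetics
  half_w <- smooth_window %/% 2L
  peaks <- sort(unique(vapply(peaks_sm, function(p) {
    lo <- max(1L, p - half_w); hi <- min(n, p + half_w)
    lo + which.max(y[lo:hi]) - 1L
  }, integer(1))))

  onset_idx <- integer(length(peaks))
  onset_s <- numeric(length(peaks))
  for (k in seq_along(peaks)) {
    p <- peaks[k]
    half <- (1 + y[p]) / 2
    j <- p
    while (j > 1L && y[j - 1L] >= half) j <- j - 1L
    if (j > 1L) {
      tcross <- (j - 2L) * fi +
        (half - y[j - 1L]) / (y[j] - y[j - 1L]) * fi
      onset_idx[k] <- j
      onset_s[k] <- tcross
    } else {
      onset_idx[k] <- 1L
      onset_s[k] <- 0
    }
  }
  data.frame(roi_id = rep(trace$roi_id, length(peaks)),
             onset_index = onset_idx, peak_index = peaks,
             onset_s = onset_s, peak_s = (peaks - 1L) * fi,
             peak_value = y[peaks],
             label = rep("UNCLASSIFIED", length(peaks)),
             stringsAsFactors = FALSE)
}

#' Classify events into main and secondary peaks
#'
#' The main peak (MP) of an ROI is the first calcium release whose onset
#' falls within the main-peak window after drug administration. Secondary
#' peaks (SPs) are the events after the MP, counted only when the ROI has
#' two or more peaks in total. Events with onset at or before drug addition
#' stay `UNCLASSIFIED` and are excluded from MP/SP statistics; if an ROI's
#' first post-drug event starts outside the window, the ROI has no MP and
#' is non-responding.
#'
#' @param events Event `data.frame` from [detect_events()] (possibly several
#'   ROIs row-bound), sorted by peak time within ROI.
#' @param protocol A [stimulus_protocol()].
#'
#' @return The events with `label` filled in (`"MP"`, `"SP"` or
#'   `"UNCLASSIFIED"`), and the responding ROI ids as attribute
#'   `"responding_rois"`.
#' @export
classify_events <- function(events, protocol) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  if (nrow(events) == 0L) {
    attr(events, "responding_rois") <- character(0)
    return(events)
  }
  events$label <- "UNCLASSIFIED"
  responding <- unique(events$roi_id)[0]
  for (id in unique(events$roi_id)) {
    rows <- which(events$roi_id == id)
    rows <- rows[order(events$peak_s[rows])]
    post <- rows[events$onset_s[rows] > protocol$drug_time]
    if (length(post) == 0L) next
    first <- post[1]
    if (events$onset_s[first] <= protocol$drug_time + protocol$mp_window) {
      events$label[first] <- "MP"
      responding <- c(responding, id)
      later <- post[-1]
      if (length(later) > 0L) events$label[later] <- "SP"
    }
  }
  attr(events, "responding_rois") <- responding
  events
}

# sub-frame apex estimate: intersect the line through the two samples
# before the apex with the line through the two samples after it, on
# whichever side of the maximum sample the vertex plausibly falls; falls
# back to the maximum sample itself when no geometrically valid
# intersection exists (e.g. in heavy noise). Returns c(time, value).
refine_apex <- function(y, p, fi) {
  n <- length(y)
  tx <- function(i) (i - 1) * fi
  best_t <- tx(p); best_v <- y[p]
  cross <- function(i1, i2, i3, i4) {
    s1 <- (y[i2] - y[i1]) / ((i2 - i1) * fi)
    s2 <- (y[i4] - y[i3]) / ((i4 - i3) * fi)
    if (!(s1 > 0 && s2 < 0)) return(NULL)
    t_star <- (y[i3] - y[i2] + s1 * tx(i2) - s2 * tx(i3)) / (s1 - s2)
    c(t_star, y[i2] + s1 * (t_star - tx(i2)))
  }
  v_max <- y[p] + max(y[p] - y[max(1L, p - 1L)], y[p] - y[min(n, p + 1L)])
  v_max <- min(v_max, 2 * y[p] - 1)   # keep half-max at or below the sample
  cands <- list()
  if (p - 1L >= 1L && p + 2L <= n)
    cands <- c(cands, list(cross(p - 1L, p, p + 1L, p + 2L)))
  if (p - 2L >= 1L && p + 1L <= n)
    cands <- c(cands, list(cross(p - 2L, p - 1L, p, p + 1L)))
  for (cc in cands) {
    if (is.null(cc)) next
    if (cc[1] <= tx(p - 1L) || cc[1] >= tx(p + 1L)) next
    if (cc[2] < y[p] || cc[2] > v_max) next
    if (cc[2] > best_v) { best_t <- cc[1]; best_v <- cc[2] }
  }
  c(best_t, best_v)
}

#' Measure half-maximum kinetics of one event
#'
#' Kinetic parameters are referenced to the half-maximum level
#' `(1 + peak F/F0) / 2`, with the resting level fixed at F/F0 = 1:
#' time to peak is the interval from the last upward half-max crossing to
#' the peak, decay is the interval from the peak to the first downward
#' half-max crossing, and duration is their sum (the full width at half
#' maximum). Crossing times are located by linear interpolation between
#' frames, and the peak apex is refined to sub-frame resolution by
#' intersecting the local rise and fall segments (falling back to the peak
#' sample when the local geometry does not support it). If the trace never
#' re-crosses half-max before `search_limit` (the next event's inter-event
#' minimum, or the end of the recording), the decay is censored and
#' decay/duration are `NA`.
#'
#' @param trace A [fluorescence_trace()].
#' @param event One event: a one-row `data.frame` or list with at least
#'   `peak_index`.
#' @param search_limit Last frame index eligible for the downward crossing
#'   (default: end of trace).
#'
#' @return List with `time_to_peak`, `decay`, `duration` (seconds),
#'   `half_max_level` and logical `decay_censored`.
#' @export
measure_kinetics <- function(trace, event, search_limit = NULL) {
  stopifnot(inherits(trace, "fluorescence_trace"))
  y <- trace$normalized
  n <- length(y)
  fi <- trace$frame_interval
  p <- as.integer(event$peak_index)
  if (p < 1L || p > n) stop("event peak outside trace")
  if (y[p] <= 1) stop("peak_value must exceed the baseline level 1.0")
  apex <- refine_apex(y, p, fi)
  t_apex <- apex[1]
  half <- (1 + apex[2]) / 2
  if (is.null(search_limit)) search_limit <- n
  search_limit <- min(as.integer(search_limit), n)

  j <- p
  while (j > 1L && y[j - 1L] >= half) j <- j - 1L
  t_up <- if (j > 1L) {
    (j - 2L) * fi + (half - y[j - 1L]) / (y[j] - y[j - 1L]) * fi
  } else {
    0
  }
  time_to_peak <- max(t_apex - t_up, 0)

  k <- p
  while (k < search_limit && y[k + 1L] >= half) k <- k + 1L
  if (k < search_limit && y[k + 1L] < half) {
    t_down <- (k - 1L) * fi + (half - y[k]) / (y[k + 1L] - y[k]) * fi
    decay <- max(t_down - t_apex, 0)
    censored <- FALSE
  } else {
    decay <- NA_real_
    censored <- TRUE
  }
  list(time_to_peak = time_to_peak, decay = decay,
       duration = if (censored) NA_real_ else time_to_peak + decay,
       half_max_level = half, decay_censored = censored)
}

#' Measure kinetics for every event of a trace
#'
#' Applies [measure_kinetics()] to each event, limiting each decay search to
#' the inter-event minimum before the next peak so that overlapping events
#' are censored rather than double-counted.
#'
#' @param trace A [fluorescence_trace()].
#' @param events Events of this trace from [detect_events()] /
#'   [classify_events()].
#' @return The events with columns `time_to_peak`, `decay`, `duration`,
#'   `half_max_level`, `decay_censored` appended.
#' @export
event_kinetics <- function(trace, events) {
  n <- length(trace$normalized)
  m <- nrow(events)
  cols <- data.frame(time_to_peak = numeric(m), decay = numeric(m),
                     duration = numeric(m), half_max_level = numeric(m),
                     decay_censored = logical(m))
  if (m > 0L) {
    ord <- order(events$peak_index)
    for (k in seq_len(m)) {
      i <- ord[k]
      limit <- if (k < m) {
        p1 <- events$peak_index[ord[k]]
        p2 <- events$peak_index[ord[k + 1L]]
        p1 + which.min(trace$normalized[p1:p2]) - 1L
      } else {
        n
      }
      kin <- measure_kinetics(trace, events[i, ], search_limit = limit)
      cols[i, ] <- kin[c("time_to_peak", "decay", "duration",
                         "half_max_level", "decay_censored")]
    }
  }
  cbind(events, cols)
}

#' Fraction of responding cells
#'
#' The number of ROIs with a detected main peak divided by the total number
#' of cells in the field of view.
#'
#' @param n_responding Count of responding ROIs (>= 0).
#' @param n_total Total cells in the field of view (> 0).
#' @return The fraction in `[0, 1]`.
#' @export
responding_fraction <- function(n_responding, n_total) {
  if (n_total <= 0) stop("n_total must be positive")
  if (n_responding < 0 || n_responding > n_total)
    stop("n_responding must be between 0 and n_total")
  n_responding / n_total
}

#' Number of classified calcium release events per ROI
#'
#' Counts MP and SP events per ROI; `UNCLASSIFIED` events are excluded.
#' ROIs listed in `roi_ids` but absent from the events contribute a zero
#' count, so the events-within-ROI histogram keeps its full denominator.
#'
#' @param events Classified events (several ROIs row-bound).
#' @param roi_ids Optional vector of all ROI ids in the field of view.
#' @return `data.frame` with `roi_id` and `n_events`.
#' @export
event_count_per_roi <- function(events, roi_ids = NULL) {
  keep <- events[events$label %in% c("MP", "SP"), , drop = FALSE]
  ids <- if (is.null(roi_ids)) unique(events$roi_id) else roi_ids
  counts <- vapply(ids, function(id) sum(keep$roi_id == id), integer(1))
  data.frame(roi_id = ids, n_events = counts, stringsAsFactors = FALSE,
             row.names = NULL)
}
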