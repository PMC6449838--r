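#' Run the calcium-release quantification pipeline
#'
#' Composes the full assay on one recording: ROI detection above statistical
#' noise, trace extraction and F/F0 normalization, event detection, MP/SP
#' classification, half-maximum kinetics, per-ROI event counts and the
#' responding fraction. When `out_dir` is given, the events and ROI tables
#' are written as CSV together with a JSON run manifest.
#'
#' @param stack A [time_series_stack()].
#' @param alpha Significance level for detection (default 0.01).
#' @param min_size Minimum ROI size in pixels (default 9).
#' @param smooth_window Temporal smoothing window in frames (default 3).
#' @param total_cells Total cells in the field of view (denominator of the
#'   responding fraction). Default: [count_total_cells()] on the mean of
#'   the pre-control (baseline) frames, where all loaded cells sit at their
#'   resting brightness.
#' @param out_dir Optional output directory.
#' @param seed Seed recorded in the manifest (the pipeline itself is
#'   deterministic).
#'
#' @return List with `rois`, `traces`, `events` (classified, with
#'   kinetics), `event_counts`, `n_responding`, `n_total`,
#'   `responding_fraction`.
#' @export
run_calcium_pipeline <- function(stack, alpha = 0.01, min_size = 9L,
                                 smooth_window = 3L, total_cells = NULL,
                                 out_dir = NULL, seed = NULL) {
  stopifnot(inherits(stack, "time_series_stack"))
  rois <- detect_rois(stack, alpha = alpha, min_size = min_size,
                      smooth_window = smooth_window)
  traces <- lapply(rois, function(r) {
    normalize_trace(extract_trace(stack, r), stack$protocol,
                    frame_interval = stack$frame_interval,
                    roi_id = r$roi_id)
  })
  events_list <- lapply(traces, function(tr) {
    ev <- detect_events(tr, alpha = alpha, smooth_window = smooth_window)
    ev <- classify_events(ev, stack$protocol)
    event_kinetics(tr, ev)
  })
  events <- if (length(events_list) > 0) {
    do.call(rbind, c(events_list, list(make.row.names = FALSE)))
  } else {
    event_kinetics(
      fluorescence_trace(c(1, 1), 1),
      classify_events(detect_events(fluorescence_trace(c(1, 1), 1)),
                      stack$protocol))
  }
  roi_ids <- vapply(rois, `[[`, 0, "roi_id")
  counts <- event_count_per_roi(events, roi_ids = roi_ids)
  n_responding <- sum(events$label == "MP")
  if (is.null(total_cells)) {
    tt <- frame_times(dim(stack$frames)[1], stack$frame_interval)
    base <- which(tt < stack$protocol$control_time)
    ref <- apply(stack$frames[base, , , drop = FALSE], c(2, 3), mean)
    total_cells <- count_total_cells(ref, min_size = min_size)
  }
  frac <- if (total_cells > 0) {
    responding_fraction(min(n_responding, total_cells), total_cells)
  } else {
    NA_real_
  }
  out <- list(rois = rois, traces = traces, events = events,
              event_counts = counts, n_responding = n_responding,
              n_total = total_cells, responding_fraction = frac)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_csv_stable(events, file.path(out_dir, "events.csv"))
    roi_df <- data.frame(
      roi_id = roi_ids,
      centroid_row = vapply(rois, function(r) r$centroid[1], 0),
      centroid_col = vapply(rois, function(r) r$centroid[2], 0),
      n_pixels = vapply(rois, function(r) nrow(r$pixel_set), 0L))
    write_csv_stable(roi_df, file.path(out_dir, "rois.csv"))
    write_csv_stable(counts, file.path(out_dir, "event_counts.csv"))
    write_manifest(
      config = list(alpha = alpha, min_size = min_size,
                    smooth_window = smooth_window, seed = seed,
                    frame_interval = stack$frame_interval,
                    control_time = stack$protocol$control_time,
                    drug_time = stack$protocol$drug_time,
                    mp_window = stack$protocol$mp_window),
      counts = list(n_rois = length(rois), n_events = nrow(events),
                    n_responding = n_responding, n_total = total_cells,
                    n_censored = sum(events$decay_censored)),
      path = file.path(out_dir, "manifest.json"))
  }
  out
}

# MP/SP kinetic samples of one analyzed population, uncensored only
kinetic_samples <- function(events, label) {
  ev <- events[events$label == label, , drop = FALSE]
  list(time_to_peak = ev$time_to_peak,
       decay = ev$decay[!ev$decay_censored],
       duration = ev$duration[!ev$decay_censored])
}

#' Compare two analyzed populations measurement by measurement
#'
#' Computes the divergence statistic D with its category for the standard
#' measurement set: events within ROI, and MP and SP time to peak, decay
#' and duration. Both populations must be compared under one binning
#' configuration.
#'
#' @param result_a,result_b Outputs of [run_calcium_pipeline()] (or any
#'   lists with `events` and `event_counts` of the same shape).
#' @param n_bins Shared bin count (default 30).
#' @return `data.frame` with `measurement`, `measurement_type`, `n_a`,
#'   `n_b`, `n_bins`, `d_value`, `category`; measurements for which either
#'   group has no samples are dropped.
#' @export
run_compare <- function(result_a, result_b, n_bins = 30L) {
  specs <- list(
    list(name = "events_within_roi", type = "events_within_roi",
         get = function(r) r$event_counts$n_events)
  )
  for (lab in c("MP", "SP")) {
    for (param in c("time_to_peak", "decay", "duration")) {
      local({
        lab <- lab; param <- param
        specs[[length(specs) + 1L]] <<- list(
          name = paste0(lab, "_", param), type = "ca_kinetics",
          get = function(r) kinetic_samples(r$events, lab)[[param]])
      })
    }
  }
  rows <- lapply(specs, function(s) {
    a <- s$get(result_a); a <- a[is.finite(a)]
    b <- s$get(result_b); b <- b[is.finite(b)]
    if (length(a) == 0L || length(b) == 0L) return(NULL)
    cmp <- compare_populations(a, b, measurement_type = s$type,
                               n_bins = n_bins)
    data.frame(measurement = s$name, measurement_type = s$type,
               n_a = length(a), n_b = length(b), n_bins = n_bins,
               d_value = cmp$d_value, category = cmp$category,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows[!vapply(rows, is.null, TRUE)],
                   list(make.row.names = FALSE)))
}

#' Run the contraction quantification pipeline
#'
#' Segments the three state images, tracks cells across them, computes the
#' per-cell relative area changes and the population comparison.
#'
#' @param frames List of 3 intensity matrices (pre-stimulus, post-control,
#'   post-drug).
#' @param min_size Minimum object size in pixels (default 9).
#' @param n_bins Histogram bins (default 30).
#' @param out_dir Optional output directory for the tracks CSV + manifest.
#' @return List with `masks`, `tracks`, `measures` (complete tracks only)
#'   and `population` (see [contraction_population()]).
#' @export
run_contraction_pipeline <- function(frames, min_size = 9L, n_bins = 30L,
                                     out_dir = NULL) {
  stopifnot(length(frames) == 3L)
  masks <- lapply(frames, segment_cells, min_size = min_size)
  tracks <- track_cells(masks)
  complete <- tracks[tracks$complete, , drop = FALSE]
  meas <- do.call(rbind, lapply(seq_len(nrow(complete)), function(i) {
    as.data.frame(compute_contraction(complete[i, ]))
  }))
  pop <- if (!is.null(meas) && nrow(meas) >= 2L) {
    contraction_population(meas, n_bins = n_bins)
  } else {
    NULL
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    out_tracks <- merge(tracks, meas, by = "track_id", all.x = TRUE)
    write_csv_stable(out_tracks, file.path(out_dir, "tracks.csv"))
    write_manifest(
      config = list(min_size = min_size, n_bins = n_bins),
      counts = list(n_tracks = nrow(tracks),
                    n_complete = nrow(complete),
                    n_centroid_fallback = attr(tracks,
                                               "n_centroid_fallback")),
      path = file.path(out_dir, "manifest.json"))
  }
  list(masks = masks, tracks = tracks, measures = meas, population = pop)
}
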