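prot <- stimulus_protocol(control_time = 60, drug_time = 120,
                          mp_window = 100)

test_that("F/F0 normalization is the baseline-mean ratio", {
  raw <- c(rep(500, 60), rep(500, 40), seq(500, 1500, length.out = 21),
           rep(500, 50))
  tr <- normalize_trace(raw, prot, frame_interval = 1)
  expect_equal(tr$f0, 500)
  expect_equal(max(tr$normalized), 3.0)                  # 1500 / 500
  expect_equal(normalize_trace(rep(7, 100), prot)$normalized, rep(1, 100))
  # scale invariance
  tr2 <- normalize_trace(2 * raw, prot)
  expect_equal(tr2$normalized, tr$normalized)
  expect_error(normalize_trace(raw, stimulus_protocol(2, 60),
                               min_baseline_frames = 5), "baseline")
  expect_error(normalize_trace(rep(0, 100), prot), "positive")
})

test_that("event detection finds well-separated pulses at the true times", {
  gt <- trace_ground_truth(1, data.frame(
    onset_time = c(130, 250, 400), peak_time = c(140, 260, 410),
    peak_amplitude = c(3, 2.5, 3.5), half_max_duration = c(12, 12, 12)))
  tr <- generate_trace(gt, 600, 1, baseline_frames = 1:60)
  ev <- detect_events(tr)
  expect_equal(nrow(ev), 3)
  expect_equal(ev$peak_s, c(140, 260, 410), tolerance = 1e-9)

  # constant trace: no events
  flat <- fluorescence_trace(rep(10, 100), 10)
  expect_equal(nrow(detect_events(flat)), 0)
})

test_that("noisy pulses are detected within a frame of the truth", {
  hits <- 0L
  for (s in 1:20) {
    gt <- pulse_gt(onset = 150, rise = 10, amplitude = 3, fwhm = 15,
                   noise_sd = 0.05)
    tr <- generate_trace(gt, 400, 1, seed = s, baseline_frames = 1:60)
    ev <- detect_events(tr)
    if (nrow(ev) >= 1 && any(abs(ev$peak_s - 160) <= 1)) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("spurious event rate on pure noise is controlled", {
  n_spurious <- 0L
  n_rep <- 300L
  withr::with_seed(2024, {
    for (r in seq_len(n_rep)) {
      tr <- fluorescence_trace(1000 + stats::rnorm(400, 0, 20), 1000,
                               baseline_frames = 1:60)
      tr$normalized <- tr$raw / mean(tr$raw[1:60])
      if (nrow(detect_events(tr, alpha = 0.01)) > 0) {
        n_spurious <- n_spurious + 1L
      }
    }
  })
  # the per-frame threshold is conservative after smoothing, but the
  # baseline noise level is itself estimated from 60 frames, which inflates
  # the family-wise rate; order-of-magnitude control is the documented
  # expectation
  expect_lte(n_spurious / n_rep, 0.10)
})

test_that("MP/SP labels follow the first-release-within-window rule", {
  mk_events <- function(onsets, roi = 1) {
    data.frame(roi_id = roi, onset_index = NA_integer_,
               peak_index = seq_along(onsets),
               onset_s = onsets, peak_s = onsets + 10,
               peak_value = 2, label = "UNCLASSIFIED",
               stringsAsFactors = FALSE)
  }
  # events at drug+20, +150, +200 -> MP then 2 SPs
  ev <- classify_events(mk_events(120 + c(20, 150, 200)), prot)
  expect_equal(ev$label, c("MP", "SP", "SP"))
  # single event inside the window -> MP alone
  ev1 <- classify_events(mk_events(170), prot)
  expect_equal(ev1$label, "MP")
  # only event outside the 100-s window -> non-responding, no MP
  ev2 <- classify_events(mk_events(120 + 150), prot)
  expect_equal(ev2$label, "UNCLASSIFIED")
  expect_length(attr(ev2, "responding_rois"), 0)
  # pre-drug events stay unclassified even when later events respond
  ev3 <- classify_events(mk_events(c(80, 140, 300)), prot)
  expect_equal(ev3$label, c("UNCLASSIFIED", "MP", "SP"))
  expect_equal(attr(ev3, "responding_rois"), 1)
})

test_that("half-max kinetics recover analytic pulse parameters", {
  # symmetric triangle rise 10 / fall 10: half-max sits at half of each
  tr <- generate_trace(pulse_gt(onset = 100, rise = 10, amplitude = 3,
                                fwhm = 10),
                       300, 1, shape = "triangular")
  ev <- detect_events(tr)
  kin <- measure_kinetics(tr, ev[1, ])
  expect_equal(kin$time_to_peak, 5)
  expect_equal(kin$decay, 5)
  expect_equal(kin$duration, 10)
  expect_equal(kin$half_max_level, 2)

  # linear rise 10 + exponential fall, half-life 4: decay = one half-life
  tr2 <- generate_trace(pulse_gt(onset = 100, rise = 10, amplitude = 3,
                                 fwhm = 9),
                        300, 1, shape = "linear_exp")
  ev2 <- detect_events(tr2)
  kin2 <- measure_kinetics(tr2, ev2[1, ])
  expect_equal(kin2$time_to_peak, 5)
  expect_equal(kin2$decay, 4, tolerance = 0.05)
  expect_equal(kin2$duration, kin2$time_to_peak + kin2$decay)

  expect_error(measure_kinetics(tr, list(peak_index = 5)), "baseline")
})

test_that("a pulse truncated above half-max at recording end is censored", {
  tr <- generate_trace(pulse_gt(onset = 180, rise = 10, amplitude = 3,
                                fwhm = 30),
                       195, 1, shape = "triangular")
  ev <- detect_events(tr)
  kin <- measure_kinetics(tr, ev[1, ])
  expect_true(kin$decay_censored)
  expect_true(is.na(kin$decay))
  expect_true(is.na(kin$duration))
})

test_that("kinetics are scale invariant and time covariant", {
  raw <- c(rep(200, 60), rep(200, 60), 200 * generate_trace(
    pulse_gt(onset = 20, rise = 8, amplitude = 3, fwhm = 12),
    100, 1, shape = "triangular")$normalized)
  tr1 <- normalize_trace(raw, prot, frame_interval = 1)
  tr5 <- normalize_trace(5 * raw, prot, frame_interval = 1)
  e1 <- detect_events(tr1); e5 <- detect_events(tr5)
  k1 <- measure_kinetics(tr1, e1[1, ])
  k5 <- measure_kinetics(tr5, e5[1, ])
  expect_equal(k1, k5)
  # doubling the frame interval doubles every kinetic parameter
  tr_fast <- normalize_trace(raw, stimulus_protocol(30, 60),
                             frame_interval = 0.5)
  k_fast <- measure_kinetics(tr_fast, detect_events(tr_fast)[1, ])
  expect_equal(k1$time_to_peak, 2 * k_fast$time_to_peak)
  expect_equal(k1$decay, 2 * k_fast$decay)
  expect_equal(k1$duration, 2 * k_fast$duration)
})

test_that("duration equals time to peak plus decay for uncensored events", {
  pop <- generate_population(60, 2, seed = 77, noise_sd = 0.03)
  for (tr in pop$traces) {
    ev <- event_kinetics(tr, detect_events(tr))
    ok <- !ev$decay_censored
    if (any(ok)) {
      expect_equal(ev$duration[ok],
                   ev$time_to_peak[ok] + ev$decay[ok])
    }
  }
})

test_that("responding fraction is guarded arithmetic", {
  expect_equal(responding_fraction(50, 200), 0.25)
  expect_equal(responding_fraction(0, 10), 0)
  expect_error(responding_fraction(11, 10), "between")
  expect_error(responding_fraction(1, 0), "positive")
})

test_that("event counts per ROI include zero-count ROIs on request", {
  ev <- data.frame(roi_id = c(1, 1, 2, 3), label = c("MP", "SP", "MP",
                                                     "UNCLASSIFIED"))
  counts <- event_count_per_roi(ev, roi_ids = 1:4)
  expect_equal(counts$n_events, c(2L, 1L, 0L, 0L))
})

test_that("population event counts are recovered through the event detector", {
  pop <- generate_population(300, event_count_mean = 2, seed = 99,
                             noise_sd = 0.03)
  prot_pop <- attr(pop, "config")$protocol
  true_counts <- vapply(pop$ground_truth, function(g) nrow(g$events), 0L)
  det_counts <- vapply(pop$traces, function(tr) {
    ev <- classify_events(detect_events(tr), prot_pop)
    sum(ev$label %in% c("MP", "SP"))
  }, 0L)
  # per-trace agreement for the large majority; the residual overcounts are
  # the family-wise false positives of the per-frame alpha = 0.01 rule
  expect_gte(mean(det_counts == true_counts), 0.85)
  # population histograms agree closely
  d <- compare_populations(true_counts, det_counts,
                           "events_within_roi")$d_value
  expect_lte(d, 0.1)
})
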