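test_that("noiseless trace generation matches analytic pulse geometry", {
  # zero events, no noise: constant baseline
  gt0 <- trace_ground_truth(1, NULL)
  tr0 <- generate_trace(gt0, 100, 1)
  expect_equal(tr0$normalized, rep(1, 101))

  # symmetric triangular pulse: width at half amplitude equals fwhm
  tr <- generate_trace(pulse_gt(onset = 100, rise = 10, amplitude = 3,
                                fwhm = 10),
                       300, 1, shape = "triangular")
  y <- tr$normalized
  above <- which(y > 2.0)          # level halfway between baseline 1 and 3
  # crossings at onset+5 and peak+5 by similar triangles -> 10 s above
  expect_equal(max(y), 3.0)
  expect_equal(which.max(y), 111L)     # peak frame at t = 110 s
  w <- sum(y >= 2.0) - 1L              # frames at or above half, inclusive
  expect_equal(w, 10L)
  expect_true(all(diff(above) == 1))   # single contiguous excursion

  # linear-rise/exponential-fall: half-life equals fwhm - rise/2
  tr2 <- generate_trace(pulse_gt(onset = 100, rise = 10, amplitude = 3,
                                 fwhm = 9),
                        300, 1, shape = "linear_exp")
  y2 <- tr2$normalized
  expect_equal(y2[111], 3.0)
  expect_equal(y2[111 + 4], 1 + 2 / 2)   # one half-life (4 s) after peak
})

test_that("generation is bit-identical under a fixed seed", {
  gt <- pulse_gt(noise_sd = 0.05)
  a <- generate_trace(gt, 200, 1, seed = 99)
  b <- generate_trace(gt, 200, 1, seed = 99)
  expect_identical(a$normalized, b$normalized)

  pa <- generate_population(10, 1.5, seed = 123)
  pb <- generate_population(10, 1.5, seed = 123)
  expect_identical(lapply(pa$traces, `[[`, "normalized"),
                   lapply(pb$traces, `[[`, "normalized"))
})

test_that("events outside the recording window are rejected", {
  gt <- pulse_gt(onset = 100, rise = 10)
  expect_error(generate_trace(gt, 105, 1), "outside recording window")
})

test_that("population event counts follow the geometric family", {
  pop <- generate_population(1000, event_count_mean = 1, seed = 5,
                             noise_sd = 0)
  counts <- vapply(pop$ground_truth, function(g) nrow(g$events), 0L)
  # geometric with mean 1: empirical histogram decreasing over counts >= 1
  h <- tabulate(counts + 1L, nbins = max(counts) + 1L)
  expect_true(all(diff(h[h > 0]) <= 0))
  expect_equal(mean(counts), 1, tolerance = 0.15)
  expect_error(generate_population(0, 1), "n_rois")
})

test_that("a two-component mixture of time to peak is bimodal", {
  pop <- generate_population(
    800, event_count_mean = 2, seed = 8, noise_sd = 0,
    kinetics = list(ttp_mixture = list(weights = c(0.5, 0.5),
                                       meanlog = log(c(4, 40)),
                                       sdlog = c(0.2, 0.2))))
  ttp <- unlist(lapply(pop$ground_truth, function(g) {
    if (nrow(g$events) == 0) return(numeric(0))
    (g$events$peak_time - g$events$onset_time) / 2   # linear rise
  }))
  # two well-separated components: mass near each mode, dip between
  expect_gt(mean(ttp < 8), 0.3)
  expect_gt(mean(ttp > 20), 0.3)
  expect_lt(mean(ttp > 8 & ttp < 20), 0.15)
})

test_that("ground truth attached to generated traces satisfies invariants", {
  pop <- generate_population(50, 2, seed = 31)
  for (g in pop$ground_truth) {
    ev <- g$events
    if (nrow(ev) == 0) next
    expect_true(all(ev$peak_time > ev$onset_time))
    expect_false(is.unsorted(ev$onset_time))
    expect_true(all(ev$peak_amplitude > g$baseline_level))
  }
})

test_that("calcium stack construction inverts through the true mask", {
  out <- demo_calcium_stack(n_cells = 1, noise_sd = 0, seed = 1)
  # silence the camera noise entirely for the inverse check
  gt <- out$ground_truth[[1]]
  tr <- generate_trace(gt, 240, 1, baseline_frames = 1:30)
  cs <- generate_calcium_stack(list(tr),
                               data.frame(row = 20, col = 20, radius = 6),
                               c(40, 40), seed = 1,
                               protocol = stimulus_protocol(30, 60),
                               read_noise_sd = 0, background = 0)
  inside <- which(cs$masks == 1)
  rec <- vapply(seq_len(dim(cs$stack$frames)[1]), function(f) {
    mean(cs$stack$frames[f, , ][inside])
  }, 0) / 1000
  expect_equal(rec, tr$normalized, tolerance = 1e-3)  # quantization only
})

test_that("calcium stack rejects overlapping footprints", {
  tr <- generate_trace(pulse_gt(), 200, 1)
  lay <- data.frame(row = c(20, 24), col = c(20, 20), radius = c(5, 5))
  expect_error(
    generate_calcium_stack(list(tr, tr), lay, c(40, 40)),
    "overlap")
})

test_that("contraction ground truth encodes the area-change arithmetic", {
  g <- contraction_ground_truth(1, c(1000, 1000, 800))
  expect_equal(g$true_delta_control, 0)
  expect_equal(g$true_delta_drug, 0.20)
  g2 <- contraction_ground_truth(2, c(1000, 800, 900))
  expect_equal(g2$true_delta_control, 0.2)
  expect_equal(g2$true_delta_drug, -0.125)
  expect_error(contraction_ground_truth(3, c(1000, 0, 800)), "positive")
})

test_that("rendered ellipse areas match prescribed areas within rasterization", {
  gts <- lapply(1:4, function(i) contraction_ground_truth(i, c(900, 700, 500)))
  out <- generate_contraction_sequence(gts, seed = 2, jitter = 0,
                                       noise_sd = 0)
  for (state in 1:3) {
    s_true <- gts[[1]]$true_areas[state]
    perim <- 2 * pi * sqrt(s_true / pi)   # circle-equivalent bound
    for (i in 1:4) {
      a <- sum(out$masks[[state]] == i)
      expect_lt(abs(a - s_true), perim)
    }
  }
})
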