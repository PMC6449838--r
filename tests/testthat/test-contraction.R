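test_that("segmentation counts interior ellipses and excludes border objects", {
  gts <- lapply(1:10, function(i) contraction_ground_truth(i, c(600, 600, 600)))
  out <- generate_contraction_sequence(gts, seed = 14, noise_sd = 20)
  frame <- out$frames[[1]]
  # paste two synthetic border-touching blobs onto the frame
  frame[1:6, 10:20] <- 30000
  frame[nrow(frame) - (0:5), 30:40] <- 30000
  lab <- segment_cells(frame)
  expect_identical(max(lab), 10L)
  expect_warning(l0 <- segment_cells(matrix(1, 10, 10)), "blank")
  expect_identical(max(l0), 0L)
})

test_that("measured object area matches the prescribed ellipse area", {
  gts <- list(contraction_ground_truth(1, c(1000, 1000, 1000)))
  out <- generate_contraction_sequence(gts, seed = 3, noise_sd = 0)
  lab <- segment_cells(out$frames[[1]])
  area <- sum(lab == 1L)
  perim <- 2 * pi * sqrt(1000 / pi)
  expect_lt(abs(area - 1000), perim)
})

test_that("jitter-free tracking links every cell across all three states", {
  gts <- lapply(1:6, function(i) {
    contraction_ground_truth(i, c(800 + 40 * i, 700 + 40 * i, 500 + 40 * i))
  })
  out <- generate_contraction_sequence(gts, seed = 8, jitter = 0,
                                       noise_sd = 20)
  masks <- lapply(out$frames, segment_cells)
  tracks <- track_cells(masks)
  expect_equal(sum(tracks$complete), 6)
  # correspondence: areas shrink monotonically per the ground truth
  complete <- tracks[tracks$complete, ]
  expect_true(all(complete$s1 > complete$s2 & complete$s2 > complete$s3))
})

test_that("a cell present in one state yields an incomplete track", {
  m <- matrix(0L, 30, 30)
  m1 <- m; m1[5:10, 5:10] <- 1L; m1[20:25, 20:25] <- 2L
  m2 <- m; m2[5:10, 5:10] <- 1L
  m3 <- m; m3[6:11, 5:10] <- 1L
  tracks <- track_cells(list(m1, m2, m3))
  expect_equal(nrow(tracks), 2)
  expect_equal(sum(tracks$complete), 1)
  expect_error(compute_contraction(tracks[!tracks$complete, ][1, ]),
               "complete")
})

test_that("cells swapping positions without overlap link by nearest centroid", {
  m <- matrix(0L, 40, 80)
  a1 <- m; a1[5:10, 5:10] <- 1L; a1[30:35, 60:65] <- 2L
  # both cells moved: no overlap with state 1 at all
  a2 <- m; a2[6:11, 14:19] <- 1L; a2[29:33, 50:55] <- 2L  # right cell 30 px
  a3 <- a2
  tracks <- track_cells(list(a1, a2, a3))
  expect_equal(sum(tracks$complete), 2)
  expect_gte(attr(tracks, "n_centroid_fallback"), 1)
  # nearest-centroid pairing keeps the left cell with the left cell
  left <- tracks[which.min(tracks$col1), ]
  expect_equal(left$s2, 36)
})

test_that("contraction follows the two area-ratio definitions", {
  tr <- list(track_id = 1, s1 = 1000, s2 = 1000, s3 = 800, complete = TRUE)
  m <- compute_contraction(tr)
  expect_equal(m$delta_control, 0)
  expect_equal(m$delta_drug, 0.2)
  tr2 <- list(track_id = 2, s1 = 500, s2 = 500, s3 = 500, complete = TRUE)
  m2 <- compute_contraction(tr2)
  expect_equal(m2$delta_control, 0)
  expect_equal(m2$delta_drug, 0)
  # expansion gives a negative value
  tr3 <- list(track_id = 3, s1 = 500, s2 = 400, s3 = 500, complete = TRUE)
  expect_lt(compute_contraction(tr3)$delta_drug, 0)
})

test_that("deltas are invariant to uniform intensity rescaling", {
  gts <- lapply(1:4, function(i) contraction_ground_truth(i, c(900, 850, 700)))
  out <- generate_contraction_sequence(gts, seed = 20, noise_sd = 20)
  res1 <- run_contraction_pipeline(out$frames)
  res2 <- run_contraction_pipeline(lapply(out$frames, function(f) f * 3.7))
  expect_equal(res1$measures, res2$measures)
})

test_that("population recovery on the prescribed-contraction fixture", {
  gts <- lapply(1:30, function(i) contraction_ground_truth(i, c(1000, 1000, 800)))
  out <- generate_contraction_sequence(gts, seed = 33, jitter = 0,
                                       noise_sd = 30)
  res <- run_contraction_pipeline(out$frames)
  pop <- res$population
  rast <- 2 * pi * sqrt(1000 / pi) / 1000   # perimeter/area bound
  expect_lt(abs(pop$summary_drug$median - 0.20), rast)
  expect_lt(abs(pop$summary_control$median), 0.01)
  expect_lt(pop$p_value, 1e-4)
})

test_that("identical control and drug distributions rarely reject the null", {
  n_reject <- 0L
  n_rep <- 200L
  withr::with_seed(71, {
    for (r in seq_len(n_rep)) {
      x <- stats::rnorm(40, 0, 0.02)
      y <- stats::rnorm(40, 0, 0.02)
      p <- stats::wilcox.test(x, y, exact = FALSE)$p.value
      meas <- data.frame(delta_control = x, delta_drug = y)
      pop <- contraction_population(meas)
      if (pop$p_value < 0.05) n_reject <- n_reject + 1L
      if (r == 1) expect_equal(pop$p_value, p)
    }
  })
  expect_lte(n_reject / n_rep, 0.06)
})
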