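# shared fixtures, built in code

# one-pulse ground truth on the F/F0 scale
pulse_gt <- function(onset = 100, rise = 10, amplitude = 3, fwhm = 10,
                     noise_sd = 0, roi_id = 1) {
  trace_ground_truth(
    roi_id,
    data.frame(onset_time = onset, peak_time = onset + rise,
               peak_amplitude = amplitude, half_max_duration = fwhm),
    noise_sd = noise_sd)
}

# small high-SNR calcium stack: n active cells on a grid, one pulse each
demo_calcium_stack <- function(n_cells = 2, seed = 42, noise_sd = 0.02,
                               amplitude = 3, image_shape = c(40, 40),
                               protocol = stimulus_protocol(30, 60),
                               duration = 240) {
  gts <- lapply(seq_len(n_cells), function(i) {
    pulse_gt(onset = protocol$drug_time + 10 + 5 * i, rise = 10,
             amplitude = amplitude, fwhm = 15, noise_sd = noise_sd,
             roi_id = i)
  })
  traces <- lapply(gts, generate_trace, duration = duration,
                   frame_interval = 1,
                   baseline_frames = seq_len(protocol$control_time))
  pos <- expand.grid(row = c(12, 29), col = c(12, 29))[seq_len(n_cells), ]
  layout <- data.frame(row = pos$row, col = pos$col, radius = 5)
  out <- generate_calcium_stack(traces, layout, image_shape, seed = seed,
                                protocol = protocol, read_noise_sd = 5)
  out$ground_truth <- gts
  out
}

jaccard <- function(mask_a, mask_b) {
  sum(mask_a & mask_b) / sum(mask_a | mask_b)
}

# random probability vector on k bins
rand_prob <- function(k) {
  x <- stats::runif(k)
  x / sum(x)
}

# brute-force total-variation: max over all bin subsets of |P_A(S) - P_B(S)|
tv_by_enumeration <- function(p_a, p_b) {
  k <- length(p_a)
  best <- 0
  for (s in 0:(2^k - 1)) {
    sel <- as.logical(bitwAnd(s, 2^(0:(k - 1))))
    best <- max(best, abs(sum(p_a[sel]) - sum(p_b[sel])))
  }
  best
}
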