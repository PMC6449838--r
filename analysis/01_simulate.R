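#!/usr/bin/env Rscript
# Generate the synthetic study data used by the downstream analyses:
# two calcium-imaging populations with different kinetics (group A fast
# unimodal, group B slower with a bimodal time-to-peak), one rendered
# calcium image stack, and one three-state contraction sequence.
# Outputs go to results/synthetic/.

suppressMessages(library(smcquant))

seed <- 2026L
out <- "results/synthetic"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

protocol <- stimulus_protocol(control_time = 60, drug_time = 120,
                              mp_window = 100)

# group A: fast kinetics, frequent secondary peaks
pop_a <- generate_population(
  400, event_count_mean = 2, seed = seed, protocol = protocol,
  kinetics = list(ttp_meanlog = log(8), ttp_sdlog = 0.35,
                  decay_meanlog = log(15), decay_sdlog = 0.45))

# group B: slower release with two time-to-peak subpopulations
pop_b <- generate_population(
  400, event_count_mean = 1.2, seed = seed + 1L, protocol = protocol,
  kinetics = list(ttp_mixture = list(weights = c(0.6, 0.4),
                                     meanlog = log(c(8, 30)),
                                     sdlog = c(0.3, 0.3)),
                  decay_meanlog = log(25), decay_sdlog = 0.45))

# ground-truth event tables (traces themselves are regenerated from seeds)
gt_table <- function(pop, group) {
  do.call(rbind, lapply(pop$ground_truth, function(g) {
    if (nrow(g$events) == 0) return(NULL)
    cbind(group = group, roi_id = g$roi_id, g$events)
  }))
}
write.csv(rbind(gt_table(pop_a, "A"), gt_table(pop_b, "B")),
          file.path(out, "ground_truth_events.csv"), row.names = FALSE)

# a small rendered field of view for the image-based pipeline
stack_pop <- generate_population(9, event_count_mean = 2, seed = seed + 2L,
                                 protocol = protocol, duration = 400,
                                 noise_sd = 0.04)
layout <- expand.grid(row = c(20, 50, 80), col = c(20, 50, 80))
layout$radius <- 7
cal <- generate_calcium_stack(stack_pop$traces, layout, c(100, 100),
                              seed = seed + 3L, protocol = protocol)
write_stack_tiff(cal$stack, file.path(out, "calcium_stack.tif"))
write_manifest(list(seed = seed, n_cells = 9, image_shape = c(100, 100),
                    frame_interval = 1, control_time = 60, drug_time = 120),
               file.path(out, "calcium_stack_manifest.json"))

# contraction: 80 cells, mean drug contraction 20%, no control response
set.seed(seed + 4L)
areas <- cbind(s1 = round(runif(80, 700, 1300)))
areas <- cbind(areas,
               s2 = round(areas[, "s1"] * (1 - rnorm(80, 0, 0.01))),
               s3 = round(areas[, "s1"] * (1 - rnorm(80, 0.20, 0.05))))
gts <- lapply(1:80, function(i) contraction_ground_truth(i, areas[i, ]))
seqs <- generate_contraction_sequence(gts, seed = seed + 5L, jitter = 1,
                                      noise_sd = 40)
invisible(tiff::writeTIFF(lapply(seqs$frames, function(f) pmin(f / 65535, 1)),
                          file.path(out, "contraction_states.tif"),
                          bits.per.sample = 16))
write.csv(data.frame(cell_id = 1:80, areas,
                     true_delta_control = sapply(gts, `[[`, "true_delta_control"),
                     true_delta_drug = sapply(gts, `[[`, "true_delta_drug")),
          file.path(out, "ground_truth_contraction.csv"), row.names = FALSE)

cat("simulated: 2 trace populations (n = 400 ROIs each),",
    "1 calcium stack (9 cells, 100x100 px, 401 frames),",
    "1 contraction sequence (80 cells)\n")
cat("outputs in", out, "\n")
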