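# smcquant

Automated quantification of vascular smooth-muscle-cell (vSMC) function
from fluorescence image sequences, for labs comparing cell sources or
differentiation protocols by their functional phenotypes rather than by
marker expression alone. The package covers the two standard assays and
the statistic that compares their outputs:

* **Intracellular Ca²⁺ release** — detection of active regions of
  interest (ROIs) above statistical noise (p < 0.01) in a Fluo-4
  recording, F/F₀ trace extraction, event detection, classification into
  a main peak (MP: first release within ~100 s of vasoconstrictor
  addition) and secondary peaks (SPs), and kinetic parameters measured at
  the half-maximum level: time to peak, decay, and duration (FWHM).
* **Contraction** — segmentation and tracking of calcein-loaded cells
  across pre-stimulus, post-control and post-drug states, with per-cell
  relative area change
  (ΔS/S)ᶜᵒⁿᵗʳᵒˡᵢ = (S1ᵢ − S2ᵢ)/S1ᵢ and (ΔS/S)ᵈʳᵘᵍᵢ = (S2ᵢ − S3ᵢ)/S2ᵢ.
* **Population comparison** — normalized histograms of any per-ROI or
  per-cell measurement compared with the divergence statistic
  D = ½ Σᵢ |Aᵢ − Bᵢ| (total-variation form; 0 = identical, 1 = disjoint),
  categorized low / moderate / high with measurement-specific ranges.

A seeded synthetic-data generator produces ground-truth-annotated traces,
Ca²⁺ image stacks and contraction sequences, so the whole chain is
testable without microscope data. See the methods vignette
(`vignettes/smcquant-methods.Rmd`) for the models, parameter defaults and
numerical choices.

## Worked example

Simulate a small field of view and run the Ca²⁺ pipeline end to end:

```r
library(smcquant)

protocol <- stimulus_protocol(control_time = 60, drug_time = 120)
pop <- generate_population(9, event_count_mean = 2, seed = 2028,
                           protocol = protocol, duration = 400,
                           noise_sd = 0.04)
layout <- expand.grid(row = c(20, 50, 80), col = c(20, 50, 80))
layout$radius <- 7
field <- generate_calcium_stack(pop$traces, layout, c(100, 100),
                                seed = 2031, protocol = protocol)

res <- run_calcium_pipeline(field$stack)
length(res$rois)                     # 7   active ROIs detected
res$n_total                          # 9   cells counted in the field
res$responding_fraction              # 0.7777778
table(res$events$label)
#> MP SP
#>  7  5
mp <- subset(res$events, label == "MP")
round(summarize_distribution(mp$time_to_peak)$median, 1)   # 10.3 s
```

Seven of the nine simulated cells fired at least one Ca²⁺ release after
drug addition; the detector finds exactly those seven, counts all nine
resting cells for the denominator, and the MP time-to-peak median matches
the generator's log-normal (median 10 s) within sampling error.

Compare two populations:

```r
hp <- build_histogram_pair(c(0, 1, 2, 3), c(10, 11, 12, 13), n_bins = 8)
d_metric(hp$a, hp$b)                 # 1  (disjoint support)
classify_d(0.47, "ca_kinetics")      # "high"
```

The analysis scripts under `analysis/` run the full simulated study:
`01_simulate.R` generates two trace populations with different kinetics
plus rendered image data, `02_calcium.R` and `03_contraction.R` run the
two assay pipelines on the rendered images, and `04_compare.R` builds the
D-value comparison table. Outputs (CSV tables, JSON manifests, PNG
figures) land under `results/`.

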