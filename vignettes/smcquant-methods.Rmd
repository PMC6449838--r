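---
title: "Quantifying calcium release and contraction in smooth-muscle-cell imaging"
author: "smcquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying calcium release and contraction in smooth-muscle-cell imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smcquant)
```

## The measurement problem

Vascular smooth muscle cells respond to vasoconstrictor agonists
(endothelin-I, carbachol, angiotensin II) with two measurable phenotypes:
a transient rise of intracellular Ca²⁺, visible as a fluorescence increase
of a Ca²⁺ indicator such as Fluo-4, and a contraction, visible as a
decrease of the cell's projected surface area in a calcein-loaded image.
Both phenotypes are heterogeneous across a population of cells, so the
informative output is not a single mean value but a population histogram
of per-cell measurements — and the scientific question is usually whether
two such histograms (two cell sources, two differentiation protocols, two
stimuli) differ.

`smcquant` implements the full chain: detection of active regions of
interest (ROIs) in an image sequence, F/F₀ trace extraction, Ca²⁺ event
detection and classification, half-maximum kinetic parameterization,
cell segmentation/tracking for contraction, and a divergence statistic on
population histograms. A seeded synthetic-data generator produces
ground-truth-annotated inputs so every stage is testable without
recordings.

## Recording model and protocol

A recording is a `time_series_stack`: frames × height × width intensities,
a frame interval, and a `stimulus_protocol` with two time points — a
control addition (medium only) at `control_time` and the vasoconstrictor at
`drug_time`. All frames before `control_time` form the baseline window:
they supply the per-pixel noise statistics for ROI detection and the F₀
for normalization. The recording geometry is configuration, not a claim:
the defaults used throughout (1 frame/s, recordings of 240–600 s, control
at 60 s, drug at 120 s) were chosen once as typical for wide-field Ca²⁺
imaging of adherent cells at desk scale.

## ROI detection above statistical noise

A pixel is called active when its temporally smoothed intensity exceeds
its own baseline mean by more than $z_{1-\alpha}$ baseline standard
deviations at any frame from the control addition onward; α defaults to
0.01 ("above statistical noise, p < 0.01"). Active pixels are grouped into
4-connected components, components smaller than `min_size` (default 9 px)
are dropped, and ROI ids are assigned in raster order of their centroids
so runs are deterministic.

Numerical choices worth stating:

* **Baseline statistics come from the unsmoothed frames**, while the test
  statistic is the 3-frame moving average. Smoothing reduces the noise
  standard deviation by roughly $\sqrt{3}$, so the per-pixel-frame flag
  rate is conservative — well below the nominal α. The Monte Carlo
  calibration in the test suite verifies the rate stays at or below α on
  pure-noise stacks.
* **Per-pixel vs per-ROI thresholding.** Whether the original analyses
  thresholded single pixels or candidate ROI traces is not recoverable;
  both are exposed here (`detect_rois` per pixel, `detect_events` per
  trace) with the per-pixel rule as the spatial default.
* Cell-wide coherent fluctuations (the whole footprint flickering
  together) can push a resting cell's pixels over the threshold in the
  same frame and create a small spurious ROI. This is a property of any
  per-pixel rule under spatially correlated noise; downstream event
  classification marks such ROIs non-responding.

The total number of cells in a field of view — the denominator of the
responding fraction — is counted on the mean of the baseline frames with a
global Otsu threshold, where every loaded cell sits at its resting
brightness.

## F/F₀ normalization and event detection

Each ROI's trace is the per-frame mean raw intensity over its pixel set.
F₀ is the mean over the baseline window, so the normalized trace has
resting level 1 and is invariant to uniform intensity rescaling (camera
gain, illumination). Events are local maxima of the 3-frame-smoothed
normalized trace above

$$1 + z_{1-\alpha}\,\mathrm{cv},$$

where cv is the coefficient of variation of the normalized trace in its
baseline window. Two maxima count as separate events only when the
smoothed trace dips below the half-maximum of the lower one between them;
otherwise they merge into the larger peak. A retained event must also
rise above its preceding valley by at least $z_{1-\alpha}\mathrm{cv}$ —
a prominence requirement. Without it, noise ripples riding on the slowly
decaying tail of a large transient (which keeps the absolute level above
threshold for tens of seconds) register as extra releases; with it, the
residual false events are the nominal family-wise false positives of the
per-frame rule, a few percent of traces per recording, which the test
suite measures and bounds. A numerical floor of $10^{-9}$ on the
threshold and the prominence keeps exact-arithmetic ripple on noiseless
traces from registering as signal.

## Main and secondary peaks

The main peak (MP) of an ROI is the first Ca²⁺ release whose onset falls
within the MP window (default exactly 100 s, configurable) after drug
administration. Later events are secondary peaks (SPs), counted when the
ROI has two or more peaks in total. Events with onset at or before
`drug_time` remain unclassified and are excluded from MP/SP statistics.
An ROI whose first post-drug release starts outside the window has no MP
and counts as non-responding; the window rule defines the MP only inside
the window, so this is the only consistent reading, and the per-run log
counts how often it fires. The responding fraction is (ROIs with an MP) /
(total cells in the field of view).

## Half-maximum kinetics

For one event with peak value $(F/F_0)_{max}$, the half-maximum level is
$(1 + (F/F_0)_{max})/2$: the resting level is fixed at 1 because F₀
normalization defines it, not re-estimated per event. Time to peak is the
interval from the last upward half-max crossing to the peak; decay is the
interval from the peak to the first downward half-max crossing; duration
is their sum — the full width at half maximum, anchored at the half-max
level on both sides. Crossings are located by linear interpolation between
frames. The peak apex is refined to sub-frame resolution by intersecting
the local rise and fall segments around the maximum sample (falling back
to the sample itself when the local geometry is not peak-like, as in heavy
noise); without this refinement a pulse vertex falling between frames
biases the half-max level and can push the decay error just past one frame
interval for fast-rise/slow-decay pulses. With it, noiseless recovery is
exact for triangular pulses and within interpolation convexity error
(≪ 1 frame) for exponential tails.

If the trace never re-crosses half-max before the next event's
inter-event minimum or the recording end, the decay is censored: decay and
duration are dropped from histograms rather than guessed. `duration =
time_to_peak + decay` holds exactly for all uncensored events by
construction.

## Contraction: segmentation, tracking, ΔS/S

The contraction assay images each field of view in three states:
pre-stimulus, after control (medium) addition, and after the drug.
Segmentation is a global Otsu threshold plus 4-connected labeling;
objects smaller than `min_size` or touching the image border (area
censored by the field of view) are removed. Objects are linked
state-to-state by maximal pixel overlap — adherent cells move little
between states — with ties broken by nearest centroid and then smaller
label; objects without any overlap fall back to nearest-centroid linking,
and the number of such fallbacks is logged. Only cells present in all
three states are measured:

$$\left(\frac{\Delta S}{S}\right)^{control}_i = \frac{S1_i - S2_i}{S1_i},
\qquad
\left(\frac{\Delta S}{S}\right)^{drug}_i = \frac{S2_i - S3_i}{S2_i},$$

with $S1$, $S2$, $S3$ the pixel areas in the three states and $i$ the
track index. Positive values are contraction; negative values (area
increase) are kept. Incomplete tracks are excluded automatically and
counted in the run manifest. Control and drug distributions are
summarized by quartiles with 10th/90th percentile whiskers
(linear-interpolation percentiles, `quantile` type 7) and compared with a
two-sided Mann–Whitney rank test — the distributions are skewed, so a
rank test matches the median/quartile reporting.

## The divergence statistic D

Two population histograms $A$ and $B$ on shared bins are compared with

$$D = \tfrac{1}{2}\sum_{i=1}^{n} |A_i - B_i|,$$

the total-variation form: 0 for identical histograms, 1 for completely
disjoint ones, symmetric, and a metric. The test suite verifies the
total-variation identity — D equals the maximum over all bin subsets of
the probability difference — by brute-force enumeration up to 12 bins.

D depends on the binning, so binning is a mandatory, logged configuration
value: the default is 30 equal-width bins spanning the pooled range of
both samples, upper edge inclusive. When the pooled range is zero the
histogram degenerates to a single bin and D is 0. Both groups of a
comparison must be analyzed under one binning configuration; mismatched
edges are an error, never silently rebinned.

D values are categorized as low / moderate / high with
measurement-type-specific ranges: events within ROI 0.0–0.1 / 0.11–0.2 /
0.21–1.0; Ca²⁺ kinetic parameters 0.0–0.3 / 0.31–0.45 / 0.46–1.0;
contraction ΔS/S 0.0–0.25 / 0.26–0.50 / 0.51–1.0. The printed two-decimal
ranges leave gaps (e.g. between 0.1 and 0.11), so the implementation makes
the intervals half-open at the midpoint of each printed gap (0.105, 0.205,
…): every D in [0, 1] maps to exactly one category, which an exhaustive
grid test confirms. The ranges themselves were calibrated on
intrapopulation replicates not available here; they are configuration
taken as given, not re-derived.

## The synthetic-data generator

The generator is first-class, tested code; its defaults are the study
conditions of the test suite and the analysis scripts.

* **Traces.** Pulses have a linear rise to the peak and, by default, an
  exponential fall whose half-life equals the half-max decay time — the
  simplest family in which time to peak (= rise/2), decay, and duration
  are known in closed form; a triangular fall is available. Gaussian noise
  (default SD 0.05 F/F₀ units, i.e. 5% of baseline) is added on top.
* **Populations.** Per-ROI event counts are geometric with configurable
  mean (the discrete analog of an exponentially distributed count);
  time-to-peak and decay are log-normal (positively skewed), with an
  optional two-component log-normal mixture of time-to-peak to emulate
  bimodal kinetics; peak amplitudes are 1 + log-normal. The first release
  is placed so its half-max onset lands inside the MP window, and
  successive pulses are spaced so each falls below half of the smaller
  neighboring peak before the next begins — the generator models distinct,
  resolvable release events, matching the detector's separation rule.
* **Images.** Ca²⁺ stacks render each trace on a disk footprint scaled to
  a 16-bit camera range (1000 counts per F/F₀ unit) over a dark background
  with Gaussian read noise and integer quantization; footprints may not
  overlap (distinct ROIs are the object of study; overlap resolution is
  out of scope). Contraction sequences render bright ellipses whose areas
  follow the prescribed S1/S2/S3, on a grid with optional centroid jitter
  to exercise tracking; touching ellipses are rejected.
* **Determinism.** Every generator takes a seed; a fixed seed gives
  bit-identical output, and the pipelines are deterministic given their
  inputs, so full runs are byte-reproducible.

What the generator deliberately omits — photobleaching, focus drift,
flow-induced motion, cell division or detachment between contraction
states, spatially varying illumination — bounds what the passing tests
show: they validate the measurement chain under the stated noise model,
not robustness to those artifacts on real recordings.

## Problem sizes and tolerances

The test suite runs at desk scale, chosen so each property is decisive yet
quick: 500 noiseless traces for kinetic recovery (±1 frame tolerance,
100% of uncensored events), populations of 200–1000 ROIs for
distributional recovery, ≥ 10⁵ pixel-frames for false-positive
calibration, 100 rendered cells for contraction recovery (drug median
within the perimeter/area rasterization bound of the prescribed 20%,
control median within ±0.01, rank-test p < 10⁻⁴). Rasterization error of
an ellipse is bounded by its perimeter in pixels, which is the tolerance
used wherever a rendered area is compared with a prescribed one.

## Known limitations

* The ROI detector's per-pixel rule has no spatial multiple-testing
  correction; min-size filtering is the only spatial regularizer.
* Event detection assumes a flat resting level after normalization; slow
  baseline drift would need detrending upstream.
* Tracking assumes cells move little between contraction states; the
  centroid fallback handles displaced cells but large rearrangements of
  similar-sized neighbors can still swap identities (logged, not
  corrected).
* Ca²⁺ concentration calibration, oscillation spectral analysis, and
  dose–response fitting are out of scope.
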