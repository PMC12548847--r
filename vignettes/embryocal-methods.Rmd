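---
title: "Quantifying calcium transient dynamics with embryocal: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying calcium transient dynamics with embryocal: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(embryocal)
library(dplyr)
```

embryocal quantifies cytosolic calcium dynamics in timelapse fluorescence
imaging of peri-implantation (egg-cylinder stage) mouse embryos carrying a
GCaMP6f reporter. The pipeline goes from labelled movies to per-cell traces,
de-trended signals, detected transient peaks, per-cell and per-tissue
summary metrics, unbiased clustering of trace dynamics, kymograph
visualisation, wave-propagation analysis, and scoring of pharmacological
inhibitor experiments. This vignette explains the underlying models, the
parameters that matter, the numerical choices we made where the design was
genuinely open, and what the synthetic-data generator does and does not
emulate.

## The signal model

A cytosolic Ca^2+^ transient appears in a GCaMP6f trace as a fast rise
followed by a slower return to baseline. We model a single transient as

$$f(t) = A\,\bigl(1 - e^{-t/\tau_r}\bigr)\,e^{-t/\tau_d}, \qquad t \ge 0,$$

rescaled so its maximum equals the amplitude $A$ (arbitrary fluorescence
units). The shape is a generic indicator-response kernel: an exponential
binding/rise phase ($\tau_r$, default 2 s) and an exponential
decay/extrusion phase ($\tau_d$). Users do not set $\tau_d$ directly —
the user-facing width parameter is the full width at half maximum (FWHM),
and `calibrate_kernel()` solves for $\tau_d$ by bisection to a tolerance of
$10^{-3}$ s. The default FWHM is 20 s, the duration scale of the transients
this pipeline is designed around.

A recorded trace is modelled as

$$y_t = b + d(t) + \sum_k f(t - s_k) + \varepsilon_t,$$

with a constant baseline $b$, a slow drift $d(t)$ (one low-frequency
sinusoid whose period is at least the trace duration — the simplest trend
that genuinely exercises the de-trender), transient onset times $s_k$, and
i.i.d. Gaussian noise $\varepsilon_t$. The default acquisition emulates a
single mid-sagittal optical section imaged every 5 s for 10 min, giving
121 frames (the frame at $t = 0$ is included; every module shares this
convention).

## The synthetic-data generator

`simulate_embryo_dataset()` draws, for every cell, a Poisson number of
events at its tissue's rate (expected transients per cell per 10 min) and
places them uniformly in time. Four tissue classes are supported: epiblast,
extraembryonic ectoderm (ExE), and the visceral endoderm split into emVE
(over the epiblast) and exVE (over the ExE). The default rates —
epiblast 0.11, ExE 0.48, emVE 0.51, exVE 0.82 — are a *calibration*: they
are chosen so the expected active-cell fractions $1 - e^{-\lambda}$ match
the per-tissue percentages observed in this imaging regime
(about 10/38/40/56%). They are not measured biophysical rates and should
not be quoted as such.

The generator's default noise level (SD 20 on amplitude-100 kernels,
i.e. an amplitude-to-noise ratio of 5) and drift amplitude (20% of the
kernel amplitude) define the study conditions every recovery benchmark in
the test suite runs under.

`simulate_wave_movie()` builds pixel movies of a planar activation front
travelling at constant speed, either down the apical–basal axis of one
columnar cell (intracellular mode, logistic front edge for sub-pixel
localisation) or across the cells of a layout in centroid-distance order
(intercellular mode). `simulate_inhibitor_experiment()` draws per-embryo
whole-embryo transient counts as Poisson with a multiplicative treatment
effect, and `simulate_cluster_benchmark()` mixes quiescent (noise-only)
cells with three periodic archetypes of distinct periods for clustering
recovery tests.

What the generator does *not* emulate: photobleaching, cell movement and
ROI drift, 3-D structure, spatially correlated noise, maternal tissue, and
inter-event dependence (true oscillators are quasi-periodic, not Poisson).
Passing recovery tests on this generator therefore demonstrates that the
analysis recovers the parameters of *this* statistical structure — it does
not certify performance on features of real data the generator lacks.

## De-trending: asymmetric least squares

Raw traces carry slow drift. `als_baseline()` fits a smooth baseline $z$
by iteratively reweighted penalised least squares,

$$\min_z \sum_i w_i (y_i - z_i)^2 + \lambda \sum_i (\Delta^2 z_i)^2,
\qquad w_i = \begin{cases} p & y_i > z_i \\ 1 - p & y_i \le z_i,\end{cases}$$

so positive excursions (transients) barely attract the baseline while the
trend underneath is followed. The banded system is solved with a sparse
Cholesky factorisation; the test suite checks it against a dense reference
solve to $10^{-8}$ relative accuracy.

Defaults: $p = 0.01$ and $\lambda = 10^3$, with up to 10 reweighting
iterations. We chose $\lambda$ by measuring the two requirements that
matter at this sampling regime (121 frames, 5-s interval): a 20-s FWHM
transient must survive, and drifts with periods of minutes must be removed.
At $\lambda = 10^3$ a half-period sinusoidal drift of amplitude 20 is
reduced to about 2 units while a kernel of amplitude 100 keeps 99% of its
height; at $\lambda = 10^5$ the same drift leaves an 11-unit residual.
Stiffer penalties are preferable for much longer traces; $\lambda$ scales
roughly with the fourth power of the number of samples per trend period,
and it is exposed everywhere. De-trending is subtractive by default
(intensity comparisons downstream are in arbitrary units); a
$\Delta F/F$-style divisive option exists but is not the tested path.

## Peak detection

Two interchangeable detectors produce peak-call tables, and every
downstream stage accepts either.

**The deterministic reference detector** (`oracle_detect()`) calls local
maxima of the de-trended trace whose robust z-score exceeds `z_thresh`
(default 3). Its numerical details matter and are all documented on the
function:

* *Noise scale.* The scale is the MAD of first differences divided by
  $\sqrt 2$, not the trace MAD: frame-to-frame differences are insensitive
  to how much of the trace the transients occupy, which otherwise inflates
  the scale and costs sensitivity. The scale is floored at 1% of the
  trace's dynamic range so that in (near-)noise-free traces numerical
  de-trending ripple is not called as peaks.
* *Support.* A transient of ~20 s spans several 5-s frames, so a candidate
  must have at least one adjacent frame above half the threshold. This
  rejects single-frame shot-noise spikes and is what keeps the false-call
  rate on pure-noise traces at the few-percent level; a bare $z > 3$ rule
  over 121 frames would flag ~15% of noise traces.
* *Prominence.* By default a peak must also rise `z_thresh` robust SDs
  above its surrounding dip, which suppresses secondary bumps riding on
  the decay tail of a real transient.
* *Apex refinement.* Noise shifts the raw argmax by a frame; calls are
  relocated to the maximum of a 3-point moving average within one frame,
  and the minimum separation (default 3 frames, greedy by height) is
  re-enforced afterwards.

**The learned detector** (`train_detector()` / `detect_peaks()`) is a
small 1-D convolutional network that scores, for a symmetrical window of
$N = 35$ frames, the probability that a transient peak sits at the window
centre — the training target is the idealized trace that is nonzero only
at peak frames (`make_idealized_trace()`). The architecture is two
convolution layers (kernels 7 and 5, with 8 and 16 channels), a
position-sensitive flatten, and a sigmoid head; it is implemented directly
in R with im2col matrix products, manual backpropagation and Adam, and
trains on a CPU in seconds. The head is deliberately *not* globally
pooled: pooling would make the network translation-invariant and unable to
distinguish a centred peak from an off-centre one, which is the task.
Windows are taken on traces scaled to robust noise units; positives are
windows centred within ±1 frame of a labelled peak; negatives are sampled
elsewhere at 6 per positive (background windows dominate at detection
time, and a moderate excess of negatives keeps the false-call rate down).
Training is deterministic under a fixed seed. At detection time the
per-frame probability trace is thresholded (default 0.5; 0.8 is the
high-precision operating point used in the recovery benchmark), local
maxima are kept with minimum separation, and calls are placed on the trace
apex with the same 3-point refinement as the reference detector so the two
paths share one localisation convention.

Event-level benchmarks match a call to a truth event within ±1 frame
(`event_match_stats()`); unmatched calls are false positives.

## Per-peak and per-tissue metrics

For each called peak, `peak_events()` measures extent at half peak height:
the start is the last frame before the rising trace reaches half, the end
is the first frame after the falling trace drops below half, and the
duration is their difference. Half-crossings are searched only within the
inter-peak interval; a peak at a trace boundary or with an unresolved
crossing is flagged truncated and reports no duration. The reference level
for "half height" is configurable and recorded: the default is zero (the
de-trended trace is zero-baselined by construction), with inter-peak
minimum and inter-peak median as alternatives.

A property worth understanding: because start and end are frame-quantised
(a floor and a ceiling on the true crossing times), a pulse of true width
$W$ measures between $W$ and $W + 2\Delta$ at frame interval $\Delta$,
with expectation close to $W + \Delta$; under noise, the first-below-half
walk on the shallow decay adds a further positive delay of a frame-fraction.
The acceptance script measures this directly: 20-s FWHM kernels at 5-s
sampling and amplitude-to-noise 5 yield a mean measured duration of about
26–27 s (24.9 s noiselessly). This is a property of the measurement rule,
not a detector defect, and is the package's known bias for this metric.

`summarize_cells()` reports per cell the peak count, mean peak intensity
(de-trended scale), mean duration, and the oscillation period as the mean
peak-to-peak distance — defined only for cells with at least two peaks and
`NA` otherwise. `summarize_tissues()` aggregates per tissue, including the
percentage of active cells (≥ 1 transient) via `percent()`, which rounds
to one decimal as all reported rates do. The emVE is not subdivided into
DVE and non-DVE.

## Unbiased clustering of trace dynamics

Similarity between two traces is the largest positive value of their
cross-correlation over all integer lags, after mean subtraction and L2
normalisation — tolerant to misalignment in peak times, invariant to
positive affine rescaling, and clipped at zero (only positive correlation
counts). Constant traces are defined to have similarity 1 with each other
and 0 with anything else. `similarity_matrix()` computes all pairs with
lag-shifted matrix products.

Clustering runs on the distance $1 - s$ with a hierarchical density-based
method implemented in `hdbscan_clusters()`: core distances at
`min_samples` neighbours define a mutual reachability distance, single
linkage on that metric gives the density hierarchy, the hierarchy is
condensed by discarding splits whose smaller side is below
`min_cluster_size`, and clusters are extracted by excess-of-mass stability
with the root excluded whenever any other cluster exists. Points in no
selected cluster form the outlier class. On a two-blob-plus-scatter
geometry the implementation reproduces the partition of the scikit-learn
HDBSCAN reference exactly (see the clustering tests).

`cluster_traces()` wires the pieces together in two modes. Global mode
pools all embryos, z-scores traces per embryo first (embryos differ in
dynamic range), and keeps the outlier class as one additional cluster —
asynchronous spikers are too dissimilar pairwise to form a core cluster
but are a biologically meaningful group. Per-embryo mode min–max
normalises within each embryo and keeps the native outlier flag. Cluster
ids are renumbered in ascending order of each group's mean transient
count, so cluster 0 is always the most quiescent. Defaults
`min_cluster_size = 20` and `min_samples = 10` suit the ~1,000-cell scale.

## Kymographs

`render_kymograph()` stacks traces as an image — one row per cell, one
column per time point, magma colours. Min–max mode normalises per embryo
with embryo-wide extrema and colours over [0, 1]; global z-score mode
colours the positive value range [0, 2] (negative z clips to 0, values
above 2 clip to 2). Rows are ordered by a stable sort on (cluster id,
first-peak time); rows without peaks follow the peaked rows of their
cluster in input order. The exported numeric matrix is the normalized,
row-permuted trace set without clipping — clipping is purely a colour
mapping — so tests compare matrices, never pixels. Rendering is a pure
function of its inputs.

## Spatiotemporal flow and wave speed

`binarize_signal()` thresholds a movie at mean + 0.5 SD over all pixels
and frames, restricting motion analysis to clear signal.
`orient_vertical()` rotates an embryo so the first principal axis of its
cell centroids is vertical with the ExE centroid mean on top, making flow
maps comparable across embryos; an isotropic centroid cloud (eigenvalue
ratio below 1.05) is an error, not a guess.

`track_flow()` is motion-sensing superpixel tracking: a regular grid of
seeds (default ~200) is advected frame to frame by a local displacement
estimate, masked to signal regions, and the mean temporal flow map is the
per-seed average displacement. Two displacement backends mirror the two
regimes: zero-normalized cross-correlation block matching (default;
robust to the large frame-to-frame displacements of fast waves and to the
gain/offset changes a blinking reporter produces — a patch whose best
correlation is below 0.5 yields no vector, so intensity change without
coherent motion produces no flow), and an iterative Lucas–Kanade solve for
smooth sub-pixel motion. Sub-pixel refinement is parabolic; ties prefer
the smallest displacement.

Wave speed is estimated independently of tracking: `front_positions()`
localises the half-max crossing of the advancing front in each frame by
linear interpolation along the axis, and `estimate_wave()` regresses front
position on time; the speed is the absolute slope, the direction label
follows its sign along the anatomical axis, and at least three localised
fronts are required. On synthetic intracellular waves sampled at
0.5 s/0.5 μm this recovers generator speeds across 1–20 μm/s to well
within 15% (sub-1% in the tested configurations).

## Inhibitor experiments

`count_transients()` totals detected peaks over all cells of an embryo
timelapse. The inhibitor protocol uses short 2-min, 10-s-interval movies
(13 frames) — far shorter than the classifier's 35-frame window, where
edge padding would dominate — so the reference detector is the default
there and a frame-interval mismatch with a supplied classifier falls back
with a warning. `compare_groups()` is one-way ANOVA plus Tukey's HSD on
all pairs (studentized range distribution), via `stats::aov()` and
`stats::TukeyHSD()`; the tests verify the adjusted p-values against a
direct studentized-range computation and the F-test's type-I error rate
under the null. `score_migration()` calls distal visceral endoderm (DVE)
migration from the reporter-domain centroid track in oriented coordinates:
migrated if the final angular displacement from the distal pole reaches
30° (a configurable stand-in for visual scoring, validated only on
synthetic tracks; the ≥ convention applies at the boundary).
`summarize_rates()` reports migration percentages and per-condition,
per-timepoint mean counts with per-embryo baseline deltas, preserving the
paired design.

## Problem sizes and determinism

The shipped tests and the acceptance script run at desk scale, chosen to
finish in minutes on one CPU while keeping Monte-Carlo standard errors
small relative to the tolerances they check: 500 traces for duration
recovery, 60 training and 150 held-out traces for the detector benchmarks,
14 embryos × 60 cells (×10 seeds) for clustering recovery, 500 synthetic
embryos for inhibitor-effect recovery, 1,000 replicates for the ANOVA
type-I calibration, and 5,000 cells for the Poisson active-fraction law.
All randomness flows through explicit seeds; identical seeds give
bit-identical traces, models and pipeline outputs.

## Known limitations

* The half-peak duration rule is frame-quantised and upward-biased by
  about one frame interval plus a noise-dependent term (see above); at
  5-s sampling a 20-s transient measures ~25–27 s. Compare durations only
  within a fixed frame interval.
* The detector pair is tuned for the 5-s/10-min regime; transferring the
  classifier across frame intervals requires retraining by design.
* Static ROI labels are assumed; moving cells are not re-segmented, and
  no motion correction is attempted before trace extraction.
* The simulator's Poisson event model has no refractoriness; real
  oscillators are quasi-periodic, so period-recovery results on synthetic
  data are about arithmetic, not biology.
* Block-matching flow reports no vector where the patch lacks structure;
  flow maps are therefore sparse in flat image regions, which is the
  correct behaviour for signal tracking but differs from dense optical
  flow.
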