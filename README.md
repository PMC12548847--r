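# embryocal

Quantification of cytosolic calcium (GCaMP6f) transient dynamics in
timelapse fluorescence imaging of peri-implantation mouse embryos, for
developmental biologists and imaging analysts who need a reproducible,
tested pipeline from labelled movies to publication-grade summary
statistics.

At the egg-cylinder stage, cells of the epiblast, extraembryonic ectoderm
(ExE) and visceral endoderm (emVE/exVE) show spontaneous cytosolic Ca²⁺
transients — a fluorescence rise followed by return to baseline — as well
as repeated transients (oscillations) and multicellular waves. embryocal
implements the full quantification chain:

- **Trace extraction** — per-cell mean ROI intensity from multi-page TIFF
  movies and integer label images (`extract_traces()`).
- **De-trending** — asymmetric least squares baseline removal: minimise
  Σ wᵢ(yᵢ − zᵢ)² + λ Σ(Δ²zᵢ)² with asymmetric weights (p where y > z,
  1 − p otherwise), solved with a sparse banded factorisation
  (`detrend_traces()`).
- **Transient peak detection** — a deterministic robust-z reference
  detector (`oracle_detect()`) and a small 1-D CNN classifier over
  symmetrical 35-frame windows, trained on idealized traces that are
  nonzero only at peak frames (`train_detector()`, `detect_peaks()`);
  either feeds every downstream stage.
- **Metrics** — per-peak half-height start/end times and durations,
  per-cell peak counts, mean intensities, and oscillation period as the
  mean peak-to-peak distance; per-tissue active-cell percentages
  (`transient_events()`, `summarize_cells()`, `summarize_tissues()`).
- **Unbiased clustering** — trace similarity as the largest positive
  cross-correlation over all lags, hierarchical density-based clustering
  (HDBSCAN-style, implemented in R) on 1 − s, per-embryo and global modes
  with outlier-as-cluster, and activity-ordered labels
  (`cluster_traces()`).
- **Kymographs** — rows = cells, columns = time points, magma colours,
  embryo-wise min–max or z-score normalisation, stable (cluster,
  first-peak) row order (`render_kymograph()`, `autoplot()`).
- **Flow and wave speed** — mean + 0.5 SD binarisation, PCA-based embryo
  orientation (long axis vertical, ExE top), superpixel signal tracking
  with block-matching or Lucas–Kanade displacement backends, and wave
  speed as the regression slope of the sub-pixel half-max front position
  on time (`track_flow()`, `wave_speed_from_movie()`).
- **Inhibitor experiments** — whole-embryo transient counts across
  baseline/treated/recovery timepoints, one-way ANOVA with Tukey HSD, and
  angular-displacement DVE-migration scoring (`count_transients()`,
  `compare_groups()`, `score_migration()`, `summarize_rates()`).
- **Synthetic data with ground truth** — a generator for embryo trace
  sets (Poisson events per tissue, calibrated GCaMP-like kernels, drift,
  noise), wave movies, clustering benchmarks and inhibitor experiments,
  so every stage has parameter-recovery tests (`simulate_*()`).

Everything is tidyverse-native: trace tables are long tibbles
(`embryo_id, cell_id, tissue, frame, time_s, intensity`), stages chain
with the pipe, fitted objects support `tidy()`/`glance()`, and result
objects have `autoplot()` methods.

## Worked example

```r
library(embryocal)
library(dplyr)

layout <- simulate_layout(seed = 1)                     # stylised egg cylinder
sim    <- simulate_embryo_dataset(sim_config(seed = 1), layout, "demo")

traces <- detrend_traces(sim$traces)                    # + baseline, detrended
peaks  <- detect_transients(traces)                     # reference detector
events <- transient_events(traces, peaks)               # half-peak measures
cells  <- summarize_cells(events, cells = distinct(traces, embryo_id, cell_id, tissue))
summarize_tissues(cells)
#> # A tibble: 4 × 8
#>   tissue   n_cells n_active percent_active mean_n_peaks mean_period_s mean_duration_s mean_peak_intensity
#>   <chr>      <int>    <int>          <dbl>        <dbl>         <dbl>           <dbl>               <dbl>
#> 1 ExE           31       15           48.4        0.677          216.            25.9                127.
#> 2 emVE          15        9           60          0.667          205             22.8                141.
#> 3 epiblast      23        0            0          0               NA             NA                   NA
#> 4 exVE          12        7           58.3        0.667          350             25                  127.
```

The tissue summary reads: of 31 simulated ExE cells, 15 (48.4%) showed at
least one transient; active cells averaged ~0.7 transients in 10 min with
a mean oscillation period of ~216 s, a mean half-peak duration of ~26 s
(a 20-s kernel plus the one-frame quantisation bias of the half-height
rule — see the methods vignette), and a mean de-trended peak intensity of
~127 AU. The quiescent epiblast has no period or duration to report.

Wave-speed estimation from a synthetic apical→basal wave movie:

```r
wave <- simulate_wave_movie(15.41, noise_sd = 3, seed = 7)   # 40-µm cell
wave_speed_from_movie(wave$movie)
#> # A tibble: 1 × 5
#>   speed_um_s direction    duration_s n_points r_squared
#>        <dbl> <chr>             <dbl>    <int>     <dbl>
#> 1       15.4 apical_basal          2        5     1.000
```

`run_pipeline(pipeline_config(seed = 1), out_dir = "run1")` executes the
whole chain on synthetic data and writes every stage table as CSV plus a
kymograph PNG and a provenance record; identical configs and seeds give
byte-identical CSVs.

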