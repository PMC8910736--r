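# carbonylr

Untargeted profiling of **reactive carbonyl compounds (RCCs)** — aldehydes,
ketones and oxo-acids arising largely from lipid peroxidation and sugar
autoxidation — measured by LC-MS as hydrazone derivatives of
**7-(diethylamino)coumarin-3-carbohydrazide (CHH)**. The package is aimed at
metabolomics analysts working with derivatization-based carbonyl assays who
need to go from an integrated feature table (retention time, m/z, per-run
peak areas) to a defensible list of differentially abundant carbonyls.

The central problem it solves: CHH derivatives are not stable on the
autosampler timescale. Over a 24 h batch, individual derivatives may gain
signal (solvent evaporation), lose it steadily (degradation), or hold
steady and then collapse. Left uncorrected, this time-dependence inflates
within-group variance and biases fold changes, hiding real regulation.

## What it does

**Annotation (hydrazone mass arithmetic).** A CHH derivative cation is
`RCC + C14H17N3O3 − H2O + H+`, i.e. the neutral carbonyl plus the
`C14H16N3O2` scaffold. For a cation composition with element counts
*n<sub>e</sub>*,

&nbsp;&nbsp;*m/z* = Σ<sub>e</sub> *n<sub>e</sub>* *M<sub>e</sub>* − *m<sub>e</sub>*,&nbsp;&nbsp;&nbsp;
ppm error = (*m/z*<sub>calc</sub> − *m/z*<sub>obs</sub>) / *m/z*<sub>calc</sub> × 10⁶,

with monoisotopic atomic masses *M<sub>e</sub>* and the electron mass
*m<sub>e</sub>* subtracted for the +1 charge. Composition candidates within
a ppm tolerance (default 3) are enumerated exhaustively under the
constraint that the coumarin scaffold atoms are present; MS/MS spectra are
screened for the diagnostic fragments at m/z 244.1 / 262.1 and for neutral
losses (H2O, NH2, N2H4, CO2, CH2O2).

**QC-based stability correction.** Pooled QC injections every 255 min trace
each derivative's intensity over the batch. Per feature, the QC series is
MinMax-scaled to [−2, 2] and clustered by shape (k-means with Euclidean,
DTW, or DTW-barycenter-averaging metrics). The cluster fixes the model
family — linear or two-segment piecewise-linear — and the model *f(t)* is
then refit on the feature's own raw QC areas. Every run injected at time
*t* gets the correction factor

&nbsp;&nbsp;*c*(*t*) = *f*(*t*<sub>ref</sub>) / *f*(*t*),&nbsp;&nbsp;*t*<sub>ref</sub> = first QC injection,

clamped to [0.2, 5]; features whose fitted series changes by less than 10%
RSD are "steady" and pass through unchanged. Kinetics types follow the
usual classification: I (linear increase), II (linear decrease), III (slow
decrease, then a rapid drop around 1000 min), steady.

**Differential abundance.** Pooled-variance two-sided t-tests
(df = n₁+n₂−2) between control and treated runs on corrected intensities,
fold changes reported as ratios ≥ 1 with an up/down direction, optional
Benjamini–Hochberg adjustment, Ward hierarchical clustering of the
significant features, volcano/heatmap/density plots.

**Synthetic batches with ground truth.** `generate_batch()` emulates the
assumed data-generating process — four planted kinetics classes
(17/95/37/45 of 194 features by default), log-uniform baselines in
[1e5, 1e8] counts, planted fold changes, multiplicative lognormal noise —
so the whole pipeline is testable end to end without any raw data.

## Worked example

```r
library(carbonylr)

derivative_from_rcc("C3H6O3")                      # glyceraldehyde
#> [1] "C17H22N3O5"
monoisotopic_mass("C17H22N3O5", charge = 1)
#> [1] 348.1554
candidate_compositions(348.1555)
#> # A tibble: 1 × 3
#>   formula       mz    ppm
#>   <chr>      <dbl>  <dbl>
#> 1 C17H22N3O5  348. -0.295

batch <- generate_batch(fold_changes = c(F001 = 2.7, F002 = 2.1), seed = 1)
corr  <- correct_features(batch$features, batch$schedule, seed = 1)
corr
#> <rcc_correction> 194 features | 5 clusters ( euclidean ) | kinetics: I:17, II:95, III:37, steady:45
#>   median QC RSD raw -> 25% corrected -> 4.29%

res <- differential_table(corr$corrected, batch$schedule)
glance(res)
#> # A tibble: 1 × 6
#>   n_tested n_significant  n_up n_down alpha adjust
#>      <int>         <int> <int>  <int> <dbl> <chr>
#> 1      194            11     6      5  0.05 none

dplyr::filter(res, feature_id %in% c("F001", "F002")) |>
  dplyr::select(feature_id, fold_change, direction, p_value, significant)
#> # A tibble: 2 × 5
#>   feature_id fold_change direction  p_value significant
#>   <chr>            <dbl> <chr>        <dbl> <lgl>
#> 1 F001              2.65 up        2.65e-13 TRUE
#> 2 F002              2.08 up        1.09e-11 TRUE
```

Reading: the per-analyte kinetics typing recovers the planted class
composition exactly (17 increasing, 95 decreasing, 37 piecewise, 45
steady); correction flattens the median QC RSD from 25% to 4.3%, i.e. back
to pure measurement noise; and both planted fold changes (2.7× and 2.1×)
are recovered within a few percent and called significant.

`run_pipeline()` chains the same stages from a config list or YAML file and
writes `annotation.tsv`, `correction_report.tsv`, `differential.tsv` and a
`run_info.yaml` stamped with a hash of the configuration.

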