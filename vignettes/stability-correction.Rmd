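---
title: "Derivative-stability correction for carbonyl metabolome profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Derivative-stability correction for carbonyl metabolome profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement and its failure mode

Reactive carbonyl compounds (RCCs) are trapped as hydrazones of
7-(diethylamino)coumarin-3-carbohydrazide (CHH, C14H17N3O3) and profiled by
positive-mode LC-MS. The derivative cation of a neutral carbonyl is the
carbonyl plus the C14H16N3O2 scaffold (CHH − H2O + H⁺); the coumarin moiety
ionizes well and fragments diagnostically at m/z 244.1 and 262.1. All mass
arithmetic in this package runs on monoisotopic atomic masses with the
electron mass (0.00054858 Da) subtracted once for the +1 charge — without
the electron correction the calculated cation m/z values disagree with
high-resolution annotation tables in the 4th decimal.

CHH derivatives, however, are not stable over a measurement batch. A pooled
quality-control (QC) sample injected at regular intervals traces each
derivative's apparent intensity over time; empirically the trajectories
fall into a small number of kinetics shapes: linear increase (type I,
consistent with solvent evaporation), linear decrease (type II, derivative
degradation), slow decrease with a rapid drop after roughly 1000 min
(type III), and no essential change (steady). Uncorrected, this
time-dependence inflates within-group variance for samples randomized
across the batch and can hide genuine regulation.

## The correction model

For each feature (one derivative ion, identified by retention time and
m/z):

1. **QC series.** Peak areas in the QC runs, ordered by injection clock
   time. At the default schedule that is 6 injections at 0, 255, ..., 1275
   min.
2. **Scaling.** MinMax scaling to [−2, 2] per feature, so that clustering
   compares *shapes*, not amplitudes. A constant series maps to 0.
3. **Shape clustering.** k-means over the scaled series, k = 5 by default
   (configurable), under one of three metrics: Euclidean, dynamic time
   warping (DTW), or DTW with barycenter-averaging (DBA) centroids. DTW is
   the classic dynamic program on squared differences; we report the square
   root of the accumulated optimal-path cost, optionally under a
   Sakoe–Chiba band. The clustering is seeded, runs `n_init = 10` restarts
   and keeps the best within-cluster sum of squared distances, so results
   are reproducible by construction.
4. **Model family from the cluster, parameters from the analyte.** Whether
   the regression for a cluster's members is linear or two-segment
   piecewise-linear is read off the cluster centroid; the parameters are
   then refit on each feature's *raw* QC areas. This split resolves a
   genuine ambiguity — a single cluster-level curve cannot supply
   analyte-specific correction coefficients, while a free per-analyte model
   choice would ignore the cluster structure entirely. The piecewise model
   is a continuous hinge, `y = a + b·t + c·(t − τ)₊`, with the breakpoint τ
   searched over the interior QC times; it is accepted over the linear fit
   only when it improves the BIC and the late slope is at least twice the
   early slope.
5. **Steady call.** A feature whose *fitted* values have a relative
   standard deviation below 10% is steady and gets correction factors of 1.
   The 10% threshold is the usual QC repeatability criterion for this kind
   of assay. The call is made per analyte on raw areas because RSD is
   undefined on scaled (zero-mean) series.
6. **Correction factors.** With fitted curve f(t) and reference time t_ref
   (default: the first QC injection, the observation closest to the
   underivatized truth for degrading analytes), every run injected at time
   t gets the multiplier f(t_ref)/f(t). Factors are clamped to [0.2, 5]
   with a warning — a decaying fit approaching zero would otherwise blow
   up — and a feature whose fitted curve is non-positive anywhere in the
   batch window is flagged uncorrectable and left unchanged.

Corrected intensities then go into a pooled-variance two-sided t-test
(control vs treated, df = n₁+n₂−2), with fold changes reported as ratios
≥ 1 plus a direction. No multiple-testing correction is applied by default,
matching the raw-p reporting convention of the assay this mirrors;
Benjamini–Hochberg is available behind `adjust = "BH"` with the obvious
caveat that the default inflates the family-wise error. A Shapiro–Wilk
p-value on within-group-centred values is reported for information only;
nothing is excluded on its basis (the normality screen in this field is
traditionally a visual density-plot check, and `plot_intensity_density()`
provides exactly that).

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `tol_ppm` | 3 | ppm | annotation gate for composition assignment |
| `intensity_threshold` | 1e5 | counts | inclusion filter, evaluated on QC maxima (QCs pool every sample, so any real feature appears there) |
| `frag_tol` | 0.3 | Da | ion-trap CID spectra are reported to 1 decimal |
| `k` | 5 | – | number of kinetics clusters |
| `metric` | `"euclidean"` | – | see below |
| `n_init` | 10 | – | k-means restarts, best objective kept |
| `steady_rsd` | 10 | % | stability criterion on fitted values |
| `clamp` | [0.2, 5] | – | correction-factor guard rails |
| `t_ref` | first QC time | min | reference state for the correction |
| `alpha` | 0.05 | – | significance level, p ≤ alpha |

**Why Euclidean by default.** All three metrics are implemented and
selectable, and on planted-class validation batches they recover the
drifting classes equally well; the Euclidean metric is the most reliable
overall (it does not let warping absorb the distinction between a uniform
decrease and a late drop) and is orders of magnitude cheaper. Which metric
produced any particular published clustering of this assay is generally
not reported, so the choice is the package's own.

## What the synthetic generator emulates — and what it does not

`generate_batch()` produces the situation the correction assumes:

* a 24 h batch with QCs every 255 min (12 run slots of 21.25 min) and 14
  biological runs (7 control / 7 treated) spread evenly over the batch in
  randomized order. The real assay re-injects each sample in several
  gas-phase-fractionation windows, which is how 14 samples fill 24 h; the
  generator keeps the QC grid and the randomized spread, not the
  fractionation;
* four planted kinetics classes in proportions 17/95/37/45 per 194
  features. Amplitudes are drawn per class: type I total increase 0.6–3×
  baseline; type II total decay 40–90%; type III 5–20% slow decay to a
  breakpoint in 900–1100 min then a drop to 2–30% of baseline; steady
  features have no drift. These draws put the drifting classes in the
  10–85% within-series RSD envelope reported for this assay while keeping
  the classes identifiable, which is what "planted ground truth" requires;
* baselines log-uniform in [1e5, 1e8] counts; group effects as
  multiplicative treated/control ratios (QC pools see the group average);
  multiplicative lognormal noise, CV 5% by default — the repeatability
  scale of a stable QC feature;
* drift shared between a feature's QC and sample runs, since degradation
  and evaporation act on the extract, not on the run type.

Not emulated: chromatographic peak shapes, missing values (off by
default), between-batch effects, isotope patterns, in-source
fragmentation, and — deliberately — any *batch-common* run-to-run effect:
noise is independent across features. That last simplification has a
visible consequence, below.

## What passing tests do and do not show

The test suite demonstrates, on generated batches: exact mass arithmetic
against published cation m/z values; DTW equal to a brute-force
warping-path oracle; DBA with a non-increasing objective; planted-class
recovery by clustering; breakpoint recovery within one QC interval;
self-flattening (QC RSD after correction below before, for essentially all
drifting features); planted fold changes recovered within 10% after
correction; the qualitative corrected-vs-uncorrected contrast (strongly
decaying up-regulated analytes are lost without correction and recovered
with it); and a type-I error at the nominal level on null batches.

Two honest caveats. First, on real data the steady features of a batch
share correlated run-to-run structure, which is why they can form their own
clusters in practice; with independent noise, a MinMax-scaled steady series
is a full-range random shape, so shape clustering cannot assign the steady
class coherently (the per-analyte RSD rule, not the k-means label, is what
identifies steady features for the correction — and it does so exactly on
the validation batches). Second, recovery results on synthetic batches
bound what the pipeline can do when its model is correct; they do not
certify behaviour under model misspecification (non-linear drift within a
segment, RT shifts, co-eluting isomers).

## Numerical choices and degenerate inputs

* Breakpoints are searched on the QC grid only — with 6 QC points a finer
  search is not identifiable.
* BIC is computed as `n·log(RSS/n) + p·log(n)`; RSS is floored at 1e-300 to
  keep exact fits finite.
* Constant series: MinMax maps to the range midpoint; RSD of a zero-mean
  series is reported `NA` with a warning; a zero-variance t-test returns
  t = 0, p = 1.
* Empty k-means clusters are re-seeded with the series farthest from its
  centroid.
* Features with any missing QC value are dropped from the correction (the
  kinetics fit needs the full grid) with a warning; missing sample
  intensities stay missing through the correction.
* Test and validation problem sizes: batches of 194 features × 20 runs for
  pipeline-level checks, 1000 features for the type-I-error check, series
  of length ≤ 6 for the brute-force DTW oracle — sizes at which every
  oracle is exact and the full suite runs in well under a minute.

## Known limitations

* Single-batch design; no between-batch harmonization.
* The correction trusts the QC pool to be representative; analytes absent
  from the pool cannot be corrected.
* LOESS/spline QC-correction variants common elsewhere in metabolomics are
  out of scope — the model family here is the linear/piecewise/steady
  taxonomy that matches observed CHH kinetics.
* Isomer resolution, isotope-pattern scoring and in-source-fragment
  adjudication are not attempted; composition assignment reports the best
  scaffold-consistent candidate by |ppm| and keeps the alternatives
  available via `candidate_compositions()`.
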