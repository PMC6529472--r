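---
title: "Quantifying growth-factor-induced mechanical phenotypes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying growth-factor-induced mechanical phenotypes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mechpheno)
```

## The problem this package addresses

Growth factors such as TGFβ drive epithelial-to-mesenchymal transition in
non-small-cell lung cancer cells, and with it coordinated changes in cell
mechanics: cells become stiffer, more motile in 2D and more invasive in 3D
collagen. Quantifying those changes requires four distinct analysis chains —
optical-stretcher rheology, single-cell track statistics, nucleus detection
in confocal z-stacks, and expression time-course analysis — each with its
own statistical conventions. `mechpheno` implements all four as tested,
reusable functions, together with a synthetic-data module that generates
instrument-like inputs with planted ground truth. Every analysis stage can
therefore be validated by parameter recovery: plant an effect, run the
pipeline, check the estimate.

## Optical-stretcher rheology

A cell suspended between two opposing laser beams elongates along the beam
axis. The measurement records 120 frames over 4 s: 1 s unloaded, 2 s under
load (creep), 1 s after release (recovery). From the stretched-axis diameter
series $L_i(t)$ of cell $i$, the dimensionless strain is

$$\varepsilon_i(t) = \frac{L_i(t)}{L_i(0)} - 1 .$$

**Baseline choice.** The formula divides by $L_i(0)$, literally the first
frame. With realistic contour noise a single-frame baseline injects its
noise into every strain value, so the default baseline is the mean diameter
over the whole 1 s unloaded phase (`baseline = "preload_mean"`);
`"first_frame"` reproduces the verbatim formula. The test suite verifies
that the preload-mean baseline strictly reduces preload strain scatter.

**Smoothing.** Diameter series are smoothed before strain computation with a
centered moving average, default window 5 frames (~0.17 s at 30 Hz) — wide
enough to suppress segmentation jitter, narrow enough not to blunt the creep
onset. A centered window leaves phase boundaries in place; `window = 1` is
the identity. LOESS is available as an alternative.

**Bootstrap averaging.** Cell-to-cell compliance variability is large and
of unknown family, so no parametric model is fit to the population.
Instead, whole cells (never individual frames) are resampled with
replacement, `n_bootstrap = 1000` times by default; each replicate yields a
pointwise mean curve. The reported curve $\varepsilon_{bs}(t)$ is the mean
of replicate means and the confidence band is two pointwise SDs of the
replicate means (~95%). The rigidity statistic is

$$\varepsilon_{\max} = \max_t \varepsilon_{bs}(t),$$

the maximum of the *bootstrap-averaged* curve — not the mean of per-cell
maxima, which would be inflated by frame noise. Per-cell maxima are used
only for the two-sided Mann–Whitney test between conditions (normal
approximation with tie correction; sample sizes here are far beyond the
exact-test regime). A treatment effect is summarized as
$100\,(1 - \varepsilon_{\max}^{treated}/\varepsilon_{\max}^{control})$
percent reduction. Whether published bands of this kind are pointwise or
curve-wise is ambiguous; ours are pointwise, and the coverage test below is
phrased accordingly (fraction of frames covered).

**Segmentation.** Frame stacks are segmented by Otsu threshold and the
largest connected component; the diameter is the component's extent along
the (horizontal) laser axis. A frame with empty foreground aborts with the
frame index, so silent cell loss cannot occur.

## The synthetic creep generator

The instrument data are emulated by a viscoelastic creep model. The default
is a Kelvin–Voigt element — exponential creep toward an equilibrium strain
$\varepsilon_\infty$ with retardation time $\tau$ — with *incomplete*
recovery (default recovered fraction 0.7): creep-and-recovery measurements
of suspended cells typically plateau during load and do not return fully to
baseline within one second. A standard-linear-solid variant (instantaneous
elastic jump) and a power-law (soft glassy) variant are selectable.
Defaults: $\varepsilon_\infty = 0.05$, $\tau = 0.5$ s, measurement noise SD
0.005 — strains of a few percent, consistent with optical-stretcher work on
epithelial lines.

Cell-to-cell variability multiplies $\varepsilon_\infty$ by a lognormal
factor (mean-parameterized, default CV 0.4): strains are positive and
right-skewed, and the lognormal is the standard minimal model for such
heterogeneity. The distributional family is a modeling decision, not a
measured fact. A treatment effect scales $\varepsilon_\infty$ down
multiplicatively and leaves $\tau$ untouched — the simplest mechanism that
produces a pure $\varepsilon_{\max}$ shift, which is what the rigidity
statistic is designed to detect. Because the lognormal is mean-parameterized
and enters linearly, the population-mean curve has a closed form
(`expected_population_curve()`), which is what the band-coverage test
checks against.

What the generator does **not** emulate: optical-force physics and
refractive-index effects (deformability in a real stretcher confounds
stiffness with optical properties), cell-size dependence of the optical
force, segmentation failure modes of phase-contrast imaging, and any
treatment effect on retardation time. Passing recovery tests therefore show
that the statistics recover a planted compliance shift under realistic
sampling noise — not that the instrument model is physically complete.

## 2D migration

Tracks are observed every 30 min for up to `t_max = 48` h. Two per-track
metrics:

* **speed** — total path length divided by tracked time (µm/h). Note that
  coarser sampling shortens the measured path, biasing speed low; the
  generator's tests use fine sampling when validating the ensemble mean.
* **persistence** — net displacement over path length, multiplied by
  $\sqrt{t_{tracked}/t_{max}}$. The square-root factor penalizes short
  tracks, which would otherwise look spuriously persistent; a straight
  full-duration track scores exactly 1, a straight quarter-duration track
  0.5, any closed loop 0.

Tracks with fewer than 3 points are excluded and reported (the retention
cutoff is a configurable choice; published track analyses rarely state
theirs). Box summaries use type-7 (linear-interpolation) quartiles, notches
at $\pm 1.58\,\mathrm{IQR}/\sqrt{n}$, and either Tukey 1.5 IQR whiskers or
5th/95th-percentile whiskers — both conventions appear in the figure styles
this mirrors, so both are implemented and recorded in the output. Condition
comparisons use the two-sided Mann–Whitney test; no specific test is
canonical for migration metrics, and rank tests are the conservative choice
for these skewed distributions. Time-resolved effects are recomputed over
sliding 12 h windows (configurable), with persistence renormalized to the
window length.

The track generator is a persistent random walk: constant per-cell speed
(lognormal, CV 0.3), heading subject to rotational diffusion with
correlation time `persistence_time` (heading-increment variance
$2\,\Delta t/P$, so directional autocorrelation decays as $e^{-t/P}$), and
exponential censoring of track durations. Its limits bracket reality:
infinite $P$ gives straight tracks (persistence 1), vanishing $P$ gives
diffusive scaling (MSD exponent ~1), both verified in tests.

## 3D invasion

Nuclei are detected in confocal-like stacks by Gaussian smoothing (σ = one
nucleus radius, 4 µm default), strict 26-neighborhood local-maxima
detection above a relative intensity floor, and greedy non-maximum
suppression within 2σ — so two blobs closer than ~1σ merge into one
detection, a documented limitation rather than a double count. Voxel size
must be given explicitly; guessing anisotropy silently corrupts depths.

The gel surface is estimated as the mode of the detected z distribution
(surface-seeded cells dominate any realistic assay). A cell is **invaded**
iff its nucleus lies deeper than `z_threshold` below the surface; the
default threshold is 10 µm, about one nucleus diameter, i.e. the nucleus
has fully entered the gel. Published invasion assays rarely print their
threshold; ours is recorded in every summary. The summary reports the
invaded percentage, the invaded-depth list and a fixed-width histogram
(default 20 µm bins) starting at the threshold; condition differences use a
two-proportion test.

The generator plants invaded depths as
$z = \text{front} + \mathrm{Exponential}(\text{scale})$, default front
10 µm and scale 40 µm, with surface cells jittered by a 2 µm Gaussian. The
front offset encodes the same "fully entered" notion as the threshold
default and makes the planted fraction identifiable: thresholding at the
front recovers it up to binomial noise, and depth below the front is
exponential with mean `depth_scale` (memoryless descent — the minimal model
for a depth frequency diagram decaying from the surface). Rendered-stack
round trips (paint Gaussian blobs, re-detect, re-classify) validate the
whole chain; nuclei deeper than the rendered volume are simply not imaged,
as in a real z-stack of finite depth.

## Expression time courses and enrichment

Input is an RMA-normalized log2 intensity matrix over the 11-point design
0, 0.5, 1, 2, 4, 6, 8, 12, 18, 24, 48 h (raw-array processing is out of
scope). Replicates are mean-averaged per timepoint on the log2 scale and
fold changes are taken against t = 0; timepoints missing for a gene are
linearly interpolated on the time axis and flagged.

Each gene's fold-change series is smoothed by Gaussian-process regression
with an RBF kernel. Hyperparameters (signal variance, length scale, noise
variance) are fit per gene by marginal-likelihood maximization (L-BFGS-B on
log parameters, time rescaled to [0, 1]); the noise SD is bounded below by
`noise_floor = 0.05` log2 units so that near-interpolating fits cannot
chase replicate noise. Optimizer failure falls back to a fixed length scale
of half the time span, with a warning. The GP posterior mean is a shrinkage
estimator: on pure noise it contracts toward zero (tested), on clean trends
with a tiny floor it interpolates (tested).

A gene is called **up** if its smoothed log2 fold change reaches +1.0
anywhere in the time course, **down** at −1.0; a gene crossing both
thresholds appears in both lists by design. The threshold-on-smoothed-curve
criterion is explicit and configurable because the exact significance
criterion behind published up/down calls of this kind typically lives in
supplementary tables; consequently this package reproduces printed set
*fractions* (e.g. 210 of 812 = 26%), never the absolute DE counts.

Gene-set enrichment uses the hypergeometric upper tail
$P(X \ge k)$ for $X \sim \mathrm{Hyper}(N, K, n_{DE})$, evaluated by
log-space summation of `lchoose` terms (stable out to genome-scale counts).
Tests verify it against brute-force enumeration for all small universes
($N \le 30$, relative error $< 10^{-12}$) and against `phyper` as an
independent cross-check. The reported `fraction_of_set` is $100\,k/K$,
rounded to whole percent in printed reports.

The expression generator plants a configurable DE fraction with smooth
saturating profiles $\pm\,\text{effect}\,(1 - e^{-t/t_{1/2}})$ (per-gene
response time 2–12 h) and Gaussian log2 replicate noise — it emulates
temporal smoothness and replicate scatter, not probe effects,
heteroscedasticity across intensity, or correlated gene modules, so DE
recovery results speak to the calling criterion, not to array preprocessing.

## Orchestration and determinism

Every generator and resampler takes a mandatory seed and is a pure function
of (parameters, seed); the caller's RNG state is left untouched. The
config-driven `run_pipeline()` derives per-stage child seeds from one
global seed, writes per-stage artifacts plus a manifest of MD5 checksums,
and `write_report()` renders the headline numbers. Identical config and
seed give identical checksums, which the tests assert.

## Problem sizes used in validation

The shipped tests and the acceptance script run at the study's scale where
that is what is being claimed — 300 cells per condition and 1000 bootstrap
replicates for rigidity recovery, 1000 genes with 50 planted DE for
expression recovery, 500 rendered nuclei for the invasion round trip,
100{,}000 bootstrap replicates against the two-cell enumeration oracle —
and at reduced sizes (tens of cells, hundreds of replicates) for structural
checks where scale adds nothing. Band-coverage is averaged over 50
independent simulations.

## Known limitations

* The creep model family is phenomenological; no viscoelastic model is fit
  to real instrument data, and treatment effects on retardation time are
  not modeled.
* $\varepsilon_{\max}$ of a noisy averaged curve is a maximum statistic and
  carries a small upward bias; it largely cancels in condition ratios but
  is not corrected.
* The spot detector is a re-specification of commercial spot detection as
  Gaussian-smoothed local maxima; it merges nuclei closer than ~1σ and has
  voxel-level localization, so depth histograms inherit ±1 voxel blur.
* Confidence bands are pointwise, not simultaneous.
* Enrichment p-values assume an exchangeable universe; no gene-length or
  expression-level bias correction is applied.
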