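# mechpheno

Quantitative analysis of growth-factor-induced mechanical phenotypes in
cancer cells. TGFβ-class growth factors drive lung-cancer cells toward a
stiffer, more motile, more invasive phenotype; `mechpheno` implements the
four analysis chains needed to quantify that shift, plus a synthetic-data
module that generates instrument-like inputs with planted ground truth so
every stage can be validated by parameter recovery.

The four stages:

1. **Optical-stretcher rheology** — from per-cell diameter series
   `L_i(t)` (or rendered frame stacks) to strain curves
   `ε_i(t) = L_i(t)/L_i(0) − 1`, bootstrap-averaged creep-and-recovery
   curves with 95% bands (2× SD of bootstrap sample means), and the
   rigidity statistic `ε_max = max_t ε_bs(t)`. Conditions are compared by
   percent reduction `100·(1 − ε_max,treated/ε_max,control)` and a
   two-sided Mann–Whitney test on per-cell maxima.
2. **2D migration** — per-track speed (path length / tracked time) and
   penalized persistence (net displacement / path length ×
   `√(t_tracked/t_max)`), notched-box summaries
   (notch = ±1.58·IQR/√n) and rank-test comparisons, including sliding-
   window time-resolved analysis.
3. **3D collagen invasion** — nucleus spot detection in z-stacks
   (Gaussian smoothing + local maxima + non-maximum suppression),
   z-threshold classification of invaded cells, invaded percentage and
   depth histograms, two-proportion condition tests.
4. **Expression time courses** — log2 fold changes vs t = 0 with replicate
   averaging, per-gene Gaussian-process smoothing (RBF kernel, marginal-
   likelihood hyperparameters), threshold DE calling, and hypergeometric
   gene-set enrichment `P(X ≥ k), X ~ Hyper(N, K, n_DE)` computed by
   stable log-space summation.

The methods vignette (`vignettes/mechanical-phenotyping.Rmd`) documents the
models, defaults and design decisions; `analysis/01…05_*.R` are narrative
drivers that run each stage on synthetic data and write tables under
`results/`.

## Worked example

Plant a 34% rigidity effect (multiplicative reduction of equilibrium
strain), then recover it with the full pipeline:

```r
library(mechpheno)

prm <- creep_params(cv_between_cells = 0.4)   # lognormal cell variability
pro <- stretch_protocol()                     # 120 frames: 1 s / 2 s / 1 s

ctrl <- simulate_creep_population(prm, pro, n_cells = 300, seed = 101)
trt  <- simulate_creep_population(prm, pro, n_cells = 300, effect = 34,
                                  seed = 102)
compare_rigidity(ctrl$curves, trt$curves, n_bootstrap = 1000, seed = 7)
#> <rigidity_comparison> control vs treated
#>   eps_max: 0.0483 vs 0.0328 -> 32.1% reduction
#>   Mann-Whitney p = 3.29e-30; bands separated at 88/120 frames
```

The control population stretches to a maximum bootstrap-averaged strain of
~0.048 (dimensionless; ~4.8% elongation); the treated population reaches
only ~0.033, a 32% reduction — the planted 34% up to sampling noise at
n = 300 — and the per-cell maxima separate decisively under the rank test.
Running all four stages end to end:

```r
bundle <- run_pipeline(list(stages = c("stretcher", "migration",
                                       "invasion", "expression"),
                            seed = 20260919, out_dir = "results/run"))
cat(write_report(bundle), sep = "\n")
#> == Optical stretcher rigidity ==   ... 33.5% reduction, p = 7.4e-34
#> == Migration: speed ==   median 19.55 -> 28.98 (up), p = 6.9e-40
#> == 3D invasion ==   invaded: 150/500 (30.0%) below 10 um
#> == Expression / enrichment ==   up: 19/185 set genes (10%), p = 5.4e-15
```

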