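# csdconn

Windowed information-theoretic analysis of interhemispheric functional
connectivity around a unilateral **cortical spreading depolarization (CSD)**
— a slowly propagating wave of near-complete cortical depolarization that
shows up in local field potential (LFP) recordings as a large negative DC
shift followed by transient AC abnormalities. The package is aimed at
electrophysiologists analyzing two-channel (left/right homotopic cortex)
LFP/ECoG recordings around a marked event, and at methodologists who need a
fully synthetic, ground-truthed test bed for windowed coupling measures.

## What it computes

For detrended residuals `x` (left) and `y` (right) in nonoverlapping 20-s
windows:

* **Mutual information** (similarity), by the k-nearest-neighbor digamma
  estimator under the max-norm,

  `MI = ψ(N) + ψ(k) − ⟨ψ(n_x + 1) + ψ(n_y + 1)⟩`  (nats, default k = 1);

* **Transfer entropy** (directed influence) in both directions from 3-D
  points `(x_{n+τ}, x_n, y_n)`,

  `TE_{y→x} = ψ(k) + ⟨ψ(n_x + 1) − ψ(n_xy + 1) − ψ(n_xxτ + 1)⟩`
  (default τ = 1);

* **Min–max group statistics**: a post-event window is significant when all
  L recordings lie on the same side of the pooled baseline mean
  (p = (1/2)^L per window), with Bonferroni correction over the K = 29
  windows and the sharper M-consecutive-interval correction
  p′ = ((1/2)^L)^M · ⌈K/M⌉, plus one-sided t tests on baseline means and a
  two-sided Fisher exact test for event incidence.

Preprocessing (moving-average detrend, ±rail ADC-saturation repair,
artifact screening), a synthetic CSD generator with known ground truth, and
analytic validation fixtures (bivariate Gaussian, coupled AR processes with
closed-form MI/TE) are included. See the methods vignette
(`vignettes/csd-connectivity-methods.Rmd`) for the model and all numerical
choices.

## Worked example

```r
library(csdconn)

# estimator vs closed form on a Gaussian fixture
p <- generate_gaussian_pair(0.9, 20000, seed = 11)
mi_ksg(p$left, p$right)        # 0.8276  (theory: 0.8304)

# directed coupling on an AR fixture
ar <- generate_coupled_ar(0.5, 0.5, 20000, seed = 1)
te_ksg(ar$right, ar$left)      # 0.1457  (theory: 0.1348)
te_ksg(ar$left, ar$right)      # 0.0090  (no reverse coupling)

# full pipeline on the default synthetic 8-animal CSD group (~1.5 min)
res <- run_pipeline(run_config(seed = 1))
print(res)
#> <pipeline_result> 8 recordings, K = 29 post windows
#>   mi: below baseline over windows 6-14 (p' = 2.29e-04)
#>   te_l2r: below baseline over windows 7-9 (p' = 2.29e-04)
#>   te_r2l: above baseline over windows 7-12 (p' = 2.29e-04)

plot(res$summary, "mi")        # group dynamics with min-max error bars
```

Reading the output: windows are 20 s, numbered from the induction marker, so
windows 6–14 span 100–280 s — MI falls significantly below its pooled
baseline (0.29 nats) exactly over the configured interhemispheric
decoupling span, for nine consecutive windows (p′ = 2.3 × 10⁻⁴ after the
M = 2 grouped correction). TE from the unaffected (right) to the affected
(left) hemisphere rises significantly over windows 7–12 (120–240 s, the
configured drive span; 2.97-fold over its 0.016-nat baseline), while TE in
the opposite direction shows no elevation anywhere — the directional
signature the min–max machinery is built to detect.

Incidence and arithmetic helpers:

```r
incidence_fisher(5, 8, 13, 14)   # 0.1167
propagation_speed(4.7, 46.8)     # 6.03 mm/min
```

A thin command-line front end is provided at
`inst/cli/csdconn-pipeline.R` (`simulate` and `run-all` subcommands).

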