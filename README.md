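# hetmeta

Random-effects meta-analysis hinges on the between-study variance τ² — the
variance of the true study effects θᵢ around the overall mean μ under the
model

    θ̂ᵢ = μ + bᵢ + eᵢ,   bᵢ ~ N(0, τ²),   eᵢ ~ N(0, σᵢ²),

where the within-study variances σᵢ² are treated as known. When τ̂² = 0,
common practice collapses to a fixed-effect analysis — yet a zero estimate
is very often a detection failure rather than evidence of homogeneity,
especially in meta-analyses of two or three studies, and the resulting
confidence intervals are too narrow. `hetmeta` is built for studying, and
guarding against, exactly this failure mode. It is aimed at biostatisticians
and methodologists who want to compare heterogeneity estimators, and at
meta-analysts who want to test how sensitive their conclusions are to the
choice of method.

The package provides:

* **Twelve τ² estimators** behind one surface (`tau2_estimate()`):
  DerSimonian–Laird (`DL`), its two-step DerSimonian–Kacker refinement
  (`DL2`), a **non-parametric bootstrap** of DL (`DLb`: resample studies
  with replacement, average the truncated estimates — better at detecting
  small but real heterogeneity), a 0.01-floored variant (`DLi`), the Hedges
  variance-component estimator (`VC`) and its two-step refinement (`VC2`),
  maximum and restricted maximum likelihood (`ML`, `REML`; truncated
  fixed-point iterations with convergence reporting), the Sidik–Jonkman
  model-error-variance estimators (`MVa`, `MVb`) and Rukhin's Bayes-type
  estimators (`B0`, `BP`).
* **Pooling**: inverse-variance fixed/random effects (weights
  `1/(σᵢ² + τ̂²)`), Mantel–Haenszel (OR/RR/RD with
  Robins–Breslow–Greenland / Greenland–Robins variances), Peto, and
  **profile-likelihood** intervals that propagate the uncertainty in τ̂².
* **Effect computation** from raw summaries (`compute_effects()`): MD,
  Hedges-g SMD, log OR/RR, RD, log Peto OR, with the documented
  zero-cell continuity rules and rare-event exclusions.
* **A simulation framework** reproducing a standard coverage-study design:
  within-study variances from a scaled χ²(1) law truncated to
  (0.009, 0.6) (mean 0.173), six true-effect distributions (normal, two
  moment-matched skewed shapes, uniform, bimodal, double-spike) with mean
  0.5 and variance τ² ∈ {0.01, 0.03, 0.10}, study sizes uniform on
  [50, 500].
* **Assessment criteria** (`assess_methods()`): mean/absolute bias, the
  percentage of zero τ̂² estimates, coverage of the true effect, and the
  error-interval ratio c (estimated CI width over the width at the true
  τ²), summarised by quartiles.
* **Conclusion-sensitivity machinery** (`run_method_matrix()`,
  `conclusion_crosstab()`): re-analyse a corpus of meta-analyses under all
  methods and cross-tabulate significant/non-significant conclusions
  against the baseline model, stratified by whether heterogeneity was
  detected and modelled.

## Worked example

Six trials with a dichotomous outcome, analysed as log odds ratios:

```r
library(hetmeta)
d <- data.frame(study_id = paste0("s", 1:6), design = "dichotomous",
                a = c(12, 5, 23, 8, 19, 3), n1 = c(120, 60, 200, 90, 150, 45),
                c = c(6, 7, 12, 11, 10, 6), n2 = c(118, 62, 205, 88, 148, 44))
ef <- compute_effects(d, "logOR")
summary(hetmeta(ef, method = "DL"))
```

```
Random-effects meta-analysis (IV pooling), k = 6
  measure: logOR
  tau^2 = 0.1539 (DL)
  pooled estimate = 0.2505, se = 0.2605
  95% CI: [-0.26, 0.7611]   conclusion: NS
  heterogeneity: Q = 8.153 (df = 5, p = 0.148), H^2 = 1.631, I^2 = 38.7%
  study weights (%): 16.07 12.73 23.27 17.18 21.11  9.64
```

The DL estimate finds moderate heterogeneity (I² ≈ 39%), widening the
fixed-effect interval (`hetmeta(ef, method = "FE")` gives se 0.1978 and CI
[-0.063, 0.713]) enough that the pooled log odds ratio stays
non-significant. The bootstrapped variant gives a slightly smaller but
still positive estimate:

```r
hetmeta(ef, method = "DLb", seed = 42)
#>   tau^2 = 0.1078 (DLb)
#>   pooled estimate = 0.2662, se = 0.2439
#>   95% CI: [-0.2118, 0.7443]   conclusion: NS
```

A command-line interface wraps the same functions:

```sh
./exec/hetmeta estimate -i studies.csv --measure logOR --methods DL,DLb,REML
./exec/hetmeta simulate --dist normal --tau2 0.03 --k 10 --reps 1000 --seed 1 -o metas.csv
./exec/hetmeta assess --dist normal,skew_extreme --tau2 0.01,0.1 --k 2,5,10 --reps 1000 -o summary.csv
./exec/hetmeta compare -i corpus.csv --candidates FE,DL,DLb -o crosstab.csv
```

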