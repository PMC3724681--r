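---
title: "Estimating between-study variance: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating between-study variance: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hetmeta)
```

## The model

A two-stage meta-analysis observes per-study effect estimates
$\hat\theta_i$, $i = 1,\dots,k$, with within-study sampling variances
$\hat\sigma_i^2$ treated as known. Under the random-effects model

$$\hat\theta_i = \mu + b_i + e_i, \qquad
  b_i \sim N(0,\tau^2), \quad e_i \sim N(0,\sigma_i^2),$$

the between-study variance $\tau^2$ measures real variation of the true
effects across studies. The pooled estimate is the inverse-variance
weighted mean with weights $w_i^\* = 1/(\hat\sigma_i^2 + \hat\tau^2)$,
standard error $(\sum w_i^\*)^{-1/2}$, and a normal-quantile confidence
interval; $\hat\tau^2 = 0$ collapses this to the fixed-effect analysis.
Everything therefore turns on how $\tau^2$ is estimated — and in small
meta-analyses most estimators return exactly zero much of the time even
when $\tau^2 > 0$, which is the failure mode this package is designed to
study.

## The estimator family

`tau2_estimate()` implements two groups. *Zero-or-positive* methods
truncate negative solutions to zero (the `truncated` flag records this);
*positive-only* methods build in a strictly positive value a priori.

**Moment estimators.** With $w_i = 1/\hat\sigma_i^2$,
$Q = \sum w_i(\hat\theta_i - \hat\theta_F)^2$ around the fixed-effect
estimate $\hat\theta_F$,

$$\hat\tau^2_{DL}
  = \max\!\left(0,\; \frac{Q - (k-1)}{\sum w_i - \sum w_i^2 / \sum w_i}\right).$$

$\hat\theta_F$ is the *respective* fixed-effect estimate — inverse-variance,
Mantel–Haenszel or Peto — so the DL value is method-dependent for
dichotomous approaches (`theta_f` argument). The Hedges variance-component
estimator partitions the unweighted sample variance:

$$\hat\tau^2_{VC} = \max\!\left(0,\;
  \frac{1}{k-1}\sum_i (\hat\theta_i - \bar\theta)^2
  - \frac{1}{k}\sum_i \hat\sigma_i^2\right).$$

The two-step refinements `DL2` and `VC2` feed the step-1 value into the
DerSimonian–Kacker generalized moment equation with weights
$a_i = 1/(\hat\sigma_i^2 + \hat\tau^2_{(1)})$, centred at the
$a_i$-weighted (i.e. step-1 random-effects) mean, and truncate once. We
read "two-step" literally: exactly one refinement step, not iteration to
convergence, and the DL2 centre is the step-1 DL random-effects estimate.

**Bootstrapped DL (`DLb`).** Draw $k$ studies — $(\hat\theta_i,
\hat\sigma_i^2)$ pairs — with replacement, compute the truncated DL
estimate on the resample, and average over replicates (default 10,000,
configurable). A resample containing one distinct study has $Q = 0$ and
contributes zero. `DLb` is zero only if *every* resample is homogeneous,
which is why it detects heterogeneity more often than DL; the price is
upward bias for very small $k$. For $k = 2$ the estimator's limit is
exactly DL/2 (two of the four equally likely ordered resamples are
degenerate), which the tests pin by exhaustive enumeration. Resampling is
seeded per call and restores the caller's RNG state.

**Floored DL (`DLi`).** The DL value when positive, else 0.01 — a fairer
comparator for the positive-only group, which assumes that much
heterogeneity a priori.

**Likelihood estimators.** `ML` and `REML` iterate the truncated
fixed-point updates (with $w_i = 1/(\hat\sigma_i^2 + \tau^2)$ and $\hat\mu$
recomputed each pass)

$$\tau^2 \leftarrow \max\!\left(0,\;
  \frac{\sum w_i^2\,[(\hat\theta_i-\hat\mu)^2 - \hat\sigma_i^2]}
       {\sum w_i^2} \;\left[+ \frac{1}{\sum w_i}\ \text{(REML)}\right]\right).$$

Truncation is applied at *every* iteration. Convergence (|change| ≤ 1e-10
within 100 iterations, starting from the truncated VC value) is not
guaranteed; non-convergence is a reportable status (`converged = FALSE`,
last iterate returned), never an exception, because the assessment and
cross-tab machinery must count it. The tests verify converged interior
solutions against grid-search maximisation of the profiled (restricted)
log-likelihood and against `metafor`.

**Sidik–Jonkman model-error-variance estimators.** With prior
variance-ratio estimates $r_i = \hat\sigma_i^2/\hat\tau_0^2$ and weights
$v_i = 1/(r_i + 1)$,

$$\hat\tau^2_{MV} = \frac{1}{k-1}\sum_i v_i(\hat\theta_i - \hat\mu_v)^2 .$$

`MVa` uses the crude prior $\hat\tau_0^2 = k^{-1}\sum(\hat\theta_i -
\bar\theta)^2$; it is always positive but *fails* when all effects are
equal (tagged `NA`, counted as not-computable downstream — a real
occurrence with dichotomous data). `MVb` uses the VC estimate as prior,
adding 0.01 when that is zero, following the estimator's authors.

**Rukhin Bayes-type estimators.** With study sizes $n_i$ and $N = \sum
n_i$,

$$\hat\tau^2_{BP} = \frac{\sum_i(\hat\theta_i-\bar\theta)^2}{k+1},
\qquad
\hat\tau^2_{B0} = \max\!\left(0,\; \hat\tau^2_{BP}
  - \frac{k-1}{k+1}\cdot\frac{\sum_i (n_i-1)\hat\sigma_i^2}{N-k}\right).$$

`BP` needs no $n_i$ and is positive for any non-degenerate input; its bias
grows with $k$ since the within-study component is never subtracted. `B0`
subtracts a size-weighted average within-variance and truncates.

## Pooling and conclusions

`pool_mh()` implements Mantel–Haenszel OR/RR/RD with the
Robins–Breslow–Greenland (OR) and Greenland–Robins (RR, RD 1985 form)
variances as documented for the software this package emulates; `metafor`
uses the 1989 Sato variant for RD, so the two agree on the estimate but
differ slightly in the RD standard error. `pool_peto()` pools
$\sum(O-E)/\sum V$. Zero-cell 2×2 tables get +0.5 on all four cells for
ratio measures (never for RD); double-zero studies are excluded for OR/RR
but retained under RD, where they still carry MH weight. A meta-analysis
left with fewer than two eligible studies is a tagged `"NoComp"` result.

Conclusions are Wald: `"Sig"` iff $|\hat\mu - \text{null}|/\text{se} \ge
z_{1-\alpha/2}$, with normal (not t) quantiles throughout, null 0 on
additive/log scales, α = 0.05 unless the data declare otherwise.

**Profile likelihood** (`pl_estimate()`, `method = "PL"`). The point
estimate is the joint ML maximiser. The interval bounds solve
$2[\ell_p(\hat\mu) - \ell_p(\mu)] = \chi^2_1(1-\alpha)$ where $\ell_p$
re-maximises $\tau^2$ (truncated at zero) at each fixed $\mu$. Root
finding expands a bracket outward from the Wald interval (up to 50
doublings) and bisects to 1e-8; failure is a `"NoConv"` status. Because
$\tau^2$ is re-estimated along the profile, the interval widens relative
to the plug-in Wald interval whenever heterogeneity is uncertain; when the
profile stays at zero across the whole interval the PL bounds coincide
with the fixed-effect ones (the tests construct both cases).

## Simulation design

`sim_meta()` generates $\sigma_i^2$ (set equal to $\hat\sigma_i^2$ —
variances known), true effects $\theta_i$ with mean 0.5 and variance
$\tau^2$, observations $\hat\theta_i = \theta_i + N(0, \sigma_i^2)$, and
integer study sizes uniform on [50, 500], independent of the effects
(they only feed `B0`).

**Within-study variances** are $X/4$, $X \sim \chi^2_1$,
rejection-sampled into (0.009, 0.6). The one degree of freedom is forced
by the design's printed calibration constants: with df = 1 the truncated
law has mean 0.173 and harmonic moment $m = E[1/\sigma_i^2] = 17.836$
(quadrature via `implied_heterogeneity()`), so $\tau^2 \in \{0.01, 0.03,
0.10\}$ implies $H^2 = 1 + \tau^2 m$ of 1.18/1.54/2.78 and
$I^2 = 100\,\tau^2 m/(1+\tau^2 m)$ of 15.1%/34.9%/64.1%. Rejection leaves
the in-interval density proportional to the untruncated one, which the
suite checks with a Kolmogorov–Smirnov test.

**Effect distributions.** Six shapes, all with exact mean and variance:
normal; moderate skew (skewness 1, kurtosis 4) and extreme skew (skewness
2, kurtosis 9) — kurtosis quoted as *full* kurtosis (normal = 3), and both
targets lie outside what the skew-normal family can reach, so they are
generated by a Fleishman third-order polynomial transform of a standard
normal whose coefficients are solved by Newton iteration at run time to
residuals below 1e-12; uniform on $0.5 \pm \sqrt{3\tau^2}$; bimodal, the
equal mixture $N(0.5 \pm \delta, \delta^2)$ with $\delta = \sqrt{\tau^2/2}$
(the simplest clearly-separated two-mode construction with exact variance);
and double-spike, equal point masses at $0.5 \pm \sqrt{\tau^2}$ (an
intervention behaving differently under two designs).

**Seeding.** A scenario seed spawns one substream seed per replicate, so
replicate $r$ is individually reproducible (`rep_index`) and whole runs
are byte-identical under one seed.

What the generator does *not* emulate: estimated (noisy) within-study
variances, correlated effects, small-study/publication bias, and
dichotomous outcome generation in the main design (the simulation operates
on the effect+variance scale; a 2×2 generator lives in
`generate_corpus()` for the sensitivity machinery). Passing tests
therefore demonstrate calibration under the stated design, not robustness
to those real-data features.

## Assessment criteria

`assess_methods()` summarises, per scenario cell and estimator: mean bias
and mean absolute bias of $\hat\tau^2$ (signed biases cancel; the absolute
version does not); the percentage of *exactly* zero estimates (truncation
assigns the literal 0, so no epsilon is used); coverage of the true effect
by the nominal-level interval; and the error-interval ratio
$c = (\hat U - \hat L)/(U - L)$ against the interval at the true $\tau^2$
on the same data, summarised by median and quartiles ($c \equiv 1$ for the
oracle estimator; $c < 1$ whenever heterogeneity is ignored).
Non-converged or failed replicates are excluded from all denominators and
reported in `n_nonconv`.

A property worth knowing: DL random-effects intervals *over-cover* when
$\tau^2 = 0$, because $\hat\tau^2 > 0$ whenever $Q > k-1$ (probability
≈ 0.43 under homogeneity), which can only widen the interval. The suite
measures about 96% at $k = 10$ rather than the nominal 95% — a property of
the method, visible in any implementation, not an artefact of this one.

## Sensitivity cross-tabulation

`run_method_matrix()` re-analyses a corpus: per analysis it computes
effects on the approach-appropriate scale, fits the approach's
fixed-effect model, centres Q at that estimate for the DL stratum
assignment, and classifies every candidate method's conclusion.
Strata mirror the three reviewer situations: heterogeneity undetected
(`FE tau2=0`, where DL reduces to fixed-effect), detected but ignored
(`FE tau2>0`), detected and modelled (`RE tau2>0`). When the corpus does
not declare a baseline model, FE is assumed iff $\hat\tau^2_{DL} = 0$.
`conclusion_crosstab()` tabulates counts and within-stratum cell
percentages and reports the share of computable analyses whose conclusion
changed. Note that the "random-effects intervals are never narrower"
invariant holds within inverse-variance weighting (and for Peto, whose
fixed-effect se equals the IV se on the $(O-E)/V$ effects) but not against
the Mantel–Haenszel fixed-effect se, which comes from a different
weighting scheme.

`generate_corpus()` builds a synthetic corpus: 55% of analyses with two or
three studies by default (mirroring how bottom-heavy real review databases
are), a geometric tail above, a τ² mixture with a point mass at zero, and
continuous or binomially generated 2×2 outcomes. It is a synthetic
stand-in — no real review data ship with the package.

## Numerical choices and problem sizes

* ML/REML: start at truncated VC, tol 1e-10 on successive iterates, 100
  iterations, truncation every pass.
* DLb: default 10,000 resamples (configurable); the assessment and
  cross-tab helpers default to a few hundred, which keeps grid studies
  tractable while the per-meta Monte-Carlo error stays well below the
  between-replicate variation being summarised.
* PL: bisection tol 1e-8, bracket doubling capped at 50 expansions.
* Quadrature: `stats::integrate` at rel.tol 1e-12.
* The suite's heavier checks use 10,000 simulation replicates for coverage
  and recovery, 1,000 replicates per cell (six distributions × three τ²
  at k = 5) for the zero-rate ordering, and one million draws for the
  within-variance mean — sizes chosen so Monte-Carlo error is negligible
  against the 3-standard-error test bands.

## Known limitations

* The Mantel–Haenszel RD standard error follows the 1985 Greenland–Robins
  form (as documented for the emulated software), not the 1989 Sato
  variant.
* Profile-likelihood intervals assume a unimodal profile; multimodal
  profiles (possible with tiny $k$ and extreme variance ratios) would be
  reported as non-convergence rather than explored.
* `B0`/`BP` follow the standard catalogued forms of Rukhin's estimators;
  they satisfy the contracts relied on here (positivity of BP, truncation
  and size-dependence of B0).
* Confidence intervals for $\hat\tau^2$ itself are out of scope, as are
  Biggerstaff–Tweedie and Sidik–Jonkman pooling variants and empirical
  Bayes estimation.
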