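---
title: "Trend-level modelling of time-course metabolomics with tcgam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trend-level modelling of time-course metabolomics with tcgam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcgam)
```

## The problem

Elicitation experiments on plant cell suspension cultures produce daily
concentration series for dozens of metabolites in treated and control
flasks.  Testing treated vs control separately at each day ignores the
longitudinal structure, multiplies the number of tests, and — with the
typical three biological replicates per group — has little power at any
single day.  `tcgam` instead compares *trends*.  For a metabolite
concentration \(C(t)\) observed over days \(t\) in two groups, it fits the
generalized additive model

\[
\log E[C(t)] \;=\; \beta_0 \;+\; \beta_T\,\mathbf{1}[\text{treated}]
\;+\; s_{cm}(t) \;+\; \mathbf{1}[\text{treated}]\; s_{diff}(t),
\qquad C(t) \sim \mathrm{Gamma},
\]

with three interpretable terms:

* the **treatment factor** \(\beta_T\): a constant multiplicative shift
  between groups (a fold change of \(e^{\beta_T}\) at every day);
* the **common smoother** \(s_{cm}(t)\): the time trend shared by both
  groups;
* the **differential smoother** \(s_{diff}(t)\): the *additional* trend
  present only in treated cultures.  Its significance is the trend-level
  answer to "did the treatment change the time course?", and its
  pointwise band shows *when* the groups diverge.

The Gamma family with log link matches the two salient features of
concentration data: positivity, and noise whose standard deviation scales
with the mean (roughly constant coefficient of variation).  A gaussian
model on log-transformed concentrations (`family = "gaussian-log"`) is
offered as an alternative with the same multiplicative reading; the two
generally agree closely at constant CV.

Smoothers flexible enough to be data-driven need enough time points;
designs with fewer than about ten distinct days are rejected as
unsuitable for this approach.

## Smoothers: basis, penalty, and effective degrees of freedom

Each smoother is a cubic regression spline of dimension `k` (default 10)
with knots at quantiles of the distinct observed days.  The basis is
parameterised by the spline's values at the knots, and the penalty is the
exact integral of the squared second derivative of the natural cubic
interpolant — a symmetric positive semi-definite matrix of rank
\(k - 2\) whose null space is exactly the affine functions.  Heavy
penalisation therefore shrinks a smoother toward a straight line, not
toward zero.  The source basis family is a deliberate design choice: no
particular basis is canonical for this problem, and CR splines are the
simplest family with an exact curvature penalty; `k = 10` leaves REML
room to shrink on a 20-day design while accommodating clearly nonlinear
trends (effective degrees of freedom up to about 8 in practice).

Identifiability: every smoother carries a sum-to-zero constraint over its
design points — the common smoother over all observations, the
differential smoother over the *treated* observations only.  This is what
makes "constant shift" (absorbed by \(\beta_T\)) and "trend difference"
(carried by \(s_{diff}\)) separable, and it is why the differential
smoother's band is a band around a *centred* function: under a sustained
late divergence it is negative early and positive late.

Complexity is measured by the effective degrees of freedom (e.d.f.), the
per-term trace of \(F = (X'WX + S_\lambda)^{-1} X'WX\).  At vanishing
smoothing the e.d.f. equals the (constrained) basis dimension \(k - 1\);
at infinite smoothing a centred CR smoother keeps exactly its linear
direction, e.d.f. \(= 1\).  An e.d.f. near 1 therefore reads as "almost
linear", larger values as increasing nonlinearity.

## Fitting and smoothing selection

For both supported families the iteratively-reweighted-least-squares
working weights are identically 1, so penalized IRLS reduces to repeated
penalized least squares on the working response
\(z = \eta + (y - \mu)/\mu\) (Gamma/log), converged when the relative
deviance change falls below \(10^{-8}\).

Smoothing parameters maximise a restricted-likelihood criterion with the
dispersion profiled out: for gaussian models the exact REML of the
working mixed model; for Gamma models the same expression evaluated on
the converged working model (*performance-iteration* REML).  This is an
approximation to a fully nested Laplace criterion; at the sample sizes
this design produces (n = 120 per model) it tracks mgcv's REML fits
closely (fitted values to ~\(10^{-5}\) relative in spot checks) and is
much simpler.  The search is coordinate-wise on \(\log_{10}\lambda \in
[-8, 8]\): a coarse grid scan (step 0.5) brackets the global maximum —
the criterion is occasionally multimodal, and a pure local search can
otherwise be trapped — followed by Brent refinement, a second sweep, and
a joint Nelder–Mead polish.  A \(\lambda\) ending on the box bound is
flagged on the fit.

Reported dispersion is the Pearson estimator on \(n - \text{total
e.d.f.}\) degrees of freedom; the posterior covariance is the Bayesian
\(V_\beta = \phi (X'WX + S_\lambda)^{-1}\), used for all standard errors
and bands.

## Inference: approximate p-values and bands

The test for a smooth term is a Wald-type statistic
\(\hat f' V_f^{-} \hat f\) on the term's fitted values at its distinct
design times, using the rank-\(r\) eigen-pseudo-inverse with
\(r = \max(1, \mathrm{round}(\text{e.d.f.}))\), referred to
\(\chi^2_r\) (gaussian) or \(F(r,\, n - \text{total e.d.f.})\) (Gamma,
estimated dispersion).  These p-values are *approximate*: the reference
distribution ignores smoothing-parameter estimation, and a p-value near
the threshold should not be over-read.  Calibration is checked by
simulation in the acceptance suite: on null data the differential
smoother rejects at the 5% level with frequency inside [0.02, 0.10].

Bands are pointwise \( \hat f \pm 1.96\,\mathrm{SE}\) from \(V_\beta\).
Simulation puts their average pointwise coverage of the true centred
smooth near 0.95 (acceptance band [0.90, 0.99]).  They are *not*
simultaneous bands; "the band excludes 0 on days 15–20" is a pointwise
statement.

## Ratio models

To ask whether a treatment affects two metabolites *in the same way*
(e.g. a glucoside and its acyl derivative), the per-observation ratio is
formed from matched (day, replicate, group) pairs and the same three-term
model is fitted to it.  If the treatment scales both series by the same
time-varying factor, the factor cancels and the ratio's differential
smoother is non-significant; this invariance is verified by simulation.
Note the ratio of two Gamma variables is not Gamma — the Gamma/log fit
on ratios is a pragmatic, variance-stabilised approximation, adequate
here because ratio CVs remain modest.

## Screening statistics

The global-overview tools are deliberately standard: autoscaling
(mean 0, sd 1 per metabolite, \(n-1\) denominator), SVD-based PCA with
variance explained \(100\,\sigma_i^2/\sum\sigma^2\) and a deterministic
sign convention (largest-magnitude loading positive), Pearson
correlations with p-values from the t transform, and the pointwise
comparator: per-day Welch two-sample t-tests with Benjamini–Hochberg
adjustment across days (within one metabolite) and a 0.01 default FDR
level.  Welch rather than pooled-variance is the safer default when only
"t-test" is specified.  The comparator exists to exhibit, on simulated
divergence data, the phenomenon that pointwise testing at three
replicates flags fewer, more erratic days than the trend-level band.

## The synthetic-data generator: a stated world

No raw data accompany the source study, so every stage is exercised
against a generator that emulates the *design*: 15 anthocyanins (five
aglycones Dp, Cy, Pt, Pn, Mv; glucoside, acetyl-glucoside and
p-coumaroyl-glucoside forms), days 1–20 sampled daily, elicitation at
day 5, three biological replicates per group.  Its fixed defaults are the
stated world of the tests:

* **Baseline trends**: logistic growth to a metabolite-specific
  asymptote (rate 0.6/day, midpoint day 5 — rapid accumulation over the
  first week, then plateau).  Asymptote magnitudes follow the study's
  reported relative abundances: Pn- and Cy-glucosides dominant (180 and
  120 units), Dp/Pt/Mv minor (35/15/10), acetyl forms scarce (0.3×)
  and coumaroyl forms abundant (2×).
* **Treatment effect**: a multiplicative fold curve equal to exactly 1 up
  to day 9, rising as a rescaled (hence exactly boundary-matching)
  logistic to a plateau at day 13: fold 3 for the delphinidin branch,
  1.63 for the cyanidin branch, 1.0 (no effect) for acetyl derivatives —
  the reported end-of-course fold changes used as plateau values.
* **Noise**: Gamma with shape \(1/\mathrm{CV}^2\), CV 0.10 (the order of
  magnitude implied by reported mean ± s.d. pairs); a lognormal
  alternative with matched CV sits behind a flag for robustness checks.
* **Branch correlation**: a shared per-replicate lognormal factor
  (sd 0.2, mean 1) multiplying all metabolites of a pathway branch,
  reproducing the within-branch correlation blocks without mechanistic
  pathway modelling.

What the generator does *not* emulate: analytical batch effects,
replicate-level autocorrelation beyond the shared factor, missingness,
limits of detection, and any kinetic coupling between metabolites.  A
green simulation-based test therefore establishes that the machinery
behaves correctly *under this stated world*, not that the study's exact
printed numbers are recovered — those depend on undeposited raw
measurements and are out of reach by construction.

`simulate_for_recovery()` generates from the model's own log-scale
decomposition (intercept + shift + \(g(t)\) + \(d(t)\,\mathbf 1[trt]\))
and returns the exact truth, enabling parameter-recovery checks: a linear
\(g\) is recovered with median common e.d.f. in [1.0, 1.3], fitted
smoothers approach the truth as replicates grow, and band coverage is
near nominal.

## Numerical choices and degenerate inputs

* PIRLS convergence \(10^{-8}\) relative deviance, 200-iteration cap,
  step-halving on overshoot of the log link.
* Penalty pseudo-determinants via eigenvalues above a \(10^{-10}\)
  relative threshold; the criterion handles the exactly-constant-response
  degeneracy (penalized working RSS 0) with a floor on the profiled
  dispersion — an identically constant ratio still yields its intercept
  exactly, with a vacuous (NA) differential p-value rather than an error.
* Exchanging the group labels is an exact symmetry of the *unpenalized*
  model (the two parameterisations span the same space); with penalties
  the relabelled fit penalises \(J(c+d) + J(d)\) instead of
  \(J(c) + J(d)\), so REML-selected fits obey the symmetry only
  approximately.  The property test pins the exact version at fixed
  near-zero \(\lambda\).
* Days are real numbers; irregular sampling is supported.  Duplicate
  times are allowed in data; knots use distinct times only.
* Evaluation outside the knot range extrapolates linearly and is flagged.

## Known limitations

Smoothing-parameter uncertainty is not propagated into the bands or
tests (p-values are approximate by design); no per-flask random effects
(the emulated design has none); no multiplicity adjustment across
metabolites in `fit_all()` (matching the source analysis — add one
downstream if your panel warrants it); the Gamma-on-ratio model is an
approximation; YAML configs are not supported (JSON only).

## A worked run

```{r example, eval = FALSE}
set.seed(1)
dat <- simulate_timecourse(synthetic_config(seed = 1))
tf <- fit_trend_model(dat, "Dp-glu", elicitation_day = 5)
tf
#> Trend model for Dp-glu (gamma, k = 10)
#>   Treatment shift: 0.6845 (SE 0.0342)  [fold 1.983]
#>   Common smoother:       e.d.f. 6.471, approx p = 5.139e-49
#>   Differential smoother: e.d.f. 5.633, approx p = 5.527e-24
#>   Elicitation day (annotation): 5
```

The constant treatment shift (fold 1.98) combines with the centred
differential smoother — negative before the onset, positive after — to
produce the roughly 3-fold late divergence the generator encodes; the
strongly nonlinear common smoother is the shared logistic accumulation.
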