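# tcgam — trend-level analysis of time-course metabolomics

`tcgam` is for experimentalists and analysts with *daily-sampled*
metabolite concentration series from two-group elicitation experiments
(typified by methyl-jasmonate-elicited grapevine cell cultures: 15
anthocyanins, 20 days, 3 biological replicates per group, elicitation at
day 5) who want to test whether a treatment changed a metabolite's
**time trend**, not just its value at isolated days.

## The model

For concentration $C(t)$ over days $t$:

$$\log E[C(t)] = \beta_0 + \beta_T\,\mathbf{1}[\mathrm{treated}] + s_{cm}(t) + \mathbf{1}[\mathrm{treated}]\,s_{diff}(t), \qquad C(t)\sim\mathrm{Gamma}$$

- $\beta_T$ — constant multiplicative treatment shift (fold $e^{\beta_T}$),
- $s_{cm}(t)$ — **common smoother**: the trend shared by both groups,
- $s_{diff}(t)$ — **differential smoother**: the additional trend in
  treated cultures only; its approximate p-value and pointwise 95% band
  tell you *whether* and *when* the groups diverge.

Smoothers are penalized cubic regression splines (curvature penalty,
sum-to-zero constrained); smoothing parameters are selected by REML;
complexity is read off as effective degrees of freedom (e.d.f. ≈ 1 means
almost linear).  Ratio models (`fit_ratio_model`) apply the same
decomposition to per-observation ratios of two metabolites to ask whether
a treatment affected both "in the same way".  Screening tools cover
autoscaled PCA, Pearson correlation matrices, and the per-day
Welch-t/BH-FDR comparator.  A synthetic-data generator emulates the whole
design so every stage is testable without raw data.

## Worked example

```r
library(tcgam)

dat <- simulate_timecourse(synthetic_config(seed = 1))   # 1800 rows, 15 metabolites
tf  <- fit_trend_model(dat, "Dp-glu", elicitation_day = 5)
tf
#> Trend model for Dp-glu (gamma, k = 10)
#>   Treatment shift: 0.6845 (SE 0.0342)  [fold 1.983]
#>   Common smoother:       e.d.f. 6.471, approx p = 5.139e-49
#>   Differential smoother: e.d.f. 5.633, approx p = 5.527e-24
#>   Elicitation day (annotation): 5
```

Reading: the delphinidin glucoside rises along a strongly nonlinear
shared trend (common e.d.f. 6.5); on top of a constant 1.98-fold shift,
the highly significant differential smoother captures the
treatment-specific divergence that the generator encodes as a 3-fold
late-plateau effect.  `tf$differential$band` gives the pointwise band
dating the divergence.  Compare with day-by-day testing:

```r
cmp <- compare_gam_vs_pointwise(dat, "Cy-glu")
cmp
#> Trend vs pointwise comparison for Cy-glu
#>   pointwise BH-significant days (alpha = 0.01): 0 []
#>   days where differential band excludes 0: 19 [1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 12, 13, 14, 15, 16, 17, 18, 19, 20]
```

— with three replicates per day, pointwise Welch tests at FDR 0.01 find
nothing for the weaker (1.63-fold) cyanidin effect, while the trend model
localises it.  `fit_all(dat)` returns the 15-row summary table; the same
pipeline is scriptable via the CLI (`simulate`, `fit`, `ratio`, `screen`,
`compare`, `report` subcommands):

```sh
Rscript inst/scripts/tcgam simulate --out data.csv --seed 1
Rscript inst/scripts/tcgam fit --data data.csv --out-dir results/
```

Utility: `total_anthocyanin_from_absorbance(a535)` converts A535 readings
with the standard constants (dilution factor 2, extinction coefficient
98.2).

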