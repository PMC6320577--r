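# erlangenscore

Interpretation of cerebrospinal-fluid (CSF) Alzheimer's disease biomarkers
with the **Erlangen Score**, and the survival toolkit needed to study
progression from mild cognitive impairment (MCI) to AD dementia.

The package is aimed at neurochemistry laboratories and biostatisticians
who work with CSF biomarker panels (Abeta1-42, Abeta1-40, the Abeta42/40
ratio, Tau, pTau181) and longitudinal MCI cohorts.

## The score

Markers belong to two pathology groups — amyloid (Abeta1-42, Abeta42/40;
pathologic when *low*) and neurodegeneration (Tau, pTau181; pathologic
when *high*). Against a laboratory-specific reference value *c* each
marker is

* **normal** (severity 0) on the normal side of *c* (inclusive),
* **border** (severity 1) when pathologic by direction but within 10%
  of *c* (band `[0.9c, c)` for low markers, `(c, 1.1c]` for high ones),
* **pathologic** (severity 2) beyond the band.

A group's severity is the worst of its available markers, and

```
ES = amyloid severity + tau severity   (0 ... 4)
```

with three reporting levels: ES 0-1 *neurochemically improbable AD*,
ES 2-3 *possible*, ES 4 *probable*. Around the score the package
provides:

* a seeded synthetic-cohort generator (log-normal marginals from printed
  median/IQR summaries, Gaussian copula, piecewise-exponential
  progression hazards driven by the scored category),
* Kaplan-Meier / Nelson-Aalen estimators, the weighted log-rank family
  (log-rank, Gehan-Wilcoxon, trend),
* counting-process episode splitting at a 3-year Heaviside point and a
  from-scratch Cox partial-likelihood fitter (Breslow/Efron ties) for
  proportional-hazards and extended (time-varying effect) models, with
  the Schoenfeld/score proportionality test,
* ordinal cohort statistics (tie-corrected Kruskal-Wallis on contingency
  tables, Dunn-Bonferroni contrasts, diagnostic accuracy), landmark
  logistic models and covariate-adjusted fast/slow-progressor biomarker
  contrasts,
* a cohort CSV schema with validation, a full-analysis orchestrator and
  a small CLI (`inst/cli/escli.R`).

## Worked example

Score the group-median panel of an MCI-progressor profile:

```r
library(erlangenscore)
erlangen_score(list(abeta42 = 459.6, abeta42_40_ratio = 0.046,
                    tau = 448, ptau181 = 59))
#> Erlangen Score: 4 (amyloid 2 + tau 2) -> neurochemically probable AD
#>   abeta42=pathologic, abeta42_40_ratio=pathologic, tau=pathologic, ptau181=pathologic
```

All four markers are beyond their 10% bands, each group scores 2, and
the sum 4 reports as "neurochemically probable AD".

The shipped published category distribution (66 controls, 74 stable MCI,
70 MCI-to-AD progressors, 168 AD dementia) reproduces the reported
ordinal statistics and the asymmetric diagnostic operating point
(positive = ES >= 2 against the disease pool; a control counts as
misclassified only at ES 4):

```r
kruskal_wallis(reference_es_distribution())
#> Kruskal-Wallis (tie-corrected): chi2(df = 3) = 151.4, p = 1.307e-32
diagnostic_accuracy(reference_es_distribution())
#> Sensitivity 226/238 = 95.0% | Specificity 65/66 = 98.5%
```

An extended Cox model on a synthetic cohort, with the "possible"
category's effect split at 3 years of follow-up:

```r
co  <- generate_cohort(simulation_config(seed = 1))
mci <- co[co$group %in% c("MCI-Stable", "MCI-AD"), ]
eps <- episode_split(mci)               # counting-process rows, split at 3y
cox_fit(eps, c("possible_early", "possible_late", "probable"))
#> Cox model (breslow ties): 196 episodes, 101 events, loglik -410.59, 5 iterations
#>                   coef     se     HR lower95 upper95      p
#> possible_early  1.7737 0.3982 5.8927  2.6999 12.8614 0.0000
#> possible_late  -0.6420 0.7979 0.5263  0.1102  2.5143 0.4211
#> probable        2.0825 0.3690 8.0249  3.8935 16.5398 0.0000
```

The fitted pattern shows the score's characteristic time structure: a
strongly elevated early hazard in the "possible" category that collapses
toward the reference after 3 years (here the generating early/late
hazard ratios are 7.67 and 1.04 at cohort size n = 144, so single-cohort
estimates are noisy), and a persistently elevated hazard for "probable".
`run_full_analysis()` chains every stage (scoring, ordinal statistics,
survival curves and tests, extended Cox models M0-M3, landmark logistic
models, fast/slow contrasts) and `write_analysis_bundle()` exports TSV
tables, a JSON stats bundle and a markdown report.

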