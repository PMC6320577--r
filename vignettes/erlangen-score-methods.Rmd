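---
title: "The Erlangen Score and MCI-to-dementia progression: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Erlangen Score and MCI-to-dementia progression: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erlangenscore)
```

## The scoring model

Cerebrospinal-fluid biomarkers of Alzheimer's disease fall into two
pathophysiological groups: amyloid markers (Abeta1-42 concentration and the
Abeta42/40 ratio, pathologically *decreased*) and neurodegeneration markers
(total Tau and pTau181, pathologically *increased*). The Erlangen Score
summarises a four-marker CSF profile on an ordinal 0-4 scale by scoring
each group 0 (normal), 1 (border-zone alteration) or 2 (evident
alteration) and summing the two group severities. Reporting to clinicians
uses three levels: 0-1 "neurochemically improbable AD", 2-3 "possible",
4 "probable".

Three modelling choices matter:

* **Border zones are multiplicative.** A value is border when it is
  pathologic by direction but within 10% of the reference value: for a
  "low" marker the band is `[0.9 c, c)`, for a "high" marker `(c, 1.1 c]`
  with cutoff `c`. The `border_fraction` is configurable per marker
  (`marker_spec()`), because reference values — and how sharp they are —
  are laboratory-specific. Classification is therefore scale invariant:
  rescaling a marker's units rescales its cutoff and changes nothing.
* **A value exactly at the cutoff is normal.** The border zone begins
  strictly beyond the reference value and includes the band edge. The
  sources that define the score leave the knife-edge case unspecified;
  an exact convention is required for testable software, and "pathology
  begins beyond the reference value" is the reading most consistent with
  a *pathologic result within 10% of the reference*.
* **Groups combine by worst-of ("or" logic).** One evidently altered
  marker makes its whole group evident; with both group markers present
  the maximum severity wins. A measured Abeta42/40 ratio takes precedence
  over one derived from the two peptide concentrations; the ratio is
  derived only when not measured. Scoring needs at least one marker per
  group — a whole missing group is an error, not a silent zero — which
  also supports three-marker panels.

Default reference values (580 pg/ml Abeta1-42, 0.068 ratio, 250 pg/ml
Tau, 37 pg/ml pTau181, 10% bands) reproduce the laboratory configuration
of the emulated cohort and are overridable from a YAML/JSON file
(`read_reference_panel()`).

## The synthetic cohort generator

The cohort the package's analyses emulate is not publicly deposited, so
`generate_cohort()` produces synthetic cohorts calibrated to its printed
summary statistics. The generator is a first-class, tested component —
every downstream stage is exercised against it.

* **Biomarker marginals** are log-normal, parameterised from the printed
  median and interquartile range: `mu = log(median)`,
  `sigma = log(q75/q25) / (2 * qnorm(0.75))`. A two-parameter log-normal
  matches the median and the *quartile ratio*; it cannot also match an
  asymmetric pair of quartiles, so sampled q25/q75 individually deviate
  where the printed IQR is skewed beyond log-normality (noticeably for
  pTau181 in the MCI-AD group).
* **Dependence** is a Gaussian copula on the latent normals. The source
  tables report no correlations; the defaults (0.8 between Tau and
  pTau181, 0.6 between the two Abeta peptides, 0 elsewhere) are
  field-plausible round values, configurable in `simulation_config()`.
* **Amyloid consistency.** The stored ratio is always `abeta42/abeta40`.
  To calibrate the *ratio's* median while keeping this arithmetic
  identity, the Abeta1-40 location is re-anchored to
  `mu42 - log(ratio median)`; its log-scale spread is kept. Two accepted
  consequences: Abeta1-40's own median drifts by the re-anchoring factor
  (about 4% in the MCI-AD group), and the ratio's IQR is emergent rather
  than calibrated. Calibration tests therefore target the medians of
  Abeta1-42, the ratio, Tau and pTau181.
* **Progression** follows a piecewise-constant hazard driven by the
  *scored* three-level category: baseline 0.04/year for "improbable"
  (which puts its 4-year cumulative incidence at `1 - exp(-0.16)`, about
  15%, matching the instability reported for biomarker-normal MCI);
  hazard ratio 7.67 before and 1.04 after the 3-year split for
  "possible"; time-constant 12.0 for "probable". Event times are drawn by
  inverting the piecewise cumulative hazard. Administrative censoring is
  `Uniform(2, 12)` years — the emulated study followed stable MCI for at
  least 2 years, with maxima of 10-16 years; the real dropout pattern is
  unknown, and uniform censoring is an explicit stand-in. A progression
  at exactly the censoring time counts as an event.
* **Group labels are assigned post hoc**: MCI subjects who progress
  before censoring become "MCI-AD", the rest "MCI-Stable", mirroring how
  observational cohorts define these groups from outcomes. Controls and
  dementia subjects carry no follow-up; controls carry no APOE genotype
  and no MMSE, as in the emulated cohort's summary table.
* Demographics: age is normal (matched median/IQR) truncated at 40;
  MMSE is a rounded truncated normal on [0, 30]; gender and APOE are
  Bernoulli draws at the printed fractions.

Passing calibration tests show that the generator reproduces the summary
statistics it is parameterised by, and that estimators recover parameters
*under this generative model*. They cannot show that real CSF cohorts
satisfy log-normality, the assumed copula, or piecewise-constant hazards;
distributional features such as assay floor/ceiling effects, batch
drift, informative dropout and diagnostic misclassification are not
emulated.

## Survival methodology

The survival stack is implemented from first principles and verified
against independent references in the test suite.

* `km_estimator()` / `na_estimator()` are the standard product-limit and
  cumulative-hazard estimators; `risk_table()` tabulates at-risk counts on
  a regular grid (2-year default).
* `weighted_logrank()` covers the log-rank family: unit weights,
  Gehan-Breslow-Wilcoxon weights (`n` at risk, emphasising early
  differences) and a 1-df trend test contrasting the observed-minus-
  expected vector with ordinal scores `0:(k-1)`.
* `episode_split()` decomposes each subject's follow-up at the 3-year
  Heaviside point into counting-process rows `(0, s]`, `(s, fu]`, turning
  the "possible" category's effect into separate early and late hazard
  ratios. An event at exactly the split belongs to the early segment
  ("less than or equal to" semantics). Exposure and event counts are
  conserved exactly.
* `cox_fit()` maximises the partial likelihood by Newton-Raphson with
  step halving (convergence `1e-9` on the log-likelihood or score,
  maximum 100 iterations). Risk sets use the half-open `(start, stop]`
  convention and are resolved by prefix-sum differences over stop- and
  start-sorted episodes, so an evaluation is `O(n log n + m p^2)`.
  Breslow is the default tie correction — matching the major commercial
  package whose Cox default is Breslow, for comparability with analyses
  run there — with Efron available. Confidence intervals are Wald on the
  log-hazard scale. Diverging coefficients (monotone likelihood /
  separation) and singular information are explicit errors.
* `schoenfeld_ph_test()` tests hazard-ratio time-constancy. It reports
  classical Schoenfeld residuals, but the test statistic is the *score
  test* for adding `x * g(t)` interactions at the fitted coefficients,
  with the augmented information assembled from per-event-time risk sums.
  The classic scaled-residual approximation replaces that information by
  an average; the score-test form is the modern formulation of the same
  Grambsch-Therneau idea and agrees with contemporary reference
  implementations to numerical precision, which makes the package's
  dual-route verification exact. Transforms: identity (default,
  untransformed analysis time) and `1 - KM(t-)`.

The extended Cox model sequence mirrors the emulated analysis: M0 with
the score terms only (`possible_early`, `possible_late`, `probable`
against the improbable reference), M1 adds age and gender, M2 APOE, M3
MMSE. The proportionality test runs on the unsplit proportional-hazards
comparison model, where the early/late switch of the "possible" category
should be — and in simulation reliably is — detected.

## Group-level statistics

* `kruskal_wallis()` computes the tie-corrected H statistic directly on
  the mid-ranks implied by an ordinal contingency table
  (`C = 1 - sum(t^3 - t)/(N^3 - N)`), identical to a rank test on the
  expanded per-subject vector (the test suite proves the equivalence
  against `stats::kruskal.test`). On the published 4x3 category table the
  statistic is 151.4 with 3 df — confirming, incidentally, that the
  printed value arises from the three-level categorisation.
* `dunn_pairwise()` uses the tie-corrected rank variance and Bonferroni
  multiplication over all `k(k-1)/2` pairs, capped at 1.
* `diagnostic_accuracy()` reproduces the *asymmetric* clinical operating
  point: sensitivity counts a diseased subject as detected unless
  "improbable" (positive = score >= 2), while specificity counts a
  control as misclassified only when "probable" (score 4). Only this
  asymmetric reading reproduces the reported 95.0% / 98.5% pair from the
  published table; a single shared threshold does not.
* `logistic_landmark()` models progression within a 3- or 5-year horizon.
  Subjects censored before the horizon without an event carry no
  information about the landmark outcome and are excluded by default
  (consistent with the emulated analysis' per-model n being below the
  cohort size); `include_censored = TRUE` codes them as non-cases for
  sensitivity analyses. Fitting is binomial IRLS with Wald intervals;
  separation is an explicit error.
* `adjusted_biomarker_contrast()` compares fast progressors (event within
  3 years) with slow progressors (dementia-free beyond 3 years) on each
  biomarker, via a linear model with category x speed interactions plus
  age, gender and MMSE. Reported cell means are population-averaged
  predictions at the covariate means with Wald intervals; empty cells are
  reported as unavailable rather than failing. An exactly flat response
  (zero residual variance) returns contrast p = 1 by convention.

## Numerical and interface choices

Times are years as floating point throughout; no day conversion.
Comparisons use full floating precision — inputs are never rounded;
percentages are rounded to one decimal for display only, and the JSON
stats bundle keeps full precision. The cohort CSV schema (one header,
empty field = missing, UTF-8, point decimal separator independent of
locale) is shared by real-format and simulated data, and all serialised
artifacts round-trip byte-identically; `generate_cohort()` seeds a
private RNG stream so identical configurations reproduce identical
cohorts without disturbing the caller's RNG.

Problem sizes used in the shipped verification: calibration checks use
100 000 draws; hazard-structure recovery uses 20 replicate cohorts of
5000 MCI subjects; test size/power calibrations use 200-1000 replicates
at the sample sizes stated in the tests. These sizes make Monte-Carlo
error small relative to the tolerances tested while keeping the full
suite fast.

## Known limitations

* The exact hazard ratios, odds ratios and confidence intervals of the
  emulated patient-level analyses require the original cohort, which is
  not deposited; the package substitutes parameter-recovery properties
  under its own generative model.
* Dunn contrasts on the three-level table make one pair (Control vs
  MCI-Stable) slightly less extreme than the published "< 0.005" claim
  (adjusted p = 0.0088); the five-level distribution, which is not fully
  printed, plausibly sharpens it.
* No frailty, stratified or penalized Cox; no competing risks (the
  emulated design excluded non-AD dementias); no alternative marker
  weighting (deliberately out of scope); no plotting beyond curve export.
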