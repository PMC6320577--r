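Package: erlangenscore
Title: Erlangen Score Interpretation of CSF Biomarkers and MCI-to-Dementia
    Progression Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the Erlangen Score, an ordinal (0-4) interpretation
    algorithm for cerebrospinal-fluid biomarkers of Alzheimer's disease
    (Abeta1-42, Abeta42/40 ratio, Tau, pTau181) with multiplicative border
    zones around laboratory-specific reference values, together with the
    survival machinery needed to study progression from mild cognitive
    impairment to Alzheimer's dementia: Kaplan-Meier and Nelson-Aalen
    estimators, the weighted log-rank family (log-rank, Gehan-Wilcoxon,
    trend), counting-process episode splitting with a Heaviside time split,
    Cox partial-likelihood fitting for proportional-hazards and extended
    (time-varying effect) models, and the Grambsch-Therneau proportionality
    test.  Group-level statistics (tie-corrected Kruskal-Wallis on ordinal
    contingency tables, Dunn-Bonferroni contrasts, diagnostic accuracy,
    landmark logistic regression, covariate-adjusted biomarker contrasts
    with marginal means) and a seeded synthetic-cohort generator with
    log-normal marginals, a Gaussian copula, and piecewise-exponential
    progression hazards complete the analysis pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    survival,
    optparse
Config/testthat/edition: 3
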