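# Shared fixtures, built in code.

# The published 4 x 3 category distribution (groups x improbable/
# possible/probable) used in the worked examples.
published_counts <- function() reference_es_distribution()

# A panel at the group medians of the emulated cohort.
median_panel <- function(group) {
  p <- default_group_profiles()[[group]]
  lapply(p$markers, `[[`, 1L)
}

# Expand a contingency table into per-subject ordinal + group vectors.
expand_table <- function(m) {
  list(x = rep(rep(seq_len(ncol(m)), nrow(m)), as.vector(t(m))),
       g = rep(rownames(m), rowSums(m)))
}

# Small MCI-style scored records for survival / landmark tests.
make_mci_records <- function(n, seed = 1,
                             cats = c("improbable", "possible",
                                      "probable"),
                             hazard = hazard_spec(),
                             censor = c(2, 12)) {
  withr::with_seed(seed, {
    cat3 <- sample(cats, n, replace = TRUE)
    tt <- sample_progression_time(cat3, hazard)
    cc <- runif(n, censor[1], censor[2])
    data.frame(
      id = sprintf("M%04d", seq_len(n)),
      group = "MCI",
      age = rnorm(n, 68, 7), female = rbinom(n, 1, 0.6),
      apoe4 = rbinom(n, 1, 0.4),
      mmse = pmax(0L, pmin(30L, as.integer(round(rnorm(n, 26, 2))))),
      es_category3 = factor(cat3, levels = c("improbable", "possible",
                                             "probable"),
                            ordered = TRUE),
      followup_years = pmin(tt, cc),
      event = as.integer(tt <= cc))
  })
}

# Simple right-censored single-group survival sample.
make_exp_sample <- function(n, rate, seed, cmax = 15) {
  withr::with_seed(seed, {
    tt <- rexp(n, rate)
    cc <- runif(n, 0.5, cmax)
    data.frame(time = pmin(tt, cc), event = as.integer(tt <= cc))
  })
}
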