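# Landmark logistic models and adjusted biomarker contrasts.

test_that("saturated one-covariate design reproduces the closed-form OR and SE", {
  # exposed: 10 events / 10 non-events; unexposed: 5 events / 15 non-events
  a <- 10; b <- 10; c_ <- 5; d <- 15
  recs <- data.frame(
    id = sprintf("r%02d", 1:40),
    followup_years = c(rep(1, a), rep(10, b), rep(1, c_), rep(10, d)),
    event = c(rep(1L, a), rep(0L, b), rep(1L, c_), rep(0L, d)),
    es_category3 = c(rep("probable", a + b), rep("improbable", c_ + d)))
  fit <- logistic_landmark(recs, horizon = 3, covariates = character(0))
  or_hand <- (a * d) / (b * c_)
  se_hand <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
  expect_equal(fit$table["probable", "or"], or_hand, tolerance = 1e-8)
  expect_equal(fit$table["probable", "se"], se_hand, tolerance = 1e-8)
  expect_equal(fit$n, 40L)
  expect_equal(fit$n_cases, 15L)
})

test_that("subjects censored before the horizon are excluded by default", {
  recs <- data.frame(
    id = letters[1:8],
    followup_years = c(1, 1.5, 4, 2, 1, 4, 5, 2),
    event = c(1L, 1L, 0L, 0L, 1L, 0L, 0L, 0L),
    es_category3 = rep(c("probable", "improbable"), each = 4))
  # subjects censored at 2 < 3 without an event are uninformative
  fit <- logistic_landmark(recs, 3, covariates = character(0))
  expect_equal(fit$n, 6L)
  expect_equal(fit$n_cases, 3L)
  # coded as non-cases when include_censored = TRUE
  fit2 <- logistic_landmark(recs, 3, covariates = character(0),
                            include_censored = TRUE)
  expect_equal(fit2$n, 8L)
  # landmark monotonicity: every case at horizon 3 is a case at horizon 5
  recs2 <- make_mci_records(400, seed = 71)
  case_at <- function(h) {
    with(recs2, id[event == 1 & followup_years <= h])
  }
  expect_true(all(case_at(3) %in% case_at(5)))
})

test_that("landmark ORs recover a known generative odds multiplier", {
  # binary outcome generated directly from a logistic model at 3 years
  withr::with_seed(73, {
    n <- 5000
    cat3 <- sample(c("improbable", "possible", "probable"), n,
                   replace = TRUE, prob = c(0.4, 0.3, 0.3))
    lp <- -2 + log(16) * (cat3 == "probable") + log(6) * (cat3 == "possible")
    y <- rbinom(n, 1, plogis(lp))
    recs <- data.frame(
      id = as.character(1:n),
      followup_years = ifelse(y == 1, 1.5, 6),
      event = y, es_category3 = cat3)
  })
  fit <- logistic_landmark(recs, 3, covariates = character(0))
  ci <- fit$table["probable", c("ci_lower", "ci_upper")]
  expect_gt(16, ci[[1]]); expect_lt(16, ci[[2]])
  ci_p <- fit$table["possible", c("ci_lower", "ci_upper")]
  expect_gt(6, ci_p[[1]]); expect_lt(6, ci_p[[2]])
})

test_that("null covariate CIs cover OR = 1 at near-nominal rate", {
  cover <- withr::with_seed(74, {
    vapply(seq_len(200), function(i) {
      n <- 300
      cat3 <- sample(c("improbable", "probable"), n, replace = TRUE)
      z <- rnorm(n)      # no effect
      y <- rbinom(n, 1, plogis(-1 + 1.2 * (cat3 == "probable")))
      recs <- data.frame(id = as.character(1:n),
                         followup_years = ifelse(y == 1, 1, 6),
                         event = y, es_category3 = cat3, z = z)
      fit <- logistic_landmark(recs, 3, covariates = "z")
      fit$table["z", "ci_lower"] < 1 && fit$table["z", "ci_upper"] > 1
    }, logical(1L))
  })
  expect_gte(mean(cover), 0.93)
})

test_that("an empty outcome class is an explicit error", {
  recs <- data.frame(id = c("a", "b"), followup_years = c(5, 6),
                     event = c(0L, 0L),
                     es_category3 = c("probable", "improbable"))
  expect_error(logistic_landmark(recs, 3, covariates = character(0)),
               "empty class")
})

test_that("orthogonal design: adjusted means equal raw stratum means", {
  # balanced cells, covariates centred identically across cells
  base <- expand.grid(cat = c("improbable", "possible", "probable"),
                      fast = c(0, 1), rep = 1:20)
  n <- nrow(base)
  # covariates balanced identically within every (category, speed) cell
  recs <- data.frame(
    id = as.character(1:n),
    followup_years = ifelse(base$fast == 1, 2, 5),
    event = ifelse(base$fast == 1, 1L, 0L),
    es_category3 = as.character(base$cat),
    age = ifelse(base$rep %% 2 == 0, 60, 70),
    female = as.integer(base$rep <= 10),
    mmse = 26L,
    tau = 300 + 100 * (base$cat == "probable") + 50 * base$fast +
      ifelse(base$rep %% 2 == 0, -5, 5))
  mm <- adjusted_biomarker_contrast(recs, "tau")
  raw <- aggregate(tau ~ es_category3 + event, recs, mean)
  for (i in seq_len(nrow(mm$means))) {
    r <- mm$means[i, ]
    raw_mean <- mean(recs$tau[recs$es_category3 == r$category &
                                (recs$event == 1) == (r$speed == "fast")])
    expect_equal(r$estimate, raw_mean, tolerance = 1e-10)
  }
})

test_that("a true gap in one category is recovered; flat markers give p = 1", {
  withr::with_seed(76, {
    n <- 900
    cat3 <- sample(c("improbable", "possible", "probable"), n,
                   replace = TRUE)
    fast <- rbinom(n, 1, 0.4)
    gap <- ifelse(cat3 == "possible" & fast == 1, -400, 0)
    recs <- data.frame(
      id = as.character(1:n),
      followup_years = ifelse(fast == 1, 2, 5),
      event = fast,
      es_category3 = cat3,
      age = rnorm(n, 68, 6), female = rbinom(n, 1, 0.5),
      mmse = as.integer(round(rnorm(n, 26, 2))),
      abeta42 = 800 + gap + rnorm(n, 0, 120))
  })
  mm <- adjusted_biomarker_contrast(recs, "abeta42")
  d_pos <- mm$contrasts[mm$contrasts$category == "possible", ]
  expect_lt(abs(d_pos$difference - (-400)), 3 * d_pos$se)
  expect_lt(d_pos$p, 0.001)
  d_imp <- mm$contrasts[mm$contrasts$category == "improbable", ]
  expect_gt(d_imp$p, 0.01)
  # constant marker: all adjusted means equal, contrast p = 1
  recs$flat <- 500
  mmf <- adjusted_biomarker_contrast(recs, "flat")
  expect_true(all(abs(mmf$means$estimate - 500) < 1e-8))
  expect_true(all(mmf$contrasts$p > 0.999 | is.na(mmf$contrasts$p)))
})

test_that("an empty cell is reported as unavailable, not an error", {
  recs <- make_mci_records(150, seed = 77,
                           cats = c("improbable", "possible"))
  recs$abeta42 <- rlnorm(150, log(600), 0.3)
  mm <- adjusted_biomarker_contrast(recs, "abeta42")
  expect_false("probable" %in% mm$means$category[!is.na(mm$means$estimate)])
})
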