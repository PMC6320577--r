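# Synthetic cohort generator: marginal calibration, copula correlations,
# progression-time sampling, determinism.

test_that("log-normal marginals hit the profile medians and quartiles", {
  prof <- default_group_profiles()[["MCI-AD"]]
  withr::with_seed(101, {
    b <- sample_biomarkers(prof, 1e5)
  })
  for (mk in c("abeta42", "tau", "ptau181", "abeta42_40_ratio")) {
    target <- prof$markers[[mk]]
    expect_equal(median(b[[mk]]), target[1], tolerance = 0.02)
  }
  for (mk in c("abeta42", "tau", "ptau181")) {
    # a two-parameter log-normal matches the quartile ratio (IQR on the
    # log scale), not each asymmetric quartile individually; the ratio
    # marker inherits its spread from the two peptides (consistency wins)
    target <- prof$markers[[mk]]
    iqr_ratio <- unname(quantile(b[[mk]], 0.75) / quantile(b[[mk]], 0.25))
    expect_equal(iqr_ratio, target[3] / target[2], tolerance = 0.03)
  }
  # arithmetic consistency of the amyloid triplet
  expect_equal(b$abeta42_40_ratio, b$abeta42 / b$abeta40)
})

test_that("copula correlations are reproduced and independence holds", {
  prof <- default_group_profiles()[["Control"]]
  withr::with_seed(5, b <- sample_biomarkers(prof, 1e5))
  expect_equal(cor(log(b$tau), log(b$ptau181)), 0.8, tolerance = 0.02)
  expect_equal(cor(log(b$abeta42), log(b$abeta40)), 0.6, tolerance = 0.02)
  expect_lt(abs(cor(log(b$abeta42), log(b$tau))), 0.02)
  withr::with_seed(6, bi <- sample_biomarkers(prof, 1e5, diag(4)))
  expect_lt(abs(cor(bi$tau, bi$ptau181, method = "spearman")), 0.01)
  expect_equal(nrow(sample_biomarkers(prof, 0)), 0L)
})

test_that("invalid profiles are rejected", {
  expect_error(group_profile("g", 5,
                             markers = list(abeta42 = c(500, 600, 400)),
                             age = c(60, 50, 70), female_fraction = 0.5),
               "IQR")
  expect_error(group_profile("g", 5,
                             markers = list(abeta42 = c(500, 400, 600)),
                             age = c(60, 50, 70), female_fraction = 1.5),
               "female_fraction")
})

test_that("progression times follow the piecewise-exponential closed forms", {
  # exponential inverse CDF: u = exp(-0.3), rate 0.1 -> T = 3 exactly
  expect_equal(sample_progression_time("improbable",
                                       hazard_spec(baseline_rate = 0.1),
                                       u = exp(-0.3)), 3)
  hs <- hazard_spec()  # baseline 0.04, HRs 7.67 / 1.04 / 12.0, split 3
  withr::with_seed(21, ti <- sample_progression_time(
    rep("improbable", 1e5), hs))
  expect_equal(mean(ti <= 4), 1 - exp(-0.16), tolerance = 0.02)
  withr::with_seed(22, tp <- sample_progression_time(
    rep("possible", 1e5), hs))
  expect_equal(mean(tp <= 3), 1 - exp(-3 * 0.04 * 7.67), tolerance = 0.01)
  # beyond the split the possible hazard drops to ~baseline
  p_late <- mean(tp <= 5) - mean(tp <= 3)
  expect_equal(p_late / mean(tp > 3), 1 - exp(-2 * 0.04 * 1.04),
               tolerance = 0.05)
  withr::with_seed(23, tq <- sample_progression_time(
    rep("probable", 1e5), hs))
  expect_equal(mean(tq <= 2), 1 - exp(-2 * 0.04 * 12), tolerance = 0.01)
  # continuity of the inverse at the split
  eps <- 1e-9
  u_split <- exp(-3 * 0.04 * 7.67)
  t1 <- sample_progression_time("possible", hs, u = u_split + eps)
  t2 <- sample_progression_time("possible", hs, u = u_split - eps)
  expect_equal(t1, 3, tolerance = 1e-5)
  expect_equal(t2, 3, tolerance = 1e-5)
})

test_that("category-specific event rates recover the configured hazard ratios", {
  hs <- hazard_spec()
  n <- 1e5
  withr::with_seed(31, {
    ti <- sample_progression_time(rep("improbable", n), hs)
    tp <- sample_progression_time(rep("possible", n), hs)
  })
  # occurrence/exposure rate on (0, 3]
  rate <- function(tt) sum(tt <= 3) / sum(pmin(tt, 3))
  expect_equal(rate(tp) / rate(ti), hs$hr_possible_early,
               tolerance = 0.03)
})

test_that("identical seeds give identical cohorts, different seeds differ", {
  cfg <- simulation_config(seed = 42)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1, c2)
  c3 <- generate_cohort(simulation_config(seed = 43))
  expect_false(identical(c1, c3))
  # generator must not disturb the caller's RNG stream
  set.seed(1); x1 <- runif(1)
  set.seed(1); invisible(generate_cohort(cfg)); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("generated cohorts have coherent structure", {
  co <- generate_cohort(simulation_config(seed = 9))
  expect_equal(nrow(co), 66 + 74 + 70 + 168)
  expect_false(anyDuplicated(co$id) > 0)
  mci <- co$group %in% c("MCI-Stable", "MCI-AD")
  expect_true(all(is.na(co$followup_years[!mci])))
  expect_true(all(co$followup_years[mci] > 0))
  expect_true(all(co$event[mci] %in% 0:1))
  # post-hoc labelling: progressors are exactly the MCI-AD group
  expect_true(all(co$event[co$group == "MCI-AD"] == 1L))
  expect_true(all(co$event[co$group == "MCI-Stable"] == 0L))
  expect_true(all(is.na(co$apoe4[co$group == "Control"])))
  expect_true(all(co$mmse[mci] >= 0 & co$mmse[mci] <= 30))
  expect_true(all(co$age >= 40))
})

test_that("scored category distributions are stochastically ordered across profiles", {
  cfg <- simulation_config(seed = 12)
  profs <- default_group_profiles()
  score_dist <- function(g) {
    withr::with_seed(100 + match(g, names(profs)), {
      b <- sample_biomarkers(profs[[g]], 4000, cfg$correlations)
    })
    mean(score_cohort(b)$es_score)
  }
  m_ctrl <- score_dist("Control")
  m_stab <- score_dist("MCI-Stable")
  m_mciad <- score_dist("MCI-AD")
  m_add <- score_dist("ADD")
  expect_lt(m_ctrl, m_stab)
  expect_lt(m_stab, m_mciad)
  expect_lt(abs(m_mciad - m_add), 0.6)  # near-identical profiles
})

test_that("probable-category subjects progress more often than improbable ones", {
  co <- generate_cohort(simulation_config(seed = 77))
  mci <- co[co$group %in% c("MCI-Stable", "MCI-AD"), ]
  p5 <- function(cat) {
    d <- mci[mci$es_category3 == cat & mci$followup_years >= 0, ]
    mean(d$event == 1 & d$followup_years <= 5)
  }
  expect_gt(p5("probable"), p5("improbable"))
})
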