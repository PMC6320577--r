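# Marker classification and Erlangen Score computation.

test_that("marker classification respects cutoff, border band and direction", {
  tau <- marker_spec("tau", 250, "high")
  ab42 <- marker_spec("abeta42", 580, "low")
  ratio <- marker_spec("abeta42_40_ratio", 0.068, "low")

  expect_equal(as.character(classify_marker(178.3, tau)$label), "normal")
  expect_equal(as.character(classify_marker(265, tau)$label), "border")
  expect_equal(as.character(classify_marker(276, tau)$label), "pathologic")
  # exact edges: cutoff itself is normal, band edge is still border
  expect_equal(classify_marker(250, tau)$severity, 0L)
  expect_equal(classify_marker(275, tau)$severity, 1L)
  expect_equal(classify_marker(580, ab42)$severity, 0L)
  expect_equal(classify_marker(522, ab42)$severity, 1L)  # 0.9 * 580
  expect_equal(classify_marker(521.9, ab42)$severity, 2L)
  expect_equal(as.character(classify_marker(0.046, ratio)$label),
               "pathologic")
})

test_that("invalid classification inputs raise named errors", {
  tau <- marker_spec("tau", 250, "high")
  expect_error(classify_marker(-5, tau), "tau")
  expect_error(classify_marker(0, tau), "non-positive")
  expect_error(marker_spec("unknown_marker", 100, "low"), "unknown marker")
  expect_error(marker_spec("tau", -3, "high"), "positive")
  expect_error(marker_spec("tau", 250, "high", border_fraction = 1.2),
               "border_fraction")
})

test_that("group severity is the maximum over available markers", {
  expect_equal(group_severity(c(0L, 0L)), 0L)
  expect_equal(group_severity(c(2L, 0L)), 2L)
  expect_equal(group_severity(c(1L, 0L)), 1L)
  expect_equal(group_severity(c(1L, NA)), 1L)
  expect_error(group_severity(c(NA_integer_, NA_integer_)),
               "missing-group")
})

test_that("all nine severity combinations sum to the verbal rule score", {
  # reconstruct panels hitting each (amyloid, tau) severity pair exactly
  ab_val <- c(600, 530, 400)     # normal / border / pathologic vs 580
  tau_val <- c(240, 260, 300)    # normal / border / pathologic vs 250
  for (a in 0:2) for (t in 0:2) {
    res <- erlangen_score(list(abeta42 = ab_val[a + 1],
                               tau = tau_val[t + 1]))
    expect_equal(res$amyloid_severity, a)
    expect_equal(res$tau_severity, t)
    expect_equal(res$score, a + t)
  }
  # verbal rules: one group border only -> 1; one evident only -> 2;
  # both border -> 2; evident + border -> 3; both evident -> 4
  expect_equal(erlangen_score(list(abeta42 = 530, tau = 240))$score, 1L)
  expect_equal(erlangen_score(list(abeta42 = 400, tau = 240))$score, 2L)
  expect_equal(erlangen_score(list(abeta42 = 530, tau = 260))$score, 2L)
  expect_equal(erlangen_score(list(abeta42 = 400, tau = 260))$score, 3L)
  expect_equal(erlangen_score(list(abeta42 = 400, tau = 300))$score, 4L)
})

test_that("category mapping is total and matches reporting convention", {
  cats <- categorize(0:4)
  expect_equal(as.character(cats$category3),
               c("improbable", "improbable", "possible", "possible",
                 "probable"))
  expect_equal(as.character(cats$category5), as.character(0:4))
  expect_error(categorize(5), "score")
  expect_error(categorize(-1), "score")
})

test_that("group medians of the emulated cohort score as expected", {
  expect_equal(erlangen_score(median_panel("Control"))$score, 0L)
  expect_equal(erlangen_score(median_panel("MCI-Stable"))$score, 0L)
  expect_equal(erlangen_score(median_panel("MCI-AD"))$score, 4L)
  expect_equal(erlangen_score(median_panel("ADD"))$score, 4L)
  expect_equal(as.character(erlangen_score(median_panel("MCI-AD"))$category3),
               "probable")
})

test_that("border in one group only gives score 1; both borders give 2", {
  r1 <- erlangen_score(list(abeta42 = 600, abeta42_40_ratio = 0.065,
                            tau = 240, ptau181 = 36))
  expect_equal(r1$score, 1L)
  expect_equal(as.character(r1$category3), "improbable")
  r2 <- erlangen_score(list(abeta42 = 600, abeta42_40_ratio = 0.064,
                            tau = 260, ptau181 = 36))
  expect_equal(r2$score, 2L)
  expect_equal(as.character(r2$category3), "possible")
})

test_that("ratio is derived from the two peptides only when not measured", {
  # derived ratio 400/10000 = 0.04 -> pathologic
  r <- erlangen_score(list(abeta42 = 600, abeta40 = 10000 / 0.04 * 600 / 400,
                           tau = 240))
  # measured ratio wins over a derivable one
  r2 <- erlangen_score(list(abeta42 = 400, abeta40 = 4000,
                            abeta42_40_ratio = 0.100, tau = 240))
  expect_equal(r2$amyloid_severity, 2L)  # abeta42 pathologic, ratio normal
  r3 <- erlangen_score(list(abeta42 = 600, abeta40 = 15000, tau = 240))
  expect_equal(r3$per_marker[["abeta42_40_ratio"]], 2L)  # 0.04 derived
})

test_that("a missing pathology group blocks scoring", {
  expect_error(erlangen_score(list(abeta42 = 600)), "tau")
  expect_error(erlangen_score(list(tau = 300, ptau181 = 50)), "amyloid")
})

test_that("moving any marker toward pathology never lowers the score", {
  refs <- default_reference_panel()
  withr::with_seed(7, {
    for (i in 1:200) {
      panel <- list(abeta42 = runif(1, 300, 900),
                    abeta42_40_ratio = runif(1, 0.03, 0.13),
                    tau = runif(1, 100, 500),
                    ptau181 = runif(1, 15, 80))
      base <- erlangen_score(panel, refs)$score
      mk <- sample(names(panel), 1)
      shift <- runif(1, 0.5, 0.95)
      panel[[mk]] <- if (mk %in% c("tau", "ptau181"))
        panel[[mk]] / shift else panel[[mk]] * shift
      expect_gte(erlangen_score(panel, refs)$score, base)
    }
  })
})

test_that("classification is invariant under joint rescaling of value and cutoff", {
  withr::with_seed(11, {
    for (i in 1:50) {
      cut <- runif(1, 10, 1000)
      val <- cut * runif(1, 0.5, 1.5)
      for (dir in c("low", "high")) {
        s1 <- classify_marker(val, marker_spec("tau", cut, "high"))
        s2 <- classify_marker(2 * val, marker_spec("tau", 2 * cut, "high"))
        expect_equal(s1$severity, s2$severity)
      }
    }
  })
})

test_that("batch scoring preserves order and flags unscoreable rows", {
  df <- data.frame(
    id = c("a", "b", "c", "d"),
    abeta42 = c(600, 400, NA, 500),
    abeta42_40_ratio = c(0.07, 0.04, 0.08, NA),
    tau = c(240, 300, NA, -2),
    ptau181 = c(30, 60, NA, 40))
  out <- score_cohort(df)
  expect_equal(out$id, df$id)
  expect_equal(out$es_score, c(0L, 4L, NA, NA))
  expect_match(out$es_reason[3], "tau group unavailable")
  expect_match(out$es_reason[4], "non-positive")
  empty <- score_cohort(data.frame(abeta42 = numeric(0)))
  expect_equal(nrow(empty), 0L)
})

test_that("batch scoring agrees with the per-subject path", {
  withr::with_seed(3, {
    df <- data.frame(abeta42 = runif(50, 300, 900),
                     abeta42_40_ratio = runif(50, 0.03, 0.13),
                     tau = runif(50, 100, 500),
                     ptau181 = runif(50, 15, 80))
    out <- score_cohort(df)
    single <- vapply(seq_len(50), function(i)
      erlangen_score(as.list(df[i, ]))$score, integer(1L))
    expect_equal(out$es_score, single)
  })
})

test_that("reference panel round-trips through YAML and JSON", {
  panel <- default_reference_panel()
  for (ext in c("yaml", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_reference_panel(panel, path)
    back <- read_reference_panel(path)
    expect_equal(unclass(back), unclass(panel), tolerance = 1e-12)
  }
  expect_error(reference_panel(marker_spec("tau", 250, "high")), "amyloid")
  expect_error(
    reference_panel(marker_spec("abeta42", 580, "low"),
                    marker_spec("abeta42", 600, "low"),
                    marker_spec("tau", 250, "high")),
    "duplicate")
})
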