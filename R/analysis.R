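# Full analysis pipeline: scoring -> group summaries -> ordinal category
# statistics -> survival curves and tests -> extended Cox models ->
# landmark logistic models -> fast/slow biomarker contrasts.

#' Run the complete progression analysis on a cohort
#'
#' Executes the analysis stages in sequence and collects their results.
#' Stages whose inputs are unavailable (e.g. no MCI follow-up data) are
#' skipped with an explanatory notice rather than failing the run; a
#' failing stage records its error and downstream stages that depend on
#' it are skipped.  The analysis itself is deterministic: rerunning on
#' the same cohort reproduces every number bit for bit.
#'
#' Model sequence for the extended Cox models (all with the Heaviside
#' split of the "possible" category at `split_time`): `M0` Erlangen Score
#' terms only; `M1` adds age and gender; `M2` adds APOE epsilon-4; `M3`
#' adds MMSE.  The proportionality test is run on the unsplit
#' proportional-hazards comparison model.
#'
#' @param cohort Cohort data frame (schema of [cohort_schema()]), scored
#'   or not.
#' @param refs Reference panel for scoring.
#' @param split_time Heaviside split in years (default 3).
#' @param horizons Landmark horizons in years (default `c(3, 5)`).
#' @param ties Tie method for the Cox fits.
#' @param mci_groups Group labels regarded as MCI (follow-up carriers).
#' @return Object of class `es_analysis`: list with elements
#'   `scored`, `group_summary`, `contingency3`, `contingency5`,
#'   `kruskal_wallis`, `dunn`, `accuracy`, `curves`, `logrank`,
#'   `wilcoxon`, `trend`, `ecm` (M0-M3), `cph`, `ph_test`, `landmark`,
#'   `contrasts`, `notes` (skip/error notices).
#' @export
run_full_analysis <- function(cohort, refs = default_reference_panel(),
                              split_time = 3, horizons = c(3, 5),
                              ties = c("breslow", "efron"),
                              mci_groups = c("MCI-Stable", "MCI-AD")) {
  ties <- match.arg(ties)
  stopifnot(is.data.frame(cohort), all(diff(horizons) > 0),
            all(horizons > 0))
  notes <- character(0)
  res <- list()
  note <- function(stage, msg)
    notes <<- c(notes, paste0("[", stage, "] ", msg))
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      note(stage, paste("failed:", conditionMessage(e)))
      NULL
    })
  }

  scored <- if ("es_score" %in% names(cohort)) cohort else
    score_cohort(cohort, refs)
  res$scored <- scored
  unscored <- sum(is.na(scored$es_score))
  if (unscored > 0)
    note("scoring", paste(unscored, "record(s) unscoreable, excluded",
                          "from category statistics"))
  ok <- scored[!is.na(scored$es_score), , drop = FALSE]

  res$group_summary <- run_stage("summary", group_summary(ok))

  res$contingency3 <- run_stage("contingency", es_contingency(ok, 3))
  res$contingency5 <- run_stage("contingency", es_contingency(ok, 5))
  if (!is.null(res$contingency3) && nrow(res$contingency3) >= 2L) {
    res$kruskal_wallis <- run_stage("kruskal_wallis",
                                    kruskal_wallis(res$contingency3))
    res$dunn <- run_stage("dunn", dunn_pairwise(res$contingency3))
  } else note("kruskal_wallis", "skipped: fewer than two groups")
  res$accuracy <- if (!is.null(res$contingency3) &&
                      all(c("Control", "MCI-AD", "ADD") %in%
                          rownames(res$contingency3)))
    run_stage("accuracy", diagnostic_accuracy(res$contingency3))
  else {
    note("accuracy", "skipped: needs Control, MCI-AD and ADD groups")
    NULL
  }

  mci <- ok[ok$group %in% mci_groups & !is.na(ok$followup_years) &
              !is.na(ok$event), , drop = FALSE]
  if (nrow(mci) == 0L) {
    note("survival", "skipped: no MCI subjects with follow-up")
  } else {
    res$curves <- run_stage("curves", lapply(
      split(mci, mci$es_category3, drop = TRUE), function(d)
        list(km = km_estimator(d$followup_years, d$event),
             na = na_estimator(d$followup_years, d$event),
             risk = risk_table(d$followup_years, d$event, by = 2))))
    if (length(unique(mci$es_category3)) >= 2L) {
      res$logrank <- run_stage("logrank", weighted_logrank(
        mci$followup_years, mci$event, mci$es_category3, "logrank"))
      res$wilcoxon <- run_stage("logrank", weighted_logrank(
        mci$followup_years, mci$event, mci$es_category3, "wilcoxon"))
      res$trend <- run_stage("logrank", weighted_logrank(
        mci$followup_years, mci$event, mci$es_category3, "trend"))
    } else note("logrank", "skipped: single category among MCI subjects")

    if (sum(mci$event) >= 3L) {
      eps <- run_stage("episodes", episode_split(mci, split_time))
      if (!is.null(eps)) {
        base_terms <- c("possible_early", "possible_late", "probable")
        msets <- list(M0 = base_terms,
                      M1 = c(base_terms, "age", "female"),
                      M2 = c(base_terms, "age", "female", "apoe4"),
                      M3 = c(base_terms, "age", "female", "apoe4",
                             "mmse"))
        res$ecm <- lapply(names(msets), function(mn) {
          if (!all(msets[[mn]] %in% names(eps))) {
            note("ecm", paste(mn, "skipped: missing covariates"))
            return(NULL)
          }
          run_stage(paste0("ecm_", mn),
                    cox_fit(eps, msets[[mn]], ties = ties))
        })
        names(res$ecm) <- names(msets)
        eps_u <- run_stage("episodes", episodes_unsplit(mci))
        if (!is.null(eps_u)) {
          res$cph <- run_stage("cph", cox_fit(
            eps_u, c("possible", "probable"), ties = ties))
          if (!is.null(res$cph))
            res$ph_test <- run_stage("ph_test", schoenfeld_ph_test(
              res$cph, eps_u))
        }
      }
    } else note("ecm", "skipped: fewer than 3 events")

    res$landmark <- lapply(horizons, function(h)
      run_stage(paste0("landmark_", h), logistic_landmark(mci, h)))
    names(res$landmark) <- paste0("h", horizons)

    markers_present <- intersect(es_markers(), names(mci))
    markers_present <- union(markers_present,
                             intersect("abeta40", names(mci)))
    res$contrasts <- lapply(markers_present, function(mk)
      run_stage(paste0("contrast_", mk),
                adjusted_biomarker_contrast(mci, mk,
                                            split_time = split_time)))
    names(res$contrasts) <- markers_present
  }

  res$notes <- notes
  res$options <- list(split_time = split_time, horizons = horizons,
                      ties = ties)
  structure(res, class = "es_analysis")
}

#' Per-group median (IQR) summary of demographics and markers
#'
#' @param scored Scored cohort data frame.
#' @return Data frame: one row per group x variable with `median`, `q25`,
#'   `q75`, `n`.
#' @export
group_summary <- function(scored) {
  vars <- intersect(c("age", "mmse", "abeta42", "abeta40",
                      "abeta42_40_ratio", "tau", "ptau181",
                      "followup_years"), names(scored))
  do.call(rbind, lapply(split(scored, scored$group), function(d) {
    do.call(rbind, lapply(vars, function(v) {
      x <- as.numeric(d[[v]]); x <- x[!is.na(x)]
      data.frame(group = d$group[1L], variable = v,
                 n = length(x),
                 median = if (length(x)) stats::median(x) else NA_real_,
                 q25 = if (length(x)) unname(stats::quantile(x, 0.25))
                 else NA_real_,
                 q75 = if (length(x)) unname(stats::quantile(x, 0.75))
                 else NA_real_)
    }))
  })) -> out
  rownames(out) <- NULL
  out
}

#' @export
print.es_analysis <- function(x, ...) {
  cat("Erlangen Score progression analysis\n")
  if (!is.null(x$contingency3)) {
    cat("\nCategory distribution (3-level):\n")
    print(unclass(x$contingency3))
  }
  if (!is.null(x$kruskal_wallis)) print(x$kruskal_wallis)
  if (!is.null(x$accuracy)) print(x$accuracy)
  if (!is.null(x$logrank))
    cat(sprintf("Log-rank chi2(%d) = %.2f; Wilcoxon chi2(%d) = %.2f; trend chi2(1) = %.2f\n",
                x$logrank$df, x$logrank$chi2, x$wilcoxon$df,
                x$wilcoxon$chi2, x$trend$chi2))
  if (!is.null(x$ecm$M0)) {
    cat("\nExtended Cox model M0:\n"); print(x$ecm$M0)
  }
  if (length(x$notes)) {
    cat("\nNotes:\n"); cat(paste(" -", x$notes), sep = "\n")
  }
  invisible(x)
}

#' Collect the analysis statistics as a plain list (for JSON export)
#'
#' Full precision; no rounding.  The same cohort always yields the same
#' bundle, so serialised outputs are byte-identical across reruns.
#'
#' @param res An `es_analysis`.
#' @return Nested list of plain numbers and tables.
#' @export
analysis_stats <- function(res) {
  stopifnot(inherits(res, "es_analysis"))
  cox_tab <- function(f) if (is.null(f)) NULL else
    list(coef = as.list(f$coef), se = as.list(f$se),
         hr = as.list(f$hr), ci_lower = as.list(f$ci_lower),
         ci_upper = as.list(f$ci_upper), loglik = f$loglik,
         n = f$n, n_events = f$n_events)
  lm_tab <- function(f) if (is.null(f)) NULL else
    list(or = as.list(f$table$or),
         ci_lower = as.list(f$table$ci_lower),
         ci_upper = as.list(f$table$ci_upper),
         term = rownames(f$table), loglik = f$loglik, n = f$n,
         n_cases = f$n_cases)
  list(
    contingency3 = if (!is.null(res$contingency3))
      list(counts = unclass(res$contingency3)[, , drop = FALSE],
           groups = rownames(res$contingency3)),
    kruskal_wallis = if (!is.null(res$kruskal_wallis))
      list(H = res$kruskal_wallis$H, df = res$kruskal_wallis$df,
           p = res$kruskal_wallis$p),
    dunn = if (!is.null(res$dunn)) as.list(as.data.frame(res$dunn)),
    accuracy = if (!is.null(res$accuracy))
      res$accuracy[c("sensitivity", "specificity", "tp", "disease_n",
                     "tn", "control_n")],
    logrank = if (!is.null(res$logrank))
      res$logrank[c("chi2", "df", "p")],
    wilcoxon = if (!is.null(res$wilcoxon))
      res$wilcoxon[c("chi2", "df", "p")],
    trend = if (!is.null(res$trend)) res$trend[c("chi2", "df", "p")],
    ecm = if (!is.null(res$ecm)) lapply(res$ecm, cox_tab),
    cph = cox_tab(res$cph),
    ph_test = if (!is.null(res$ph_test))
      list(table = cbind(term = rownames(res$ph_test$table),
                         res$ph_test$table)),
    landmark = if (!is.null(res$landmark))
      lapply(res$landmark, lm_tab),
    contrasts = if (!is.null(res$contrasts))
      lapply(res$contrasts, function(cc) if (is.null(cc)) NULL else
        list(means = cc$means, contrasts = cc$contrasts)),
    notes = res$notes
  )
}

#' Write the analysis bundle to disk
#'
#' Emits TSV tables (contingency, Cox and landmark coefficient tables,
#' survival curves with risk tables), a machine-readable `stats.json`
#' (full precision) and a human-readable `report.md` with display
#' rounding.
#'
#' @param res An `es_analysis`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_analysis_bundle <- function(res, dir) {
  stopifnot(inherits(res, "es_analysis"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wtsv <- function(df, name)
    utils::write.table(df, file.path(dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(res$contingency3)) {
    m <- as.data.frame(unclass(res$contingency3))
    wtsv(cbind(group = rownames(res$contingency3), m),
         "contingency3.tsv")
  }
  if (!is.null(res$curves))
    for (nm in names(res$curves)) {
      write_curve_tsv(res$curves[[nm]]$km,
                      file.path(dir, paste0("km_", nm, ".tsv")))
      write_curve_tsv(res$curves[[nm]]$na,
                      file.path(dir, paste0("na_", nm, ".tsv")))
      wtsv(res$curves[[nm]]$risk, paste0("risktable_", nm, ".tsv"))
    }
  if (!is.null(res$ecm))
    for (mn in names(res$ecm)) {
      f <- res$ecm[[mn]]
      if (is.null(f)) next
      wtsv(data.frame(term = names(f$coef), coef = f$coef, se = f$se,
                      hr = f$hr, ci_lower = f$ci_lower,
                      ci_upper = f$ci_upper),
           paste0("ecm_", mn, ".tsv"))
    }
  if (!is.null(res$landmark))
    for (hn in names(res$landmark)) {
      f <- res$landmark[[hn]]
      if (is.null(f)) next
      wtsv(cbind(term = rownames(f$table), f$table),
           paste0("landmark_", hn, ".tsv"))
    }
  jsonlite::write_json(analysis_stats(res), file.path(dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  writeLines(render_report(res), file.path(dir, "report.md"))
  invisible(dir)
}

#' Render a markdown report of the analysis
#'
#' @param res An `es_analysis`.
#' @return Character vector of markdown lines.
#' @export
render_report <- function(res) {
  stopifnot(inherits(res, "es_analysis"))
  out <- c("# Erlangen Score progression analysis", "")
  md_table <- function(df) {
    df[] <- lapply(df, function(x)
      if (is.numeric(x)) signif(x, 4) else x)
    c(paste("|", paste(names(df), collapse = " | "), "|"),
      paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|"),
      apply(df, 1L, function(r)
        paste("|", paste(r, collapse = " | "), "|")))
  }
  if (!is.null(res$contingency3)) {
    pc <- attr(res$contingency3, "percent")
    df <- data.frame(group = rownames(res$contingency3))
    for (j in seq_len(ncol(res$contingency3)))
      df[[colnames(res$contingency3)[j]]] <-
        sprintf("%d (%.1f%%)", res$contingency3[, j], pc[, j])
    out <- c(out, "## Category distribution", "", md_table(df), "")
  }
  if (!is.null(res$kruskal_wallis))
    out <- c(out, sprintf(
      "Kruskal-Wallis chi2(df = %d) = %.1f, p = %.3g",
      res$kruskal_wallis$df, res$kruskal_wallis$H,
      res$kruskal_wallis$p), "")
  if (!is.null(res$accuracy))
    out <- c(out, sprintf(
      "Sensitivity %.1f%% (%d/%d), specificity %.1f%% (%d/%d)",
      100 * res$accuracy$sensitivity, res$accuracy$tp,
      res$accuracy$disease_n, 100 * res$accuracy$specificity,
      res$accuracy$tn, res$accuracy$control_n), "")
  if (!is.null(res$logrank))
    out <- c(out, "## Survival comparison", "", sprintf(
      "Log-rank chi2(%d) = %.2f (p = %.3g); Wilcoxon chi2 = %.2f; trend chi2(1) = %.2f",
      res$logrank$df, res$logrank$chi2, res$logrank$p,
      res$wilcoxon$chi2, res$trend$chi2), "")
  if (!is.null(res$ecm)) {
    out <- c(out, "## Extended Cox models (HR, 95% CI)", "")
    terms_all <- unique(unlist(lapply(res$ecm, function(f)
      if (!is.null(f)) names(f$coef))))
    df <- data.frame(term = terms_all)
    for (mn in names(res$ecm)) {
      f <- res$ecm[[mn]]
      df[[mn]] <- if (is.null(f)) "-" else {
        i <- match(terms_all, names(f$coef))
        ifelse(is.na(i), "-", sprintf("%.2f (%.2f-%.2f)",
                                      f$hr[i], f$ci_lower[i],
                                      f$ci_upper[i]))
      }
    }
    out <- c(out, md_table(df), "")
    lls <- vapply(res$ecm, function(f)
      if (is.null(f)) NA_real_ else f$loglik, numeric(1L))
    out <- c(out, paste("Log likelihood:",
                        paste(sprintf("%s %.1f", names(lls), lls),
                              collapse = ", ")), "")
  }
  if (!is.null(res$ph_test))
    out <- c(out, sprintf(
      "Proportionality (Schoenfeld, global): chi2 = %.2f, p = %.3g",
      res$ph_test$table["GLOBAL", "chisq"],
      res$ph_test$table["GLOBAL", "p"]), "")
  if (!is.null(res$landmark)) {
    out <- c(out, "## Landmark logistic models (OR, 95% CI)", "")
    for (hn in names(res$landmark)) {
      f <- res$landmark[[hn]]
      if (is.null(f)) next
      df <- data.frame(term = rownames(f$table),
                       OR = sprintf("%.2f (%.2f-%.2f)", f$table$or,
                                    f$table$ci_lower, f$table$ci_upper))
      out <- c(out, paste0("### Horizon ", sub("h", "", hn), " years",
                           " (n = ", f$n, ")"), "", md_table(df), "")
    }
  }
  if (length(res$notes))
    out <- c(out, "## Notes", "", paste("-", res$notes), "")
  out
}
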