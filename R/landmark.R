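# Landmark logistic models of progression within a fixed horizon, and
# covariate-adjusted fast/slow-progressor biomarker contrasts with
# population-averaged (marginal) predictions.

#' Landmark logistic regression for progression within a horizon
#'
#' Models the probability of progressing to dementia within `horizon`
#' years as a function of the three-level Erlangen Score category (two
#' indicators against the "improbable" reference) and optional adjustment
#' covariates.  Cases are subjects with an event at or before the
#' horizon; controls are subjects still dementia-free beyond the horizon;
#' subjects censored before the horizon without an event carry no
#' information about the landmark outcome and are excluded (configurable
#' via `include_censored`, which codes them as non-cases).  Fitting uses
#' [stats::glm()] (iteratively reweighted least squares); confidence
#' intervals are Wald on the log-odds scale.
#'
#' @param records Scored MCI records with `followup_years`, `event`,
#'   `es_category3` and the covariate columns.
#' @param horizon Landmark horizon in years (> 0).
#' @param covariates Adjustment covariate names (default
#'   `c("age", "female", "mmse")`); rows with missing covariates are
#'   dropped listwise.
#' @param include_censored Keep early-censored subjects as non-cases
#'   (default `FALSE`).
#' @return Object of class `landmark_fit`: data frame `table` with `or`,
#'   `ci_lower`, `ci_upper`, `coef`, `se`, `p` per term; plus `loglik`,
#'   `n`, `n_cases`, `horizon`.
#' @export
logistic_landmark <- function(records, horizon,
                              covariates = c("age", "female", "mmse"),
                              include_censored = FALSE) {
  stopifnot(is.data.frame(records), horizon > 0)
  need <- c("followup_years", "event", "es_category3")
  miss <- setdiff(c(need, covariates), names(records))
  if (length(miss))
    stop("records lack columns: ", paste(miss, collapse = ", "))
  fu <- as.numeric(records$followup_years)
  ev <- as.integer(records$event)
  keep <- !is.na(fu) & !is.na(ev)
  case <- keep & ev == 1L & fu <= horizon
  control <- keep & fu > horizon
  uninformative <- keep & !case & !control
  use <- case | control | (include_censored & uninformative)
  df <- records[use, , drop = FALSE]
  outcome <- as.integer(case[use])
  cat3 <- factor(as.character(df$es_category3),
                 levels = c("improbable", "possible", "probable"))
  mf <- data.frame(outcome = outcome,
                   possible = as.integer(cat3 == "possible"),
                   probable = as.integer(cat3 == "probable"),
                   df[, covariates, drop = FALSE])
  mf <- mf[stats::complete.cases(mf), , drop = FALSE]
  if (length(unique(mf$outcome)) < 2L)
    stop("landmark outcome has an empty class at horizon ", horizon)
  terms <- c("possible", "probable", covariates)
  fml <- stats::as.formula(paste("outcome ~",
                                 paste(terms, collapse = " + ")))
  fit <- stats::glm(fml, family = stats::binomial(), data = mf,
                    control = stats::glm.control(epsilon = 1e-13,
                                                 maxit = 50L))
  if (!fit$converged) stop("logistic landmark model did not converge")
  cf <- stats::coef(fit)
  cf <- cf[!is.na(cf)]              # drop aliased (absent-category) terms
  se <- sqrt(diag(stats::vcov(fit)))[names(cf)]
  if (any(abs(cf[-1L]) > 15))
    stop("separation detected in the landmark model (diverging odds ratio)")
  z <- stats::qnorm(0.975)
  tab <- data.frame(
    coef = cf, se = se, or = exp(cf),
    ci_lower = exp(cf - z * se), ci_upper = exp(cf + z * se),
    p = 2 * stats::pnorm(-abs(cf / se)))
  structure(list(table = tab, loglik = as.numeric(stats::logLik(fit)),
                 n = nrow(mf), n_cases = sum(mf$outcome),
                 horizon = horizon, glm = fit),
            class = "landmark_fit")
}

#' @export
print.landmark_fit <- function(x, ...) {
  cat(sprintf("Landmark logistic model, %g-year horizon: n = %d (%d cases), loglik %.1f\n",
              x$horizon, x$n, x$n_cases, x$loglik))
  print(round(x$table[, c("or", "ci_lower", "ci_upper", "p")], 4))
  invisible(x)
}

#' Covariate-adjusted fast/slow-progressor biomarker contrast
#'
#' Stratifies MCI subjects into fast progressors (event within
#' `split_time` years) and slow progressors (dementia-free follow-up
#' beyond `split_time`; others are excluded), then fits a linear model of
#' the marker on the Erlangen-Score-category x speed interaction plus
#' adjustment covariates.  Marginal (population-averaged) predictions —
#' model predictions with the covariates held at their sample means — are
#' reported per category x speed cell with Wald 95% CIs, together with a
#' fast-vs-slow contrast p value per category.
#'
#' @param records Scored MCI records.
#' @param marker Name of the biomarker column to model.
#' @param covariates Adjustment covariates (default age, female, mmse).
#' @param split_time Fast/slow split in years (default 3).
#' @return Object of class `marginal_means`: data frame `means`
#'   (category, speed, n, estimate, ci_lower, ci_upper) and data frame
#'   `contrasts` (category, difference, se, p); cells without subjects are
#'   reported as `NA` (unavailable), not an error.
#' @export
adjusted_biomarker_contrast <- function(records, marker,
                                        covariates = c("age", "female",
                                                       "mmse"),
                                        split_time = 3) {
  stopifnot(is.data.frame(records), marker %in% names(records))
  fu <- as.numeric(records$followup_years)
  ev <- as.integer(records$event)
  fast <- !is.na(fu) & !is.na(ev) & ev == 1L & fu <= split_time
  slow <- !is.na(fu) & fu > split_time
  use <- fast | slow
  df <- records[use, , drop = FALSE]
  mf <- data.frame(
    y = as.numeric(df[[marker]]),
    category = factor(as.character(df$es_category3),
                      levels = c("improbable", "possible", "probable")),
    fast = as.integer(fast[use]),
    df[, covariates, drop = FALSE])
  mf <- mf[stats::complete.cases(mf), , drop = FALSE]
  if (nrow(mf) < length(covariates) + 7L)
    stop("too few complete records for the contrast model")
  mf$category <- droplevels(mf$category)
  fml <- stats::as.formula(paste(
    "y ~ category * fast +", paste(covariates, collapse = " + ")))
  fit <- stats::lm(fml, data = mf)
  cf <- stats::coef(fit)
  cf <- cf[!is.na(cf)]              # aliased terms (e.g. constant covariate)
  V <- suppressWarnings(stats::vcov(fit))[names(cf), names(cf)]
  cov_means <- colMeans(mf[, covariates, drop = FALSE])
  # a perfectly flat response makes every contrast exactly null
  sigma <- sqrt(sum(stats::residuals(fit)^2) / fit$df.residual)
  degenerate <- sigma < 1e-8 * (stats::sd(mf$y) + mean(abs(mf$y)) + 1e-300)

  cells <- expand.grid(category = levels(mf$category), fast = c(0L, 1L),
                       stringsAsFactors = FALSE)
  design_row <- function(category, fast) {
    nd <- data.frame(category = factor(category,
                                       levels = levels(mf$category)),
                     fast = fast, as.list(cov_means))
    mm <- drop(stats::model.matrix(stats::delete.response(stats::terms(fit)),
                                   nd))
    mm[names(cf)]
  }
  z <- stats::qnorm(0.975)
  means <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    ct <- cells$category[i]; fs <- cells$fast[i]
    n_cell <- sum(mf$category == ct & mf$fast == fs)
    if (n_cell == 0L)
      return(data.frame(category = ct, speed = ifelse(fs == 1L, "fast",
                                                      "slow"),
                        n = 0L, estimate = NA_real_, ci_lower = NA_real_,
                        ci_upper = NA_real_))
    xr <- design_row(ct, fs)
    est <- sum(xr * cf)
    se <- sqrt(drop(t(xr) %*% V %*% xr))
    data.frame(category = ct, speed = ifelse(fs == 1L, "fast", "slow"),
               n = n_cell, estimate = est, ci_lower = est - z * se,
               ci_upper = est + z * se)
  }))
  contrasts <- do.call(rbind, lapply(levels(mf$category), function(ct) {
    n_fast <- sum(mf$category == ct & mf$fast == 1L)
    n_slow <- sum(mf$category == ct & mf$fast == 0L)
    if (n_fast == 0L || n_slow == 0L)
      return(data.frame(category = ct, difference = NA_real_,
                        se = NA_real_, p = NA_real_))
    cvec <- design_row(ct, 1L) - design_row(ct, 0L)
    diff <- sum(cvec * cf)
    se <- sqrt(drop(t(cvec) %*% V %*% cvec))
    pval <- if (degenerate) 1 else
      2 * stats::pt(-abs(diff / se), df = fit$df.residual)
    data.frame(category = ct, difference = diff, se = se, p = pval)
  }))
  structure(list(marker = marker, means = means, contrasts = contrasts,
                 n = nrow(mf), lm = fit),
            class = "marginal_means")
}

#' @export
print.marginal_means <- function(x, ...) {
  cat("Adjusted marginal means for", x$marker, "(n =", x$n, ")\n")
  print(transform(x$means, estimate = round(estimate, 3),
                  ci_lower = round(ci_lower, 3),
                  ci_upper = round(ci_upper, 3)), row.names = FALSE)
  cat("Fast-vs-slow contrasts:\n")
  print(transform(x$contrasts, difference = round(difference, 3),
                  se = round(se, 3), p = signif(p, 3)), row.names = FALSE)
  invisible(x)
}
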