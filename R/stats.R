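# Group-level ordinal statistics: contingency tables of Erlangen Score
# categories, tie-corrected Kruskal-Wallis on mid-ranks, Dunn-Bonferroni
# pairwise contrasts, and the diagnostic operating point.

#' Cross-tabulate Erlangen Score categories by diagnostic group
#'
#' @param records Scored cohort (see [score_cohort()]); every row must
#'   carry a score.
#' @param categories 3 (improbable/possible/probable, default) or 5
#'   (scores 0-4).
#' @param groups Optional group level order; defaults to order of
#'   appearance.
#' @return Object of class `es_table`: integer matrix (groups x ordered
#'   categories) with a `percent` attribute (row percentages, 1 decimal).
#' @export
es_contingency <- function(records, categories = 3, groups = NULL) {
  stopifnot(is.data.frame(records), categories %in% c(3, 5))
  col <- if (categories == 3) "es_category3" else "es_category5"
  if (!col %in% names(records))
    stop("records are not scored (missing ", col, "); run score_cohort()")
  if (anyNA(records[[col]]))
    stop("unscored records present (ids: ",
         paste(utils::head(records$id[is.na(records[[col]])], 5L),
               collapse = ", "), ")")
  g <- if (is.null(groups)) factor(records$group,
                                   levels = unique(records$group))
  else factor(records$group, levels = groups)
  tab <- table(g, records[[col]])
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = dimnames(tab))
  names(dimnames(m)) <- NULL
  structure(m, percent = round(100 * prop.table(m, 1L), 1L),
            class = c("es_table", class(m)))
}

#' Build an `es_table` from printed counts
#'
#' Convenience for analysing published category counts directly.
#'
#' @param counts Integer matrix, rows = diagnostic groups, columns =
#'   ordinal categories in increasing order.
#' @return An `es_table`.
#' @export
es_table_from_counts <- function(counts) {
  m <- as.matrix(counts)
  if (any(m < 0) || any(m != round(m))) stop("counts must be non-negative integers")
  storage.mode(m) <- "integer"
  structure(m, percent = round(100 * prop.table(m, 1L), 1L),
            class = c("es_table", class(m)))
}

# Column mid-ranks of an ordinal contingency table and the tie terms.
.midrank_stats <- function(m) {
  ct <- colSums(m)
  N <- sum(ct)
  cum <- cumsum(ct)
  mid <- cum - (ct - 1) / 2
  list(N = N, ct = ct, mid = mid,
       mean_rank = as.vector(m %*% mid / rowSums(m)),
       tie_sum = sum(ct^3 - ct))
}

#' Tie-corrected Kruskal-Wallis test on an ordinal contingency table
#'
#' Computes the Kruskal-Wallis H statistic on the mid-ranks implied by the
#' table's column totals and divides by the tie correction
#' `C = 1 - sum(t^3 - t) / (N^3 - N)`; this is exactly the statistic a
#' rank test on the expanded per-subject ordinal vector would give.  The
#' p value uses the chi-square approximation with `k - 1` df.
#'
#' @param x An `es_table`/matrix of counts (groups x ordinal categories),
#'   or a vector of ordinal values when `g` is given.
#' @param g Optional group labels when `x` is a per-subject vector.
#' @return Object of class `kw_test`: `H`, `df`, `p`, `mean_ranks`.
#' @export
kruskal_wallis <- function(x, g = NULL) {
  m <- if (is.null(g)) as.matrix(x) else
    as.matrix(table(factor(g, levels = unique(g)), x))
  if (nrow(m) < 2L) stop("need at least two groups")
  if (any(rowSums(m) == 0L)) stop("every group must have observations")
  st <- .midrank_stats(m)
  if (ncol(m) < 2L || sum(colSums(m) > 0) < 2L) {
    H <- 0
  } else {
    ni <- rowSums(m)
    H <- 12 / (st$N * (st$N + 1)) *
      sum(ni * (st$mean_rank - (st$N + 1) / 2)^2)
    C <- 1 - st$tie_sum / (st$N^3 - st$N)
    if (C <= 0) stop("degenerate table: all observations in one category")
    H <- H / C
  }
  df <- nrow(m) - 1L
  structure(list(H = H, df = df,
                 p = stats::pchisq(H, df, lower.tail = FALSE),
                 mean_ranks = stats::setNames(st$mean_rank, rownames(m))),
            class = "kw_test")
}

#' @export
print.kw_test <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis (tie-corrected): chi2(df = %d) = %.4g, p = %.4g\n",
              x$df, x$H, x$p))
  invisible(x)
}

#' Dunn's pairwise comparisons with Bonferroni correction
#'
#' For each pair of groups, `z = (Rbar_i - Rbar_j) / sqrt(sigma2 (1/n_i +
#' 1/n_j))` with the tie-corrected rank variance
#' `sigma2 = N(N+1)/12 - sum(t^3 - t) / (12 (N - 1))`.  Two-sided normal
#' p values are Bonferroni-multiplied by the number of pairs and capped
#' at 1.
#'
#' @inheritParams kruskal_wallis
#' @return Object of class `dunn_test`: data frame with `group1`,
#'   `group2`, `z`, `p_raw`, `p_adjusted`.
#' @export
dunn_pairwise <- function(x, g = NULL) {
  m <- if (is.null(g)) as.matrix(x) else
    as.matrix(table(factor(g, levels = unique(g)), x))
  if (nrow(m) < 2L) stop("need at least two groups")
  if (any(rowSums(m) == 0L)) stop("every group must have observations")
  st <- .midrank_stats(m)
  ni <- rowSums(m)
  sigma2 <- st$N * (st$N + 1) / 12 - st$tie_sum / (12 * (st$N - 1))
  k <- nrow(m)
  pairs <- utils::combn(k, 2L)
  n_pairs <- ncol(pairs)
  z <- vapply(seq_len(n_pairs), function(q) {
    i <- pairs[1L, q]; j <- pairs[2L, q]
    se <- sqrt(sigma2 * (1 / ni[[i]] + 1 / ni[[j]]))
    if (se == 0) 0 else (st$mean_rank[[i]] - st$mean_rank[[j]]) / se
  }, numeric(1L))
  p_raw <- 2 * stats::pnorm(-abs(z))
  out <- data.frame(
    group1 = rownames(m)[pairs[1L, ]], group2 = rownames(m)[pairs[2L, ]],
    z = z, p_raw = p_raw, p_adjusted = pmin(1, n_pairs * p_raw))
  rownames(out) <- NULL
  structure(out, class = c("dunn_test", "data.frame"))
}

#' Diagnostic accuracy of the three-level categorisation
#'
#' Sensitivity and specificity at the asymmetric operating point used for
#' clinical reporting: a diseased subject counts as detected unless
#' classified "improbable" (i.e. positive = score >= 2), while a control
#' counts as misclassified only when called "probable" (score = 4) —
#' border and intermediate control results are not treated as false
#' positives.
#'
#' @param tab An `es_table` over the three categories.
#' @param disease_groups Row names pooled as the disease group (default
#'   `c("MCI-AD", "ADD")`).
#' @param control_group Row name of the control group.
#' @return Object of class `diag_accuracy`: sensitivity and specificity
#'   (proportions) with their numerators and denominators.
#' @export
diagnostic_accuracy <- function(tab, disease_groups = c("MCI-AD", "ADD"),
                                control_group = "Control") {
  m <- as.matrix(tab)
  if (ncol(m) != 3L)
    stop("diagnostic_accuracy expects the 3-category table")
  if (!all(disease_groups %in% rownames(m)) ||
      !control_group %in% rownames(m))
    stop("table must contain rows ", paste(
      c(disease_groups, control_group), collapse = ", "))
  dis <- colSums(m[disease_groups, , drop = FALSE])
  ctr <- m[control_group, ]
  n_dis <- sum(dis); n_ctr <- sum(ctr)
  if (n_dis == 0L || n_ctr == 0L) stop("empty disease or control pool")
  structure(list(
    sensitivity = (n_dis - dis[[1L]]) / n_dis,
    specificity = (n_ctr - ctr[[3L]]) / n_ctr,
    tp = n_dis - dis[[1L]], disease_n = n_dis,
    tn = n_ctr - ctr[[3L]], control_n = n_ctr,
    missed_disease = dis[[1L]], false_probable = ctr[[3L]]),
    class = "diag_accuracy")
}

#' @export
print.diag_accuracy <- function(x, ...) {
  cat(sprintf("Sensitivity %d/%d = %.1f%% | Specificity %d/%d = %.1f%%\n",
              x$tp, x$disease_n, 100 * x$sensitivity,
              x$tn, x$control_n, 100 * x$specificity))
  invisible(x)
}

#' Two-sample t test (pooled variance by default)
#'
#' Thin wrapper around [stats::t.test()] matching the reporting
#' convention of the group comparisons: two-tailed, Student's pooled
#' variance unless `welch = TRUE`.  Two identical constant samples give
#' `t = 0, p = 1` rather than an error.
#'
#' @param x,y Numeric samples (n >= 2 each).
#' @param welch Use the Welch unequal-variance form.
#' @return List with `t`, `df`, `p`.
#' @export
two_sample_ttest <- function(x, y, welch = FALSE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L)
    stop("each sample needs at least 2 observations")
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y))
      return(list(t = 0, df = length(x) + length(y) - 2, p = 1))
    return(list(t = Inf, df = length(x) + length(y) - 2, p = 0))
  }
  ht <- stats::t.test(x, y, var.equal = !welch)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}
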