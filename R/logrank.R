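# Weighted log-rank family for k-sample comparison of survival curves:
# standard log-rank (w = 1), Gehan-Breslow-Wilcoxon (w = n at risk) and a
# df = 1 trend test over ordinal group scores.

#' Weighted log-rank tests
#'
#' At every pooled event time the observed group event counts are compared
#' with their hypergeometric expectation given the risk sets; the weighted
#' sums are combined into a chi-square statistic with `k - 1` degrees of
#' freedom.  `type = "logrank"` weights every event time equally;
#' `type = "wilcoxon"` (Gehan-Breslow) weights by the pooled number at
#' risk, emphasising early differences; `type = "trend"` contrasts the
#' observed-minus-expected vector with ordinal group scores, giving a
#' 1-df test for ordered alternatives.
#'
#' @param time,event Survival input (positive times, 0/1 events).
#' @param group Group labels (factor or coercible); each group must be
#'   non-empty.
#' @param type One of `"logrank"`, `"wilcoxon"`, `"trend"`.
#' @param scores Ordinal scores for `type = "trend"`, one per group level;
#'   default `0:(k-1)` in level order.
#' @return Object of class `logrank_test`: list with `chi2`, `df`, `p`,
#'   `observed`, `expected` (per group) and `type`.
#' @examples
#' weighted_logrank(c(1, 2, 3, 4), c(1, 1, 1, 0), c("a", "a", "b", "b"))
#' @export
weighted_logrank <- function(time, event, group,
                             type = c("logrank", "wilcoxon", "trend"),
                             scores = NULL) {
  type <- match.arg(type)
  .check_surv_input(time, event)
  if (!is.factor(group)) group <- factor(group)   # keep declared levels
  if (nlevels(group) < 2L) stop("need at least two groups")
  if (any(table(group) == 0L)) stop("every group must contain subjects")
  k <- nlevels(group)

  dt <- sort(unique(time[event == 1]))
  OmE <- numeric(k)
  V <- matrix(0, k, k)
  for (t in dt) {
    at_risk <- time >= t
    n_j <- sum(at_risk)
    d_j <- sum(event[time == t])
    n_ij <- vapply(levels(group), function(g)
      sum(at_risk & group == g), numeric(1L))
    d_ij <- vapply(levels(group), function(g)
      sum(event[time == t & group == g]), numeric(1L))
    w <- if (type == "wilcoxon") n_j else 1
    p_i <- n_ij / n_j
    OmE <- OmE + w * (d_ij - d_j * p_i)
    if (n_j > 1) {
      mult <- w^2 * d_j * (n_j - d_j) / (n_j - 1)
      V <- V + mult * (diag(p_i, k) - outer(p_i, p_i))
    }
  }
  observed <- vapply(levels(group), function(g)
    sum(event[group == g]), numeric(1L))
  expected <- vapply(levels(group), function(g) {
    sum(vapply(dt, function(t)
      sum(event[time == t]) * sum(time >= t & group == g) / sum(time >= t),
      numeric(1L)))
  }, numeric(1L))                     # plain (unweighted) expected counts

  if (type == "trend") {
    if (is.null(scores)) scores <- seq_len(k) - 1
    if (length(scores) != k) stop("scores must have one entry per group")
    num <- sum(scores * OmE)
    den <- as.numeric(scores %*% V %*% scores)
    chi2 <- if (den <= .Machine$double.eps) 0 else num^2 / den
    df <- 1L
  } else {
    idx <- seq_len(k - 1L)
    Vsub <- V[idx, idx, drop = FALSE]
    oe <- OmE[idx]
    chi2 <- if (all(abs(oe) < 1e-12)) 0 else {
      sol <- tryCatch(solve(Vsub, oe), error = function(e) NULL)
      if (is.null(sol)) {
        as.numeric(oe %*% MASS::ginv(Vsub) %*% oe)
      } else as.numeric(oe %*% sol)
    }
    df <- k - 1L
  }
  structure(list(chi2 = chi2, df = df,
                 p = stats::pchisq(chi2, df, lower.tail = FALSE),
                 observed = observed, expected = expected, type = type),
            class = "logrank_test")
}

#' @export
print.logrank_test <- function(x, ...) {
  lab <- switch(x$type, logrank = "Log-rank",
                wilcoxon = "Wilcoxon (Gehan-Breslow)",
                trend = "Log-rank trend")
  cat(sprintf("%s test: chi2(df = %d) = %.4g, p = %.4g\n",
              lab, x$df, x$chi2, x$p))
  print(data.frame(observed = x$observed, expected = round(x$expected, 2)))
  invisible(x)
}
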