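# Cox partial-likelihood fitting on counting-process data (start, stop]
# by Newton-Raphson with step halving.  Risk sets are resolved with prefix
# sums over stop- and start-sorted episodes, so one evaluation is
# O(n log n + m p^2) for n episodes and m event times.  Breslow (default)
# and Efron tie corrections are available.

# Validate episodes and precompute sort orders / event-time groupings.
.cox_prep <- function(episodes, covariates) {
  stopifnot(is.data.frame(episodes))
  need <- c("start", "stop", "event")
  miss <- setdiff(c(need, covariates), names(episodes))
  if (length(miss))
    stop("episodes lack columns: ", paste(miss, collapse = ", "))
  keep <- stats::complete.cases(episodes[, c(need, covariates),
                                         drop = FALSE])
  ep <- episodes[keep, , drop = FALSE]
  start <- as.numeric(ep$start); stop_ <- as.numeric(ep$stop)
  event <- as.integer(ep$event)
  if (any(start < 0) || any(stop_ <= start))
    stop("episodes must satisfy 0 <= start < stop")
  if (any(!event %in% 0:1)) stop("event must be 0/1")
  if (sum(event) < 1L) stop("need at least one event")
  X <- as.matrix(ep[, covariates, drop = FALSE])
  storage.mode(X) <- "double"
  ev_idx <- which(event == 1L)
  ev_time <- stop_[ev_idx]
  o <- order(ev_time)
  ev_idx <- ev_idx[o]; ev_time <- ev_time[o]
  ut <- unique(ev_time)
  grp <- match(ev_time, ut)                 # tie group of each event row
  list(X = X, start = start, stop = stop_, event = event,
       n = nrow(X), p = ncol(X), covariates = covariates,
       ord_stop = order(stop_), ord_start = order(start),
       ev_idx = ev_idx, ev_time = ev_time, ut = ut, grp = grp,
       d = as.numeric(tabulate(grp, nbins = length(ut))),
       n_dropped = sum(!keep))
}

# Risk-set sums at each unique event time via prefix-sum differences:
# sum over {start < t <= stop} v  =  P_start[#start < t] - P_stop[#stop < t].
.risk_sums <- function(prep, V) {
  V <- as.matrix(V)
  cs_stop <- apply(V[prep$ord_stop, , drop = FALSE], 2L, cumsum)
  cs_start <- apply(V[prep$ord_start, , drop = FALSE], 2L, cumsum)
  pick <- function(cs, k) {
    out <- matrix(0, length(k), ncol(cs))
    nz <- k > 0L
    out[nz, ] <- cs[k[nz], , drop = FALSE]
    out
  }
  kstop <- findInterval(prep$ut, prep$stop[prep$ord_stop], left.open = TRUE)
  kstart <- findInterval(prep$ut, prep$start[prep$ord_start],
                         left.open = TRUE)
  pick(cs_start, kstart) - pick(cs_stop, kstop)
}

# Partial log-likelihood, score and information at beta.
# Returns per-event-time means (mu) for Schoenfeld residuals.
.cox_eval <- function(prep, beta, ties = "breslow") {
  X <- prep$X; p <- prep$p
  lp <- drop(X %*% beta)
  w <- exp(lp)
  pp_idx <- which(upper.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  XX <- X[, pp_idx[, 1L], drop = FALSE] * X[, pp_idx[, 2L], drop = FALSE]
  S0 <- drop(.risk_sums(prep, w))
  S1 <- .risk_sums(prep, X * w)
  S2 <- .risk_sums(prep, XX * w)
  if (any(S0 <= 0)) stop("empty risk set at an event time")

  d <- prep$d
  mu <- S1 / S0
  sumx <- rowsum(X[prep$ev_idx, , drop = FALSE], prep$grp)
  sumlp <- rowsum(lp[prep$ev_idx], prep$grp)

  sym <- function(v) {               # pp vector -> symmetric p x p
    M <- matrix(0, p, p)
    M[cbind(pp_idx[, 1L], pp_idx[, 2L])] <- v
    M[cbind(pp_idx[, 2L], pp_idx[, 1L])] <- v
    M
  }

  # Breslow accumulation (exact for untied event times)
  ll <- sum(sumlp) - sum(d * log(S0))
  U <- colSums(sumx) - colSums(d * mu)
  Imat <- sym(colSums(S2 * (d / S0))) - crossprod(mu, mu * d)

  if (ties == "efron" && any(d > 1)) {
    for (j in which(d > 1)) {
      rows <- prep$ev_idx[prep$grp == j]
      dj <- d[j]
      s0d <- sum(w[rows])
      s1d <- colSums(X[rows, , drop = FALSE] * w[rows])
      s2d <- colSums(XX[rows, , drop = FALSE] * w[rows])
      # remove the Breslow contribution of this tie group
      ll <- ll + dj * log(S0[j])
      U <- U + dj * mu[j, ]
      Imat <- Imat - sym(S2[j, ] * dj / S0[j]) +
        dj * tcrossprod(mu[j, ])
      for (l in seq_len(dj) - 1L) {
        f <- l / dj
        s0l <- S0[j] - f * s0d
        s1l <- S1[j, ] - f * s1d
        mul <- s1l / s0l
        ll <- ll - log(s0l)
        U <- U - mul
        Imat <- Imat + sym((S2[j, ] - f * s2d) / s0l) - tcrossprod(mul)
      }
    }
  }
  list(ll = ll, U = U, I = Imat, mu = mu, S0 = S0)
}

#' Fit a Cox model on counting-process episodes
#'
#' Maximises the partial likelihood over the requested covariate columns
#' by Newton-Raphson with step halving.  A subject is at risk at time `t`
#' on an episode `(start, stop]` iff `start < t <= stop`, which makes the
#' fitter equally applicable to time-constant data (`start = 0`) and to
#' Heaviside-split episodes from [episode_split()] — the extended Cox
#' model with time-varying covariate effects.  Standard errors come from
#' the inverse observed information; 95% confidence limits are Wald
#' (`coef +/- 1.96 se`), symmetric on the log-hazard scale.
#'
#' @param episodes Episode data frame (columns `start`, `stop`, `event`
#'   plus covariates); rows with missing covariates are dropped listwise.
#' @param covariates Character vector of covariate column names.
#' @param ties `"breslow"` (default) or `"efron"` tie correction.
#' @param init Initial coefficient vector (default zeros).
#' @param max_iter,tol Newton-Raphson controls: convergence when the
#'   log-likelihood improves by less than `tol` or the score's maximum
#'   absolute component falls below `tol`.
#' @return Object of class `cox_fit`: `coef`, `se`, `hr`, `ci_lower`,
#'   `ci_upper` (hazard-ratio scale), `var`, `loglik` (at optimum),
#'   `loglik_null`, `iter`, `ties`, `n`, `n_events`, `n_dropped`.
#' @export
cox_fit <- function(episodes, covariates, ties = c("breslow", "efron"),
                    init = NULL, max_iter = 100L, tol = 1e-9) {
  ties <- match.arg(ties)
  prep <- .cox_prep(episodes, covariates)
  p <- prep$p
  beta <- if (is.null(init)) rep(0, p) else as.numeric(init)
  stopifnot(length(beta) == p)

  ev <- .cox_eval(prep, beta, ties)
  ll0 <- .cox_eval(prep, rep(0, p), ties)$ll
  iter <- 0L
  repeat {
    iter <- iter + 1L
    step <- tryCatch(solve(ev$I, ev$U), error = function(e)
      stop("singular information matrix (collinear covariates?)"))
    halve <- 0L
    repeat {
      beta_new <- beta + step
      ev_new <- tryCatch(.cox_eval(prep, beta_new, ties),
                         error = function(e) NULL)
      if (!is.null(ev_new) && is.finite(ev_new$ll) &&
          ev_new$ll >= ev$ll - 1e-12) break
      halve <- halve + 1L
      if (halve > 30L)
        stop("Cox fit failed to improve the likelihood (iteration ",
             iter, "); monotone likelihood / separation suspected")
      step <- step / 2
    }
    delta_ll <- ev_new$ll - ev$ll
    beta <- beta_new; ev <- ev_new
    if (max(abs(beta)) > 20)
      stop("diverging coefficients (|beta| > 20); monotone likelihood ",
           "(complete separation) suspected")
    if (delta_ll < tol || max(abs(ev$U)) < tol) break
    if (iter >= max_iter)
      stop("Cox fit did not converge in ", max_iter,
           " iterations (last |dloglik| = ", format(delta_ll), ")")
  }
  V <- solve(ev$I)
  se <- sqrt(diag(V))
  names(beta) <- names(se) <- prep$covariates
  dimnames(V) <- list(prep$covariates, prep$covariates)
  z <- stats::qnorm(0.975)
  structure(
    list(coef = beta, se = se, var = V, hr = exp(beta),
         ci_lower = exp(beta - z * se), ci_upper = exp(beta + z * se),
         loglik = ev$ll, loglik_null = ll0, iter = iter, ties = ties,
         n = prep$n, n_events = length(prep$ev_idx),
         n_dropped = prep$n_dropped, covariates = prep$covariates),
    class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox model (%s ties): %d episodes, %d events, loglik %.2f, %d iterations\n",
              x$ties, x$n, x$n_events, x$loglik, x$iter))
  tab <- data.frame(coef = x$coef, se = x$se, HR = x$hr,
                    lower95 = x$ci_lower, upper95 = x$ci_upper,
                    p = 2 * stats::pnorm(-abs(x$coef / x$se)))
  print(round(tab, 4))
  invisible(x)
}

#' Schoenfeld residuals and the proportional-hazards score test
#'
#' For each event the Schoenfeld residual is the covariate value of the
#' subject that failed minus the risk-set weighted mean at that time; a
#' time trend in the residuals indicates a time-varying hazard ratio
#' (Grambsch-Therneau).  The test statistic is the score test for adding
#' the interaction `x * g(t)` of every covariate with a transform of
#' event time to the fitted model, evaluated at the fitted coefficients:
#' with `u_k = sum_i g_i s_ik` (residuals weighted by the centred
#' transform) and the observed information of the augmented model
#' assembled from the per-event-time risk sums, `chi2 = u' I^{-1} u`.
#' Per-covariate tests have 1 df; the global test has `p` df.
#' `transform = "identity"` tests against untransformed analysis time;
#' `"km"` uses `1 - KM(t-)` of the pooled follow-up distribution, which
#' damps the leverage of late event times.
#'
#' @param fit A [cox_fit()].
#' @param episodes The episode data the model was fitted on.
#' @param transform `"identity"` (default) or `"km"`.
#' @return Object of class `ph_test`: data frame `table` (chisq, df, p per
#'   covariate plus GLOBAL row) and the residual matrix in
#'   `residuals` with event times in `time`.
#' @export
schoenfeld_ph_test <- function(fit, episodes,
                               transform = c("identity", "km")) {
  transform <- match.arg(transform)
  stopifnot(inherits(fit, "cox_fit"))
  prep <- .cox_prep(episodes, fit$covariates)
  d_total <- length(prep$ev_idx)
  if (d_total < 3L) stop("need at least 3 events for the PH test")
  ev <- .cox_eval(prep, fit$coef, fit$ties)
  p <- prep$p
  # per-event residuals; within a tie group all events share the mean
  resid <- prep$X[prep$ev_idx, , drop = FALSE] -
    ev$mu[prep$grp, , drop = FALSE]
  g_ut <- if (transform == "identity") prep$ut else {
    km <- km_estimator(prep$stop, prep$event)
    idx <- findInterval(prep$ut, km$time, left.open = TRUE)
    1 - c(1, km$estimate)[idx + 1L]
  }
  g_ev <- g_ut[prep$grp]
  gc_ut <- g_ut - mean(g_ev)          # centre at the event mean
  gc_ev <- g_ev - mean(g_ev)

  u2 <- drop(gc_ev %*% resid)
  # information blocks of the augmented model (x, x * g(t)), Breslow form
  d <- prep$d
  pp_idx <- which(upper.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  sym <- function(v) {
    M <- matrix(0, p, p)
    M[cbind(pp_idx[, 1L], pp_idx[, 2L])] <- v
    M[cbind(pp_idx[, 2L], pp_idx[, 1L])] <- v
    M
  }
  lp <- drop(prep$X %*% fit$coef)
  w <- exp(lp)
  XX <- prep$X[, pp_idx[, 1L], drop = FALSE] *
    prep$X[, pp_idx[, 2L], drop = FALSE]
  S0 <- drop(.risk_sums(prep, w))
  S1 <- .risk_sums(prep, prep$X * w)
  S2 <- .risk_sums(prep, XX * w)
  mu <- S1 / S0
  Vj_weight <- function(a)            # sum_j a_j d_j (S2/S0 - mu mu')
    sym(colSums(S2 * (a * d / S0))) - crossprod(mu, mu * (a * d))
  I11 <- Vj_weight(rep(1, length(d)))
  I12 <- Vj_weight(gc_ut)
  I22 <- Vj_weight(gc_ut^2)
  imat <- rbind(cbind(I11, I12), cbind(I12, I22))

  chisq <- vapply(seq_len(p), function(k) {
    kk <- c(seq_len(p), p + k)
    u <- c(rep(0, p), u2[k])
    drop(u %*% solve(imat[kk, kk], u))
  }, numeric(1L))
  u_full <- c(rep(0, p), u2)
  global <- drop(u_full %*% solve(imat, u_full))
  tab <- data.frame(
    chisq = c(chisq, global),
    df = c(rep(1L, p), p),
    p = stats::pchisq(c(chisq, global), c(rep(1L, p), p),
                      lower.tail = FALSE),
    row.names = c(fit$covariates, "GLOBAL"))
  structure(list(table = tab, residuals = resid, time = prep$ev_time,
                 transform = transform),
            class = "ph_test")
}

#' @export
print.ph_test <- function(x, ...) {
  cat("Proportional-hazards test (scaled Schoenfeld residuals vs ",
      x$transform, " time)\n", sep = "")
  print(round(x$table, 4))
  invisible(x)
}
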