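# Nonparametric estimators: Kaplan-Meier product-limit survival and
# Nelson-Aalen cumulative hazard, plus an interval risk table.

.check_surv_input <- function(time, event) {
  if (length(time) == 0L) stop("empty survival input")
  if (length(event) != length(time))
    stop("time and event must have the same length")
  if (any(!is.finite(time)) || any(time <= 0))
    stop("all times must be positive and finite")
  if (any(!event %in% c(0, 1)))
    stop("event must be 0/1")
  invisible(NULL)
}

.surv_table <- function(time, event) {
  ut <- sort(unique(time))
  idx <- match(time, ut)
  n_total <- tabulate(idx, nbins = length(ut))
  n_event <- as.vector(rowsum(as.numeric(event), idx))
  n_risk <- length(time) - c(0, cumsum(n_total))[seq_along(ut)]
  data.frame(time = ut, n_risk = n_risk, n_event = n_event,
             n_censor = n_total - n_event)
}

#' Kaplan-Meier product-limit estimator
#'
#' `S(t) = prod over event times t_i <= t of (1 - d_i / n_i)` with `d_i`
#' events among `n_i` at risk.  No variance estimate is attached; the
#' estimator is meant for curve comparison and risk tables.
#'
#' @param time Positive follow-up times (years).
#' @param event 0/1 event indicators.
#' @return Object of class `surv_curve` (type `"km"`): data frame of
#'   `time`, `n_risk`, `n_event`, `n_censor`, `estimate` (S(t) after the
#'   time point), with attributes `type` and `n`.
#' @examples
#' km_estimator(c(1, 2, 3), c(1, 1, 0))
#' @export
km_estimator <- function(time, event) {
  .check_surv_input(time, event)
  tab <- .surv_table(time, event)
  tab$estimate <- cumprod(1 - tab$n_event / tab$n_risk)
  structure(tab, class = c("surv_curve", "data.frame"),
            type = "km", n = length(time))
}

#' Nelson-Aalen cumulative hazard estimator
#'
#' `H(t) = sum over event times t_i <= t of d_i / n_i`.
#'
#' @inheritParams km_estimator
#' @return Object of class `surv_curve` (type `"na"`); `estimate` holds
#'   H(t).
#' @export
na_estimator <- function(time, event) {
  .check_surv_input(time, event)
  tab <- .surv_table(time, event)
  tab$estimate <- cumsum(tab$n_event / tab$n_risk)
  structure(tab, class = c("surv_curve", "data.frame"),
            type = "na", n = length(time))
}

#' Evaluate a step curve at arbitrary times
#'
#' @param curve A `surv_curve`.
#' @param at Times at which to read off the estimate (right-continuous
#'   step function; before the first event time KM returns 1 and NA 0).
#' @return Numeric vector.
#' @export
curve_at <- function(curve, at) {
  stopifnot(inherits(curve, "surv_curve"))
  base <- if (attr(curve, "type") == "km") 1 else 0
  idx <- findInterval(at, curve$time)
  ifelse(idx == 0L, base, curve$estimate[pmax(idx, 1L)])
}

#' Interval risk table
#'
#' Number of subjects at risk at the start of each interval of a regular
#' grid, and the numbers of events and censorings within each interval —
#' the tabulation conventionally printed under a Kaplan-Meier plot.
#'
#' @param time,event Survival input (as [km_estimator()]).
#' @param by Interval width in years (default 2).
#' @param max_time Upper end of the grid; defaults to the largest follow-up.
#' @return Data frame with `interval_start`, `n_risk`, `n_event`,
#'   `n_censor`.
#' @export
risk_table <- function(time, event, by = 2, max_time = max(time)) {
  .check_surv_input(time, event)
  starts <- seq(0, max_time, by = by)
  data.frame(
    interval_start = starts,
    n_risk = vapply(starts, function(s) sum(time >= s), numeric(1L)),
    n_event = vapply(starts, function(s)
      sum(event == 1 & time >= s & time < s + by), numeric(1L)),
    n_censor = vapply(starts, function(s)
      sum(event == 0 & time >= s & time < s + by), numeric(1L))
  )
}

#' @export
print.surv_curve <- function(x, ...) {
  lab <- if (attr(x, "type") == "km") "Kaplan-Meier survival" else
    "Nelson-Aalen cumulative hazard"
  cat(lab, " estimate (n = ", attr(x, "n"), ", ",
      sum(x$n_event), " events)\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 20L), row.names = FALSE)
  if (nrow(x) > 20L) cat("  ... ", nrow(x) - 20L, " more rows\n", sep = "")
  invisible(x)
}

#' Export a curve as TSV
#'
#' Columns `time`, `estimate`, `n_risk`, `n_events`, `n_censored`.
#'
#' @param curve A `surv_curve`.
#' @param path Output path.
#' @export
write_curve_tsv <- function(curve, path) {
  stopifnot(inherits(curve, "surv_curve"))
  out <- data.frame(time = curve$time, estimate = curve$estimate,
                    n_risk = curve$n_risk, n_events = curve$n_event,
                    n_censored = curve$n_censor)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
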