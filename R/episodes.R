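# Counting-process episode splitting with a Heaviside time split: the
# "possible" category's effect is decomposed into an early segment
# (t <= split_time) and a late segment (t > split_time), so a Cox model on
# the split data estimates two hazard ratios for one covariate.

#' Split follow-up into counting-process episodes at a Heaviside point
#'
#' Each subject contributes one row `(0, followup]` if followed at most
#' `split_time` years, otherwise two rows `(0, split_time]` and
#' `(split_time, followup]`; the event flag sits on the last row.  The
#' time-varying indicators are `possible_early = possible * 1(t <=
#' split_time)` and `possible_late = possible * 1(t > split_time)`;
#' `probable` stays time constant.  An event at exactly `split_time`
#' belongs to the early segment.  Total exposure and total events are
#' preserved exactly.
#'
#' @param records Data frame with columns `id`, `followup_years`, `event`
#'   and `es_category3` (improbable/possible/probable); any further
#'   columns (e.g. covariates `age`, `female`, `apoe4`, `mmse`) are
#'   carried through unchanged.
#' @param split_time Heaviside split point in years (> 0), default 3.
#' @return Data frame of episodes: `id`, `start`, `stop`, `event`,
#'   `possible_early`, `possible_late`, `probable`, plus carried columns.
#' @examples
#' recs <- data.frame(id = "a", followup_years = 5, event = 1,
#'                    es_category3 = "possible")
#' episode_split(recs)
#' @export
episode_split <- function(records, split_time = 3) {
  stopifnot(is.data.frame(records), split_time > 0)
  need <- c("id", "followup_years", "event", "es_category3")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("records lack required columns: ", paste(miss, collapse = ", "))
  fu <- as.numeric(records$followup_years)
  ev <- as.integer(records$event)
  if (any(is.na(fu)) || any(fu <= 0))
    stop("invalid record: followup_years must be positive (ids: ",
         paste(utils::head(records$id[is.na(fu) | fu <= 0], 5L),
               collapse = ", "), ")")
  if (any(is.na(ev)) || any(!ev %in% 0:1))
    stop("invalid record: event must be 0/1")
  cat3 <- as.character(records$es_category3)
  if (any(!cat3 %in% c("improbable", "possible", "probable")))
    stop("es_category3 must be improbable/possible/probable")

  carry <- setdiff(names(records), c("followup_years", "event"))
  possible <- as.integer(cat3 == "possible")
  probable <- as.integer(cat3 == "probable")

  long <- fu > split_time
  # early rows: everyone; late rows: only subjects followed past the split
  early <- data.frame(start = 0, stop = pmin(fu, split_time),
                      event = ifelse(long, 0L, ev),
                      possible_early = possible, possible_late = 0L,
                      probable = probable,
                      records[, carry, drop = FALSE],
                      check.names = FALSE)
  out <- early
  if (any(long)) {
    late <- data.frame(start = rep(split_time, sum(long)),
                       stop = fu[long], event = ev[long],
                       possible_early = integer(sum(long)),
                       possible_late = possible[long],
                       probable = probable[long],
                       records[long, carry, drop = FALSE],
                       check.names = FALSE)
    out <- rbind(early, late)
  }
  out <- out[order(match(out$id, records$id), out$start), ]
  rownames(out) <- NULL
  front <- c("id", "start", "stop", "event", "possible_early",
             "possible_late", "probable")
  out[, c(front, setdiff(names(out), front))]
}

#' Build unsplit (time-constant) episodes
#'
#' One `(0, followup]` row per subject with the plain `possible` and
#' `probable` indicators — the input for the proportional-hazards
#' comparison model.
#'
#' @inheritParams episode_split
#' @return Episode data frame with `possible` and `probable` columns.
#' @export
episodes_unsplit <- function(records) {
  stopifnot(is.data.frame(records))
  cat3 <- as.character(records$es_category3)
  carry <- setdiff(names(records), c("followup_years", "event"))
  out <- data.frame(start = 0, stop = as.numeric(records$followup_years),
                    event = as.integer(records$event),
                    possible = as.integer(cat3 == "possible"),
                    probable = as.integer(cat3 == "probable"),
                    records[, carry, drop = FALSE], check.names = FALSE)
  if (any(is.na(out$stop)) || any(out$stop <= 0))
    stop("invalid record: followup_years must be positive")
  rownames(out) <- NULL
  front <- c("id", "start", "stop", "event", "possible", "probable")
  out[, c(front, setdiff(names(out), front))]
}
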