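# Erlangen Score: per-marker classification, group severities, total score.
#
# The score combines two pathology axes. Amyloid markers (Abeta1-42 and the
# Abeta42/40 ratio) are pathologic when LOW, tau markers (Tau, pTau181) when
# HIGH. Each marker is normal (0), border (1: pathologic by direction but
# within the border band of the cutoff) or evidently pathologic (2); a
# group's severity is the worst of its available markers, and the total
# score is the sum of the two group severities (0-4).

.status_levels <- c("normal", "border", "pathologic")

# Vectorised severity classification; NA passes through, no validation.
.classify_severity <- function(value, spec) {
  lo <- (1 - spec$border_fraction) * spec$cutoff
  hi <- (1 + spec$border_fraction) * spec$cutoff
  if (spec$direction == "low") {
    ifelse(value >= spec$cutoff, 0L, ifelse(value >= lo, 1L, 2L))
  } else {
    ifelse(value <= spec$cutoff, 0L, ifelse(value <= hi, 1L, 2L))
  }
}

#' Classify a marker value against its reference specification
#'
#' A value exactly at the cutoff is normal; the border zone lies strictly
#' beyond the cutoff, up to and including the band edge
#' (`(1 -/+ border_fraction) * cutoff`); values strictly beyond the band are
#' evidently pathologic.  Classification is scale invariant: doubling both
#' the value and the cutoff leaves the status unchanged.
#'
#' @param value Numeric vector of positive marker values (concentration or
#'   ratio).
#' @param spec A [marker_spec()].
#' @return A `marker_status` data frame with columns `label` (factor:
#'   normal/border/pathologic) and `severity` (integer 0/1/2), one row per
#'   value.
#' @examples
#' classify_marker(178.3, marker_spec("tau", 250, "high"))    # normal
#' classify_marker(522,   marker_spec("abeta42", 580, "low")) # border edge
#' @export
classify_marker <- function(value, spec) {
  if (!inherits(spec, "marker_spec")) stop("spec must be a marker_spec")
  if (!is.numeric(value) || length(value) < 1L)
    stop("value for marker '", spec$name, "' must be numeric")
  bad <- !is.na(value) & (!is.finite(value) | value <= 0)
  if (any(bad))
    stop("non-positive value for marker '", spec$name, "': ",
         paste(utils::head(value[bad], 3L), collapse = ", "))
  sev <- .classify_severity(value, spec)
  structure(
    data.frame(label = factor(.status_levels[sev + 1L],
                              levels = .status_levels),
               severity = sev),
    class = c("marker_status", "data.frame")
  )
}

#' Combine the marker statuses of one group into a group severity
#'
#' A single evidently altered marker suffices for an evident group
#' alteration ("or" logic): the group severity is the maximum severity among
#' the group's available markers.
#'
#' @param severities Integer vector of 0/1/2 severities (or a
#'   `marker_status` data frame); `NA`s (unavailable markers) are dropped.
#' @return Integer scalar 0, 1 or 2.
#' @export
group_severity <- function(severities) {
  if (inherits(severities, "marker_status")) severities <- severities$severity
  severities <- severities[!is.na(severities)]
  if (length(severities) == 0L)
    stop("no marker available for this group (missing-group)")
  if (!all(severities %in% 0:2)) stop("severities must be 0, 1 or 2")
  max(as.integer(severities))
}

#' Map a total score to its interpretive categories
#'
#' Five-level category equals the score itself; the three-level reporting
#' categories combine 0-1 as "improbable", 2-3 as "possible" and 4 as
#' "probable" (neurochemical evidence for Alzheimer's disease).
#'
#' @param score Integer vector with values in 0..4.
#' @return Data frame with columns `category5` (ordered factor `0`..`4`) and
#'   `category3` (ordered factor improbable < possible < probable).
#' @export
categorize <- function(score) {
  if (!is.numeric(score) || any(!is.na(score) & !(score %in% 0:4)))
    stop("score must be an integer between 0 and 4")
  data.frame(
    category5 = factor(score, levels = 0:4, ordered = TRUE),
    category3 = es_category3(score)
  )
}

#' @rdname categorize
#' @export
es_category3 <- function(score) {
  lab <- ifelse(is.na(score), NA_character_,
                ifelse(score <= 1, "improbable",
                       ifelse(score <= 3, "possible", "probable")))
  factor(lab, levels = c("improbable", "possible", "probable"),
         ordered = TRUE)
}

#' Compute the Erlangen Score for one biomarker panel
#'
#' Classifies each available marker against the reference panel, takes the
#' worst status per pathology group (amyloid: Abeta1-42, Abeta42/40; tau:
#' Tau, pTau181) and sums the two group severities into the 0-4 score.  If
#' the ratio is not measured but both Abeta concentrations are present, the
#' ratio is derived as `abeta42 / abeta40` and classified; a measured ratio
#' always takes precedence over a derivable one.  At least one marker per
#' group must be available.
#'
#' @param panel Named list or numeric vector with any subset of `abeta42`,
#'   `abeta40`, `abeta42_40_ratio`, `tau`, `ptau181` (positive values,
#'   missing markers `NA` or absent).
#' @param refs A [reference_panel()]; defaults to
#'   [default_reference_panel()].
#' @return An object of class `es_result`: list with `amyloid_severity`,
#'   `tau_severity`, `score`, `category5`, `category3` and `per_marker`
#'   (named severity vector for the markers that were classified).
#' @examples
#' erlangen_score(list(abeta42 = 459.6, abeta42_40_ratio = 0.046,
#'                     tau = 448, ptau181 = 59))
#' @export
erlangen_score <- function(panel, refs = default_reference_panel()) {
  stopifnot(inherits(refs, "reference_panel"))
  panel <- as.list(panel)
  get1 <- function(nm) {
    v <- panel[[nm]]
    if (is.null(v) || length(v) == 0L || is.na(v)) NA_real_ else {
      if (!is.numeric(v) || length(v) != 1L)
        stop("panel entry '", nm, "' must be a single numeric value")
      as.numeric(v)
    }
  }
  vals <- c(abeta42 = get1("abeta42"),
            abeta42_40_ratio = get1("abeta42_40_ratio"),
            tau = get1("tau"), ptau181 = get1("ptau181"))
  ab40 <- get1("abeta40")
  bad <- !is.na(c(vals, abeta40 = ab40)) & c(vals, abeta40 = ab40) <= 0
  if (any(bad))
    stop("non-positive value for marker '",
         names(bad)[bad][1L], "'")
  if (is.na(vals["abeta42_40_ratio"]) && !is.na(vals["abeta42"]) &&
      !is.na(ab40))
    vals["abeta42_40_ratio"] <- vals[["abeta42"]] / ab40
  avail <- names(vals)[!is.na(vals) & names(vals) %in% names(refs)]
  sev <- vapply(avail, function(nm)
    .classify_severity(vals[[nm]], refs[[nm]]), integer(1L))
  amy <- sev[avail %in% amyloid_markers()]
  tau <- sev[avail %in% tau_markers()]
  if (length(amy) == 0L)
    stop("no amyloid-group marker available (missing-group)")
  if (length(tau) == 0L)
    stop("no tau-group marker available (missing-group)")
  amyloid_severity <- max(amy)
  tau_severity <- max(tau)
  score <- amyloid_severity + tau_severity
  cats <- categorize(score)
  structure(
    list(amyloid_severity = amyloid_severity, tau_severity = tau_severity,
         score = score, category5 = cats$category5,
         category3 = cats$category3, per_marker = sev),
    class = "es_result"
  )
}

#' @export
print.es_result <- function(x, ...) {
  cat("Erlangen Score:", x$score,
      sprintf("(amyloid %d + tau %d) -> neurochemically %s AD\n",
              x$amyloid_severity, x$tau_severity, as.character(x$category3)))
  st <- .status_levels[x$per_marker + 1L]
  cat("  ", paste(sprintf("%s=%s", names(x$per_marker), st),
                  collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Score a cohort table
#'
#' Vectorised batch scoring.  Input rows that cannot be scored (non-positive
#' marker value, or a whole pathology group unavailable) are kept, flagged
#' in `es_reason`, and carry `NA` in the score columns; valid rows get
#' `amyloid_severity`, `tau_severity`, `es_score`, `es_category5`,
#' `es_category3`.
#'
#' @param data Data frame with (any of) columns `abeta42`, `abeta40`,
#'   `abeta42_40_ratio`, `tau`, `ptau181`; other columns pass through
#'   untouched and row order is preserved.
#' @param refs A [reference_panel()].
#' @return `data` with the five score columns and `es_reason` (`NA` for
#'   scored rows) appended.
#' @export
score_cohort <- function(data, refs = default_reference_panel()) {
  stopifnot(is.data.frame(data), inherits(refs, "reference_panel"))
  n <- nrow(data)
  col <- function(nm) {
    if (nm %in% names(data)) as.numeric(data[[nm]]) else rep(NA_real_, n)
  }
  vals <- list(abeta42 = col("abeta42"),
               abeta42_40_ratio = col("abeta42_40_ratio"),
               tau = col("tau"), ptau181 = col("ptau181"))
  ab40 <- col("abeta40")

  nonpos <- rep(FALSE, n)
  for (v in c(vals, list(ab40)))
    nonpos <- nonpos | (!is.na(v) & (!is.finite(v) | v <= 0))

  derive <- is.na(vals$abeta42_40_ratio) & !is.na(vals$abeta42) & !is.na(ab40)
  vals$abeta42_40_ratio[derive] <- vals$abeta42[derive] / ab40[derive]

  sev <- lapply(names(vals), function(nm) {
    if (nm %in% names(refs)) .classify_severity(vals[[nm]], refs[[nm]])
    else rep(NA_integer_, n)
  })
  names(sev) <- names(vals)
  pmax_na <- function(a, b) {
    out <- pmax(a, b, na.rm = TRUE)
    out[is.na(a) & is.na(b)] <- NA_integer_
    out
  }
  amy <- pmax_na(sev$abeta42, sev$abeta42_40_ratio)
  tau <- pmax_na(sev$tau, sev$ptau181)

  reason <- rep(NA_character_, n)
  reason[is.na(tau)] <- "tau group unavailable"
  reason[is.na(amy)] <- "amyloid group unavailable"
  reason[is.na(amy) & is.na(tau)] <- "amyloid and tau groups unavailable"
  reason[nonpos] <- "non-positive marker value"
  ok <- is.na(reason)

  score <- rep(NA_integer_, n)
  score[ok] <- as.integer(amy[ok] + tau[ok])
  data$amyloid_severity <- ifelse(ok, amy, NA_integer_)
  data$tau_severity <- ifelse(ok, tau, NA_integer_)
  data$es_score <- score
  data$es_category5 <- factor(score, levels = 0:4, ordered = TRUE)
  data$es_category3 <- es_category3(score)
  data$es_reason <- reason
  data
}
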