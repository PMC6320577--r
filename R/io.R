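# Cohort CSV schema, readers and writers.  One schema serves both
# externally supplied and simulated cohorts: since study data of this
# kind are rarely deposited, the file format is the integration contract.

#' Cohort CSV schema
#'
#' Column names and types of the cohort file: comma-separated, UTF-8,
#' header required, missing values as empty fields.
#'
#' @return Named character vector mapping column name to type.
#' @export
cohort_schema <- function() {
  c(id = "character", group = "character", age = "numeric",
    female = "integer", apoe4 = "integer", mmse = "integer",
    abeta42 = "numeric", abeta40 = "numeric",
    abeta42_40_ratio = "numeric", tau = "numeric", ptau181 = "numeric",
    followup_years = "numeric", event = "integer")
}

cohort_schema_empty <- function() {
  sch <- cohort_schema()
  df <- lapply(sch, function(tp) vector(tp, 0L))
  as.data.frame(df, stringsAsFactors = FALSE)
}

#' Read a cohort CSV
#'
#' Enforces the header of [cohort_schema()] exactly (order included) and
#' validates rows: non-positive marker values or follow-up times,
#' out-of-range flags and malformed numbers reject the affected row with
#' its line number; duplicate ids or a wrong header are fatal.
#'
#' @param path Path to the CSV file.
#' @return Data frame of valid rows in input order, with attribute
#'   `"rejected"` (data frame `line`, `id`, `reason`; zero rows when
#'   clean).  A message summarises rejections.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, fileEncoding = "UTF-8")
  sch <- cohort_schema()
  if (!identical(names(raw), names(sch)))
    stop("malformed header in ", path, "\n  expected: ",
         paste(names(sch), collapse = ","), "\n  found:    ",
         paste(names(raw), collapse = ","))
  if (anyDuplicated(raw$id[raw$id != ""]))
    stop("duplicate ids in ", path, ": ",
         paste(unique(raw$id[duplicated(raw$id)]), collapse = ", "))

  n <- nrow(raw)
  reason <- rep(NA_character_, n)
  out <- cohort_schema_empty()[rep(1L, max(n, 1L))[seq_len(n)], ,
                               drop = FALSE]
  num <- function(x) suppressWarnings(as.numeric(ifelse(x == "", NA, x)))
  flag_bad <- function(bad, msg)
    reason <<- ifelse(is.na(reason) & bad, msg, reason)

  out$id <- raw$id
  flag_bad(raw$id == "", "missing id")
  out$group <- ifelse(raw$group == "", NA_character_, raw$group)
  for (cn in c("age", "abeta42", "abeta40", "abeta42_40_ratio", "tau",
               "ptau181", "followup_years")) {
    v <- num(raw[[cn]])
    flag_bad(raw[[cn]] != "" & is.na(v), paste("malformed", cn))
    if (cn == "age") flag_bad(!is.na(v) & (v <= 0 | v > 120),
                              "implausible age")
    else flag_bad(!is.na(v) & v <= 0,
                  paste0("non-positive ", if (cn == "followup_years")
                    "follow-up" else "concentration", " (", cn, ")"))
    out[[cn]] <- v
  }
  for (cn in c("female", "apoe4", "mmse", "event")) {
    v <- num(raw[[cn]])
    flag_bad(raw[[cn]] != "" & is.na(v), paste("malformed", cn))
    rng <- if (cn == "mmse") 0:30 else 0:1
    flag_bad(!is.na(v) & !v %in% rng, paste("out-of-range", cn))
    out[[cn]] <- as.integer(v)
  }
  bad <- !is.na(reason)
  rejected <- data.frame(line = which(bad) + 1L, id = raw$id[bad],
                         reason = reason[bad])
  if (nrow(rejected))
    message(nrow(rejected), " row(s) rejected while reading ", path,
            " (see attr(., 'rejected'))")
  res <- out[!bad, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "rejected") <- rejected
  res
}

#' Write a cohort (or scored cohort) CSV
#'
#' Writes the schema columns plus, when present, the score columns
#' appended by [score_cohort()].  Missing values become empty fields; the
#' decimal separator is always the point, independent of locale.
#'
#' @param data Cohort data frame.
#' @param path Output path.
#' @param scored Include score columns if present (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(data, path, scored = TRUE) {
  cols <- names(cohort_schema())
  miss <- setdiff(cols, names(data))
  if (length(miss))
    stop("cohort data lack columns: ", paste(miss, collapse = ", "))
  extra <- c("amyloid_severity", "tau_severity", "es_score",
             "es_category5", "es_category3")
  if (scored) cols <- c(cols, intersect(extra, names(data)))
  df <- data[, cols, drop = FALSE]
  for (cn in names(df)) if (is.factor(df[[cn]]))
    df[[cn]] <- as.character(df[[cn]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read or write a simulation configuration file
#'
#' YAML or JSON (by extension) with keys `profiles` (per group: `n`,
#' `markers` as `[median, q25, q75]`, `age`, `female_fraction`,
#' `apoe4_fraction`, `mmse`), `hazard`, `correlations`, `censor_window`
#' and `seed`; omitted keys fall back to the package defaults.
#'
#' @param path Config file path.
#' @return A [simulation_config()].
#' @export
read_simulation_config <- function(path) {
  if (!file.exists(path)) stop("simulation config not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  profiles <- if (is.null(cfg$profiles)) default_group_profiles() else
    lapply(names(cfg$profiles), function(g) {
      p <- cfg$profiles[[g]]
      group_profile(
        g, p$n, markers = lapply(p$markers, as.numeric),
        age = as.numeric(p$age),
        female_fraction = p$female_fraction,
        apoe4_fraction = p$apoe4_fraction %||% NA_real_,
        mmse = if (is.null(p$mmse)) NA else as.numeric(p$mmse))
    })
  hz <- cfg$hazard %||% list()
  hazard <- hazard_spec(
    baseline_rate = hz$baseline_rate %||% 0.04,
    hr_possible_early = hz$hr_possible_early %||% 7.67,
    hr_possible_late = hz$hr_possible_late %||% 1.04,
    hr_probable = hz$hr_probable %||% 12.0,
    split_time = hz$split_time %||% 3)
  corr <- if (is.null(cfg$correlations)) default_marker_correlations()
  else {
    m <- as.matrix(as.data.frame(cfg$correlations))
    dimnames(m) <- list(colnames(m), colnames(m))
    m
  }
  simulation_config(profiles = profiles, hazard = hazard,
                    correlations = corr,
                    censor_window = as.numeric(cfg$censor_window %||%
                                                 c(2, 12)),
                    seed = cfg$seed %||% 1L)
}

#' Write simulation metadata sidecar
#'
#' Records the seed, hazard specification, censor window and per-group
#' sizes of a simulation run as JSON next to the cohort file.
#'
#' @param config The [simulation_config()] used.
#' @param path Output JSON path.
#' @export
write_simulation_metadata <- function(config, path) {
  meta <- list(
    seed = config$seed,
    hazard = unclass(config$hazard),
    censor_window = config$censor_window,
    groups = lapply(config$profiles, function(p)
      list(group = p$group, n = p$n)))
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
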