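# Reference panels: per-marker cutoffs, pathology directions and border zones.

#' Supported CSF marker names
#'
#' The four markers the Erlangen Score operates on, by canonical column name.
#' `abeta42` and `abeta42_40_ratio` form the amyloid group; `tau` and
#' `ptau181` form the tau (neurodegeneration) group.
#'
#' @return Character vector of the four marker identifiers.
#' @export
es_markers <- function() c("abeta42", "abeta42_40_ratio", "tau", "ptau181")

#' @rdname es_markers
#' @export
amyloid_markers <- function() c("abeta42", "abeta42_40_ratio")

#' @rdname es_markers
#' @export
tau_markers <- function() c("tau", "ptau181")

#' Create a marker specification
#'
#' A `marker_spec` holds the reference value (cutoff) for one CSF marker,
#' the direction in which the marker becomes pathologic, and the relative
#' width of the border zone around the cutoff.  Values pathologic by
#' direction but within `border_fraction` of the cutoff are classified as
#' border-zone results (severity 1) rather than evident alterations
#' (severity 2).  The border band is multiplicative: for a "low" marker it
#' spans `[(1 - border_fraction) * cutoff, cutoff)`, for a "high" marker
#' `(cutoff, (1 + border_fraction) * cutoff]`.
#'
#' @param name Marker identifier, one of [es_markers()].
#' @param cutoff Reference value in the marker's native units (pg/ml for the
#'   concentrations, dimensionless for the ratio); must be positive.
#' @param direction `"low"` if values below the cutoff are pathologic
#'   (amyloid markers) or `"high"` if values above are (tau markers).
#' @param border_fraction Relative half-width of the border zone, in (0, 1).
#'   Default 0.10, i.e. a 10% band.
#' @return An object of class `marker_spec`.
#' @seealso [default_reference_panel()], [classify_marker()]
#' @export
marker_spec <- function(name, cutoff, direction = c("low", "high"),
                        border_fraction = 0.10) {
  direction <- match.arg(direction)
  if (!is.character(name) || length(name) != 1L || !name %in% es_markers())
    stop("unknown marker name: ", paste(name, collapse = ", "),
         " (expected one of ", paste(es_markers(), collapse = ", "), ")")
  if (!is.numeric(cutoff) || length(cutoff) != 1L || !is.finite(cutoff) ||
      cutoff <= 0)
    stop("cutoff for marker '", name, "' must be a positive number")
  if (!is.numeric(border_fraction) || length(border_fraction) != 1L ||
      !is.finite(border_fraction) || border_fraction <= 0 ||
      border_fraction >= 1)
    stop("border_fraction for marker '", name, "' must lie in (0, 1)")
  structure(
    list(name = name, cutoff = as.numeric(cutoff), direction = direction,
         border_fraction = as.numeric(border_fraction)),
    class = "marker_spec"
  )
}

#' Assemble a reference panel from marker specifications
#'
#' @param ... `marker_spec` objects, at most one per marker.  The panel must
#'   contain at least one amyloid-group and one tau-group marker.
#' @return An object of class `reference_panel`: a named list of
#'   `marker_spec`s.
#' @export
reference_panel <- function(...) {
  specs <- list(...)
  if (length(specs) == 1L && is.list(specs[[1L]]) &&
      !inherits(specs[[1L]], "marker_spec"))
    specs <- specs[[1L]]
  ok <- vapply(specs, inherits, logical(1L), what = "marker_spec")
  if (!all(ok)) stop("all panel entries must be marker_spec objects")
  nms <- vapply(specs, `[[`, character(1L), "name")
  if (anyDuplicated(nms))
    stop("duplicate marker specification: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  names(specs) <- nms
  if (!any(nms %in% amyloid_markers()))
    stop("reference panel needs at least one amyloid marker (",
         paste(amyloid_markers(), collapse = ", "), ")")
  if (!any(nms %in% tau_markers()))
    stop("reference panel needs at least one tau marker (",
         paste(tau_markers(), collapse = ", "), ")")
  structure(specs, class = "reference_panel")
}

#' Default reference panel
#'
#' The laboratory reference values used throughout this package's worked
#' examples: 580 pg/ml for Abeta1-42, 0.068 for the Abeta42/40 ratio,
#' 250 pg/ml for Tau and 37 pg/ml for pTau181, each with a 10% border zone.
#' Reference values are laboratory- and platform-specific; use
#' [read_reference_panel()] to supply your own.
#'
#' @return A `reference_panel`.
#' @export
default_reference_panel <- function() {
  reference_panel(
    marker_spec("abeta42", 580, "low"),
    marker_spec("abeta42_40_ratio", 0.068, "low"),
    marker_spec("tau", 250, "high"),
    marker_spec("ptau181", 37, "high")
  )
}

#' Read or write a reference panel configuration file
#'
#' The file (YAML or JSON, chosen by extension) maps marker names to
#' `{cutoff, direction, border_fraction}`; `direction` and `border_fraction`
#' default to the marker's conventional direction and 0.10 when omitted.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return `read_reference_panel()` returns a `reference_panel`;
#'   `write_reference_panel()` returns `path` invisibly.
#' @export
read_reference_panel <- function(path) {
  if (!file.exists(path)) stop("reference panel file not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.list(cfg) || is.null(names(cfg)))
    stop("reference panel config must map marker names to settings")
  default_dir <- c(abeta42 = "low", abeta42_40_ratio = "low",
                   tau = "high", ptau181 = "high")
  specs <- lapply(names(cfg), function(nm) {
    entry <- cfg[[nm]]
    if (is.numeric(entry)) entry <- list(cutoff = entry)
    if (is.null(entry$cutoff))
      stop("marker '", nm, "' in ", path, " has no cutoff")
    marker_spec(
      nm, entry$cutoff,
      direction = entry$direction %||% unname(default_dir[nm]),
      border_fraction = entry$border_fraction %||% 0.10
    )
  })
  reference_panel(specs)
}

#' @param panel A `reference_panel`.
#' @rdname read_reference_panel
#' @export
write_reference_panel <- function(panel, path) {
  stopifnot(inherits(panel, "reference_panel"))
  cfg <- lapply(unclass(panel), function(s)
    list(cutoff = s$cutoff, direction = s$direction,
         border_fraction = s$border_fraction))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(cfg, path)
  }
  invisible(path)
}

#' @export
print.reference_panel <- function(x, ...) {
  cat("Reference panel (", length(x), " markers)\n", sep = "")
  for (s in x)
    cat(sprintf("  %-18s cutoff %-8g direction %-4s border +/-%g%%\n",
                s$name, s$cutoff, s$direction, 100 * s$border_fraction))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
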