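# Shipped reference data.

#' Published Erlangen Score category distribution
#'
#' The 4 x 3 contingency table of three-level Erlangen Score categories
#' (improbable / possible / probable AD) across the diagnostic groups of
#' the single-center memory-clinic cohort whose analyses this package
#' reimplements (66 neurologic controls, 74 stable MCI, 70 MCI
#' progressing to AD dementia, 168 AD dementia).  The patient-level data
#' of that cohort are not publicly deposited; the printed category counts
#' are shipped so the ordinal statistics and the diagnostic operating
#' point can be reproduced exactly.
#'
#' @return An `es_table` (see [es_table_from_counts()]).
#' @examples
#' kruskal_wallis(reference_es_distribution())
#' @export
reference_es_distribution <- function() {
  path <- system.file("extdata", "reference_es_distribution.csv",
                      package = "erlangenscore", mustWork = TRUE)
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1L])
  rownames(m) <- df$group
  es_table_from_counts(m)
}
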