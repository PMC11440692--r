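# Bundled count tables from the 54-patient glioma TEM cohort the package's
# analyses are designed around; shipped as plain CSV so examples and
# consistency checks need no clinical images.

#' Baseline characteristics of the bundled glioma cohort
#'
#' Counts of the 54-patient cohort by sex and WHO grade.
#'
#' @return Data frame with columns `characteristic`, `level`, `count`.
#' @examples
#' cohort_percentages(glioma_cohort())
#' @export
glioma_cohort <- function() {
  read.csv(system.file("extdata", "glioma_cohort.csv", package = "mitomorph"),
           stringsAsFactors = FALSE)
}

#' Per-grade mitochondrion counts of the bundled TEM dataset
#'
#' Number of annotated mitochondria per WHO grade; the grades sum to the
#' dataset total of 7141 instances from 276 cells.
#'
#' @return Data frame with columns `grade`, `n_mitochondria`.
#' @export
mito_grade_counts <- function() {
  read.csv(system.file("extdata", "grade_mito_counts.csv",
                       package = "mitomorph"),
           stringsAsFactors = FALSE)
}

#' Recompute percentages from a cohort count table
#'
#' Adds a `percent` column per characteristic (one-decimal rounding, the
#' convention of clinical baseline tables).
#'
#' @param cohort Data frame as returned by [glioma_cohort()].
#' @return The table with an added `percent` column.
#' @export
cohort_percentages <- function(cohort) {
  totals <- tapply(cohort$count, cohort$characteristic, sum)
  cohort$percent <- round(100 * cohort$count /
                            as.numeric(totals[cohort$characteristic]), 1)
  cohort
}
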