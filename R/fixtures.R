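# Packaged reference tables from the published Finnish ICU TBI cohort
# (N = 3031): NIRIS category against vital status, and NIRIS against
# Marshall class. Shipped as plain CSV under inst/extdata and
# regenerable with write_reference_fixtures().

#' Reference NIRIS-by-outcome table
#'
#' Per-NIRIS-category patient counts and deaths (ICU, in-hospital,
#' 6-month) of the published Finnish ICU TBI reference cohort
#' (N = 3031, 710 six-month deaths).
#'
#' @return A `data.frame` with columns `category`, `n`, `dead_icu`,
#'   `dead_hospital`, `dead_6mo`.
#' @seealso [niris_outcome_crosstab()] for the events/non-events form,
#'   [expand_crosstab()] for the patient-level expansion.
#' @export
niris_outcome_table <- function() {
  utils::read.csv(system.file("extdata", "niris_outcome_counts.csv",
                              package = "tbict"),
                  stringsAsFactors = FALSE)
}

#' Reference NIRIS-by-outcome cross-tabulation
#'
#' The 6-month vital-status cross-tab of [niris_outcome_table()] as a
#' [crosstab()] object (events = 6-month deaths).
#'
#' @return A `ct_crosstab`.
#' @export
niris_outcome_crosstab <- function() {
  tab <- niris_outcome_table()
  crosstab(labels = tab$category,
           events = tab$dead_6mo,
           nonevents = tab$n - tab$dead_6mo)
}

#' Reference NIRIS-by-Marshall concordance table
#'
#' Counts of patients in each Marshall class (V and VI pooled, as
#' reported) within each NIRIS category for the reference cohort.
#'
#' @return A matrix with Marshall classes as rows and NIRIS categories
#'   0-4 as columns.
#' @export
niris_marshall_table <- function() {
  tab <- utils::read.csv(system.file("extdata",
                                     "niris_marshall_counts.csv",
                                     package = "tbict"),
                         stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1])
  dimnames(m) <- list(tab$marshall, 0:4)
  m
}

#' Write the reference fixture tables to a directory
#'
#' Re-emits the packaged reference CSVs (NIRIS-by-outcome counts and
#' NIRIS-by-Marshall concordance) so external tools can consume them.
#'
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_reference_fixtures <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("niris_outcome_counts.csv",
                            "niris_marshall_counts.csv"))
  file.copy(system.file("extdata", basename(paths), package = "tbict"),
            paths, overwrite = TRUE)
  invisible(paths)
}
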