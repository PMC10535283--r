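# Reference summary tables shipped with the package. These are the printed
# descriptive statistics of the EudraVigilance NSAID (ATC M01A) cohort of
# patients over 65, 2018-2021, that the synthetic defaults emulate; they
# also drive the printed-table consistency checks (weighted-mean pooling,
# polypharmacy case accounting, post-hoc mean differences).

read_extdata_tsv <- function(file, col_types) {
  path <- system.file("extdata", file, package = "icsrcompare")
  if (!nzchar(path)) abort(paste0("bundled data file not found: ", file))
  readr::read_tsv(path, col_types = col_types, progress = FALSE)
}

#' Reference subgroup descriptive statistics
#'
#' Count / mean / sd / quartile summaries of the four per-case count
#' variables in the four reporter-by-seriousness subgroups (plus the two
#' reporter-group marginals) of the elderly-NSAID reference cohort. These
#' moments are the default targets of [default_synthetic_config()].
#'
#' @return A tibble with columns `reporter_group`, `seriousness` (`SERIOUS`,
#'   `NON_SERIOUS`, or `ALL` for the marginal rows), `variable`, `count`,
#'   `mean`, `sd`, `min`, `q25`, `q50`, `q75`, `max`.
#' @export
reference_descriptives <- function() {
  read_extdata_tsv("reference_descriptives.tsv", "cccnnnnnnnn")
}

#' Reference post-hoc subgroup means
#'
#' Subgroup means of `reaction_cnt` and `suspect_drug_cnt` for Groups 1-4
#' (HP/non-HP crossed with non-serious/serious) as used in the Tukey
#' post-hoc comparison of the reference cohort.
#'
#' @return A tibble with columns `variable`, `group`, `mean`.
#' @export
reference_posthoc_means <- function() {
  read_extdata_tsv("reference_posthoc_means.tsv", "cin")
}

#' Reference polypharmacy case counts
#'
#' Numbers of reference-cohort cases passing the five-or-more-drugs
#' polypharmacy filter, by reporter group and in total.
#'
#' @return A named numeric vector.
#' @export
reference_case_counts <- function() {
  tbl <- read_extdata_tsv("reference_case_counts.tsv", "cn")
  setNames(tbl$value, tbl$metric)
}

#' Pool stratum means into a marginal mean
#'
#' Count-weighted pooling of per-stratum means, used to combine serious and
#' non-serious strata into a reporter-group marginal (e.g. combining the
#' serious and non-serious mean reaction counts of each reporter group and
#' differencing them yields the non-HP minus HP reactions-per-case
#' difference).
#'
#' @param counts Numeric vector of stratum sizes.
#' @param means Numeric vector of stratum means, same length.
#' @return The pooled mean.
#' @export
#' @examples
#' weighted_mean_pool(c(2193, 7183), c(2.03, 3.50))
weighted_mean_pool <- function(counts, means) {
  stopifnot(length(counts) == length(means), all(counts >= 0))
  if (sum(counts) == 0) abort("cannot pool strata with zero total count")
  sum(counts * means) / sum(counts)
}
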