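# Per-case drug-list preparation: merge suspect + concomitant lists,
# collapse to unique canonical names, remove the primary drug (and all its
# synonyms), and filter to polypharmacy cases.

#' Build curated per-case drug profiles
#'
#' For each case, the suspect and concomitant drug lists are merged, every
#' name is normalized through the synonym map, the merged list is collapsed
#' to unique canonical names, and the primary drug is removed (all of its
#' synonyms collapse to the same canonical name, so they are removed too).
#' `raw_total` is the raw list-length total `suspect_drug_cnt +
#' concomitant_drug_cnt`, counted *before* deduplication - the quantity the
#' polypharmacy filter uses. `unique_total` counts unique canonical names in
#' the merged lists (primary included), for the deduplicated filter variant.
#'
#' @param cohort An `icsr_cohort`.
#' @param map A `synonym_map`; defaults to the shipped map.
#' @return A tibble of class `case_drug_profiles` with columns `case_id`,
#'   `reporter_group`, `seriousness`, `primary_drug` (canonical), `co_drugs`
#'   (list of unique canonical co-drug names), `raw_total`, `unique_total`.
#' @export
#' @examples
#' ch <- icsr_cohort(
#'   case_id = "C1", reporter_group = "HP", seriousness = "SERIOUS",
#'   primary_drug = "ibuprofen",
#'   reaction_pts = list("Dyspepsia"),
#'   suspect_drugs = list(c("ibuprofen", "Pantoprazole")),
#'   concomitant_drugs = list(c("pantoprazole", "Furosemide"))
#' )
#' build_profiles(ch)
build_profiles <- function(cohort, map = default_synonym_map()) {
  validate_cohort(cohort)
  primary <- normalize_drug_name(cohort$primary_drug, map)
  n <- nrow(cohort)
  co_drugs <- vector("list", n)
  unique_total <- integer(n)
  for (i in seq_len(n)) {
    merged <- c(cohort$suspect_drugs[[i]], cohort$concomitant_drugs[[i]])
    canon <- unique(normalize_drug_name(merged, map))
    unique_total[i] <- length(canon)
    co_drugs[[i]] <- setdiff(canon, primary[i])
  }
  out <- tibble::tibble(
    case_id = cohort$case_id,
    reporter_group = cohort$reporter_group,
    seriousness = cohort$seriousness,
    primary_drug = primary,
    co_drugs = co_drugs,
    raw_total = lengths(cohort$suspect_drugs) +
      lengths(cohort$concomitant_drugs),
    unique_total = unique_total
  )
  class(out) <- c("case_drug_profiles", class(out))
  out
}

#' Restrict profiles to polypharmacy cases
#'
#' Keeps exactly the cases whose drug total is at least `min_total`
#' (default 5, the polypharmacy definition: five or more suspect plus
#' concomitant drugs), preserving input order. The default counts raw list
#' totals before deduplication, matching how the per-case totals are
#' tabulated in the descriptive statistics (the printed subgroup means obey
#' suspect + concomitant = total on the raw scale); `count_basis = "unique"`
#' switches to unique canonical names.
#'
#' @param profiles A `case_drug_profiles` tibble from [build_profiles()].
#' @param min_total Minimum drug total, `>= 1` (default 5).
#' @param count_basis `"raw"` (default) or `"unique"`.
#' @return The filtered `case_drug_profiles`.
#' @export
polypharmacy_filter <- function(profiles, min_total = 5,
                                count_basis = c("raw", "unique")) {
  count_basis <- match.arg(count_basis)
  if (!is.numeric(min_total) || length(min_total) != 1 || min_total < 1) {
    abort("min_total must be a single number >= 1")
  }
  total <- if (count_basis == "raw") profiles$raw_total else
    profiles$unique_total
  profiles[total >= min_total, , drop = FALSE]
}
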