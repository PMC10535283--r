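#' Construct an ICSR cohort
#'
#' An ICSR cohort is a tibble with one row per individual case safety report
#' and list-columns holding the per-case reaction and drug lists. It is the
#' canonical in-memory representation used by every analysis stage.
#'
#' @param case_id Character vector of unique case identifiers.
#' @param reporter_group `"HP"` (healthcare professional: physician, dentist,
#'   pharmacist, nurse) or `"NON_HP"` (consumer: patient, relative, caregiver).
#' @param seriousness `"SERIOUS"` or `"NON_SERIOUS"`, the case-level
#'   classification of the report.
#' @param age_group Age-group label; the intended cohort is patients over 65.
#' @param sex `"F"`, `"M"` or `"UNKNOWN"`.
#' @param primary_drug The M01A substance whose line listing the case came
#'   from (one canonical name per case).
#' @param reaction_pts List of character vectors of MedDRA Preferred Terms;
#'   every case must report at least one reaction.
#' @param suspect_drugs List of character vectors of drug names the reporter
#'   suspects caused the reaction; at least one per case.
#' @param concomitant_drugs List of character vectors of co-used drugs the
#'   reporter does not suspect (may be empty per case).
#' @param provenance Free-text description of where the records came from.
#' @param extraction_date ISO date string.
#'
#' @return A tibble of class `icsr_cohort`.
#' @export
#' @examples
#' icsr_cohort(
#'   case_id = "C1", reporter_group = "HP", seriousness = "SERIOUS",
#'   primary_drug = "ibuprofen",
#'   reaction_pts = list("Gastrointestinal haemorrhage"),
#'   suspect_drugs = list("ibuprofen"),
#'   concomitant_drugs = list(c("pantoprazole", "furosemide"))
#' )
icsr_cohort <- function(case_id = character(),
                        reporter_group = character(),
                        seriousness = character(),
                        age_group = ">65",
                        sex = "UNKNOWN",
                        primary_drug = character(),
                        reaction_pts = list(),
                        suspect_drugs = list(),
                        concomitant_drugs = list(),
                        provenance = "constructed in memory",
                        extraction_date = NA_character_) {
  tbl <- tibble::tibble(
    case_id = as.character(case_id),
    reporter_group = as.character(reporter_group),
    seriousness = as.character(seriousness),
    age_group = as.character(age_group),
    sex = as.character(sex),
    primary_drug = as.character(primary_drug),
    reaction_pts = as.list(reaction_pts),
    suspect_drugs = as.list(suspect_drugs),
    concomitant_drugs = as.list(concomitant_drugs)
  )
  new_icsr_cohort(tbl, provenance = provenance,
                  extraction_date = extraction_date, validate = TRUE)
}

new_icsr_cohort <- function(tbl, provenance = "unspecified",
                            extraction_date = NA_character_,
                            validate = TRUE) {
  stopifnot(is.data.frame(tbl))
  tbl <- tibble::as_tibble(tbl)
  class(tbl) <- c("icsr_cohort", class(tbl))
  attr(tbl, "provenance") <- provenance
  attr(tbl, "extraction_date") <- extraction_date
  if (validate) validate_cohort(tbl)
  tbl
}

#' Validate an ICSR cohort
#'
#' Checks the cohort invariants: unique case identifiers, valid enum values,
#' at least one reaction and one suspect drug per case.
#'
#' @param cohort An `icsr_cohort`.
#' @return The cohort, invisibly, if valid; otherwise an error.
#' @export
validate_cohort <- function(cohort) {
  required <- c("case_id", "reporter_group", "seriousness", "age_group",
                "sex", "primary_drug", "reaction_pts", "suspect_drugs",
                "concomitant_drugs")
  missing <- setdiff(required, names(cohort))
  if (length(missing) > 0) {
    abort(paste0("cohort is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(cohort$case_id)) {
    dup <- unique(cohort$case_id[duplicated(cohort$case_id)])
    abort(paste0("case_id values must be unique; duplicated: ",
                 paste(head(dup, 5), collapse = ", ")))
  }
  if (!all(cohort$reporter_group %in% REPORTER_GROUPS)) {
    abort("reporter_group must be one of 'HP', 'NON_HP' for every case")
  }
  if (!all(cohort$seriousness %in% SERIOUSNESS_LEVELS)) {
    abort("seriousness must be one of 'SERIOUS', 'NON_SERIOUS' for every case")
  }
  if (!all(cohort$sex %in% SEX_LEVELS)) {
    abort("sex must be one of 'F', 'M', 'UNKNOWN' for every case")
  }
  if (nrow(cohort) > 0) {
    if (any(lengths(cohort$reaction_pts) < 1)) {
      abort("every case must report at least one reaction PT")
    }
    if (any(lengths(cohort$suspect_drugs) < 1)) {
      abort("every case must list at least one suspect drug")
    }
    if (any(!nzchar(cohort$primary_drug))) {
      abort("every case must carry a non-empty primary drug")
    }
  }
  invisible(cohort)
}

#' Per-case count variables
#'
#' Derives the four count variables analysed throughout: the number of
#' reported reactions, suspect drugs, concomitant drugs, and their raw total
#' (`suspect_and_concomitant_cnt = suspect_drug_cnt + concomitant_drug_cnt`,
#' counted before any deduplication).
#'
#' @param cohort An `icsr_cohort`.
#' @return A tibble with `case_id`, `reporter_group`, `seriousness` and the
#'   four count columns.
#' @export
case_counts <- function(cohort) {
  validate_cohort(cohort)
  tibble::tibble(
    case_id = cohort$case_id,
    reporter_group = cohort$reporter_group,
    seriousness = cohort$seriousness,
    reaction_cnt = lengths(cohort$reaction_pts),
    suspect_drug_cnt = lengths(cohort$suspect_drugs),
    concomitant_drug_cnt = lengths(cohort$concomitant_drugs),
    suspect_and_concomitant_cnt =
      lengths(cohort$suspect_drugs) + lengths(cohort$concomitant_drugs)
  )
}

#' Subgroup labels for the four reporter-by-seriousness strata
#'
#' Group 1 = HP and non-serious, Group 2 = HP and serious, Group 3 = non-HP
#' and non-serious, Group 4 = non-HP and serious.
#'
#' @param reporter_group,seriousness Character vectors of enum values.
#' @return Integer vector of group numbers 1-4.
#' @export
subgroup_number <- function(reporter_group, seriousness) {
  stopifnot(all(reporter_group %in% REPORTER_GROUPS),
            all(seriousness %in% SERIOUSNESS_LEVELS))
  base <- ifelse(reporter_group == "HP", 0L, 2L)
  base + ifelse(seriousness == "NON_SERIOUS", 1L, 2L)
}

#' @export
print.icsr_cohort <- function(x, ...) {
  cat(sprintf(
    "<icsr_cohort> %d case(s); provenance: %s\n",
    nrow(x), attr(x, "provenance") %||% "unspecified"
  ))
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
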