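#' Describe a line-listing CSV dialect
#'
#' Public line-listing exports of suspected-ADR cases vary in column naming
#' and in how list fields (reactions, suspect drugs, concomitant drugs) are
#' serialized. A dialect bundles the column-name mapping, the list-element
#' separator, the pattern that strips per-element parenthesized annotations
#' (dose, route, duration, outcome ...), and the vocabulary maps for reporter
#' qualification, seriousness and sex. The default matches the conventions of
#' the public EudraVigilance portal "Line Listing" CSV as far as they can be
#' reconstructed; the export schema is not formally documented, so every part
#' is overrideable.
#'
#' @param columns Named list mapping the canonical roles (`case_id`,
#'   `reporter`, `seriousness`, `age_group`, `sex`, `primary_drug`,
#'   `reactions`, `suspect`, `concomitant`) to column names in the file.
#' @param list_sep Regular expression splitting list fields into elements.
#' @param annotation_pattern Regular expression, applied repeatedly, that
#'   removes parenthesized per-element annotations from names.
#' @param reporter_map Named character vector mapping lowercased reporter
#'   qualifications to `"HP"` / `"NON_HP"`.
#' @param seriousness_map Named character vector mapping lowercased
#'   seriousness labels to `"SERIOUS"` / `"NON_SERIOUS"`.
#' @param sex_map Named character vector mapping lowercased sex labels to
#'   `"F"` / `"M"` / `"UNKNOWN"`.
#'
#' @return A `line_listing_dialect` object.
#' @export
line_listing_dialect <- function(
    columns = list(
      case_id = "EU Local Number",
      reporter = "Primary Source Qualification",
      seriousness = "Seriousness",
      age_group = "Patient Age Group",
      sex = "Patient Sex",
      primary_drug = "Primary Drug",
      reactions = "Reaction List PT",
      suspect = "Suspect Drug List",
      concomitant = "Concomitant Drug List"
    ),
    list_sep = ",\\s*",
    annotation_pattern = "\\s*\\([^()]*\\)",
    reporter_map = c(
      "physician" = "HP",
      "dentist" = "HP",
      "pharmacist" = "HP",
      "nurse" = "HP",
      "other health professional" = "HP",
      "healthcare professional" = "HP",
      "consumer" = "NON_HP",
      "consumer or other non health professional" = "NON_HP",
      "non health professional" = "NON_HP",
      "non-health professional" = "NON_HP",
      "lawyer" = "NON_HP",
      "patient" = "NON_HP",
      "caregiver" = "NON_HP"
    ),
    seriousness_map = c(
      "serious" = "SERIOUS",
      "yes" = "SERIOUS",
      "non-serious" = "NON_SERIOUS",
      "non serious" = "NON_SERIOUS",
      "not serious" = "NON_SERIOUS",
      "no" = "NON_SERIOUS"
    ),
    sex_map = c(
      "female" = "F", "f" = "F",
      "male" = "M", "m" = "M",
      "not specified" = "UNKNOWN", "unknown" = "UNKNOWN"
    )) {
  required_roles <- c("case_id", "reporter", "seriousness", "reactions",
                      "suspect")
  missing <- setdiff(required_roles, names(columns))
  if (length(missing) > 0) {
    abort(paste0("dialect must map the role(s): ",
                 paste(missing, collapse = ", ")))
  }
  structure(
    list(
      columns = columns,
      list_sep = list_sep,
      annotation_pattern = annotation_pattern,
      reporter_map = reporter_map,
      seriousness_map = seriousness_map,
      sex_map = sex_map
    ),
    class = "line_listing_dialect"
  )
}

# Strip parenthesized annotations, repeatedly so nested groups collapse too.
strip_annotations <- function(x, pattern) {
  repeat {
    y <- gsub(pattern, "", x)
    if (identical(y, x)) break
    x <- y
  }
  x
}

# Split one serialized list field into clean element names.
split_list_field <- function(x, dialect) {
  x[is.na(x)] <- ""
  cleaned <- strip_annotations(x, dialect$annotation_pattern)
  parts <- strsplit(cleaned, dialect$list_sep)
  lapply(parts, function(p) {
    p <- trimws(p)
    p[nzchar(p)]
  })
}
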