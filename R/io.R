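# Reading and writing cohorts: line-listing CSV in a configurable dialect,
# plus a lossless canonical TSV / JSON-lines interchange format.

CANONICAL_COLUMNS <- c(
  "case_id", "reporter_group", "seriousness", "age_group", "sex",
  "primary_drug", "reaction_pts", "suspect_drugs", "concomitant_drugs"
)
LIST_COLUMNS <- c("reaction_pts", "suspect_drugs", "concomitant_drugs")
LIST_DELIM <- "|"

#' Read a line-listing CSV into an ICSR cohort
#'
#' Parses one row per case, splits the serialized reaction and drug list
#' fields into element vectors, strips parenthesized per-element annotations
#' (duration, outcome, dose, route ...), and maps reporter qualification,
#' seriousness and sex onto the canonical enums. Rows missing a mandatory
#' field (unmappable reporter, no reaction, no suspect drug, unmappable
#' seriousness) are rejected with a per-row diagnostic collected into the
#' `rejects` attribute of the result - never silently dropped.
#'
#' A case is classified `SERIOUS` when any element of its seriousness field
#' maps to serious; seriousness is treated as a case-level stratum.
#'
#' @param path Path to the CSV file (header row required).
#' @param dialect A [line_listing_dialect()].
#' @param primary_drug Optional canonical primary-drug name applied to all
#'   rows; used when the export has no primary-drug column (public portal
#'   line listings are downloaded per substance, so the primary drug is
#'   implied by the file, not stored in it).
#' @param provenance Free-text source description stored on the cohort.
#'
#' @return An `icsr_cohort`; rejected rows are in `attr(x, "rejects")`, a
#'   tibble with `row`, `case_id` and `reason`.
#' @export
read_line_listing <- function(path, dialect = line_listing_dialect(),
                              primary_drug = NULL,
                              provenance = paste0("line listing: ", path)) {
  if (!file.exists(path)) abort(paste0("file does not exist: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  cols <- dialect$columns

  mandatory_roles <- c("case_id", "reporter", "seriousness", "reactions",
                       "suspect")
  if (is.null(primary_drug)) {
    mandatory_roles <- c(mandatory_roles, "primary_drug")
  }
  for (role in mandatory_roles) {
    cn <- cols[[role]]
    if (is.null(cn) || !cn %in% names(raw)) {
      abort(paste0(
        "line listing is missing the mandatory column '", cn %||% role,
        "' (role: ", role, "); adjust the dialect or the file"
      ))
    }
  }

  n <- nrow(raw)
  get_col <- function(role, default = NA_character_) {
    cn <- cols[[role]]
    if (!is.null(cn) && cn %in% names(raw)) raw[[cn]] else rep(default, n)
  }

  case_id <- get_col("case_id")
  reporter_raw <- tolower(trimws(get_col("reporter")))
  seriousness_raw <- get_col("seriousness")
  age_group <- get_col("age_group", ">65")
  age_group[is.na(age_group)] <- ">65"
  sex_raw <- tolower(trimws(get_col("sex", "unknown")))
  sex_raw[is.na(sex_raw)] <- "unknown"

  reporter_group <- unname(dialect$reporter_map[reporter_raw])
  sex <- unname(dialect$sex_map[sex_raw])
  sex[is.na(sex)] <- "UNKNOWN"

  seriousness_parts <- split_list_field(seriousness_raw, dialect)
  seriousness <- vapply(seriousness_parts, function(p) {
    mapped <- unname(dialect$seriousness_map[tolower(p)])
    if (length(mapped) == 0 || all(is.na(mapped))) return(NA_character_)
    if (any(mapped == "SERIOUS", na.rm = TRUE)) "SERIOUS" else "NON_SERIOUS"
  }, character(1))

  reaction_pts <- split_list_field(get_col("reactions"), dialect)
  suspect_drugs <- split_list_field(get_col("suspect"), dialect)
  concomitant_drugs <- split_list_field(get_col("concomitant", ""), dialect)

  if (is.null(primary_drug)) {
    primary <- get_col("primary_drug")
  } else {
    primary <- rep(primary_drug, n)
  }

  reason <- rep(NA_character_, n)
  flag <- function(bad, msg) {
    ifelse(bad & is.na(reason), msg, reason)
  }
  reason <- flag(is.na(case_id) | !nzchar(trimws(case_id)),
                 "missing case identifier")
  reason <- flag(is.na(reporter_group),
                 "unmappable reporter qualification")
  reason <- flag(is.na(seriousness), "unmappable seriousness")
  reason <- flag(lengths(reaction_pts) < 1, "no reaction PT")
  reason <- flag(lengths(suspect_drugs) < 1, "no suspect drug")
  reason <- flag(is.na(primary) | !nzchar(trimws(primary)),
                 "missing primary drug")

  keep <- is.na(reason)
  rejects <- tibble::tibble(
    row = which(!keep),
    case_id = case_id[!keep],
    reason = reason[!keep]
  )
  if (nrow(rejects) > 0) {
    warn(paste0(nrow(rejects), " row(s) rejected while reading ", path,
                "; see attr(x, 'rejects')"))
  }

  cohort <- new_icsr_cohort(
    tibble::tibble(
      case_id = case_id[keep],
      reporter_group = reporter_group[keep],
      seriousness = seriousness[keep],
      age_group = age_group[keep],
      sex = sex[keep],
      primary_drug = primary[keep],
      reaction_pts = reaction_pts[keep],
      suspect_drugs = suspect_drugs[keep],
      concomitant_drugs = concomitant_drugs[keep]
    ),
    provenance = provenance,
    extraction_date = format(Sys.Date())
  )
  attr(cohort, "rejects") <- rejects
  cohort
}

#' Write a cohort as a line-listing CSV
#'
#' Emits a CSV in the given dialect, the inverse of [read_line_listing()].
#' List fields are joined with `", "`; with `annotate = TRUE`, per-element
#' parenthesized annotations are appended to drug names the way portal
#' exports carry dose/route details, which the reader strips again.
#'
#' @param cohort An `icsr_cohort`.
#' @param path Output path.
#' @param dialect A [line_listing_dialect()].
#' @param annotate Append `" (Oral)"`-style annotations to drug elements.
#' @return `path`, invisibly.
#' @export
write_line_listing <- function(cohort, path,
                               dialect = line_listing_dialect(),
                               annotate = FALSE) {
  validate_cohort(cohort)
  join <- function(lst, ann) {
    vapply(lst, function(p) {
      if (ann && length(p) > 0) p <- paste0(p, " (Oral)")
      paste(p, collapse = ", ")
    }, character(1))
  }
  reporter_label <- ifelse(cohort$reporter_group == "HP",
                           "Healthcare Professional", "Consumer")
  seriousness_label <- ifelse(cohort$seriousness == "SERIOUS",
                              "Serious", "Non-Serious")
  sex_label <- c("F" = "Female", "M" = "Male",
                 "UNKNOWN" = "Not Specified")[cohort$sex]
  out <- tibble::tibble(
    a = cohort$case_id,
    b = reporter_label,
    c = seriousness_label,
    d = cohort$age_group,
    e = unname(sex_label),
    f = cohort$primary_drug,
    g = join(cohort$reaction_pts, FALSE),
    h = join(cohort$suspect_drugs, annotate),
    i = join(cohort$concomitant_drugs, annotate)
  )
  names(out) <- unlist(dialect$columns[c(
    "case_id", "reporter", "seriousness", "age_group", "sex",
    "primary_drug", "reactions", "suspect", "concomitant"
  )])
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

serialize_list_column <- function(lst, column) {
  bad <- vapply(lst, function(p) any(grepl(LIST_DELIM, p, fixed = TRUE)),
                logical(1))
  if (any(bad)) {
    abort(paste0(
      "column '", column, "' contains the reserved delimiter '", LIST_DELIM,
      "' inside a name; escape or rename it before writing"
    ))
  }
  vapply(lst, paste, character(1), collapse = LIST_DELIM)
}

#' Write a cohort in the canonical tab-separated format
#'
#' One row per case; list fields are serialized with the reserved `"|"`
#' delimiter. The round trip through [read_canonical()] is lossless, and the
#' output is byte-identical for identical cohorts.
#'
#' @param cohort An `icsr_cohort`.
#' @param path Output path (TSV, UTF-8).
#' @return `path`, invisibly.
#' @export
write_canonical <- function(cohort, path) {
  validate_cohort(cohort)
  flat <- tibble::as_tibble(cohort[, CANONICAL_COLUMNS])
  for (col in LIST_COLUMNS) {
    flat[[col]] <- serialize_list_column(flat[[col]], col)
  }
  readr::write_tsv(flat, path, progress = FALSE)
  invisible(path)
}

#' Read a cohort from the canonical tab-separated format
#'
#' @param path Path written by [write_canonical()].
#' @param provenance Source description stored on the cohort.
#' @return An `icsr_cohort`.
#' @export
read_canonical <- function(path, provenance = paste0("canonical: ", path)) {
  if (!file.exists(path)) abort(paste0("file does not exist: ", path))
  flat <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                          na = character(), trim_ws = FALSE,
                          progress = FALSE)
  missing <- setdiff(CANONICAL_COLUMNS, names(flat))
  if (length(missing) > 0) {
    abort(paste0("canonical file is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  for (col in LIST_COLUMNS) {
    flat[[col]] <- lapply(strsplit(flat[[col]], LIST_DELIM, fixed = TRUE),
                          function(p) p[nzchar(p)])
  }
  new_icsr_cohort(flat[, CANONICAL_COLUMNS], provenance = provenance)
}

#' Write / read a cohort as JSON lines
#'
#' A JSON-lines alternative to the canonical TSV with an identical schema:
#' one JSON object per case, list fields as JSON arrays.
#'
#' @param cohort An `icsr_cohort`.
#' @param path File path.
#' @return `path` (writer) or an `icsr_cohort` (reader).
#' @export
write_canonical_jsonl <- function(cohort, path) {
  validate_cohort(cohort)
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(cohort))) {
    rec <- list(
      case_id = cohort$case_id[i],
      reporter_group = cohort$reporter_group[i],
      seriousness = cohort$seriousness[i],
      age_group = cohort$age_group[i],
      sex = cohort$sex[i],
      primary_drug = cohort$primary_drug[i],
      reaction_pts = cohort$reaction_pts[[i]],
      suspect_drugs = cohort$suspect_drugs[[i]],
      concomitant_drugs = cohort$concomitant_drugs[[i]]
    )
    writeLines(jsonlite::toJSON(rec, auto_unbox = FALSE), con)
  }
  invisible(path)
}

#' @rdname write_canonical_jsonl
#' @param provenance Source description stored on the cohort.
#' @export
read_canonical_jsonl <- function(path,
                                 provenance = paste0("jsonl: ", path)) {
  if (!file.exists(path)) abort(paste0("file does not exist: ", path))
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  recs <- lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE)
  as_chr <- function(field) {
    vapply(recs, function(r) as.character(r[[field]])[1], character(1))
  }
  as_lst <- function(field) {
    lapply(recs, function(r) as.character(unlist(r[[field]])))
  }
  new_icsr_cohort(
    tibble::tibble(
      case_id = as_chr("case_id"),
      reporter_group = as_chr("reporter_group"),
      seriousness = as_chr("seriousness"),
      age_group = as_chr("age_group"),
      sex = as_chr("sex"),
      primary_drug = as_chr("primary_drug"),
      reaction_pts = as_lst("reaction_pts"),
      suspect_drugs = as_lst("suspect_drugs"),
      concomitant_drugs = as_lst("concomitant_drugs")
    ),
    provenance = provenance
  )
}
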