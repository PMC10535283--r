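# Drug-name curation: whitespace/case normalization, salt-suffix stripping,
# and synonym collapsing so every surface form maps to one canonical
# active-compound name (e.g. cholecalciferol and ergocalciferol -> vitamin d).

# Trailing salt/ester words removed during normalization. Conservative by
# design: only words that never end a distinct active-compound name are
# listed (so "potassium chloride" keeps its trailing word, while
# "diclofenac sodium" and "metoprolol tartrate" lose theirs), and stripping
# never empties the name.
SALT_SUFFIXES <- c(
  "sodium", "disodium", "potassium", "dipotassium", "calcium",
  "hydrochloride", "dihydrochloride", "hydrobromide", "sulfate", "sulphate",
  "tartrate", "bitartrate", "maleate", "mesylate", "mesilate", "besylate",
  "besilate", "tosylate", "succinate", "fumarate", "citrate", "phosphate",
  "diphosphate", "acetate", "propionate", "valerate", "palmitate",
  "stearate", "lactate", "gluconate", "trometamol", "hemihydrate",
  "monohydrate", "dihydrate"
)

#' Build a synonym map
#'
#' A synonym map sends surface drug names to canonical active-compound
#' names. Lookup happens after case/whitespace normalization and
#' salt-suffix stripping, and the map is idempotent: canonical names map to
#' themselves.
#'
#' @param surface Character vector of surface names.
#' @param canonical Character vector of canonical names, same length.
#' @return A `synonym_map` (named character vector, normalized keys).
#' @export
#' @examples
#' m <- synonym_map(c("cholecalciferol", "ergocalciferol"),
#'                  c("vitamin d", "vitamin d"))
#' normalize_drug_name("Cholecalciferol", m)
synonym_map <- function(surface = character(), canonical = character()) {
  stopifnot(length(surface) == length(canonical))
  key <- basic_normalize(surface)
  value <- basic_normalize(canonical)
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    conflicting <- vapply(dup, function(k) {
      length(unique(value[key == k])) > 1
    }, logical(1))
    if (any(conflicting)) {
      abort(paste0("surface name(s) map to more than one canonical name: ",
                   paste(dup[conflicting], collapse = ", ")))
    }
    keep <- !duplicated(key)
    key <- key[keep]
    value <- value[keep]
  }
  # canonical names map to themselves (idempotence)
  self <- setdiff(value, key)
  map <- c(setNames(value, key), setNames(self, self))
  structure(map, class = c("synonym_map", "character"))
}

#' The synonym map shipped with the package
#'
#' Covers the vitamin D family, common vitamin aliases, and widely used
#' brand/INN aliases of the drugs that recur in elderly-NSAID co-reporting
#' analyses. Salt forms are handled by suffix stripping, not by the map.
#' Extend it from a two-column TSV with [read_synonym_map()].
#'
#' @return A `synonym_map`.
#' @export
default_synonym_map <- function() {
  path <- system.file("extdata", "synonyms.tsv", package = "icsrcompare")
  read_synonym_map(path)
}

#' Read / write a synonym map as two-column TSV
#'
#' The file has columns `surface` and `canonical`.
#'
#' @param path File path.
#' @return A `synonym_map` (reader) or `path` invisibly (writer).
#' @export
read_synonym_map <- function(path) {
  if (!file.exists(path)) abort(paste0("file does not exist: ", path))
  tbl <- readr::read_tsv(path, col_types = "cc", progress = FALSE)
  if (!all(c("surface", "canonical") %in% names(tbl))) {
    abort("synonym map file needs columns 'surface' and 'canonical'")
  }
  synonym_map(tbl$surface, tbl$canonical)
}

#' @rdname read_synonym_map
#' @param map A `synonym_map`.
#' @export
write_synonym_map <- function(map, path) {
  tbl <- tibble::tibble(surface = names(map), canonical = unname(map))
  readr::write_tsv(tbl, path, progress = FALSE)
  invisible(path)
}

# lowercase + collapse internal whitespace + trim
basic_normalize <- function(x) {
  stringr::str_squish(tolower(x))
}

strip_salt_suffix <- function(x) {
  words <- strsplit(x, " ", fixed = TRUE)
  vapply(words, function(w) {
    while (length(w) > 1 && w[length(w)] %in% SALT_SUFFIXES) {
      w <- w[-length(w)]
    }
    paste(w, collapse = " ")
  }, character(1))
}

#' Normalize a drug name to its canonical form
#'
#' Lowercases, collapses whitespace, strips trailing salt/ester words from a
#' fixed suffix list, then applies the synonym map. Unknown names pass
#' through in normalized form. The operation is idempotent.
#'
#' @param raw Character vector of raw drug names (non-empty).
#' @param map A `synonym_map`; defaults to the shipped map.
#' @return Character vector of canonical names.
#' @export
#' @examples
#' normalize_drug_name("Metoprolol tartrate")  # "metoprolol"
#' normalize_drug_name("  IBUPROFEN ")         # "ibuprofen"
normalize_drug_name <- function(raw, map = default_synonym_map()) {
  if (length(raw) == 0) return(character())
  if (any(is.na(raw)) || any(!nzchar(trimws(raw)))) {
    abort("drug names must be non-empty strings")
  }
  x <- strip_salt_suffix(basic_normalize(raw))
  mapped <- unname(map[x])
  hit <- !is.na(mapped)
  x[hit] <- mapped[hit]
  x
}
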