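# Co-reporting and reaction-reporting ratio tables, compared between
# reporter groups with two-proportion Z tests on the percentage-point scale.

new_ratio_table <- function(rows, stratum, n_cases) {
  out <- tibble::as_tibble(rows)
  attr(out, "stratum") <- stratum
  attr(out, "n_cases") <- n_cases
  class(out) <- c("ratio_table", class(out))
  out
}

#' Number of cases behind a ratio table
#'
#' @param table A `ratio_table`.
#' @return The denominator (number of cases) of the table's ratios.
#' @export
ratio_table_n <- function(table) attr(table, "n_cases")

count_items_once_per_case <- function(item_lists) {
  items <- unlist(lapply(item_lists, unique), use.names = FALSE)
  if (length(items) == 0) {
    return(tibble::tibble(item = character(), count = integer()))
  }
  tab <- table(items)
  tibble::tibble(item = names(tab), count = as.integer(tab)) |>
    dplyr::arrange(dplyr::desc(.data$count), .data$item)
}

#' Co-reporting ratio table for one primary drug and reporter group
#'
#' For the polypharmacy-filtered cases of one primary drug reported by one
#' group, counts in how many cases each co-drug appears (profiles hold
#' unique-name sets, so a drug counts at most once per case) and divides by
#' the number of cases. The ratio estimates how often a given additional
#' drug was used in patients receiving the primary drug.
#'
#' @param profiles A `case_drug_profiles` tibble, already
#'   polypharmacy-filtered.
#' @param primary Canonical primary-drug name.
#' @param group `"HP"` or `"NON_HP"`.
#' @return A `ratio_table` with columns `item`, `count`, `ratio`.
#' @export
coreporting_table <- function(profiles, primary, group) {
  stopifnot(group %in% REPORTER_GROUPS)
  sel <- profiles[profiles$primary_drug == primary &
                    profiles$reporter_group == group, ]
  n <- nrow(sel)
  if (n == 0) {
    abort(paste0("no cases for primary drug '", primary, "' in group ",
                 group, "; ratios are undefined"))
  }
  rows <- count_items_once_per_case(sel$co_drugs)
  rows$ratio <- rows$count / n
  new_ratio_table(rows, stratum = list(kind = "coreporting",
                                       primary = primary, group = group),
                  n_cases = n)
}

#' Reaction-reporting ratio table for one reporter group and stratum
#'
#' Counts in how many of the group's cases each reaction Preferred Term was
#' reported (a case's PT list is treated as a set) and divides by the number
#' of cases, optionally restricted to serious or non-serious reports.
#'
#' @param cohort An `icsr_cohort`.
#' @param group `"HP"` or `"NON_HP"`.
#' @param stratum `"ALL"`, `"SERIOUS"` or `"NON_SERIOUS"`.
#' @return A `ratio_table` with columns `item`, `count`, `ratio`.
#' @export
reaction_table <- function(cohort, group, stratum = "ALL") {
  stopifnot(group %in% REPORTER_GROUPS,
            stratum %in% c("ALL", SERIOUSNESS_LEVELS))
  validate_cohort(cohort)
  keep <- cohort$reporter_group == group
  if (stratum != "ALL") keep <- keep & cohort$seriousness == stratum
  sel <- cohort[keep, ]
  n <- nrow(sel)
  if (n == 0) {
    abort(paste0("empty stratum: group ", group, ", stratum ", stratum,
                 "; ratios are undefined"))
  }
  rows <- count_items_once_per_case(sel$reaction_pts)
  rows$ratio <- rows$count / n
  new_ratio_table(rows, stratum = list(kind = "reaction", group = group,
                                       stratum = stratum),
                  n_cases = n)
}

#' Pooled two-proportion Z test
#'
#' The plain two-sample Z test for proportions with pooled variance:
#' `p_hat = (c1 + c2) / (n1 + n2)`,
#' `z = (p1 - p2) / sqrt(p_hat (1 - p_hat) (1/n1 + 1/n2))`, two-sided
#' `p = 2 (1 - Phi(|z|))`. No continuity correction (an unpooled-variance
#' variant is available via `pooled = FALSE`). When the pooled proportion is
#' degenerate (0 or 1) there is no evidence either way: `z = 0`, `p = 1`,
#' flagged in the `degenerate` column. Vectorized over all arguments;
#' antisymmetric under swapping the two samples.
#'
#' @param count1,n1 Successes and size of sample 1.
#' @param count2,n2 Successes and size of sample 2.
#' @param pooled Use the pooled-variance form (default `TRUE`).
#' @return A tibble with columns `z`, `p_value`, `degenerate`.
#' @export
#' @examples
#' two_proportion_z(10, 100, 20, 100)  # z about -1.98, p about 0.048
two_proportion_z <- function(count1, n1, count2, n2, pooled = TRUE) {
  if (any(n1 < 1) || any(n2 < 1)) abort("sample sizes must be >= 1")
  if (any(count1 < 0) || any(count2 < 0) ||
      any(count1 > n1) || any(count2 > n2)) {
    abort("counts must satisfy 0 <= count <= n")
  }
  p1 <- count1 / n1
  p2 <- count2 / n2
  if (pooled) {
    p_hat <- (count1 + count2) / (n1 + n2)
    se <- sqrt(p_hat * (1 - p_hat) * (1 / n1 + 1 / n2))
  } else {
    se <- sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
  }
  degenerate <- se == 0
  z <- ifelse(degenerate, 0, (p1 - p2) / ifelse(degenerate, 1, se))
  p <- ifelse(degenerate, 1, 2 * pnorm(-abs(z)))
  tibble::tibble(z = z, p_value = p, degenerate = degenerate)
}

#' Compare two ratio tables item by item
#'
#' Takes the union of item names of an HP and a non-HP ratio table (an item
#' absent from one table counts 0 there), and for every item reports both
#' ratios, the difference in percentage points (`pp_diff = 100 * (ratio_nonhp
#' - ratio_hp)`), the two-proportion Z statistic and p-value, and the
#' significance flag at `alpha`. Rows are ordered by decreasing `|pp_diff|`.
#'
#' @param t_hp,t_nonhp `ratio_table`s for the HP and non-HP group over the
#'   same stratum definition.
#' @param alpha Significance level (default 0.05).
#' @param pooled Pooled-variance Z (default `TRUE`).
#' @param adjust `"none"` (default, per-item reporting) or `"bonferroni"`
#'   across the union of items.
#' @return A tibble with columns `item`, `count_hp`, `n_hp`, `ratio_hp`,
#'   `count_nonhp`, `n_nonhp`, `ratio_nonhp`, `pp_diff`, `z`, `p_value`,
#'   `significant`.
#' @export
compare_ratios <- function(t_hp, t_nonhp, alpha = 0.05, pooled = TRUE,
                           adjust = c("none", "bonferroni")) {
  adjust <- match.arg(adjust)
  n_hp <- ratio_table_n(t_hp)
  n_nonhp <- ratio_table_n(t_nonhp)
  merged <- dplyr::full_join(
    dplyr::select(tibble::as_tibble(t_hp), "item", count_hp = "count"),
    dplyr::select(tibble::as_tibble(t_nonhp), "item", count_nonhp = "count"),
    by = "item"
  )
  merged$count_hp[is.na(merged$count_hp)] <- 0L
  merged$count_nonhp[is.na(merged$count_nonhp)] <- 0L
  zt <- two_proportion_z(merged$count_nonhp, n_nonhp,
                         merged$count_hp, n_hp, pooled = pooled)
  p <- if (adjust == "bonferroni") bonferroni_adjust(zt$p_value) else
    zt$p_value
  out <- tibble::tibble(
    item = merged$item,
    count_hp = merged$count_hp,
    n_hp = n_hp,
    ratio_hp = merged$count_hp / n_hp,
    count_nonhp = merged$count_nonhp,
    n_nonhp = n_nonhp,
    ratio_nonhp = merged$count_nonhp / n_nonhp,
    pp_diff = 100 * (merged$count_nonhp / n_nonhp - merged$count_hp / n_hp),
    z = zt$z,
    p_value = p,
    significant = p < alpha
  )
  dplyr::arrange(out, dplyr::desc(abs(.data$pp_diff)), .data$item)
}

#' Top-k items of a ratio table
#'
#' The `k` highest-ratio items, ties broken by item name ascending; if the
#' table has fewer than `k` items, all are returned. Selection never changes
#' any statistic's value - it only picks rows.
#'
#' @param table A `ratio_table`.
#' @param k Number of items (default 20, the usual reporting cut).
#' @return A `ratio_table` with at most `k` rows.
#' @export
top_k <- function(table, k = 20) {
  if (!is.numeric(k) || length(k) != 1 || k < 1) {
    abort("k must be a single number >= 1")
  }
  ordered <- dplyr::arrange(tibble::as_tibble(table),
                            dplyr::desc(.data$ratio), .data$item)
  new_ratio_table(head(ordered, k), stratum = attr(table, "stratum"),
                  n_cases = ratio_table_n(table))
}

#' Number of distinct reaction Preferred Terms in a reporter group
#'
#' Cardinality of the union of all reaction PTs over the group's cases - a
#' measure of reporting diversity.
#'
#' @param cohort An `icsr_cohort`.
#' @param group `"HP"` or `"NON_HP"`.
#' @return An integer.
#' @export
distinct_pt_count <- function(cohort, group) {
  stopifnot(group %in% REPORTER_GROUPS)
  sel <- cohort[cohort$reporter_group == group, ]
  length(unique(unlist(sel$reaction_pts, use.names = FALSE)))
}

#' Primary drugs eligible for the co-reporting analysis
#'
#' The co-reporting analysis runs for the primary drugs with the most
#' polypharmacy-filtered cases (default: the top five, both groups pooled),
#' unless an explicit override list is given. Ties are broken by drug name.
#'
#' @param profiles A polypharmacy-filtered `case_drug_profiles`.
#' @param k Number of primary drugs (default 5).
#' @param override Optional character vector of primary drugs to use
#'   instead of the automatic selection.
#' @return Character vector of primary-drug names.
#' @export
eligible_primary_drugs <- function(profiles, k = 5, override = NULL) {
  if (!is.null(override)) return(override)
  counts <- profiles |>
    dplyr::count(.data$primary_drug, name = "cases") |>
    dplyr::arrange(dplyr::desc(.data$cases), .data$primary_drug)
  head(counts$primary_drug, k)
}
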