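# End-to-end pipeline: curate -> polypharmacy filter -> co-reporting
# analysis per eligible primary drug -> reaction analysis (all / serious /
# non-serious) -> descriptives -> Mann-Whitney + bootstrap -> Tukey
# post-hoc -> correlations, with every table written to disk, a
# machine-readable summary JSON, and a run manifest.

#' Pipeline configuration
#'
#' Bundles every tunable of [run_pipeline()]. The defaults are the analysis
#' constants used throughout: polypharmacy threshold 5, top-20 reporting
#' cut, alpha 0.05, ten thousand bootstrap replicates.
#'
#' @param input Path to a cohort file, or an `icsr_cohort`, or `NULL` to
#'   simulate from `synthetic` instead.
#' @param input_format `"canonical"`, `"jsonl"` or `"line_listing"`.
#' @param dialect Line-listing dialect (used for `"line_listing"` input).
#' @param synthetic A `synthetic_config` used when `input` is `NULL`.
#' @param synonym_map_path Optional path to a two-column synonym TSV;
#'   `NULL` uses the shipped map.
#' @param min_total Polypharmacy threshold (default 5).
#' @param count_basis `"raw"` or `"unique"` drug totals for the filter.
#' @param primary_override Optional explicit list of primary drugs.
#' @param n_primary Number of primary drugs analysed when not overridden
#'   (default 5).
#' @param k Top-k cut for reported tables (default 20).
#' @param alpha Significance level (default 0.05).
#' @param adjust `"none"` or `"bonferroni"` across items in ratio
#'   comparisons.
#' @param pooled Pooled-variance Z test (default `TRUE`).
#' @param correlation_method `"rank"` or `"linear"`.
#' @param n_boot Bootstrap replicates (default 10000).
#' @param seed Integer seed for all stochastic stages.
#' @param out_dir Output directory.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL,
                            input_format = c("canonical", "jsonl",
                                             "line_listing"),
                            dialect = line_listing_dialect(),
                            synthetic = NULL,
                            synonym_map_path = NULL,
                            min_total = 5,
                            count_basis = "raw",
                            primary_override = NULL,
                            n_primary = 5,
                            k = 20,
                            alpha = 0.05,
                            adjust = "none",
                            pooled = TRUE,
                            correlation_method = "rank",
                            n_boot = 10000,
                            seed = 1L,
                            out_dir = tempfile("icsr_run_")) {
  input_format <- match.arg(input_format)
  structure(
    list(input = input, input_format = input_format, dialect = dialect,
         synthetic = synthetic, synonym_map_path = synonym_map_path,
         min_total = min_total, count_basis = count_basis,
         primary_override = primary_override, n_primary = n_primary,
         k = k, alpha = alpha, adjust = adjust, pooled = pooled,
         correlation_method = correlation_method, n_boot = n_boot,
         seed = as.integer(seed), out_dir = out_dir),
    class = "pipeline_config"
  )
}

pipeline_log <- function(...) {
  message(sprintf("[icsrcompare] %s", sprintf(...)))
}

#' Run the full comparison pipeline
#'
#' Loads or simulates a cohort, then executes every analysis stage and
#' writes its artifacts under `config$out_dir`: the canonical cohort, the
#' curated profiles, per-primary-drug co-reporting comparisons, reaction
#' comparisons for the all/serious/non-serious strata, subgroup
#' descriptives, Mann-Whitney/bootstrap comparisons of the four count
#' variables between reporter groups (Bonferroni family of 4), Tukey
#' post-hoc matrices, correlation tables, a `summary.json`, and a
#' `manifest.json` recording the configuration, seed and row counts at each
#' stage. Identical configuration and seed give an identical summary.
#'
#' @param config A [pipeline_config()].
#' @return The summary list, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  cohort <- if (inherits(config$input, "icsr_cohort")) {
    config$input
  } else if (is.null(config$input)) {
    if (is.null(config$synthetic)) {
      abort("config error: neither input nor synthetic config given")
    }
    pipeline_log("simulating cohort (seed %d)", config$synthetic$seed)
    generate_cohort(config$synthetic)
  } else {
    pipeline_log("reading %s (%s)", config$input, config$input_format)
    switch(config$input_format,
      canonical = read_canonical(config$input),
      jsonl = read_canonical_jsonl(config$input),
      line_listing = read_line_listing(config$input, config$dialect)
    )
  }
  write_canonical(cohort, file.path(config$out_dir, "cohort.tsv"))

  map <- if (is.null(config$synonym_map_path)) default_synonym_map() else
    read_synonym_map(config$synonym_map_path)

  pipeline_log("curating %d case(s)", nrow(cohort))
  profiles <- build_profiles(cohort, map)
  filtered <- polypharmacy_filter(profiles, config$min_total,
                                  config$count_basis)
  pipeline_log("polypharmacy filter (>= %d drugs): %d of %d case(s) kept",
               config$min_total, nrow(filtered), nrow(profiles))
  readr::write_tsv(
    dplyr::mutate(filtered,
                  co_drugs = vapply(.data$co_drugs, paste, character(1),
                                    collapse = "|")),
    file.path(config$out_dir, "filtered_profiles.tsv"), progress = FALSE
  )

  primaries <- eligible_primary_drugs(filtered, config$n_primary,
                                      config$primary_override)
  coreporting <- list()
  for (pd in primaries) {
    has_hp <- any(filtered$primary_drug == pd &
                    filtered$reporter_group == "HP")
    has_nonhp <- any(filtered$primary_drug == pd &
                       filtered$reporter_group == "NON_HP")
    if (!has_hp || !has_nonhp) {
      pipeline_log("skipping primary '%s': one reporter group empty", pd)
      next
    }
    t_hp <- coreporting_table(filtered, pd, "HP")
    t_nonhp <- coreporting_table(filtered, pd, "NON_HP")
    cmp <- compare_ratios(t_hp, t_nonhp, alpha = config$alpha,
                          pooled = config$pooled, adjust = config$adjust)
    top_items <- unique(c(top_k(t_hp, config$k)$item,
                          top_k(t_nonhp, config$k)$item))
    cmp_top <- cmp[cmp$item %in% top_items, ]
    readr::write_tsv(cmp_top, file.path(
      config$out_dir, paste0("coreporting_", gsub("[^a-z0-9]+", "_", pd),
                             ".tsv")), progress = FALSE)
    coreporting[[pd]] <- cmp_top
  }

  reaction_cmp <- list()
  for (stratum in c("ALL", "SERIOUS", "NON_SERIOUS")) {
    if (stratum != "ALL" && !any(cohort$seriousness == stratum)) {
      pipeline_log("skipping reaction stratum %s: no cases", stratum)
      next
    }
    t_hp <- reaction_table(cohort, "HP", stratum)
    t_nonhp <- reaction_table(cohort, "NON_HP", stratum)
    cmp <- compare_ratios(t_hp, t_nonhp, alpha = config$alpha,
                          pooled = config$pooled, adjust = config$adjust)
    top_items <- unique(c(top_k(t_hp, config$k)$item,
                          top_k(t_nonhp, config$k)$item))
    cmp_top <- cmp[cmp$item %in% top_items, ]
    readr::write_tsv(cmp_top, file.path(
      config$out_dir, paste0("reactions_", tolower(stratum), ".tsv")),
      progress = FALSE)
    reaction_cmp[[stratum]] <- cmp_top
  }

  descriptives <- describe_subgroups(cohort)
  readr::write_tsv(descriptives,
                   file.path(config$out_dir, "descriptives.tsv"),
                   progress = FALSE)

  counts <- case_counts(cohort)
  hp <- counts[counts$reporter_group == "HP", ]
  nonhp <- counts[counts$reporter_group == "NON_HP", ]
  mw <- lapply(seq_along(COUNT_VARIABLES), function(i) {
    v <- COUNT_VARIABLES[i]
    res <- mann_whitney_compare(
      nonhp[[v]], hp[[v]], n_boot = config$n_boot,
      seed = config$seed + i, n_comparisons = length(COUNT_VARIABLES)
    )
    list(variable = v, U = res$U, p_value = res$p_value,
         p_adjusted = res$p_adjusted, rank_biserial = res$rank_biserial,
         boot_mean_diff = res$boot_mean_diff,
         boot_ci_95 = res$boot_ci_95, n_nonhp = res$n1, n_hp = res$n2)
  })
  names(mw) <- COUNT_VARIABLES

  posthoc <- list()
  for (v in c("reaction_cnt", "suspect_drug_cnt")) {
    ph <- tukey_posthoc(cohort, v)
    readr::write_tsv(
      tibble::as_tibble(ph$p_matrix, rownames = "group"),
      file.path(config$out_dir, paste0("posthoc_", v, ".tsv")),
      progress = FALSE
    )
    posthoc[[v]] <- list(group_means = as.list(round(ph$group_means, 4)),
                         p_matrix = ph$p_matrix)
  }

  correlations <- correlate_counts_all(cohort,
                                       method = config$correlation_method)
  readr::write_tsv(correlations,
                   file.path(config$out_dir, "correlations.tsv"),
                   progress = FALSE)

  summary <- list(
    n_cases = nrow(cohort),
    n_profiles = nrow(profiles),
    n_filtered = nrow(filtered),
    primaries = primaries,
    distinct_pts = list(HP = distinct_pt_count(cohort, "HP"),
                        NON_HP = distinct_pt_count(cohort, "NON_HP")),
    coreporting_significant = lapply(coreporting, function(cmp) {
      sum(cmp$significant)
    }),
    reaction_significant = lapply(reaction_cmp, function(cmp) {
      sum(cmp$significant)
    }),
    mann_whitney = lapply(mw, function(r) {
      r$boot_ci_95 <- as.numeric(r$boot_ci_95)
      r
    }),
    posthoc = lapply(posthoc, function(p) {
      p$p_matrix <- unname(apply(p$p_matrix, 1, as.list, simplify = FALSE))
      p
    }),
    correlations = correlations
  )
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)

  manifest <- list(
    seed = config$seed,
    alpha = config$alpha,
    min_total = config$min_total,
    count_basis = config$count_basis,
    k = config$k,
    n_boot = config$n_boot,
    adjust = config$adjust,
    pooled = config$pooled,
    correlation_method = config$correlation_method,
    package_version = as.character(utils::packageVersion("icsrcompare")),
    row_counts = list(cohort = nrow(cohort), profiles = nrow(profiles),
                      filtered = nrow(filtered))
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  pipeline_log("done; artifacts in %s", config$out_dir)
  invisible(summary)
}
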