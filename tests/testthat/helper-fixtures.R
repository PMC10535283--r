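# Shared fixtures: compact cohort builders and small synthetic
# configurations so every test generates its data in code.

make_cohort <- function(...) {
  rows <- list(...)
  icsr_cohort(
    case_id = vapply(rows, `[[`, character(1), "id"),
    reporter_group = vapply(rows, `[[`, character(1), "grp"),
    seriousness = vapply(rows, `[[`, character(1), "ser"),
    primary_drug = vapply(rows, function(r) r$primary %||% "ibuprofen",
                          character(1)),
    reaction_pts = lapply(rows, `[[`, "pts"),
    suspect_drugs = lapply(rows, `[[`, "sus"),
    concomitant_drugs = lapply(rows, function(r) r$con %||% character())
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A small, fast synthetic configuration: two serious subgroups, compact
# catalogs. Arguments override individual pieces.
tiny_config <- function(seed = 1L, n_hp = 150L, n_nonhp = 150L,
                        coupling = 0.8, noise = 0,
                        drug_catalog = NULL, primary_weights = NULL,
                        count_means = c(reaction = 2.5, suspect = 2.2,
                                        concomitant = 2.0),
                        count_sds = c(reaction = 2.2, suspect = 2.0,
                                      concomitant = 2.5)) {
  sizes <- tibble::tibble(
    reporter_group = c("HP", "NON_HP"),
    seriousness = c("SERIOUS", "SERIOUS"),
    n = as.integer(c(n_hp, n_nonhp))
  )
  params <- tidyr::expand_grid(
    reporter_group = c("HP", "NON_HP"),
    seriousness = "SERIOUS",
    variable = c("reaction", "suspect", "concomitant")
  )
  params$mean <- unname(count_means[params$variable])
  params$sd <- unname(count_sds[params$variable])
  if (is.null(drug_catalog)) {
    drug_catalog <- tibble::tibble(
      drug = c("pantoprazole", "furosemide", "vitamin d", "levothyroxine"),
      primary = "*",
      prob_hp = c(0.20, 0.15, 0.10, 0.10),
      prob_nonhp = c(0.20, 0.15, 0.10, 0.10)
    )
  }
  if (is.null(primary_weights)) {
    primary_weights <- tibble::tibble(
      drug = c("ibuprofen", "diclofenac"),
      weight = c(0.7, 0.3)
    )
  }
  synthetic_config(
    subgroup_sizes = sizes,
    count_params = params,
    severity_coupling = coupling,
    drug_catalog = drug_catalog,
    background_drugs = tibble::tibble(
      drug = sprintf("bg-%03d", 1:120),
      weight = 1 / (1:120)
    ),
    primary_drug_weights = primary_weights,
    reaction_catalog = tibble::tibble(
      pt = sprintf("pt-%03d", 1:150),
      w_hp_serious = 1 / (1:150)^0.7,
      w_hp_nonserious = 1 / (1:150)^0.7,
      w_nonhp_serious = 1 / (1:150)^1.1,
      w_nonhp_nonserious = 1 / (1:150)^1.1
    ),
    synonym_variants = tibble::tibble(
      canonical = c("vitamin d", "vitamin d", "furosemide", "pantoprazole"),
      variant = c("Cholecalciferol", "VITAMIN D3", "Frusemide",
                  "PANTOPRAZOLE")
    ),
    synonym_noise = noise,
    seed = seed
  )
}
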