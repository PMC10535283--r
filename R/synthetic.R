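# Seeded synthetic ICSR cohort generator.
#
# Count model: per case a latent severity s ~ Gamma(shape = 1/c^2, scale =
# c^2) (mean 1, coefficient of variation c = severity_coupling) multiplies
# the underlying negative-binomial mean of all three count variables, which
# induces the positive reaction-count / drug-count correlation the analyses
# look for. Reaction and suspect counts are zero-truncated (every report has
# at least one reaction and one suspect drug); concomitant counts permit
# zero. For each subgroup and variable the underlying NB mean and size are
# calibrated numerically so that the *marginal* mean matches the configured
# target exactly and the marginal sd as closely as the severity floor
# allows.
#
# Drug identities: catalog drugs enter a case by independent Bernoulli draws
# at their configured per-(primary drug x reporter group) inclusion
# probability - so the co-reporting ratio estimated downstream is an
# unbiased estimate of that probability, and planted percentage-point
# effects are recovered on the same scale. The drawn raw list lengths are
# then honoured exactly: background filler drugs complete the list, and in
# the rare case the Bernoulli inclusions exceed the list capacity a uniform
# random subset is kept.

#' Create a synthetic cohort configuration
#'
#' @param subgroup_sizes Tibble with columns `reporter_group`, `seriousness`,
#'   `n`: number of cases per subgroup.
#' @param count_params Tibble with columns `reporter_group`, `seriousness`,
#'   `variable` (`"reaction"`, `"suspect"`, `"concomitant"`), `mean`, `sd`:
#'   target marginal moments of the count distributions.
#' @param severity_coupling Nonnegative real; coefficient of variation of the
#'   shared latent severity factor linking reaction and drug counts
#'   (0 switches the coupling off).
#' @param drug_catalog Tibble with columns `drug`, `primary` (`"*"` for a
#'   wildcard applying to every primary drug), `prob_hp`, `prob_nonhp`:
#'   per-case inclusion probabilities of named co-drugs.
#' @param background_drugs Tibble with columns `drug`, `weight`: filler
#'   co-drug pool completing the drawn list lengths.
#' @param primary_drug_weights Tibble with columns `drug`, `weight`:
#'   sampling weights of the primary drug.
#' @param reaction_catalog Tibble with columns `pt`, `w_hp_serious`,
#'   `w_hp_nonserious`, `w_nonhp_serious`, `w_nonhp_nonserious`: reaction
#'   Preferred-Term sampling weights per reporter group and seriousness.
#' @param synonym_variants Tibble with columns `canonical`, `variant`: surface
#'   forms used to corrupt drug names; every variant must normalize back to
#'   its canonical name under the shipped synonym map.
#' @param synonym_noise Probability that a drug name is replaced by a surface
#'   variant (a table variant, a salt-suffixed form, or a case/whitespace
#'   mutation).
#' @param seed Integer seed; the whole generation is reproducible from it.
#'
#' @return A `synthetic_config` object.
#' @export
synthetic_config <- function(subgroup_sizes,
                             count_params,
                             severity_coupling = 0.8,
                             drug_catalog,
                             background_drugs,
                             primary_drug_weights,
                             reaction_catalog,
                             synonym_variants = NULL,
                             synonym_noise = 0,
                             seed = 1L) {
  cfg <- structure(
    list(
      subgroup_sizes = tibble::as_tibble(subgroup_sizes),
      count_params = tibble::as_tibble(count_params),
      severity_coupling = severity_coupling,
      drug_catalog = tibble::as_tibble(drug_catalog),
      background_drugs = tibble::as_tibble(background_drugs),
      primary_drug_weights = tibble::as_tibble(primary_drug_weights),
      reaction_catalog = tibble::as_tibble(reaction_catalog),
      synonym_variants = if (is.null(synonym_variants)) {
        tibble::tibble(canonical = character(), variant = character())
      } else tibble::as_tibble(synonym_variants),
      synonym_noise = synonym_noise,
      seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  sz <- cfg$subgroup_sizes
  stopifnot(all(c("reporter_group", "seriousness", "n") %in% names(sz)))
  if (any(sz$n < 0)) abort("subgroup sizes must be >= 0")
  cp <- cfg$count_params
  stopifnot(all(c("reporter_group", "seriousness", "variable",
                  "mean", "sd") %in% names(cp)))
  if (any(cp$sd <= 0)) abort("count sd parameters must be > 0")
  if (any(cp$mean <= 0)) abort("count mean parameters must be > 0")
  trunc_vars <- cp$variable %in% c("reaction", "suspect")
  if (any(cp$mean[trunc_vars] <= 1)) {
    abort(paste0("zero-truncated count variables need a target mean > 1; ",
                 "the truncated distribution cannot have mean <= 1"))
  }
  if (cfg$severity_coupling < 0) abort("severity_coupling must be >= 0")
  probs <- c(cfg$drug_catalog$prob_hp, cfg$drug_catalog$prob_nonhp)
  if (any(probs < 0 | probs > 1)) {
    abort("drug catalog inclusion probabilities must lie in [0, 1]")
  }
  if (cfg$synonym_noise < 0 || cfg$synonym_noise > 1) {
    abort("synonym_noise must lie in [0, 1]")
  }
  if (nrow(cfg$synonym_variants) > 0) {
    back <- normalize_drug_name(cfg$synonym_variants$variant)
    bad <- back != cfg$synonym_variants$canonical
    if (any(bad)) {
      abort(paste0(
        "synonym variant(s) do not normalize back to their canonical name: ",
        paste(head(cfg$synonym_variants$variant[bad], 5), collapse = ", ")
      ))
    }
    if (anyDuplicated(cfg$synonym_variants$variant)) {
      abort("each synonym variant must map back to exactly one canonical name")
    }
  }
  invisible(cfg)
}

#' Default synthetic configuration emulating the reference cohort
#'
#' Subgroup sizes and count moments come from [reference_descriptives()]
#' (the elderly-NSAID reference cohort: 2193 / 7183 HP and 1049 / 2317
#' non-HP non-serious / serious cases with their printed means and standard
#' deviations). The drug and reaction catalogs mix the substances and
#' Preferred Terms that recur in elderly-NSAID reports with long background
#' tails; catalog weights give healthcare professionals a flatter reaction
#' profile (more distinct PTs) and tilt e.g. proton-pump inhibitors and
#' vitamins toward non-HP reporting.
#'
#' @param seed Integer seed.
#' @param synonym_noise Drug-name corruption probability (default 0.1).
#' @param severity_coupling Latent-severity coefficient of variation
#'   (default 0.8).
#' @return A `synthetic_config`.
#' @export
default_synthetic_config <- function(seed = 20230831L, synonym_noise = 0.1,
                                     severity_coupling = 0.8) {
  ref <- reference_descriptives()
  sub <- ref[ref$seriousness != "ALL" & ref$variable == "reaction_cnt", ]
  subgroup_sizes <- tibble::tibble(
    reporter_group = sub$reporter_group,
    seriousness = sub$seriousness,
    n = as.integer(sub$count)
  )
  var_map <- c(reaction_cnt = "reaction", suspect_drug_cnt = "suspect",
               concomitant_drug_cnt = "concomitant")
  cp <- ref[ref$seriousness != "ALL" & ref$variable %in% names(var_map), ]
  count_params <- tibble::tibble(
    reporter_group = cp$reporter_group,
    seriousness = cp$seriousness,
    variable = unname(var_map[cp$variable]),
    mean = cp$mean,
    sd = cp$sd
  )

  drug_catalog <- tibble::tribble(
    ~drug, ~prob_hp, ~prob_nonhp,
    "pantoprazole",          0.10, 0.07,
    "omeprazole",            0.08, 0.10,
    "esomeprazole",          0.05, 0.09,
    "furosemide",            0.09, 0.05,
    "rivaroxaban",           0.06, 0.03,
    "methotrexate",          0.06, 0.05,
    "vitamin d",             0.07, 0.11,
    "ascorbic acid",         0.04, 0.07,
    "levothyroxine",         0.08, 0.10,
    "hydrochlorothiazide",   0.05, 0.07,
    "acetylsalicylic acid",  0.10, 0.09,
    "metoprolol",            0.06, 0.06,
    "bisoprolol",            0.05, 0.04,
    "amlodipine",            0.07, 0.07,
    "simvastatin",           0.06, 0.06,
    "tramadol",              0.05, 0.06,
    "gabapentin",            0.04, 0.05,
    "pregabalin",            0.03, 0.04,
    "chlorphenamine",        0.02, 0.05,
    "pseudoephedrine",       0.01, 0.03,
    "paracetamol",           0.12, 0.12,
    "folic acid",            0.05, 0.03,
    "hydroxychloroquine",    0.03, 0.03,
    "prednisolone",          0.06, 0.05,
    "ramipril",              0.06, 0.05
  )
  drug_catalog$primary <- "*"

  background_drugs <- tibble::tibble(
    drug = sprintf("co-drug-%03d", seq_len(300)),
    weight = 1 / seq_len(300)
  )

  primary_drug_weights <- tibble::tribble(
    ~drug, ~weight,
    "ibuprofen",  0.34,
    "diclofenac", 0.22,
    "naproxen",   0.17,
    "celecoxib",  0.13,
    "meloxicam",  0.08,
    "etoricoxib", 0.04,
    "piroxicam",  0.02
  )

  named_pts <- tibble::tribble(
    ~pt, ~w_hp_serious, ~w_hp_nonserious, ~w_nonhp_serious, ~w_nonhp_nonserious,
    "Gastrointestinal haemorrhage",          9.0, 1.0, 3.5, 0.5,
    "Acute kidney injury",                   8.5, 1.0, 3.2, 0.5,
    "Melaena",                               5.5, 0.8, 2.0, 0.4,
    "Upper gastrointestinal haemorrhage",    5.0, 0.5, 1.8, 0.3,
    "Drug interaction",                      4.0, 1.0, 1.8, 0.6,
    "Angioedema",                            3.8, 1.2, 1.4, 0.8,
    "Anaemia",                               4.5, 1.0, 2.2, 0.7,
    "Chronic kidney disease",                2.2, 0.5, 6.0, 1.0,
    "Drug ineffective",                      2.5, 2.0, 5.5, 4.5,
    "Product use in unapproved indication",  1.5, 1.5, 4.0, 4.0,
    "Off label use",                         1.2, 1.5, 2.5, 4.0,
    "Headache",                              2.5, 3.0, 4.8, 5.5,
    "Pain",                                  2.2, 2.5, 4.2, 4.8,
    "Renal failure",                         2.0, 0.4, 4.5, 0.8,
    "Pruritus",                              1.5, 2.0, 3.8, 3.0,
    "Peripheral swelling",                   1.2, 1.5, 3.2, 2.5,
    "Fatigue",                               1.5, 1.8, 3.0, 4.0,
    "Arthralgia",                            1.5, 1.5, 2.8, 3.5,
    "Rash",                                  3.0, 5.0, 2.5, 2.0,
    "Urticaria",                             2.5, 4.5, 2.0, 1.8,
    "Dyspepsia",                             3.0, 3.0, 3.0, 3.0,
    "Nausea",                                3.0, 3.5, 3.5, 4.0,
    "Dizziness",                             2.5, 3.0, 3.0, 3.5,
    "Vomiting",                              2.5, 2.5, 2.5, 2.5,
    "Diarrhoea",                             2.2, 2.5, 2.2, 2.5,
    "Abdominal pain",                        2.8, 3.0, 3.0, 3.2
  )
  n_bg <- 800
  bg_rank <- seq_len(n_bg)
  background_pts <- tibble::tibble(
    pt = sprintf("reaction-%04d", bg_rank),
    w_hp_serious = 60 / bg_rank^0.70,
    w_hp_nonserious = 60 / bg_rank^0.70,
    w_nonhp_serious = 60 / bg_rank^1.10,
    w_nonhp_nonserious = 60 / bg_rank^1.10
  )
  reaction_catalog <- dplyr::bind_rows(named_pts, background_pts)

  variants <- tibble::tribble(
    ~canonical, ~variant,
    "vitamin d",            "Cholecalciferol",
    "vitamin d",            "Ergocalciferol",
    "vitamin d",            "VITAMIN D3",
    "ascorbic acid",        "Vitamin C",
    "acetylsalicylic acid", "Aspirin",
    "paracetamol",          "Acetaminophen",
    "levothyroxine",        "Levothyroxine sodium",
    "levothyroxine",        "L-Thyroxine",
    "furosemide",           "Frusemide",
    "chlorphenamine",       "Chlorpheniramine",
    "hydrochlorothiazide",  "HCTZ",
    "metoprolol",           "Metoprolol tartrate",
    "metoprolol",           "Metoprolol succinate",
    "diclofenac",           "Diclofenac sodium",
    "diclofenac",           "Diclofenac potassium",
    "naproxen",             "Naproxen sodium",
    "amlodipine",           "Amlodipine besylate",
    "esomeprazole",         "Nexium"
  )

  synthetic_config(
    subgroup_sizes = subgroup_sizes,
    count_params = count_params,
    severity_coupling = severity_coupling,
    drug_catalog = drug_catalog,
    background_drugs = background_drugs,
    primary_drug_weights = primary_drug_weights,
    reaction_catalog = reaction_catalog,
    synonym_variants = variants,
    synonym_noise = synonym_noise,
    seed = seed
  )
}

# --- count-law calibration ------------------------------------------------

severity_grid <- function(coupling, n_points = 4096) {
  if (coupling <= 0) return(1)
  shape <- 1 / coupling^2
  qgamma((seq_len(n_points) - 0.5) / n_points, shape = shape,
         scale = coupling^2)
}

# marginal mean / variance of the (possibly zero-truncated) NB count when the
# underlying mean is m0 * s over the severity grid
marginal_moments <- function(m0, theta, grid, truncated) {
  m <- m0 * grid
  if (truncated) {
    p0 <- dnbinom(0, size = theta, mu = m)
    tm <- m / (1 - p0)
    ex2 <- (m + m^2 * (1 + 1 / theta)) / (1 - p0)
  } else {
    tm <- m
    ex2 <- m + m^2 * (1 + 1 / theta)
  }
  mean1 <- mean(tm)
  list(mean = mean1, var = mean(ex2) - mean1^2)
}

# Solve underlying NB mean m0 so the marginal mean hits the target.
solve_m0 <- function(target_mean, theta, grid, truncated) {
  f <- function(log_m0) {
    marginal_moments(exp(log_m0), theta, grid, truncated)$mean - target_mean
  }
  uniroot(f, lower = log(1e-8), upper = log(1e6), tol = 1e-12)$root |> exp()
}

# Calibrate (m0, theta) to target marginal mean and sd. The sd is matched
# where attainable; below the severity/truncation floor the quasi-Poisson
# boundary is used (the mean always matches exactly). Solutions are cached
# per session: the same targets recur across subgroups and generator calls.
calibration_cache <- new.env(parent = emptyenv())

calibrate_count_law <- function(target_mean, target_sd, coupling, truncated,
                                n_points = 4096) {
  key <- paste(format(c(target_mean, target_sd, coupling), digits = 15),
               truncated, n_points, collapse = "|")
  cached <- calibration_cache[[key]]
  if (!is.null(cached)) return(cached)
  result <- calibrate_count_law_impl(target_mean, target_sd, coupling,
                                     truncated, n_points)
  calibration_cache[[key]] <- result
  result
}

calibrate_count_law_impl <- function(target_mean, target_sd, coupling,
                                     truncated, n_points) {
  if (truncated && target_mean <= 1) {
    abort("zero-truncated count law cannot reach a marginal mean <= 1")
  }
  grid <- severity_grid(coupling, n_points)
  sd_at <- function(log_theta) {
    theta <- exp(log_theta)
    m0 <- solve_m0(target_mean, theta, grid, truncated)
    sqrt(marginal_moments(m0, theta, grid, truncated)$var)
  }
  lo <- log(1e-2)
  hi <- log(1e6)
  f_lo <- sd_at(lo) - target_sd
  f_hi <- sd_at(hi) - target_sd
  log_theta <- if (f_lo > 0 && f_hi > 0) {
    hi  # target sd below the attainable floor: least-overdispersed boundary
  } else if (f_lo < 0 && f_hi < 0) {
    lo
  } else {
    uniroot(function(lt) sd_at(lt) - target_sd, lower = lo, upper = hi,
            tol = 1e-10)$root
  }
  theta <- exp(log_theta)
  list(theta = theta,
       m0 = solve_m0(target_mean, theta, grid, truncated))
}

# Draw zero-truncated NB deviates by inverse-CDF conditioning on X >= 1.
rztnb <- function(mu, theta) {
  p0 <- dnbinom(0, size = theta, mu = mu)
  u <- runif(length(mu), min = p0, max = 1)
  pmax(qnbinom(u, size = theta, mu = mu), 1)
}

# inclusion probabilities of catalog drugs for one (primary, group),
# preferring a primary-specific row over the "*" wildcard
catalog_probs <- function(catalog, primary, group) {
  col <- if (group == "HP") "prob_hp" else "prob_nonhp"
  specific <- catalog[catalog$primary == primary, ]
  wildcard <- catalog[catalog$primary == "*", ]
  wildcard <- wildcard[!wildcard$drug %in% specific$drug, ]
  rows <- rbind(specific, wildcard)
  rows <- rows[rows$drug != primary, ]
  setNames(rows[[col]], rows$drug)
}

corrupt_names <- function(names, noise, variant_tbl) {
  hit <- runif(length(names)) < noise
  if (!any(hit)) return(names)
  for (i in which(hit)) {
    nm <- names[i]
    variants <- variant_tbl$variant[variant_tbl$canonical == nm]
    style <- c("upper", "title", "pad")[sample.int(3, 1)]
    styled <- switch(style,
      upper = toupper(nm),
      title = stringr::str_to_title(nm),
      pad = paste0("  ", nm, " ")
    )
    pool <- c(variants, styled)
    names[i] <- pool[sample.int(length(pool), 1)]
  }
  names
}

#' Generate a synthetic ICSR cohort
#'
#' Draws exactly the configured number of cases per subgroup, with count
#' variables from the calibrated (zero-truncated) negative-binomial laws
#' coupled through a shared latent severity, drug identities from the
#' catalog inclusion probabilities, reaction Preferred Terms from the
#' reaction catalog, and optional drug-name synonym corruption. Fully
#' reproducible given `config$seed`: the same configuration yields a
#' byte-identical canonical TSV.
#'
#' @param config A `synthetic_config`.
#' @return An `icsr_cohort`.
#' @export
generate_cohort <- function(config) {
  validate_synthetic_config(config)
  clean <- withr::with_seed(config$seed, generate_clean_cohort(config))
  if (config$synonym_noise > 0 && nrow(clean) > 0) {
    clean <- withr::with_seed(config$seed + 1L, {
      clean$suspect_drugs <- lapply(clean$suspect_drugs, corrupt_names,
                                    noise = config$synonym_noise,
                                    variant_tbl = config$synonym_variants)
      clean$concomitant_drugs <- lapply(clean$concomitant_drugs,
                                        corrupt_names,
                                        noise = config$synonym_noise,
                                        variant_tbl = config$synonym_variants)
      clean
    })
  }
  clean
}

generate_clean_cohort <- function(config) {
  sizes <- config$subgroup_sizes
  pts <- config$reaction_catalog$pt
  n_pts <- length(pts)
  bg <- config$background_drugs
  chunks <- vector("list", nrow(sizes))
  case_counter <- 0L

  for (g in seq_len(nrow(sizes))) {
    n <- sizes$n[g]
    if (n == 0) {
      chunks[[g]] <- NULL
      next
    }
    group <- sizes$reporter_group[g]
    serious <- sizes$seriousness[g]
    par_for <- function(variable) {
      row <- config$count_params[
        config$count_params$reporter_group == group &
          config$count_params$seriousness == serious &
          config$count_params$variable == variable, ]
      if (nrow(row) != 1) {
        abort(paste0("count_params must have exactly one row for ",
                     group, "/", serious, "/", variable))
      }
      row
    }
    p_r <- par_for("reaction")
    p_s <- par_for("suspect")
    p_c <- par_for("concomitant")
    cal_r <- calibrate_count_law(p_r$mean, p_r$sd, config$severity_coupling,
                                 truncated = TRUE)
    cal_s <- calibrate_count_law(p_s$mean, p_s$sd, config$severity_coupling,
                                 truncated = TRUE)
    cal_c <- calibrate_count_law(p_c$mean, p_c$sd, config$severity_coupling,
                                 truncated = FALSE)

    s <- if (config$severity_coupling > 0) {
      shape <- 1 / config$severity_coupling^2
      rgamma(n, shape = shape, scale = config$severity_coupling^2)
    } else rep(1, n)

    r_cnt <- rztnb(cal_r$m0 * s, cal_r$theta)
    s_cnt <- rztnb(cal_s$m0 * s, cal_s$theta)
    c_cnt <- rnbinom(n, size = cal_c$theta, mu = cal_c$m0 * s)

    if (max(r_cnt) > n_pts) {
      abort(paste0("a case requests ", max(r_cnt), " distinct reaction PTs ",
                   "but the reaction catalog has only ", n_pts))
    }

    primary <- sample(config$primary_drug_weights$drug, n, replace = TRUE,
                      prob = config$primary_drug_weights$weight)

    w_col <- paste0("w_", tolower(ifelse(group == "HP", "hp", "nonhp")),
                    "_", tolower(ifelse(serious == "SERIOUS", "serious",
                                        "nonserious")))
    pt_w <- config$reaction_catalog[[w_col]]
    if (is.null(pt_w)) {
      abort(paste0("reaction catalog lacks weight column ", w_col))
    }

    reaction_pts <- vector("list", n)
    suspect_drugs <- vector("list", n)
    concomitant_drugs <- vector("list", n)

    for (p in unique(primary)) {
      idx <- which(primary == p)
      probs <- catalog_probs(config$drug_catalog, p, group)
      n_cat <- length(probs)
      inc <- matrix(runif(length(idx) * n_cat) < rep(probs, each = length(idx)),
                    nrow = length(idx))
      for (j in seq_along(idx)) {
        i <- idx[j]
        capacity <- s_cnt[i] + c_cnt[i] - 1L
        included <- names(probs)[inc[j, ]]
        if (length(included) > capacity) {
          included <- if (capacity == 0) character() else
            included[sample.int(length(included), capacity)]
        }
        n_fill <- capacity - length(included)
        if (n_fill > 0) {
          if (n_fill > nrow(bg)) {
            abort(paste0("a case needs ", n_fill, " background co-drugs but ",
                         "the background pool has only ", nrow(bg)))
          }
          fills <- sample(bg$drug, n_fill, prob = bg$weight)
        } else {
          fills <- character()
        }
        co <- c(included, fills)
        if (length(co) > 1) co <- co[sample.int(length(co))]
        suspect_drugs[[i]] <- c(p, co[seq_len(s_cnt[i] - 1L)])
        concomitant_drugs[[i]] <-
          if (c_cnt[i] > 0) co[s_cnt[i] - 1L + seq_len(c_cnt[i])] else
            character()
        reaction_pts[[i]] <- sample(pts, r_cnt[i], prob = pt_w)
      }
    }

    chunks[[g]] <- tibble::tibble(
      case_id = sprintf("SYN-%07d", case_counter + seq_len(n)),
      reporter_group = group,
      seriousness = serious,
      age_group = ">65",
      sex = sample(c("F", "M", "UNKNOWN"), n, replace = TRUE,
                   prob = c(0.55, 0.40, 0.05)),
      primary_drug = primary,
      reaction_pts = reaction_pts,
      suspect_drugs = suspect_drugs,
      concomitant_drugs = concomitant_drugs
    )
    case_counter <- case_counter + n
  }

  tbl <- dplyr::bind_rows(chunks)
  if (nrow(tbl) == 0) {
    tbl <- tibble::tibble(
      case_id = character(), reporter_group = character(),
      seriousness = character(), age_group = character(), sex = character(),
      primary_drug = character(), reaction_pts = list(),
      suspect_drugs = list(), concomitant_drugs = list()
    )
  }
  new_icsr_cohort(
    tbl,
    provenance = sprintf("synthetic cohort (seed %d)", config$seed),
    extraction_date = format(Sys.Date())
  )
}

#' Plant a co-reporting effect into a configuration
#'
#' Returns a configuration in which the non-HP inclusion probability of
#' `drug` under primary drug `primary` is `delta_pp / 100` above the HP
#' probability; everything else is unchanged. Used as a test harness for
#' percentage-point effect recovery by the co-reporting Z analysis.
#'
#' @param config A `synthetic_config`.
#' @param drug Catalog drug receiving the effect.
#' @param primary Primary drug the effect applies under.
#' @param delta_pp Effect size in percentage points (may be negative).
#' @return The modified `synthetic_config`.
#' @export
plant_effect <- function(config, drug, primary, delta_pp) {
  if (delta_pp == 0) return(config)
  cat <- config$drug_catalog
  if (!drug %in% cat$drug) {
    abort(paste0("drug not in catalog: ", drug))
  }
  if (!primary %in% config$primary_drug_weights$drug) {
    abort(paste0("primary drug not in catalog: ", primary))
  }
  specific <- which(cat$drug == drug & cat$primary == primary)
  if (length(specific) == 0) {
    wild <- which(cat$drug == drug & cat$primary == "*")
    if (length(wild) == 0) abort(paste0("drug not in catalog: ", drug))
    row <- cat[wild[1], ]
    row$primary <- primary
    cat <- rbind(cat, row)
    specific <- nrow(cat)
  }
  new_p <- cat$prob_hp[specific] + delta_pp / 100
  if (new_p < 0 || new_p > 1) {
    abort(paste0("planted non-HP probability out of [0, 1]: ", new_p))
  }
  cat$prob_nonhp[specific] <- new_p
  config$drug_catalog <- cat
  config
}
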