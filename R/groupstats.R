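# Subgroup descriptives, Mann-Whitney U with rank-biserial effect size and
# percentile-bootstrap mean-difference CIs, Bonferroni correction,
# Tukey-Kramer post-hoc comparisons, and count correlation analyses.

describe_vector <- function(x) {
  n <- length(x)
  if (n == 0) {
    return(tibble::tibble(count = 0L, mean = NA_real_, sd = NA_real_,
                          min = NA_real_, q25 = NA_real_, q50 = NA_real_,
                          q75 = NA_real_, max = NA_real_))
  }
  q <- unname(quantile(x, c(0.25, 0.5, 0.75), type = 7))
  tibble::tibble(
    count = n, mean = mean(x),
    sd = if (n > 1) sd(x) else 0,  # single observation: sd 0 by convention
    min = min(x), q25 = q[1], q50 = q[2], q75 = q[3], max = max(x)
  )
}

#' Subgroup descriptive statistics of the count variables
#'
#' Count, mean, sample sd, min, quartiles and max of the four count
#' variables (`reaction_cnt`, `suspect_drug_cnt`, `concomitant_drug_cnt`,
#' `suspect_and_concomitant_cnt`) in each of the four
#' reporter-by-seriousness subgroups, plus the two reporter-group marginals
#' (`seriousness = "ALL"`). The marginal count of each reporter group equals
#' the sum of its two subgroup counts, and the marginal mean is their
#' count-weighted pool.
#'
#' @param cohort An `icsr_cohort`.
#' @return A tibble with columns `reporter_group`, `seriousness`, `group`
#'   (1-4, `NA` for marginals), `variable`, and the eight summary columns.
#' @export
describe_subgroups <- function(cohort) {
  counts <- case_counts(cohort)
  long <- tidyr::pivot_longer(counts, dplyr::all_of(COUNT_VARIABLES),
                              names_to = "variable", values_to = "value")
  strata <- tidyr::expand_grid(
    reporter_group = REPORTER_GROUPS,
    seriousness = c("NON_SERIOUS", "SERIOUS", "ALL"),
    variable = COUNT_VARIABLES
  )
  out <- purrr::pmap_dfr(strata, function(reporter_group, seriousness,
                                          variable) {
    keep <- long$reporter_group == reporter_group &
      long$variable == variable
    if (seriousness != "ALL") keep <- keep & long$seriousness == seriousness
    desc <- describe_vector(long$value[keep])
    tibble::tibble(
      reporter_group = reporter_group,
      seriousness = seriousness,
      group = if (seriousness == "ALL") NA_integer_ else
        subgroup_number(reporter_group, seriousness),
      variable = variable,
      desc
    )
  })
  out
}

mann_whitney_u <- function(x, y) {
  n1 <- length(x)
  r <- rank(c(x, y))
  sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2  # U1, ties counted one half
}

# Exact two-sided permutation p-value of U by enumerating every assignment
# of the pooled values to the two groups (feasible for small n1 + n2).
mann_whitney_exact_p <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  u_obs <- mann_whitney_u(x, y)
  centre <- n1 * length(y) / 2
  idx <- combn(length(pooled), n1)
  u_all <- apply(idx, 2, function(i) {
    mann_whitney_u(pooled[i], pooled[-i])
  })
  mean(abs(u_all - centre) >= abs(u_obs - centre) - 1e-12)
}

#' Mann-Whitney comparison with effect size and bootstrap mean difference
#'
#' Compares two count samples with the Mann-Whitney U test (no
#' distributional assumptions), reports the rank-biserial correlation
#' derived from U as the effect size, and estimates the mean difference
#' between the samples with a percentile bootstrap.
#'
#' The U statistic counts pairs where a group-1 value exceeds a group-2
#' value, with ties counted one half; the rank-biserial correlation is
#' `2 U / (n1 n2) - 1`. For `n1 + n2 <= exact_limit` the two-sided p-value
#' is computed by exhaustive enumeration of all group assignments (exact
#' even with ties); otherwise by the normal approximation with midranks and
#' tie-corrected variance (continuity correction optional). The bootstrap
#' draws `n_boot` resamples of each group at its own size with replacement,
#' takes the difference of resample means, and forms the 95% confidence
#' interval from the 2.5th and 97.5th percentiles of those differences.
#'
#' @param x,y Numeric samples (group 1 and group 2).
#' @param n_boot Number of bootstrap replicates (default 10000).
#' @param seed Integer seed for the bootstrap; required, so every stochastic
#'   result is reproducible and logged.
#' @param exact_limit Maximum `n1 + n2` for the exact enumeration (default
#'   12).
#' @param continuity Continuity correction in the normal approximation
#'   (default `TRUE`).
#' @param n_comparisons Bonferroni family size applied to `p_adjusted`
#'   (default 1 = no adjustment).
#' @return A list of class `mann_whitney_result` with elements `U`,
#'   `p_value`, `p_adjusted`, `rank_biserial`, `boot_mean_diff`,
#'   `boot_ci_95`, `n1`, `n2`, `n_boot`, `seed`.
#' @export
#' @examples
#' mann_whitney_compare(c(3, 4), c(1, 2), n_boot = 100, seed = 1)
mann_whitney_compare <- function(x, y, n_boot = 10000, seed,
                                 exact_limit = 12, continuity = TRUE,
                                 n_comparisons = 1) {
  n1 <- length(x)
  n2 <- length(y)
  if (n1 < 1 || n2 < 1) abort("both samples must be non-empty")
  if (n_boot < 1) abort("n_boot must be >= 1")
  if (missing(seed)) abort("seed is required for the bootstrap")

  u1 <- mann_whitney_u(x, y)
  if (n1 + n2 <= exact_limit) {
    p <- mann_whitney_exact_p(x, y)
  } else {
    nn <- n1 + n2
    ties <- table(c(x, y))
    mu <- n1 * n2 / 2
    sigma2 <- n1 * n2 / 12 *
      ((nn + 1) - sum(ties^3 - ties) / (nn * (nn - 1)))
    if (sigma2 <= 0) {
      p <- 1  # all values tied: no ordering information
    } else {
      cc <- if (continuity) 0.5 else 0
      z <- (abs(u1 - mu) - cc) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-max(z, 0)))
    }
  }

  boot <- withr::with_seed(seed, {
    chunk <- max(1L, floor(1e6 / max(n1, n2)))
    diffs <- numeric(n_boot)
    done <- 0L
    while (done < n_boot) {
      b <- min(chunk, n_boot - done)
      mx <- matrix(sample(x, n1 * b, replace = TRUE), nrow = b)
      my <- matrix(sample(y, n2 * b, replace = TRUE), nrow = b)
      diffs[done + seq_len(b)] <- rowMeans(mx) - rowMeans(my)
      done <- done + b
    }
    diffs
  })
  ci <- unname(quantile(boot, c(0.025, 0.975), type = 7))

  structure(
    list(
      U = u1,
      p_value = p,
      p_adjusted = min(1, p * n_comparisons),
      rank_biserial = 2 * u1 / (n1 * n2) - 1,
      boot_mean_diff = mean(boot),
      boot_ci_95 = ci,
      n1 = n1, n2 = n2, n_boot = n_boot, seed = seed
    ),
    class = "mann_whitney_result"
  )
}

#' @export
print.mann_whitney_result <- function(x, ...) {
  cat(sprintf(
    paste0("Mann-Whitney comparison (n1 = %d, n2 = %d)\n",
           "  U = %.1f, p = %.4g (adjusted %.4g)\n",
           "  rank-biserial = %.4f\n",
           "  bootstrap mean difference = %.4f, 95%% CI [%.4f, %.4f]\n"),
    x$n1, x$n2, x$U, x$p_value, x$p_adjusted, x$rank_biserial,
    x$boot_mean_diff, x$boot_ci_95[1], x$boot_ci_95[2]
  ))
  invisible(x)
}

#' Bonferroni correction
#'
#' Multiplies each p-value by the number of comparisons and clips at 1,
#' preserving order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order.
#' @export
bonferroni_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "bonferroni")
}

#' Tukey post-hoc comparison of the four subgroups
#'
#' Tukey-Kramer pairwise comparisons (studentized-range distribution,
#' unequal group sizes supported) of one count variable across the four
#' reporter-by-seriousness subgroups, via a one-way analysis of variance.
#' `rank_transform = TRUE` runs the same procedure on midranks instead of
#' raw counts.
#'
#' @param cohort An `icsr_cohort` with at least two non-empty subgroups.
#' @param variable One of the four count variables.
#' @param rank_transform Compare midranks instead of raw counts.
#' @return A list of class `posthoc_result` with elements `variable`,
#'   `group_means` (named by group number), `p_matrix` (symmetric 4x4,
#'   `NA` diagonal), `diff_matrix` (pairwise mean differences row - column).
#' @export
tukey_posthoc <- function(cohort, variable = COUNT_VARIABLES,
                          rank_transform = FALSE) {
  variable <- match.arg(variable)
  counts <- case_counts(cohort)
  value <- counts[[variable]]
  grp <- subgroup_number(counts$reporter_group, counts$seriousness)
  sizes <- table(factor(grp, levels = 1:4))
  small <- names(sizes)[sizes > 0 & sizes < 2]
  if (length(small) > 0) {
    abort(paste0("subgroup(s) with fewer than 2 observations: group ",
                 paste(small, collapse = ", ")))
  }
  present <- names(sizes)[sizes >= 2]
  if (length(present) < 2) abort("need at least 2 non-empty subgroups")

  keep <- grp %in% as.integer(present)
  df <- data.frame(value = if (rank_transform) rank(value[keep]) else
    value[keep], group = factor(grp[keep]))
  tk <- TukeyHSD(aov(value ~ group, data = df))$group

  group_means <- tapply(counts[[variable]], factor(grp, levels = 1:4), mean)
  p_matrix <- matrix(NA_real_, 4, 4, dimnames = list(1:4, 1:4))
  diff_matrix <- matrix(NA_real_, 4, 4, dimnames = list(1:4, 1:4))
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  for (i in seq_along(pairs)) {
    a <- as.integer(pairs[[i]][1])
    b <- as.integer(pairs[[i]][2])
    p_matrix[a, b] <- p_matrix[b, a] <- tk[i, "p adj"]
    diff_matrix[a, b] <- tk[i, "diff"]
    diff_matrix[b, a] <- -tk[i, "diff"]
  }
  structure(
    list(variable = variable, group_means = group_means,
         p_matrix = p_matrix, diff_matrix = diff_matrix,
         rank_transform = rank_transform),
    class = "posthoc_result"
  )
}

#' @export
print.posthoc_result <- function(x, ...) {
  cat(sprintf("Tukey post-hoc comparison; variable: %s%s\n", x$variable,
              if (x$rank_transform) " (rank-transformed)" else ""))
  cat("Group means:\n")
  print(round(x$group_means, 4))
  cat("Pairwise p-values:\n")
  print(round(x$p_matrix, 6))
  invisible(x)
}

#' Correlation between reaction counts and drug counts
#'
#' Correlates the per-case reaction count with either the suspect-drug count
#' or the total suspect-plus-concomitant count, over the whole cohort or
#' within one of the four subgroups. Counts are discrete and heavily skewed,
#' so the rank (Spearman) coefficient is the default; the linear (Pearson)
#' coefficient is available via `method`.
#'
#' @param cohort An `icsr_cohort`.
#' @param pair `"reaction_vs_suspect"` or
#'   `"reaction_vs_suspect_and_concomitant"`.
#' @param scope `"ALL"` or a subgroup number 1-4.
#' @param method `"rank"` (Spearman) or `"linear"` (Pearson).
#' @return A tibble with columns `scope`, `pair`, `method`, `r`, `p_value`,
#'   `n`, `degenerate` (zero variance in either variable: `r` undefined).
#' @export
correlate_counts <- function(cohort,
                             pair = c("reaction_vs_suspect",
                                      "reaction_vs_suspect_and_concomitant"),
                             scope = "ALL",
                             method = c("rank", "linear")) {
  pair <- match.arg(pair)
  method <- match.arg(method)
  counts <- case_counts(cohort)
  if (!identical(scope, "ALL")) {
    stopifnot(scope %in% 1:4)
    grp <- subgroup_number(counts$reporter_group, counts$seriousness)
    counts <- counts[grp == scope, ]
  }
  if (nrow(counts) < 3) {
    abort("need at least 3 records in the requested scope")
  }
  xvar <- counts$reaction_cnt
  yvar <- if (pair == "reaction_vs_suspect") counts$suspect_drug_cnt else
    counts$suspect_and_concomitant_cnt
  if (sd(xvar) == 0 || sd(yvar) == 0) {
    return(tibble::tibble(scope = as.character(scope), pair = pair,
                          method = method, r = NA_real_, p_value = NA_real_,
                          n = nrow(counts), degenerate = TRUE))
  }
  ct <- suppressWarnings(cor.test(
    xvar, yvar,
    method = if (method == "rank") "spearman" else "pearson",
    exact = FALSE
  ))
  tibble::tibble(scope = as.character(scope), pair = pair, method = method,
                 r = unname(ct$estimate), p_value = ct$p.value,
                 n = nrow(counts), degenerate = FALSE)
}

#' Correlation analyses over all scopes
#'
#' Runs [correlate_counts()] for the whole cohort and each of the four
#' subgroups, for both variable pairs.
#'
#' @inheritParams correlate_counts
#' @return A tibble, one row per scope and pair.
#' @export
correlate_counts_all <- function(cohort, method = c("rank", "linear")) {
  method <- match.arg(method)
  scopes <- list("ALL", 1L, 2L, 3L, 4L)
  pairs <- c("reaction_vs_suspect", "reaction_vs_suspect_and_concomitant")
  purrr::map_dfr(pairs, function(p) {
    purrr::map_dfr(scopes, function(s) {
      tryCatch(
        correlate_counts(cohort, pair = p, scope = s, method = method),
        error = function(e) {
          # scope too small to correlate: flagged row instead of an abort
          tibble::tibble(scope = as.character(s), pair = p, method = method,
                         r = NA_real_, p_value = NA_real_, n = NA_integer_,
                         degenerate = TRUE)
        }
      )
    })
  })
}
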