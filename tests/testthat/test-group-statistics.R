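# Subgroup descriptives, Mann-Whitney/rank-biserial/bootstrap, Bonferroni,
# Tukey post-hoc, correlations

test_that("marginal descriptives pool the subgroup moments", {
  ch <- generate_cohort(tiny_config(seed = 23, n_hp = 180, n_nonhp = 140))
  desc <- describe_subgroups(ch)
  for (grp in c("HP", "NON_HP")) {
    sub <- desc[desc$reporter_group == grp &
                  desc$variable == "reaction_cnt", ]
    marg <- sub[sub$seriousness == "ALL", ]
    strata <- sub[sub$seriousness != "ALL" & sub$count > 0, ]
    expect_equal(marg$count, sum(strata$count))
    expect_equal(marg$mean,
                 weighted_mean_pool(strata$count, strata$mean))
  }
  # quartile ordering invariant
  filled <- desc[desc$count > 0, ]
  expect_true(all(filled$min <= filled$q25 & filled$q25 <= filled$q50 &
                    filled$q50 <= filled$q75 & filled$q75 <= filled$max))
})

test_that("descriptives match brute-force computation per subgroup", {
  ch <- generate_cohort(tiny_config(seed = 29))
  cc <- case_counts(ch)
  desc <- describe_subgroups(ch)
  sel <- cc$reporter_group == "HP" & cc$seriousness == "SERIOUS"
  x <- sort(cc$suspect_drug_cnt[sel])
  row <- desc[desc$reporter_group == "HP" & desc$seriousness == "SERIOUS" &
                desc$variable == "suspect_drug_cnt", ]
  expect_equal(row$count, length(x))
  expect_equal(row$mean, mean(x))
  expect_equal(row$sd, sd(x))
  expect_equal(row$q50, unname(quantile(x, 0.5)))
  expect_equal(row$min, min(x))
  expect_equal(row$max, max(x))
})

test_that("empty and single-observation strata are handled by convention", {
  ch <- make_cohort(
    list(id = "A", grp = "HP", ser = "SERIOUS", pts = c("a", "b"),
         sus = "ibuprofen")
  )
  desc <- describe_subgroups(ch)
  row <- desc[desc$reporter_group == "HP" & desc$seriousness == "SERIOUS" &
                desc$variable == "reaction_cnt", ]
  expect_equal(row$mean, 2)
  expect_equal(row$min, 2)
  expect_equal(row$max, 2)
  expect_equal(row$sd, 0)
  empty <- desc[desc$reporter_group == "NON_HP" &
                  desc$seriousness == "ALL" &
                  desc$variable == "reaction_cnt", ]
  expect_equal(empty$count, 0)
  expect_true(is.na(empty$mean))
})

test_that("rank-biserial follows the U formula in the edge cases", {
  # identical multisets: U = n1 n2 / 2, effect 0
  res <- mann_whitney_compare(c(1, 2, 3), c(1, 2, 3), n_boot = 50, seed = 1)
  expect_equal(res$rank_biserial, 0)
  # complete separation
  res2 <- mann_whitney_compare(c(3, 4), c(1, 2), n_boot = 50, seed = 1)
  expect_equal(res2$rank_biserial, 1)
  res3 <- mann_whitney_compare(c(1, 2), c(3, 4), n_boot = 50, seed = 1)
  expect_equal(res3$rank_biserial, -1)
  # degenerate resampling: constant groups give a point CI
  res4 <- mann_whitney_compare(rep(5, 4), rep(3, 4), n_boot = 200, seed = 2)
  expect_equal(res4$boot_mean_diff, 2)
  expect_equal(res4$boot_ci_95, c(2, 2))
})

test_that("U and exact p match the independent enumeration oracle", {
  set.seed(99)
  for (n in 2:6) {
    for (rep in 1:3) {
      x <- sample(0:4, n, replace = TRUE)
      y <- sample(0:4, n, replace = TRUE)
      res <- mann_whitney_compare(x, y, n_boot = 10, seed = 1)
      expect_equal(res$U, oracle_u(x, y),
                   label = sprintf("U for n=%d rep=%d", n, rep))
      expect_equal(res$p_value, oracle_exact_p(x, y),
                   label = sprintf("p for n=%d rep=%d", n, rep))
    }
  }
})

test_that("large-sample U and p agree with wilcox.test", {
  set.seed(7)
  x <- rpois(80, 3) + 1
  y <- rpois(70, 4) + 1
  res <- mann_whitney_compare(x, y, n_boot = 10, seed = 1)
  wt <- suppressWarnings(wilcox.test(x, y, correct = TRUE))
  expect_equal(res$U, unname(wt$statistic))
  expect_equal(res$p_value, wt$p.value, tolerance = 1e-10)
  # effect sign matches the mean-rank ordering
  r <- rank(c(x, y))
  mean_rank_diff <- mean(r[seq_along(x)]) - mean(r[length(x) + seq_along(y)])
  expect_equal(sign(res$rank_biserial), sign(mean_rank_diff))
})

test_that("bootstrap CI width shrinks like one over root n", {
  widths <- vapply(c(50, 200, 800), function(n) {
    x <- withr::with_seed(100 + n, rnorm(n, mean = 1))
    y <- withr::with_seed(200 + n, rnorm(n))
    res <- mann_whitney_compare(x, y, n_boot = 2000, seed = n)
    diff(res$boot_ci_95)
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
  # quadrupling n should roughly halve the width
  expect_equal(widths[1] / widths[2], 2, tolerance = 0.35)
  expect_equal(widths[2] / widths[3], 2, tolerance = 0.35)
})

test_that("Bonferroni adjustment is the clipped product", {
  expect_equal(bonferroni_adjust(0.01), 0.01)
  expect_equal(bonferroni_adjust(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.08, 0.12, 0.16))
  p <- withr::with_seed(1, runif(20))
  adj <- bonferroni_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  expect_error(bonferroni_adjust(1.2), "\\[0, 1\\]")
})

test_that("Tukey post-hoc separates shifted groups and stays symmetric", {
  mk <- function(mu, grp, ser, n, seed) {
    vals <- pmax(1, round(withr::with_seed(seed, rnorm(n, mu, 1))))
    lapply(seq_len(n), function(i) {
      list(id = sprintf("%s-%s-%d", grp, ser, i), grp = grp, ser = ser,
           pts = rep("Pain", vals[i]), sus = "ibuprofen")
    })
  }
  rows <- c(mk(2, "HP", "NON_SERIOUS", 50, 1), mk(12, "HP", "SERIOUS", 50, 2),
            mk(2, "NON_HP", "NON_SERIOUS", 50, 3),
            mk(12, "NON_HP", "SERIOUS", 50, 4))
  ch <- do.call(make_cohort, rows)
  ph <- tukey_posthoc(ch, "reaction_cnt")
  expect_true(isSymmetric(ph$p_matrix, tol = 1e-12))
  expect_true(all(is.na(diag(ph$p_matrix))))
  expect_lt(ph$p_matrix[1, 2], 1e-6)   # means 2 vs 12
  expect_gt(ph$p_matrix[1, 3], 0.05)   # same distribution
  expect_equal(unname(ph$diff_matrix[2, 1]),
               unname(ph$group_means[2] - ph$group_means[1]),
               tolerance = 1e-9)
})

test_that("Tukey post-hoc names undersized subgroups in its error", {
  ch <- make_cohort(
    list(id = "A", grp = "HP", ser = "SERIOUS", pts = "a", sus = "x"),
    list(id = "B", grp = "HP", ser = "NON_SERIOUS", pts = "a", sus = "x"),
    list(id = "C", grp = "HP", ser = "NON_SERIOUS", pts = c("a", "b"),
         sus = "x")
  )
  expect_error(tukey_posthoc(ch, "reaction_cnt"), "group 2")
})

test_that("perfectly monotone counts give r = 1 for both methods", {
  rows <- lapply(1:8, function(i) {
    list(id = paste0("M", i), grp = "HP", ser = "SERIOUS",
         pts = paste0("pt", seq_len(i)),
         sus = paste0("drug", seq_len(i)))
  })
  ch <- do.call(make_cohort, rows)
  expect_equal(correlate_counts(ch, "reaction_vs_suspect",
                                method = "rank")$r, 1)
  expect_equal(correlate_counts(ch, "reaction_vs_suspect",
                                method = "linear")$r, 1)
})

test_that("count correlations behave on planted and null structure", {
  ch <- generate_cohort(tiny_config(seed = 37, n_hp = 2500, n_nonhp = 2500,
                                    coupling = 0.8))
  res <- correlate_counts(ch, "reaction_vs_suspect_and_concomitant",
                          scope = "ALL")
  expect_gt(res$r, 0)
  expect_lt(res$p_value, 0.01)
  # independent counts: near-zero correlation
  ch0 <- generate_cohort(tiny_config(seed = 38, n_hp = 2500, n_nonhp = 2500,
                                     coupling = 0))
  res0 <- correlate_counts(ch0, "reaction_vs_suspect", scope = "ALL")
  expect_lt(abs(res0$r), 0.05)
  # degenerate variable flagged
  chd <- make_cohort(
    list(id = "A", grp = "HP", ser = "SERIOUS", pts = "a", sus = "x"),
    list(id = "B", grp = "HP", ser = "SERIOUS", pts = "b", sus = "y"),
    list(id = "C", grp = "HP", ser = "SERIOUS", pts = "c", sus = "z")
  )
  resd <- correlate_counts(chd, "reaction_vs_suspect", scope = "ALL")
  expect_true(resd$degenerate)
  expect_true(is.na(resd$r))
})
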