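# Co-reporting and reaction ratio tables, the pooled two-proportion Z test,
# table comparison, top-k selection, distinct-PT counts

test_that("co-reporting ratios are cases-containing-drug over cases", {
  ch <- make_cohort(
    list(id = "A", grp = "HP", ser = "SERIOUS", primary = "ibuprofen",
         pts = "Pain", sus = c("ibuprofen", "a"), con = c("b", "c", "d")),
    list(id = "B", grp = "HP", ser = "SERIOUS", primary = "ibuprofen",
         pts = "Pain", sus = c("ibuprofen", "a"), con = c("c", "e", "f")),
    list(id = "C", grp = "HP", ser = "SERIOUS", primary = "ibuprofen",
         pts = "Pain", sus = c("ibuprofen", "a", "c"), con = c("g", "h"))
  )
  f <- polypharmacy_filter(build_profiles(ch))
  tab <- coreporting_table(f, "ibuprofen", "HP")
  expect_equal(ratio_table_n(tab), 3)
  expect_equal(tab$ratio[tab$item == "a"], 1.0)
  expect_equal(tab$ratio[tab$item == "c"], 1.0)
  expect_equal(tab$ratio[tab$item == "b"], 2 / 3 - 1 / 3)
  expect_error(coreporting_table(f, "ibuprofen", "NON_HP"), "no cases")
})

test_that("ratio tables match a brute-force recount on synthetic data", {
  ch <- generate_cohort(tiny_config(seed = 13, n_hp = 250, n_nonhp = 250))
  f <- polypharmacy_filter(build_profiles(ch))
  for (grp in c("HP", "NON_HP")) {
    sel <- f[f$primary_drug == "ibuprofen" & f$reporter_group == grp, ]
    expected <- oracle_item_counts(sel$co_drugs)
    tab <- coreporting_table(f, "ibuprofen", grp)
    expect_equal(setNames(tab$count, tab$item)[names(expected)], expected)
    expect_equal(tab$ratio, tab$count / nrow(sel))
    # conservation: summed counts equal summed per-case set sizes
    expect_equal(sum(tab$count), sum(lengths(sel$co_drugs)))
  }
  rt <- reaction_table(ch, "HP", "SERIOUS")
  sel <- ch[ch$reporter_group == "HP" & ch$seriousness == "SERIOUS", ]
  expected <- oracle_item_counts(sel$reaction_pts)
  expect_equal(setNames(rt$count, rt$item)[names(expected)], expected)
})

test_that("reaction table counts each PT once per case", {
  ch <- make_cohort(
    list(id = "A", grp = "HP", ser = "SERIOUS",
         pts = c("Headache", "Headache", "Pain"), sus = "ibuprofen"),
    list(id = "B", grp = "HP", ser = "SERIOUS", pts = "Headache",
         sus = "ibuprofen")
  )
  tab <- reaction_table(ch, "HP")
  expect_equal(tab$ratio[tab$item == "Headache"], 1.0)
  expect_equal(tab$ratio[tab$item == "Pain"], 0.5)
  expect_false("Nausea" %in% tab$item)
  expect_error(reaction_table(ch, "NON_HP"), "empty stratum")
})

test_that("pooled two-proportion Z matches the closed form", {
  res <- two_proportion_z(10, 100, 20, 100)
  expect_equal(res$z, -1.9803, tolerance = 1e-4)
  expect_equal(res$p_value, 0.0477, tolerance = 1e-3)
  # independent check against the chi-square identity z^2 = X^2
  pt <- suppressWarnings(prop.test(c(10, 20), c(100, 100), correct = FALSE))
  expect_equal(res$z^2, unname(pt$statistic))
  expect_equal(res$p_value, pt$p.value)
  # symmetry and antisymmetry
  same <- two_proportion_z(15, 60, 15, 60)
  expect_equal(same$z, 0)
  expect_equal(same$p_value, 1)
  swap <- two_proportion_z(20, 100, 10, 100)
  expect_equal(swap$z, -res$z)
  expect_equal(swap$p_value, res$p_value)
})

test_that("degenerate pooled proportions are flagged, not propagated", {
  res <- two_proportion_z(0, 50, 0, 80)
  expect_true(res$degenerate)
  expect_equal(res$z, 0)
  expect_equal(res$p_value, 1)
  res2 <- two_proportion_z(50, 50, 80, 80)
  expect_true(res2$degenerate)
})

test_that("compare_ratios unions items and is antisymmetric", {
  ch <- make_cohort(
    list(id = "A", grp = "HP", ser = "SERIOUS", primary = "ibuprofen",
         pts = "Pain", sus = c("ibuprofen", "a", "b"), con = c("c", "d")),
    list(id = "B", grp = "NON_HP", ser = "SERIOUS", primary = "ibuprofen",
         pts = "Pain", sus = c("ibuprofen", "e", "b"), con = c("c", "f"))
  )
  f <- polypharmacy_filter(build_profiles(ch))
  t_hp <- coreporting_table(f, "ibuprofen", "HP")
  t_nonhp <- coreporting_table(f, "ibuprofen", "NON_HP")
  cmp <- compare_ratios(t_hp, t_nonhp)
  expect_setequal(cmp$item, c("a", "b", "c", "d", "e", "f"))
  expect_equal(cmp$ratio_hp[cmp$item == "e"], 0)
  expect_equal(cmp$pp_diff[cmp$item == "a"], -100)
  swapped <- compare_ratios(t_nonhp, t_hp)
  m <- match(cmp$item, swapped$item)
  expect_equal(swapped$pp_diff[m], -cmp$pp_diff)
  expect_equal(swapped$z[m], -cmp$z)
  expect_equal(swapped$p_value[m], cmp$p_value)
  # identical tables: no differences, nothing significant
  self_cmp <- compare_ratios(t_hp, t_hp)
  expect_true(all(self_cmp$pp_diff == 0))
  expect_false(any(self_cmp$significant))
})

test_that("top_k ranks by ratio with alphabetical tie-break", {
  tab <- icsrcompare:::new_ratio_table(
    tibble::tibble(item = c("b", "a", "c", "d"),
                   count = c(3L, 3L, 5L, 1L),
                   ratio = c(0.3, 0.3, 0.5, 0.1)),
    stratum = list(), n_cases = 10
  )
  expect_equal(top_k(tab, 2)$item, c("c", "a"))
  expect_equal(nrow(top_k(tab, 20)), 4)
  full <- top_k(tab, nrow(tab))
  expect_setequal(full$item, tab$item)
  expect_equal(full$ratio, sort(tab$ratio, decreasing = TRUE))
  expect_error(top_k(tab, 0), "k must")
})

test_that("distinct PT counts equal the brute-force union size", {
  expect_equal(distinct_pt_count(icsr_cohort(), "HP"), 0)
  ch <- generate_cohort(tiny_config(seed = 17))
  for (grp in c("HP", "NON_HP")) {
    manual <- length(unique(unlist(
      ch$reaction_pts[ch$reporter_group == grp]
    )))
    expect_equal(distinct_pt_count(ch, grp), manual)
  }
})

test_that("eligible primaries are the most frequent filtered cases", {
  ch <- generate_cohort(tiny_config(seed = 19, n_hp = 300, n_nonhp = 300))
  f <- polypharmacy_filter(build_profiles(ch))
  counts <- sort(table(f$primary_drug), decreasing = TRUE)
  expect_equal(eligible_primary_drugs(f, k = 1), names(counts)[1])
  expect_equal(eligible_primary_drugs(f, override = c("x", "y")),
               c("x", "y"))
})
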