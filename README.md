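# icsrcompare

Compare adverse-drug-reaction (ADR) case reports filed by healthcare
professionals (HPs: physicians, dentists, pharmacists, nurses) with those
filed by consumers (non-HPs: patients, relatives, caregivers), in the style
of EudraVigilance line listings for non-steroidal anti-inflammatory drugs
(NSAIDs, ATC group M01A) in patients over 65. The package is aimed at
pharmacovigilance analysts who want a tested, reproducible version of this
comparison — from raw line-listing CSVs to significance-tested tables — and
at methodologists who want to probe how such analyses behave, using the
built-in synthetic cohort generator instead of a database download.

## What it computes

Every case is an individual case safety report (ICSR) with a reaction list
(MedDRA Preferred Terms), a suspect-drug list, an optional concomitant-drug
list, and a primary drug (the M01A substance whose line listing the case
came from). The pipeline:

1. **Curation** — suspect and concomitant lists are merged, normalized
   (case, whitespace, trailing salt/ester words), collapsed to unique
   canonical names through a synonym map (cholecalciferol and
   ergocalciferol both become *vitamin d*), and the primary drug and all
   its synonyms are removed.
2. **Polypharmacy filter** — only cases with at least five reported drugs
   (raw suspect + concomitant total) are kept for the interaction-oriented
   co-reporting analysis.
3. **Co-reporting ratios** — for each of the five primary drugs with the
   most filtered cases, each co-drug's ratio is
   `r_g = (cases in group g containing the drug) / n_g`, computed
   separately for HPs and non-HPs. Groups are compared on the
   percentage-point scale, `Δpp = 100 (r_nonHP − r_HP)`, with the pooled
   two-proportion Z test:

   `z = (p̂₁ − p̂₂) / √( p̂(1−p̂)(1/n₁ + 1/n₂) )`, `p̂ = (c₁+c₂)/(n₁+n₂)`.

4. **Reaction ratios** — the same per-case ratio and Z comparison for each
   reaction PT, over all reports and separately for serious and
   non-serious reports, plus distinct-PT counts per group.
5. **Group statistics** — Table-style descriptives (count/mean/sd/quartiles)
   of the four count variables (`reaction_cnt`, `suspect_drug_cnt`,
   `concomitant_drug_cnt`, `suspect_and_concomitant_cnt`) in the four
   reporter-by-seriousness subgroups; Mann–Whitney U tests with the
   rank-biserial effect size `r_rb = 2U/(n₁n₂) − 1`; percentile-bootstrap
   mean-difference 95% CIs (10 000 resamples, 2.5th/97.5th percentiles);
   Bonferroni correction; Tukey–Kramer post-hoc comparisons across the four
   subgroups; and Spearman (default) or Pearson correlations between
   reaction counts and drug counts.

The synthetic generator draws zero-truncated, overdispersed
negative-binomial counts calibrated to the reference cohort's printed
moments, couples reaction and drug counts through a shared latent severity
factor, samples drug identities at configured per-group inclusion
probabilities (so planted percentage-point effects are recoverable), and
corrupts drug names with realistic synonym/formatting noise that the
curation step must undo.

## Worked example

```r
library(icsrcompare)

cfg     <- default_synthetic_config(seed = 42)
cohort  <- generate_cohort(cfg)           # 12,742 cases, 4 subgroups
filtered <- polypharmacy_filter(build_profiles(cohort), min_total = 5)
nrow(filtered)
#> [1] 4156

eligible_primary_drugs(filtered)
#> [1] "ibuprofen"  "diclofenac" "naproxen"   "celecoxib"  "meloxicam"

cmp <- compare_ratios(
  coreporting_table(filtered, "ibuprofen", "HP"),
  coreporting_table(filtered, "ibuprofen", "NON_HP")
)
head(dplyr::select(cmp, item, ratio_hp, ratio_nonhp, pp_diff, z, p_value), 3)
#> # A tibble: 3 × 6
#>   item        ratio_hp ratio_nonhp pp_diff     z   p_value
#>   <chr>          <dbl>       <dbl>   <dbl> <dbl>     <dbl>
#> 1 co-drug-001   0.615       0.545    -6.97 -2.19 0.0283
#> 2 vitamin d     0.0595      0.126     6.67  3.94 0.0000816
#> 3 furosemide    0.102       0.0432   -5.89 -3.18 0.00148
```

`vitamin d` is co-reported with ibuprofen in 12.6% of non-HP polypharmacy
cases against 6.0% of HP cases — 6.7 percentage points more, and the Z test
says a gap that large is incompatible with equal reporting rates
(p ≈ 8 × 10⁻⁵). Negative rows (furosemide) run the other way: more often
co-reported by HPs.

```r
cc <- case_counts(cohort)
mann_whitney_compare(cc$reaction_cnt[cc$reporter_group == "NON_HP"],
                     cc$reaction_cnt[cc$reporter_group == "HP"],
                     n_boot = 10000, seed = 43)
#> Mann-Whitney comparison (n1 = 3366, n2 = 9376)
#>   U = 17786772.0, p = 1.538e-30 (adjusted 1.538e-30)
#>   rank-biserial = 0.1272
#>   bootstrap mean difference = 0.4284, 95% CI [0.2744, 0.5842]
```

Non-HPs report on average ~0.43 more reactions per case than HPs in this
simulated cohort (a small effect, rank-biserial 0.13, but decisively
non-zero), mirroring the structure the generator was configured with.

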