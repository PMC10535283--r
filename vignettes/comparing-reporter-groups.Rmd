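---
title: "Methods: comparing healthcare-professional and consumer ADR reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing healthcare-professional and consumer ADR reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Since 2012, EU pharmacovigilance law lets patients and caregivers
(non-healthcare professionals, non-HPs) report suspected adverse drug
reactions directly, alongside physicians, dentists, pharmacists and nurses
(HPs). The two report streams differ systematically: HPs tend to report
diagnoses that require clinical work-up (gastrointestinal haemorrhage,
acute kidney injury), non-HPs tend to report lived symptoms and
quality-of-life complaints (pain, headache, fatigue, drug ineffectiveness).
For NSAIDs in patients over 65 — a population where polypharmacy and
drug–drug interactions are the central safety concern — quantifying those
differences tells us what each reporter stream can and cannot contribute to
interaction surveillance.

`icsrcompare` implements that comparison as a reusable pipeline over
individual case safety reports (ICSRs): each case has a reporter group, a
case-level seriousness, a reaction list of MedDRA Preferred Terms (PTs), a
suspect-drug list (at least one entry — the minimum reporting criterion), an
optional concomitant-drug list, and a primary drug, the M01A substance whose
line listing the case came from.

## Drug-list curation

Public line listings carry free-text drug names. Curation proceeds in a
fixed order, and each step is idempotent:

1. lowercase and collapse whitespace;
2. strip *trailing* salt/ester words from a fixed list (`sodium`,
   `tartrate`, `hydrochloride`, ...) — conservative by construction: a word
   is only stripped if at least one other word remains, so
   `potassium chloride` survives while `diclofenac sodium` becomes
   `diclofenac`;
3. map through a synonym table (surface → canonical), shipped with the
   vitamin D family, vitamin aliases, and common INN/brand pairs, and
   user-extensible from a two-column TSV.

Per case, the suspect and concomitant lists are merged, collapsed to unique
canonical names, and the primary drug is removed. Because removal happens
*after* normalization, every synonym and salt form of the primary is removed
with it.

### Raw versus deduplicated totals

The polypharmacy filter keeps cases with at least five reported drugs. We
count the *raw* list totals (suspect + concomitant, before deduplication),
because in the reference descriptives the per-case total is exactly the sum
of the two per-list counts (e.g. 3.00 + 2.64 = 5.64 in the HP serious
stratum), which is only possible if totals are tabulated before collapsing.
Whether the filter should instead count unique canonical names is genuinely
open; the choice is exposed as `count_basis = "raw" | "unique"` and the
default is the raw total.

## Ratio analyses

Co-drug and reaction items are counted **once per case** (the curated
profile is a set; a reaction list is treated as a set), so a ratio is the
fraction of cases in which the item appears and is a proper proportion.
Groups are compared per item on the percentage-point scale,
`pp = 100 (r_nonHP − r_HP)`, with the pooled two-proportion Z test and
two-sided normal p-values. Design choices:

* **Pooled variance, no continuity correction** — the plain "two-sample
  Z test for proportions"; an unpooled variant sits behind
  `pooled = FALSE`. Degenerate pooled proportions (0 or 1) carry no
  evidence either way and are reported as `z = 0, p = 1` with a flag
  rather than `NaN`.
* **No multiplicity adjustment across items by default**, matching per-item
  reporting of such analyses; `adjust = "bonferroni"` is available.
* **Top-20 selection ranks by ratio** with alphabetical tie-break. Within a
  fixed stratum ranking by ratio and by raw count coincide (same
  denominator); ratio is chosen because it is the reported quantity.
  Selection only picks rows — it never alters a statistic.
* **Eligible primary drugs** are the five with the most filtered cases
  (both groups pooled), overrideable with an explicit list.

## Group statistics

The four count variables are discrete, heavily overdispersed and skewed, so
the group comparison machinery is distribution-free:

* **Mann–Whitney U** with midranks; `U` counts pairs where a group-1 value
  exceeds a group-2 value, ties counted one half. For `n1 + n2 ≤ 12` the
  two-sided p-value is computed by exhaustive enumeration of all group
  assignments (exact even under ties); above that, the normal approximation
  with tie-corrected variance and (by default) a 0.5 continuity correction.
* **Rank-biserial correlation** `2U/(n1 n2) − 1` as the effect size; its
  sign always matches the mean-rank ordering.
* **Percentile bootstrap** for the mean difference: 10 000 resamples of
  each group at its own size with replacement, difference of resample
  means, CI from the 2.5th and 97.5th percentiles (quantile type 7). The
  percentile method — not BCa — is used deliberately, matching the simple
  percentile description of the procedure being reproduced. The seed is a
  required argument of every stochastic operation and is recorded in the
  result.
* **Tukey–Kramer post-hoc** across the four subgroups (Group 1 = HP
  non-serious, 2 = HP serious, 3 = non-HP non-serious, 4 = non-HP serious)
  via a one-way ANOVA and the studentized-range distribution, which handles
  the unequal group sizes. The procedure is labelled only "Tukey" in the
  tables being reproduced; we run it on raw counts, with
  `rank_transform = TRUE` available for a rank-based variant.
* **Correlations** between reaction and drug counts default to Spearman —
  the declared non-normal count data make a rank coefficient the safer
  default, and the source analysis never names its coefficient — with
  Pearson behind `method = "linear"`. Results carry a method tag so the two
  are never conflated.

Bonferroni correction is the clipped product `min(1, m·p)`; in the pipeline
the four count-variable comparisons form one family (`m = 4`).

## The synthetic cohort generator

The generator exists so that every downstream stage is testable without any
database access. It emulates, by default, an elderly-NSAID reference cohort
of 12 742 cases in four subgroups (HP/non-HP × serious/non-serious, sizes
2193/7183/1049/2317).

### Count law and calibration

Counts are zero-truncated negative binomial (reactions, suspect drugs;
every case has at least one of each) or plain negative binomial
(concomitant drugs, zero permitted). The reference moments show variance
far above the mean (e.g. mean 3.50, sd 4.90 for HP serious reactions) with
minima of 1 — which the zero-truncated NB reproduces and a Poisson cannot.

A case's three counts share a latent severity factor
`s ~ Gamma(shape = 1/c², scale = c²)` (mean 1, coefficient of variation
`c = severity_coupling`, default 0.8) multiplying all underlying NB means —
the simplest mechanism producing the positive reaction-count/drug-count
correlations the correlation analyses must recover. With the default
coupling the induced Spearman correlations sit roughly between 0.1 and 0.3
depending on subgroup, the order of magnitude seen in real report streams.

Configuration is in terms of the *marginal* target mean and sd — the form
reference tables print. For each subgroup and variable the underlying NB
mean `m0` and size `θ` are solved numerically: a 4096-point quantile grid
over the severity distribution approximates the marginal moments, an inner
root-solve matches the mean exactly, and an outer root-solve matches the sd
where attainable (severity plus truncation impose a variance floor; targets
below it fall back to the quasi-Poisson boundary, and only the sd is then
approximate — the mean always calibrates exactly). A 2-million-draw check
of the HP-serious reaction law gives mean 3.496 ± 0.003 against the 3.50
target.

### Drug identities

Catalog drugs (the named substances analyses care about) enter a case by
independent Bernoulli draws at their configured per-(primary drug ×
reporter group) inclusion probability. This is a deliberate design choice:
the co-reporting ratio downstream is then an unbiased estimator of the
configured probability, so a planted percentage-point effect
(`plant_effect()`) is recovered on exactly the scale it was planted —
weighted sampling without replacement would make inclusion a nonlinear
function of the weight and break that contract. The drawn raw list lengths
are honoured exactly: background filler names complete the lists, and in
the rare case Bernoulli inclusions exceed capacity a uniform random subset
is kept (this truncation hits both reporter groups symmetrically, so null
drugs stay null and planted effects shrink only marginally). Reaction PTs
are sampled without replacement from a weighted catalog whose background
tail is flatter for HPs — giving HPs the greater PT diversity seen in real
data.

Drug-name noise replaces canonical names with surface variants (synonyms,
salt forms, case/whitespace mutations) at a configured probability, using
only variants that the curation step provably inverts; corruption consumes
an independent RNG substream, so a noise-free twin of the same seed is
byte-identical elsewhere.

### What the generator does not emulate

Reporting latency, duplicate reports, country strata, within-case
dependence between *specific* drugs and *specific* reactions (conditionally
independent given subgroup and severity), and MedDRA hierarchy structure
(PTs are opaque strings). Passing tests therefore demonstrate that the
*machinery* is correct and calibrated — not that real EudraVigilance
extracts would yield any particular substantive finding.

## Numerical and testing choices

* Exact Mann–Whitney enumeration is limited to `n1 + n2 ≤ 12`
  (`choose(12,6) = 924` assignments); tests check it against an
  independently coded pair-counting oracle, and the large-sample branch
  against `wilcox.test`.
* The two-proportion Z is cross-checked against the `prop.test` chi-square
  identity `z² = X²`.
* Calibration checks run at the sizes the procedures are specified at:
  type-I error over 2000 null items at n = 1000/group (expected rejection
  rate in [0.03, 0.07] at α = 0.05), bootstrap coverage over 500
  replications at n = 100 (expected in [93%, 97%]), moment recovery at
  10 000 cases per subgroup (each mean within 3 standard errors), planted
  10-pp recovery at ~2000 filtered cases per group (±2 pp). These sizes
  keep the full suite under two minutes on one CPU while leaving the
  binomial/Monte-Carlo noise well inside the stated bands.
* Ties in `top_k` and in primary-drug selection break alphabetically, so
  every output is deterministic given the seed.

## Limitations

The default line-listing dialect is a best-effort reconstruction — the
public portal's export schema is not formally documented, so the reader is
fully configurable and rejects (with per-row diagnostics) anything it
cannot map. The shipped synonym map is small and curated for the substances
that recur in elderly-NSAID analyses; real-world curation needs a larger
table (the format is a plain TSV). The pooled Z treats cases as independent
and ignores duplicate reporting. Bootstrap CIs are percentile CIs: at
n = 100 their true coverage runs slightly under the nominal 95%, which is
inherent to the method, not a defect of the implementation.
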