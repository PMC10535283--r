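Package: icsrcompare
Title: Comparing Healthcare-Professional and Consumer Adverse Drug Reaction
    Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for comparing adverse-drug-reaction case reports filed by
    healthcare professionals with those filed by patients and caregivers, in
    the style of EudraVigilance line listings for non-steroidal
    anti-inflammatory drugs in patients over 65. Provides a canonical
    individual-case-safety-report (ICSR) data model with line-listing
    readers and writers, drug-name curation with synonym collapsing, a
    polypharmacy (five-or-more drugs) case filter, co-reporting and
    reaction-reporting ratio tables compared by two-proportion Z tests,
    subgroup descriptive statistics, Mann-Whitney U tests with rank-biserial
    effect sizes and percentile-bootstrap mean-difference confidence
    intervals, Tukey-Kramer post-hoc comparisons, count correlation
    analyses, and a seeded synthetic ICSR cohort generator so the whole
    pipeline runs without any database download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
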