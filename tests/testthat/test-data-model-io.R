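# Cohort data model and line-listing / canonical / JSON-lines IO

test_that("cohort constructor enforces the report invariants", {
  expect_s3_class(make_cohort(
    list(id = "A", grp = "HP", ser = "SERIOUS", pts = "Headache",
         sus = "ibuprofen")
  ), "icsr_cohort")
  expect_error(make_cohort(
    list(id = "A", grp = "HP", ser = "SERIOUS", pts = "Headache",
         sus = "ibuprofen"),
    list(id = "A", grp = "HP", ser = "SERIOUS", pts = "Pain",
         sus = "naproxen")
  ), "unique")
  expect_error(make_cohort(
    list(id = "A", grp = "HP", ser = "SERIOUS", pts = character(),
         sus = "ibuprofen")
  ), "reaction")
  expect_error(make_cohort(
    list(id = "A", grp = "HP", ser = "SERIOUS", pts = "Headache",
         sus = character())
  ), "suspect")
  expect_error(make_cohort(
    list(id = "A", grp = "doctor", ser = "SERIOUS", pts = "Headache",
         sus = "ibuprofen")
  ), "reporter_group")
})

test_that("suspect_and_concomitant_cnt is the sum of its parts", {
  ch <- generate_cohort(tiny_config(seed = 11))
  cc <- case_counts(ch)
  expect_identical(cc$suspect_and_concomitant_cnt,
                   cc$suspect_drug_cnt + cc$concomitant_drug_cnt)
  expect_true(all(cc$reaction_cnt >= 1))
  expect_true(all(cc$suspect_drug_cnt >= 1))
  expect_true(all(cc$concomitant_drug_cnt >= 0))
})

test_that("line-listing reader splits lists and strips annotations", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    paste("EU Local Number", "Primary Source Qualification", "Seriousness",
          "Patient Age Group", "Patient Sex", "Primary Drug",
          "Reaction List PT", "Suspect Drug List", "Concomitant Drug List",
          sep = ","),
    'C1,Physician,Serious,>65,Female,ibuprofen,Gastrointestinal haemorrhage,IBUPROFEN (Oral),"pantoprazole (40mg, Oral), furosemide"',
    "C2,Consumer,Non-Serious,>65,Male,ibuprofen,Headache,IBUPROFEN,",
    "C3,Lawyer,Serious,>65,,ibuprofen,Pain,NAPROXEN (Oral (daily)),"
  ), path)
  ch <- read_line_listing(path)
  expect_equal(nrow(ch), 3)
  expect_equal(ch$suspect_drugs[[1]], "IBUPROFEN")
  expect_equal(ch$concomitant_drugs[[1]], c("pantoprazole", "furosemide"))
  expect_equal(ch$reaction_pts[[1]], "Gastrointestinal haemorrhage")
  expect_equal(ch$reporter_group, c("HP", "NON_HP", "NON_HP"))
  expect_equal(ch$seriousness, c("SERIOUS", "NON_SERIOUS", "SERIOUS"))
  expect_equal(ch$sex, c("F", "M", "UNKNOWN"))
  # nested annotation on C3 stripped completely
  expect_equal(ch$suspect_drugs[[3]], "NAPROXEN")
})

test_that("rows missing a mandatory field are rejected with diagnostics", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    paste("EU Local Number", "Primary Source Qualification", "Seriousness",
          "Reaction List PT", "Suspect Drug List", sep = ","),
    "C1,Physician,Serious,Headache,IBUPROFEN",
    "C2,Robot,Serious,Headache,IBUPROFEN",
    "C3,Physician,Serious,,IBUPROFEN",
    "C4,Physician,Maybe,Headache,IBUPROFEN"
  ), path)
  expect_warning(
    ch <- read_line_listing(path, primary_drug = "ibuprofen"),
    "3 row"
  )
  expect_equal(nrow(ch), 1)
  rejects <- attr(ch, "rejects")
  expect_equal(rejects$case_id, c("C2", "C3", "C4"))
  expect_equal(rejects$reason,
               c("unmappable reporter qualification", "no reaction PT",
                 "unmappable seriousness"))
})

test_that("a missing mandatory column is a configuration error", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "EU Local Number,Seriousness,Reaction List PT,Suspect Drug List",
    "C1,Serious,Headache,IBUPROFEN"
  ), path)
  expect_error(read_line_listing(path, primary_drug = "ibuprofen"),
               "Primary Source Qualification")
})

test_that("header-only file yields an empty cohort", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(paste(
    "EU Local Number", "Primary Source Qualification", "Seriousness",
    "Reaction List PT", "Suspect Drug List", sep = ","), path)
  ch <- read_line_listing(path, primary_drug = "ibuprofen")
  expect_equal(nrow(ch), 0)
})

test_that("canonical TSV and JSON-lines round trips are lossless", {
  cols <- c("case_id", "reporter_group", "seriousness", "age_group", "sex",
            "primary_drug", "reaction_pts", "suspect_drugs",
            "concomitant_drugs")
  for (seed in c(3, 4)) {
    ch <- generate_cohort(tiny_config(seed = seed, n_hp = 40, n_nonhp = 40,
                                      noise = 0.3))
    tsv <- withr::local_tempfile(fileext = ".tsv")
    write_canonical(ch, tsv)
    back <- read_canonical(tsv)
    expect_equal(tibble::as_tibble(back)[cols], tibble::as_tibble(ch)[cols],
                 ignore_attr = TRUE)
    jl <- withr::local_tempfile(fileext = ".jsonl")
    write_canonical_jsonl(ch, jl)
    back2 <- read_canonical_jsonl(jl)
    expect_equal(tibble::as_tibble(back2)[cols], tibble::as_tibble(ch)[cols],
                 ignore_attr = TRUE)
  }
})

test_that("line-listing round trip survives annotation noise", {
  ch <- generate_cohort(tiny_config(seed = 9, n_hp = 25, n_nonhp = 25))
  csv <- withr::local_tempfile(fileext = ".csv")
  write_line_listing(ch, csv, annotate = TRUE)
  back <- read_line_listing(csv)
  expect_equal(back$suspect_drugs, ch$suspect_drugs)
  expect_equal(back$concomitant_drugs, ch$concomitant_drugs)
  expect_equal(back$reaction_pts, ch$reaction_pts)
  expect_equal(back$reporter_group, ch$reporter_group)
  expect_equal(back$seriousness, ch$seriousness)
})

test_that("writing an empty cohort gives a header-only canonical file", {
  empty <- icsr_cohort()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_canonical(empty, path)
  expect_length(readLines(path), 1)
  expect_equal(nrow(read_canonical(path)), 0)
})

test_that("names containing the reserved delimiter are refused", {
  ch <- make_cohort(list(id = "A", grp = "HP", ser = "SERIOUS",
                         pts = "Headache", sus = "drug|with|pipes"))
  expect_error(write_canonical(ch, withr::local_tempfile()), "delimiter")
})
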