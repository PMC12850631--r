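test_that("rows sharing a case number merge into one report", {
  csv <- paste(
    "case_number,report_date,age,sex,trade_name,active_ingredient,role,meddra_terms",
    "C1,2020-01-05,55,F,LYRICA,Pregabalin,suspected,Dizziness;Somnolence",
    "C1,2020-01-05,55,F,,Oxycodone,not suspected,Dizziness;Somnolence",
    "C2,2021-06-30,60,male,,gabapentin,suspected,Nausea",
    sep = "\n")
  reports <- parse_daen_export(csv)
  expect_equal(n_cases(reports), 2)
  expect_equal(sum(reports$drugs$case_id == "C1"), 2)
  # ingredients lower-cased, events de-duplicated preserving first-seen order
  expect_equal(reports$drugs$ingredient[reports$drugs$role == "suspected"],
               c("pregabalin", "gabapentin"))
  expect_equal(reports$events$term[reports$events$case_id == "C1"],
               c("Dizziness", "Somnolence"))
})

test_that("unparseable age and out-of-vocabulary sex become missing", {
  csv <- paste(
    "case_number,report_date,age,sex,trade_name,active_ingredient,role,meddra_terms",
    "C1,2020-01-05,—,unknown,,pregabalin,suspected,Nausea",
    "C2,2020-01-06,-3,F,,pregabalin,suspected,Nausea",
    sep = "\n")
  reports <- parse_daen_export(csv)
  expect_true(all(is.na(reports$cases$age_years)))
  expect_equal(reports$cases$sex, c("missing", "female"))
})

test_that("schema and consolidation errors are informative", {
  no_role <- paste(
    "case_number,report_date,age,sex,active_ingredient,meddra_terms",
    "C1,2020-01-05,55,F,pregabalin,Nausea", sep = "\n")
  expect_error(parse_daen_export(no_role), "role")
  conflict <- paste(
    "case_number,report_date,age,sex,active_ingredient,role,meddra_terms",
    "C1,2020-01-05,55,F,pregabalin,suspected,Nausea",
    "C1,2020-02-05,55,F,oxycodone,not suspected,Nausea", sep = "\n")
  expect_error(parse_daen_export(conflict), "C1")
})

test_that("a simulated collection round-trips through write and re-parse", {
  sim <- simulate_reports(sim_config(
    n_cases = 10, seed = 11,
    drug_mix = c(pregabalin = 0.5, gabapentin = 0.3)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_daen_csv(sim$reports, path)
  back <- parse_daen_export(path)
  expect_equal(back$cases, sim$reports$cases)
  expect_equal(back$drugs, sim$reports$drugs)
  expect_equal(back$events, sim$reports$events)

  # serialising the re-parsed collection reproduces the file byte for byte
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_daen_csv(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("missing age and sex survive a write/parse round trip", {
  reports <- mk_reports(mk_case("C1", age = NA, sex = "missing"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_daen_csv(reports, path)
  back <- parse_daen_export(path)
  expect_true(is.na(back$cases$age_years))
  expect_equal(back$cases$sex, "missing")
})

test_that("window filtering is a closed interval and matches a date scan", {
  reports <- mk_reports(
    mk_case("A", date = "2005-04-01"),
    mk_case("B", date = "2005-03-31"),
    mk_case("C", date = "2024-12-31"))
  kept <- filter_window(reports, "2005-04-01", "2024-12-31")
  expect_equal(kept$cases$case_id, c("A", "C"))

  sim <- simulate_reports(sim_config(
    n_cases = 1000, seed = 5, date_start = "2000-01-01",
    date_end = "2030-12-31"))
  w <- filter_window(sim$reports, "2005-04-01", "2024-12-31")
  expected <- sum(sim$reports$cases$report_date >= as.Date("2005-04-01") &
                  sim$reports$cases$report_date <= as.Date("2024-12-31"))
  expect_equal(n_cases(w), expected)
  expect_error(filter_window(sim$reports, "2024-01-01", "2005-01-01"))
})

test_that("drug canonicalization maps trade names and ingredients to groups", {
  groups <- drug_groups(
    drug_group("pregabalin", "pregabalin", "lyrica"),
    drug_group("oxycodone", "oxycodone", c("endone", "oxycontin")))
  reports <- mk_reports(
    mk_case("C1", drugs = list(c("unknown stuff", "suspected", "LYRICA"),
                               c("Endone", "not_suspected"))),
    mk_case("C2", drugs = list(c("  PREGABALIN ", "suspected"))))
  out <- canonicalize_drugs(reports, groups)
  expect_equal(out$drugs$ingredient, c("pregabalin", "oxycodone", "pregabalin"))
  # relabelling never alters the role multiset per case
  expect_identical(table(out$drugs$role), table(reports$drugs$role))
  # the input collection is not mutated
  expect_equal(reports$drugs$ingredient[2], "Endone")
})

test_that("randomized casing and whitespace never defeats group matching", {
  set.seed(42)
  scramble <- function(x) {
    chars <- strsplit(x, "")[[1]]
    flip <- runif(length(chars)) < 0.5
    chars[flip] <- toupper(chars[flip])
    paste0(paste(rep(" ", sample(0:2, 1)), collapse = ""),
           paste(chars, collapse = ""),
           paste(rep(" ", sample(0:2, 1)), collapse = ""))
  }
  groups <- fixture_groups()
  truth <- sample(names(groups), 50, replace = TRUE)
  specs <- lapply(seq_along(truth), function(i) {
    mk_case(sprintf("C%02d", i), drugs = list(c(scramble(truth[i]),
                                                "suspected")))
  })
  out <- canonicalize_drugs(mk_reports(specs), groups)
  expect_equal(out$drugs$ingredient, truth)
})

test_that("an entry matching two different groups is an ambiguity error", {
  groups <- drug_groups(
    drug_group("pregabalin", "pregabalin"),
    drug_group("oxycodone", "oxycodone", "lyrica"))  # deliberately wrong map
  reports <- mk_reports(
    mk_case("C1", drugs = list(c("pregabalin", "suspected", "lyrica"))))
  expect_error(canonicalize_drugs(reports, groups), "two groups")
})

test_that("report collections enforce their invariants", {
  expect_error(mk_reports(mk_case("C1"), mk_case("C1")), "duplicate")
  expect_error(
    mk_reports(mk_case("C1", drugs = list(c("pregabalin", "not_suspected")))),
    "suspected")
  expect_error(
    daen_reports(tibble::tibble(case_id = "C1",
                                report_date = as.Date("2020-01-01"),
                                age_years = NA_real_, sex = "missing"),
                 tibble::tibble(case_id = "C1", ingredient = "pregabalin",
                                trade_name = NA_character_,
                                role = "suspected"),
                 tibble::tibble(case_id = character(), term = character())),
    "without events")
})
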