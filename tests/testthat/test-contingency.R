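test_that("cases are classified exposed / comparator / excluded per the rules", {
  reports <- mk_reports(
    mk_case("C1", drugs = list(c("pregabalin", "suspected"))),
    mk_case("C2", drugs = list(c("duloxetine", "suspected"),
                               c("amitriptyline", "suspected"))),
    mk_case("C3", drugs = list(c("paracetamol", "suspected"))),
    mk_case("C4", drugs = list(c("pregabalin", "suspected"),
                               c("gabapentin", "suspected"))))
  cls <- classify_exposure(reports, np_design())
  expect_equal(cls$arm[cls$case_id == "C1"], "exposed")
  # multiple comparator drugs: one comparator case, not two
  expect_equal(cls$arm[cls$case_id == "C2"], "comparator")
  expect_equal(sum(cls$case_id == "C2"), 1)
  expect_equal(cls$arm[cls$case_id == "C3"], "excluded")
  # suspected for both arms: assigned to the exposed arm only
  expect_equal(cls$arm[cls$case_id == "C4"], "exposed")
})

test_that("single-suspected restriction excludes multi-ingredient cases", {
  reports <- mk_reports(
    mk_case("C1", drugs = list(c("pregabalin", "suspected"),
                               c("oxycodone", "suspected"))),
    mk_case("C2", drugs = list(c("pregabalin", "suspected"),
                               c("pregabalin", "suspected", "LYRICA"))),
    mk_case("C3", drugs = list(c("pregabalin", "suspected"),
                               c("oxycodone", "not_suspected"))))
  cls <- classify_exposure(reports,
                           np_design(restrict_single_suspected = TRUE))
  expect_equal(cls$arm[cls$case_id == "C1"], "excluded")
  # one ingredient under several entries is still single suspected,
  # and not-suspected co-medication does not count
  expect_equal(cls$arm[cls$case_id == "C2"], "exposed")
  expect_equal(cls$arm[cls$case_id == "C3"], "exposed")
})

hand_cases <- function() {
  mk_reports(
    mk_case("E1", sex = "male", drugs = list(c("pregabalin", "suspected")),
            events = "drug dependence"),
    mk_case("E2", sex = "female", drugs = list(c("pregabalin", "suspected")),
            events = "drug abuse"),
    mk_case("E3", sex = "male", drugs = list(c("pregabalin", "suspected")),
            events = "nausea"),
    mk_case("K1", sex = "male", drugs = list(c("gabapentin", "suspected")),
            events = "drug dependence"),
    mk_case("K2", sex = "female", drugs = list(c("duloxetine", "suspected")),
            events = "nausea"),
    mk_case("K3", sex = "male", drugs = list(c("amitriptyline", "suspected")),
            events = "dizziness"))
}

test_that("case-level tables match hand enumeration, with and without strata", {
  reports <- hand_cases()
  hits <- map_cases(reports, fixture_smqs(), "broad")
  tab <- build_table_cases(reports, hits, np_design())
  expect_tables_equal(tab, contingency_table(2, 1, 1, 2))

  # the female stratum removes one exposed hit case and one comparator
  # non-hit case
  tab_m <- build_table_cases(reports, hits, np_design(sex = "male"))
  expect_tables_equal(tab_m, contingency_table(1, 1, 1, 1))

  # scope mismatch between hits and design is refused
  expect_error(build_table_cases(reports, hits, np_design(scope = "narrow")),
               "scope")
})

test_that("case-level tables equal an independent brute-force scan", {
  smqs <- fixture_smqs()
  sim <- simulate_reports(sim_config(
    n_cases = 2000, seed = 17,
    drug_mix = c(pregabalin = 0.25, gabapentin = 0.15, duloxetine = 0.15,
                 amitriptyline = 0.1)))
  reports <- sim$reports
  designs <- list(
    np_design(),
    np_design("psychosis and psychotic disorders", sex = "female"),
    np_design("drug withdrawal", age_bin = "55-64"),
    np_design(restrict_single_suspected = TRUE),
    np_design("suicide and self-injury", years = 2010:2014),
    design_spec("pregabalin", "duloxetine", "drug abuse and dependence",
                scope = "narrow"))
  for (d in designs) {
    hits <- map_cases(reports, smqs, d$scope)
    expect_tables_equal(build_table_cases(reports, hits, d),
                        brute_force_table(reports, smqs, d))
  }
})

test_that("summary-count tables remove exposed cases from both comparator margins", {
  counts <- fixture_summary()
  tab <- build_table_summary(counts, "pregabalin", "drug abuse and dependence")
  expect_tables_equal(tab, contingency_table(418, 1598, 8698, 449814))
  expect_equal(tab$a + tab$b + tab$c + tab$d, counts$total_reports)

  # zero exposed events is a valid table
  sc0 <- summary_counts(1000, c(drugA = 100),
                        data.frame(drug = "drugA", query_name = "q", n = 0),
                        c(q = 60))
  expect_tables_equal(build_table_summary(sc0, "drugA", "q"),
                      contingency_table(0, 100, 60, 840))

  # named-comparator margins come from that drug's own rows
  tab5 <- build_table_summary(counts, "pregabalin",
                              "drug abuse and dependence",
                              comparator = "gabapentin")
  expect_tables_equal(tab5, contingency_table(418, 1598, 35, 391))
})

test_that("summary tables always conserve the report total", {
  set.seed(31)
  for (i in 1:25) {
    total <- sample(500:5000, 1)
    n_exp <- sample(10:(total / 4), 1)
    all_ev <- sample(5:(total / 4), 1)
    a <- sample(0:min(n_exp, all_ev), 1)
    sc <- summary_counts(total, c(x = n_exp),
                         data.frame(drug = "x", query_name = "q", n = a),
                         c(q = all_ev))
    tab <- build_table_summary(sc, "x", "q")
    expect_equal(tab$a + tab$b + tab$c + tab$d, total)
  }
  # inconsistent margins are refused, naming the offending cell
  bad <- summary_counts(100, c(x = 90),
                        data.frame(drug = "x", query_name = "q", n = 5),
                        c(q = 20))
  expect_error(build_table_summary(bad, "x", "q"), "negative")
})

test_that("conservation, scope monotonicity and restriction monotonicity hold", {
  smqs <- fixture_smqs()
  sim <- simulate_reports(sim_config(
    n_cases = 1500, seed = 23,
    drug_mix = c(pregabalin = 0.3, gabapentin = 0.2, duloxetine = 0.2)))
  reports <- sim$reports
  d <- design_spec("pregabalin", c("gabapentin", "duloxetine"),
                   "drug abuse and dependence")
  hits_b <- map_cases(reports, smqs, "broad")
  hits_n <- map_cases(reports, smqs, "narrow")
  tab_b <- build_table_cases(reports, hits_b, d)
  cls <- classify_exposure(reports, d)
  expect_equal(tab_b$a + tab_b$b + tab_b$c + tab_b$d,
               sum(cls$arm != "excluded"))

  d_n <- d; d_n$scope <- "narrow"
  tab_n <- build_table_cases(reports, hits_n, d_n)
  expect_lte(tab_n$a, tab_b$a)

  d_s <- d; d_s$restrict_single_suspected <- TRUE
  tab_s <- build_table_cases(reports, hits_b, d_s)
  for (cell in c("a", "b", "c", "d")) {
    expect_lte(tab_s[[cell]], tab_b[[cell]])
  }
})

test_that("annual tables match per-year scans and flag unsupported years", {
  smqs <- fixture_smqs()
  sim <- simulate_reports(sim_config(
    n_cases = 800, seed = 29,
    drug_mix = c(pregabalin = 0.35, gabapentin = 0.35),
    date_start = "2018-01-01", date_end = "2022-12-31"))
  reports <- sim$reports
  d <- design_spec("pregabalin", "gabapentin", "drug abuse and dependence")
  hits <- map_cases(reports, smqs, "broad")
  ann <- annual_tables(reports, hits, d, 2018:2022)
  expect_equal(nrow(ann), 5)
  for (i in seq_len(nrow(ann))) {
    dy <- d; dy$years <- ann$year[i]
    expect_tables_equal(ann$table[[i]], brute_force_table(reports, smqs, dy))
  }
  expect_equal(ann$supported, ann$n_cases >= 3)

  # a dataset confined to one year gives a length-1 series equal to the
  # whole-dataset table
  one <- filter_window(reports, "2019-01-01", "2019-12-31")
  hits1 <- map_cases(one, smqs, "broad")
  ann1 <- annual_tables(one, hits1, d, 2019)
  expect_tables_equal(ann1$table[[1]], build_table_cases(one, hits1, d))

  # a year with too few exposed hit cases is flagged, never estimated
  tiny <- mk_reports(
    mk_case("T1", date = "2019-05-01",
            drugs = list(c("pregabalin", "suspected")),
            events = "drug dependence"),
    mk_case("T2", date = "2019-06-01",
            drugs = list(c("pregabalin", "suspected")),
            events = "drug dependence"),
    mk_case("T3", date = "2019-07-01",
            drugs = list(c("gabapentin", "suspected")),
            events = "nausea"))
  h <- map_cases(tiny, smqs, "broad")
  a2 <- annual_tables(tiny, h, d, 2019)
  expect_false(a2$supported[1])
  expect_equal(a2$n_cases[1], 2)
})

test_that("design specs validate their strata and arm disjointness", {
  expect_error(design_spec("pregabalin", c("pregabalin", "gabapentin"), "q"),
               "comparator")
  expect_error(np_design(age_bin = "0-17"), "age_bin")
  expect_error(np_design(sex = "other"), "sex")
  expect_error(contingency_table(-1, 2, 3, 4), "non-negative")
  expect_error(contingency_table(1.5, 2, 3, 4), "non-negative")
})
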