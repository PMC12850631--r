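# Shared fixture builders: everything is constructed in code so the suite
# needs no external data beyond the package's own plain-text extdata files.

fixture_smqs <- function() {
  read_smq(system.file("extdata", "smq_fictional.csv", package = "pvsignal"))
}

fixture_groups <- function() {
  read_drug_groups(system.file("extdata", "drug_groups.csv",
                               package = "pvsignal"))
}

fixture_summary <- function() {
  read_summary_counts(
    system.file("extdata", "daen_summary_totals.csv", package = "pvsignal"),
    system.file("extdata", "daen_summary_events.csv", package = "pvsignal"))
}

# one case specification for mk_reports()
mk_case <- function(id, date = "2020-06-01", age = NA, sex = "missing",
                    drugs = list(c("pregabalin", "suspected")),
                    events = "dizziness") {
  list(id = id, date = date, age = age, sex = sex, drugs = drugs,
       events = events)
}

mk_reports <- function(...) {
  specs <- list(...)
  if (length(specs) == 1 && is.null(specs[[1]]$id)) {
    specs <- specs[[1]]  # a list of case specs was passed
  }
  cases <- dplyr::bind_rows(lapply(specs, function(s) {
    tibble::tibble(case_id = s$id, report_date = as.Date(s$date),
                   age_years = as.numeric(s$age), sex = s$sex)
  }))
  drugs <- dplyr::bind_rows(lapply(specs, function(s) {
    dplyr::bind_rows(lapply(s$drugs, function(d) {
      tibble::tibble(case_id = s$id, ingredient = d[1],
                     trade_name = if (length(d) > 2) d[3] else NA_character_,
                     role = d[2])
    }))
  }))
  events <- dplyr::bind_rows(lapply(specs, function(s) {
    tibble::tibble(case_id = s$id, term = s$events)
  }))
  daen_reports(cases, drugs, events)
}

# comparator-design fixture used across contingency/pipeline tests
np_design <- function(query = "drug abuse and dependence", ...) {
  design_spec("pregabalin", c("gabapentin", "duloxetine", "amitriptyline"),
              query, ...)
}

# independent per-case scan used as the brute-force oracle for contingency
# construction: classifies each case and checks hit membership directly from
# the raw tibbles, without build_table_cases()
brute_force_table <- function(reports, smqs, design) {
  terms <- smq_terms(smqs[[match(design$query,
                                 vapply(smqs, `[[`, character(1), "name"))]],
                     design$scope)
  comp <- if (identical(design$comparator, "full_dataset")) character()
          else design$comparator
  a <- b <- cc <- d <- 0L
  for (i in seq_len(nrow(reports$cases))) {
    id <- reports$cases$case_id[i]
    if (!is.null(design$age_bin)) {
      bb <- age_bins()[[design$age_bin]]
      age <- reports$cases$age_years[i]
      if (is.na(age) || age < bb[1] || age >= bb[2]) next
    }
    if (!is.null(design$sex) && reports$cases$sex[i] != design$sex) next
    if (!is.null(design$years) &&
        !(as.integer(format(reports$cases$report_date[i], "%Y")) %in%
          design$years)) next
    dr <- reports$drugs[reports$drugs$case_id == id &
                        reports$drugs$role == "suspected", , drop = FALSE]
    ing <- unique(dr$ingredient)
    if (design$restrict_single_suspected && length(ing) > 1) next
    arm <- if (design$exposed %in% ing) "exposed"
           else if (any(ing %in% comp)) "comparator" else next
    hit <- any(canonical_term(
      reports$events$term[reports$events$case_id == id]) %in% terms)
    if (arm == "exposed" && hit) a <- a + 1L
    else if (arm == "exposed") b <- b + 1L
    else if (hit) cc <- cc + 1L
    else d <- d + 1L
  }
  contingency_table(a, b, cc, d)
}

expect_tables_equal <- function(t1, t2) {
  expect_identical(unlist(t1[c("a", "b", "c", "d")]),
                   unlist(t2[c("a", "b", "c", "d")]))
}
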