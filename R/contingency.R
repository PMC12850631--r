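#' A 2x2 contingency table of case counts
#'
#' Cell `a` counts exposed cases reporting the event of interest, `b` exposed
#' cases without it, `c` comparator cases with the event and `d` comparator
#' cases without it. All cells are non-negative integers; `a + b` is the
#' number of exposed cases in the design and `c + d` the number of comparator
#' cases.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @return A `pv_table` object.
#' @export
#' @examples
#' contingency_table(418, 1598, 8698, 449814)
contingency_table <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells))) {
    stop("contingency cells must be non-negative integers (got ",
         paste(cells, collapse = ", "), ")", call. = FALSE)
  }
  structure(as.list(stats::setNames(as.integer(cells), names(cells))),
            class = "pv_table")
}

#' @export
print.pv_table <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, 2, byrow = TRUE,
              dimnames = list(c("exposed", "comparator"),
                              c("event", "no event")))
  cat("<pv_table>\n"); print(m)
  invisible(x)
}

#' @export
as.matrix.pv_table <- function(x, ...) {
  matrix(c(x$a, x$b, x$c, x$d), 2, 2, byrow = TRUE,
         dimnames = list(c("exposed", "comparator"), c("event", "no event")))
}

#' Age bins used in subgroup analyses
#'
#' Bins are closed on the left and open on the right (18-34 means
#' 18 <= age < 35); the top bin ">65" means age >= 65. Ages below 18 or
#' missing fall in no bin and are excluded from age-stratified analyses only.
#'
#' @return Named list of `c(lower, upper)` bounds.
#' @export
age_bins <- function() {
  list("18-34" = c(18, 35), "35-44" = c(35, 45), "45-54" = c(45, 55),
       "55-64" = c(55, 65), ">65" = c(65, Inf))
}

#' Reporting-period bins used in subgroup analyses
#'
#' @return Named list of calendar-year vectors.
#' @export
period_bins <- function() {
  list("2005-2009" = 2005:2009, "2010-2014" = 2010:2014,
       "2015-2019" = 2015:2019, "2020-2024" = 2020:2024)
}

#' Specify an exposure-comparator-event design
#'
#' Describes one disproportionality contrast: the exposed drug group, the
#' comparator (either the token `"full_dataset"` or a set of drug-group
#' names), the event query and its scope, and optional restrictions
#' (single-suspected cases only; an age bin, a sex, or a set of calendar
#' years).
#'
#' @param exposed Exposed drug-group name.
#' @param comparator `"full_dataset"` or a character vector of drug-group
#'   names (not containing `exposed`).
#' @param query Query name.
#' @param scope `"broad"` or `"narrow"`.
#' @param restrict_single_suspected If `TRUE`, cases with more than one
#'   distinct suspected active ingredient are excluded.
#' @param age_bin Optional, one of `names(age_bins())`.
#' @param sex Optional, `"female"` or `"male"`.
#' @param years Optional integer vector of calendar years.
#' @return A `design_spec` object.
#' @export
design_spec <- function(exposed, comparator = "full_dataset", query,
                        scope = c("broad", "narrow"),
                        restrict_single_suspected = FALSE,
                        age_bin = NULL, sex = NULL, years = NULL) {
  scope <- match.arg(scope)
  is_full <- identical(comparator, "full_dataset")
  if (!is_full && exposed %in% comparator) {
    stop("exposed group must not be part of the comparator set", call. = FALSE)
  }
  if (!is.null(age_bin) && !age_bin %in% names(age_bins())) {
    stop("age_bin must be one of: ", paste(names(age_bins()), collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(sex) && !sex %in% c("female", "male")) {
    stop("sex stratum must be 'female' or 'male'", call. = FALSE)
  }
  structure(list(exposed = exposed, comparator = comparator, query = query,
                 scope = scope,
                 restrict_single_suspected = isTRUE(restrict_single_suspected),
                 age_bin = age_bin, sex = sex,
                 years = if (is.null(years)) NULL else as.integer(years)),
            class = "design_spec")
}

#' Classify each case as exposed, comparator or excluded
#'
#' A case is exposed if any suspected drug entry belongs to the exposed
#' group; otherwise it is a comparator case if any suspected entry belongs to
#' a comparator group, contributing exactly once however many comparator
#' drugs it lists; otherwise it is excluded. Cases suspected for both the
#' exposed group and a comparator group are assigned to the exposed arm, so
#' no case can appear in both margins. Under
#' `restrict_single_suspected`, cases with more than one distinct suspected
#' active ingredient are excluded regardless of arm.
#'
#' @param reports A [daen_reports()] collection with canonicalised drugs.
#' @param design A [design_spec()].
#' @return A tibble with columns `case_id` and `arm` (one of `"exposed"`,
#'   `"comparator"`, `"excluded"`).
#' @export
classify_exposure <- function(reports, design) {
  if (!nrow(reports$cases)) {
    return(tibble::tibble(case_id = character(), arm = character()))
  }
  susp <- reports$drugs[reports$drugs$role == "suspected", , drop = FALSE]
  susp <- susp[!duplicated(susp[c("case_id", "ingredient")]), , drop = FALSE]
  comp <- if (identical(design$comparator, "full_dataset")) character()
          else design$comparator
  ids <- reports$cases$case_id
  n_distinct <- as.integer(table(factor(susp$case_id, levels = ids)))
  is_exposed <- ids %in% susp$case_id[susp$ingredient == design$exposed]
  is_comp <- ids %in% susp$case_id[susp$ingredient %in% comp]
  arm <- ifelse(design$restrict_single_suspected & n_distinct > 1, "excluded",
                ifelse(is_exposed, "exposed",
                       ifelse(is_comp, "comparator", "excluded")))
  tibble::tibble(case_id = ids, arm = arm)
}

apply_strata <- function(reports, design) {
  cases <- reports$cases
  keep <- rep(TRUE, nrow(cases))
  if (!is.null(design$age_bin)) {
    b <- age_bins()[[design$age_bin]]
    keep <- keep & !is.na(cases$age_years) &
      cases$age_years >= b[1] & cases$age_years < b[2]
  }
  if (!is.null(design$sex)) {
    keep <- keep & cases$sex == design$sex
  }
  if (!is.null(design$years)) {
    keep <- keep & report_year(cases$report_date) %in% design$years
  }
  subset_cases(reports, cases$case_id[keep])
}

report_year <- function(date) as.integer(format(date, "%Y"))

#' Build a 2x2 table from case-level data
#'
#' Applies the design's strata restrictions (cases with a missing age or sex
#' are dropped only when that variable is stratified on), classifies every
#' case into the exposed or comparator arm, and counts query hits at case
#' level.
#'
#' @param reports A [daen_reports()] collection with canonicalised drugs,
#'   already filtered to the study window.
#' @param hits Hit table from [map_cases()], computed at `design$scope`.
#' @param design A [design_spec()].
#' @return A [contingency_table()].
#' @export
build_table_cases <- function(reports, hits, design) {
  if (nrow(hits) && !all(hits$scope == design$scope)) {
    stop("hits were computed at a different scope than the design",
         call. = FALSE)
  }
  strat <- apply_strata(reports, design)
  cls <- classify_exposure(strat, design)
  hit_ids <- hits$case_id[hits$query_name == design$query]
  has_hit <- cls$case_id %in% hit_ids
  a <- sum(cls$arm == "exposed" & has_hit)
  b <- sum(cls$arm == "exposed" & !has_hit)
  cc <- sum(cls$arm == "comparator" & has_hit)
  d <- sum(cls$arm == "comparator" & !has_hit)
  contingency_table(a, b, cc, d)
}

#' Build a 2x2 table from summary counts
#'
#' For the full-database design the comparator is all *other* drugs: exposed
#' cases are removed from both comparator margins, so
#' `a = n(exposed, query)`, `b = N(exposed) - a`,
#' `c = n(all, query) - a` and `d = N(total) - N(exposed) - c`. With a named
#' comparator drug the comparator margins come from that drug's rows instead.
#'
#' @param counts A [summary_counts()] object.
#' @param exposed Exposed drug-group name.
#' @param query Query name.
#' @param comparator `"full_dataset"` (default) or a drug-group name present
#'   in `counts`.
#' @return A [contingency_table()].
#' @export
#' @examples
#' sc <- summary_counts(
#'   total_reports = 1000,
#'   drug_totals = c(drugA = 100, drugB = 50),
#'   drug_event_counts = data.frame(drug = c("drugA", "drugB"),
#'                                  query_name = "toy", n = c(20, 5)),
#'   all_drug_event_counts = c(toy = 60)
#' )
#' build_table_summary(sc, "drugA", "toy")
build_table_summary <- function(counts, exposed, query,
                                comparator = "full_dataset") {
  stopifnot(inherits(counts, "summary_counts"))
  get_n <- function(drug, q) {
    i <- counts$drug_event_counts$drug == drug &
         counts$drug_event_counts$query_name == q
    if (!any(i)) stop("no event count for (", drug, ", ", q, ")",
                      call. = FALSE)
    counts$drug_event_counts$n[i][1]
  }
  get_total <- function(drug) {
    if (!drug %in% names(counts$drug_totals)) {
      stop("no report total for drug '", drug, "'", call. = FALSE)
    }
    counts$drug_totals[[drug]]
  }
  a <- get_n(exposed, query)
  b <- get_total(exposed) - a
  if (identical(comparator, "full_dataset")) {
    if (!query %in% names(counts$all_drug_event_counts)) {
      stop("no all-drug event count for query '", query, "'", call. = FALSE)
    }
    cc <- counts$all_drug_event_counts[[query]] - a
    d <- counts$total_reports - get_total(exposed) - cc
  } else {
    cc <- get_n(comparator, query)
    d <- get_total(comparator) - cc
  }
  for (nm in c("b", "cc", "d")) {
    v <- get(nm)
    if (v < 0) {
      stop("inconsistent summary margins: derived cell '",
           switch(nm, b = "b", cc = "c", d = "d"),
           "' is negative for (", exposed, ", ", query, ")", call. = FALSE)
    }
  }
  contingency_table(a, b, cc, d)
}

#' Per-year 2x2 tables for an annual series
#'
#' Builds one table per calendar year from that year's reports only. Years
#' where the exposed-with-event cell falls below `min_cases` are flagged
#' unsupported: too few cases to assess disproportionality.
#'
#' @inheritParams build_table_cases
#' @param years Integer vector of calendar years.
#' @param min_cases Minimum exposed event count for a supported year.
#' @return A tibble with columns `year`, `table` (list of
#'   [contingency_table()]s), `n_cases` (the `a` cell) and `supported`.
#' @export
annual_tables <- function(reports, hits, design, years, min_cases = 3) {
  rows <- lapply(as.integer(years), function(y) {
    d <- design
    d$years <- y
    tab <- build_table_cases(reports, hits, d)
    tibble::tibble(year = y, table = list(tab), n_cases = tab$a,
                   supported = tab$a >= min_cases)
  })
  dplyr::bind_rows(rows)
}
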