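#' Case report collections
#'
#' A `daen_reports` object holds a collection of spontaneous adverse-event
#' case reports in relational form: one row per case in `$cases`, one row per
#' case-drug pair in `$drugs` and one row per case-event pair in `$events`.
#' Cases are kept sorted by case id so that serialisation is bit-stable.
#'
#' @param cases Tibble with columns `case_id` (character, unique),
#'   `report_date` (`Date`), `age_years` (numeric, `NA` for missing) and `sex`
#'   (one of `"female"`, `"male"`, `"missing"`).
#' @param drugs Tibble with columns `case_id`, `ingredient` (non-empty,
#'   lower-cased), `trade_name` (character, `NA` allowed) and `role` (one of
#'   `"suspected"`, `"not_suspected"`, `"interacting"`). Row order within a
#'   case is preserved.
#' @param events Tibble with columns `case_id` and `term`. Every case must
#'   have at least one event and at least one suspected drug.
#'
#' @return An object of class `daen_reports`.
#' @export
daen_reports <- function(cases, drugs, events) {
  cases <- tibble::as_tibble(cases)
  drugs <- tibble::as_tibble(drugs)
  events <- tibble::as_tibble(events)
  ord <- order(cases$case_id)
  cases <- cases[ord, , drop = FALSE]
  drugs <- drugs[order(match(drugs$case_id, cases$case_id)), , drop = FALSE]
  events <- events[order(match(events$case_id, cases$case_id)), , drop = FALSE]
  out <- structure(list(cases = cases, drugs = drugs, events = events),
                   class = "daen_reports")
  validate_daen_reports(out)
}

validate_daen_reports <- function(x) {
  cases <- x$cases
  if (anyDuplicated(cases$case_id)) {
    dup <- unique(cases$case_id[duplicated(cases$case_id)])
    stop("duplicate case_id: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (!inherits(cases$report_date, "Date")) {
    stop("report_date must be a Date", call. = FALSE)
  }
  if (any(!is.na(cases$age_years) & cases$age_years < 0)) {
    stop("age_years must be non-negative or NA", call. = FALSE)
  }
  if (!all(cases$sex %in% c("female", "male", "missing"))) {
    stop("sex must be one of 'female', 'male', 'missing'", call. = FALSE)
  }
  if (!all(x$drugs$role %in% c("suspected", "not_suspected", "interacting"))) {
    stop("drug role must be 'suspected', 'not_suspected' or 'interacting'",
         call. = FALSE)
  }
  if (any(is.na(x$drugs$ingredient) | x$drugs$ingredient == "")) {
    stop("drug ingredient must be non-empty", call. = FALSE)
  }
  suspected <- unique(x$drugs$case_id[x$drugs$role == "suspected"])
  no_susp <- setdiff(cases$case_id, suspected)
  if (length(no_susp)) {
    stop("cases without a suspected drug: ",
         paste(utils::head(no_susp, 5), collapse = ", "), call. = FALSE)
  }
  no_event <- setdiff(cases$case_id, unique(x$events$case_id))
  if (length(no_event)) {
    stop("cases without events: ",
         paste(utils::head(no_event, 5), collapse = ", "), call. = FALSE)
  }
  orphans <- setdiff(unique(c(x$drugs$case_id, x$events$case_id)),
                     cases$case_id)
  if (length(orphans)) {
    stop("drug/event rows reference unknown case_id: ",
         paste(utils::head(orphans, 5), collapse = ", "), call. = FALSE)
  }
  x
}

#' @export
print.daen_reports <- function(x, ...) {
  cat("<daen_reports> ", nrow(x$cases), " cases, ",
      nrow(x$drugs), " drug entries, ", nrow(x$events), " event terms\n",
      sep = "")
  if (nrow(x$cases)) {
    cat("  report dates ", format(min(x$cases$report_date)), " to ",
        format(max(x$cases$report_date)), "\n", sep = "")
  }
  invisible(x)
}

#' @export
length.daen_reports <- function(x) nrow(x$cases)

#' Number of case reports
#'
#' @param reports A [daen_reports()] collection.
#' @return Integer count of cases.
#' @export
n_cases <- function(reports) nrow(reports$cases)

parse_age <- function(x, dialect) {
  x <- trimws(x)
  x[x %in% dialect$missing_markers] <- NA
  age <- suppressWarnings(as.numeric(x))
  age[!is.na(age) & age < 0] <- NA
  age
}

parse_sex <- function(x, dialect) {
  x <- tolower(trimws(x))
  out <- rep("missing", length(x))
  out[x %in% dialect$female_markers] <- "female"
  out[x %in% dialect$male_markers] <- "male"
  out
}

parse_role <- function(x, dialect) {
  x <- tolower(trimws(x))
  markers <- tolower(dialect$role_markers)
  out <- names(markers)[match(x, markers)]
  if (anyNA(out)) {
    bad <- unique(x[is.na(out)])
    stop("unrecognised drug role marker(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  out
}

#' Read a DAEN-style case report export
#'
#' Parses the one-row-per-case-drug CSV layout used by public adverse event
#' database exports into a [daen_reports()] collection. Rows sharing a case id
#' are merged into a single report; event terms are de-duplicated within a
#' case preserving first-seen order; unparseable age or sex values become
#' missing.
#'
#' @param source Path to a CSV file, or a character scalar containing CSV
#'   text (anything `readr::read_csv()` accepts).
#' @param dialect A [daen_dialect()] describing column names and markers.
#'
#' @return A [daen_reports()] collection with one report per distinct case id.
#' @export
#' @examples
#' csv <- paste(
#'   "case_number,report_date,age,sex,trade_name,active_ingredient,role,meddra_terms",
#'   "C1,2020-01-05,55,F,LYRICA,Pregabalin,suspected,Dizziness;Somnolence",
#'   "C1,2020-01-05,55,F,,Oxycodone,not suspected,Dizziness;Somnolence",
#'   "C2,2021-06-30,—,male,,gabapentin,suspected,Nausea",
#'   sep = "\n")
#' reports <- parse_daen_export(csv)
#' n_cases(reports)
parse_daen_export <- function(source, dialect = daen_dialect()) {
  raw <- readr::read_csv(if (is.character(source) && length(source) == 1 &&
                             !file.exists(source)) I(source) else source,
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, show_col_types = FALSE)
  needed <- c(dialect$col_case, dialect$col_date, dialect$col_age,
              dialect$col_sex, dialect$col_ingredient, dialect$col_role,
              dialect$col_events)
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!dialect$col_trade %in% names(raw)) raw[[dialect$col_trade]] <- NA_character_

  case_id <- trimws(raw[[dialect$col_case]])
  date <- as.Date(trimws(raw[[dialect$col_date]]), format = dialect$date_format)
  if (anyNA(date)) {
    stop("unparseable report_date in case(s): ",
         paste(utils::head(unique(case_id[is.na(date)]), 5), collapse = ", "),
         call. = FALSE)
  }

  # consolidate rows by case id; a case reported with two different dates is
  # a consolidation failure, not something to guess around
  first <- !duplicated(case_id)
  conflicting <- unique(case_id[!first][
    date[!first] != date[first][match(case_id[!first], case_id[first])]])
  if (length(conflicting)) {
    stop("conflicting report_date for case_id: ",
         paste(conflicting, collapse = ", "), call. = FALSE)
  }

  cases <- tibble::tibble(
    case_id = case_id[first],
    report_date = date[first],
    age_years = parse_age(raw[[dialect$col_age]][first], dialect),
    sex = parse_sex(raw[[dialect$col_sex]][first], dialect)
  )

  trade <- trimws(raw[[dialect$col_trade]])
  trade[is.na(trade) | trade %in% dialect$missing_markers] <- NA
  drugs <- tibble::tibble(
    case_id = case_id,
    ingredient = tolower(trimws(raw[[dialect$col_ingredient]])),
    trade_name = trade,
    role = parse_role(raw[[dialect$col_role]], dialect)
  )

  ev <- strsplit(raw[[dialect$col_events]][first], dialect$event_sep,
                 fixed = TRUE)
  events <- tibble::tibble(
    case_id = rep(case_id[first], lengths(ev)),
    term = trimws(unlist(ev))
  )
  events <- events[events$term != "", , drop = FALSE]
  events <- events[!duplicated(events[c("case_id", "term")]), , drop = FALSE]

  daen_reports(cases, drugs, events)
}

#' Write a case report collection in the DAEN-style CSV dialect
#'
#' Emits one row per case-drug pair with events as a delimited field, ordered
#' by case id, so that the file round-trips losslessly through
#' [parse_daen_export()] and is byte-identical across runs.
#'
#' @param reports A [daen_reports()] collection.
#' @param path Destination file path.
#' @param dialect A [daen_dialect()].
#' @return `path`, invisibly.
#' @export
write_daen_csv <- function(reports, path, dialect = daen_dialect()) {
  ev <- vapply(split(reports$events$term, reports$events$case_id),
               paste, character(1), collapse = dialect$event_sep)
  cases <- reports$cases
  drugs <- reports$drugs
  idx <- match(drugs$case_id, cases$case_id)
  out <- tibble::tibble(
    case = drugs$case_id,
    date = format(cases$report_date[idx], dialect$date_format),
    age = ifelse(is.na(cases$age_years[idx]), "",
                 format(cases$age_years[idx], trim = TRUE)),
    sex = ifelse(cases$sex[idx] == "missing", "", cases$sex[idx]),
    trade = ifelse(is.na(drugs$trade_name), "", drugs$trade_name),
    ingredient = drugs$ingredient,
    role = unname(dialect$role_markers[drugs$role]),
    events = unname(ev[drugs$case_id])
  )
  names(out) <- c(dialect$col_case, dialect$col_date, dialect$col_age,
                  dialect$col_sex, dialect$col_trade, dialect$col_ingredient,
                  dialect$col_role, dialect$col_events)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Write one-row-per-case normalised output
#'
#' Flattens a report collection to one row per case with drugs and events as
#' semicolon-joined lists, ordered by case id.
#'
#' @inheritParams write_daen_csv
#' @return `path`, invisibly.
#' @export
write_normalized_csv <- function(reports, path) {
  drug_str <- vapply(
    split(paste0(reports$drugs$ingredient, " (", reports$drugs$role, ")"),
          reports$drugs$case_id),
    paste, character(1), collapse = "; ")
  ev_str <- vapply(split(reports$events$term, reports$events$case_id),
                   paste, character(1), collapse = "; ")
  out <- dplyr::mutate(reports$cases,
                       drugs = unname(drug_str[.data$case_id]),
                       events = unname(ev_str[.data$case_id]))
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Restrict reports to a study window
#'
#' Keeps exactly the reports whose report date falls inside the closed
#' interval `[start, end]`; both endpoints are retained. Input order is
#' preserved and the input is not modified.
#'
#' @param reports A [daen_reports()] collection.
#' @param start,end Study window bounds (`Date` or parseable string).
#' @return A new [daen_reports()] collection.
#' @export
filter_window <- function(reports, start, end) {
  start <- as.Date(start); end <- as.Date(end)
  stopifnot(start <= end)
  keep <- reports$cases$case_id[reports$cases$report_date >= start &
                                reports$cases$report_date <= end]
  subset_cases(reports, keep)
}

subset_cases <- function(reports, case_ids) {
  structure(
    list(cases = reports$cases[reports$cases$case_id %in% case_ids, , drop = FALSE],
         drugs = reports$drugs[reports$drugs$case_id %in% case_ids, , drop = FALSE],
         events = reports$events[reports$events$case_id %in% case_ids, , drop = FALSE]),
    class = "daen_reports"
  )
}
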