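#' Summary count tables
#'
#' Full-database comparisons are computed from published summary counts
#' rather than case-level data: the total number of reports in the database,
#' per-drug report totals, per-drug event-of-interest counts and all-drug
#' event counts. Internal consistency (every event count within its total) is
#' enforced at construction.
#'
#' @param total_reports Total number of case reports in the database.
#' @param drug_totals Named numeric vector: drug-group name -> report count.
#' @param drug_event_counts Tibble with columns `drug`, `query_name`, `n`.
#' @param all_drug_event_counts Named numeric vector: query name -> report
#'   count across the whole database.
#' @return A `summary_counts` object.
#' @export
summary_counts <- function(total_reports, drug_totals, drug_event_counts,
                           all_drug_event_counts) {
  drug_event_counts <- tibble::as_tibble(drug_event_counts)
  stopifnot(all(c("drug", "query_name", "n") %in% names(drug_event_counts)),
            total_reports >= 0, all(drug_totals >= 0))
  if (any(drug_totals > total_reports)) {
    stop("per-drug total exceeds total_reports", call. = FALSE)
  }
  tot <- drug_totals[drug_event_counts$drug]
  bad <- is.na(tot) | drug_event_counts$n > tot
  if (any(bad)) {
    stop("event count exceeds (or references a missing) drug total for: ",
         paste(unique(drug_event_counts$drug[bad]), collapse = ", "),
         call. = FALSE)
  }
  if (any(all_drug_event_counts > total_reports)) {
    stop("all-drug event count exceeds total_reports", call. = FALSE)
  }
  structure(list(total_reports = total_reports,
                 drug_totals = drug_totals,
                 drug_event_counts = drug_event_counts,
                 all_drug_event_counts = all_drug_event_counts),
            class = "summary_counts")
}

#' @export
print.summary_counts <- function(x, ...) {
  cat("<summary_counts> total reports:", format(x$total_reports, big.mark = " "),
      "\n  drugs:", paste(names(x$drug_totals), collapse = ", "),
      "\n  queries:", paste(names(x$all_drug_event_counts), collapse = ", "), "\n")
  invisible(x)
}

#' Read summary counts from a two-file CSV pair
#'
#' `totals_path` must have columns `drug` and `total` with one row per drug
#' group plus a row whose drug equals `all_label` carrying the database-wide
#' report total. `events_path` must have columns `drug`, `query_name` and
#' `n`, with `all_label` rows giving the all-drug event counts.
#'
#' @param totals_path,events_path CSV file paths.
#' @param all_label Label identifying the whole-database rows.
#' @return A [summary_counts()] object.
#' @export
#' @examples
#' totals <- system.file("extdata", "daen_summary_totals.csv", package = "pvsignal")
#' events <- system.file("extdata", "daen_summary_events.csv", package = "pvsignal")
#' read_summary_counts(totals, events)
read_summary_counts <- function(totals_path, events_path,
                                all_label = "all drugs") {
  totals <- readr::read_csv(totals_path, show_col_types = FALSE,
                            progress = FALSE,
                            col_types = readr::cols(drug = "c", total = "d"))
  events <- readr::read_csv(events_path, show_col_types = FALSE,
                            progress = FALSE,
                            col_types = readr::cols(drug = "c",
                                                    query_name = "c", n = "d"))
  is_all <- totals$drug == all_label
  if (sum(is_all) != 1) {
    stop("totals file must contain exactly one '", all_label, "' row",
         call. = FALSE)
  }
  all_ev <- events[events$drug == all_label, , drop = FALSE]
  summary_counts(
    total_reports = totals$total[is_all],
    drug_totals = stats::setNames(totals$total[!is_all], totals$drug[!is_all]),
    drug_event_counts = events[events$drug != all_label, , drop = FALSE],
    all_drug_event_counts = stats::setNames(all_ev$n, all_ev$query_name)
  )
}
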