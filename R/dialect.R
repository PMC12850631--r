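#' Parsing options for DAEN-style case report exports
#'
#' The public DAEN export is a CSV with one row per case-drug pair: the case
#' number, report date, age, sex and the MedDRA terms are repeated on every
#' row belonging to the same case, while the drug columns differ. The exact
#' column headers, role markers and missing-value tokens vary between
#' extractions, so they are configurable here rather than hard-coded.
#'
#' @param col_case,col_date,col_age,col_sex Column names for the case number,
#'   report date, age in years and sex.
#' @param col_trade,col_ingredient,col_role Column names for the drug trade
#'   name, active ingredient and reported role.
#' @param col_events Column name holding the event terms for the case, joined
#'   by `event_sep`.
#' @param role_markers Named character vector mapping the canonical roles
#'   `suspected`, `not_suspected` and `interacting` to the marker text used in
#'   the file. The marker for the interacting role in particular is not
#'   standardized across exports and must be declarable.
#' @param missing_markers Tokens (besides an empty field) treated as missing
#'   for age, sex and trade name.
#' @param female_markers,male_markers Tokens (case-insensitive) recognised as
#'   female/male; anything else becomes `"missing"`.
#' @param event_sep Separator between event terms within the events field.
#' @param date_format `strptime()` format for `col_date`.
#'
#' @return A list of class `daen_dialect`.
#' @export
#' @examples
#' d <- daen_dialect(role_markers = c(
#'   suspected = "S", not_suspected = "N", interacting = "I"
#' ))
#' d$role_markers
daen_dialect <- function(col_case = "case_number",
                         col_date = "report_date",
                         col_age = "age",
                         col_sex = "sex",
                         col_trade = "trade_name",
                         col_ingredient = "active_ingredient",
                         col_role = "role",
                         col_events = "meddra_terms",
                         role_markers = c(suspected = "suspected",
                                          not_suspected = "not suspected",
                                          interacting = "interacting"),
                         missing_markers = c("", "-", "—", "NA", "N/A"),
                         female_markers = c("female", "f"),
                         male_markers = c("male", "m"),
                         event_sep = ";",
                         date_format = "%Y-%m-%d") {
  stopifnot(setequal(names(role_markers),
                     c("suspected", "not_suspected", "interacting")))
  structure(
    list(col_case = col_case, col_date = col_date, col_age = col_age,
         col_sex = col_sex, col_trade = col_trade,
         col_ingredient = col_ingredient, col_role = col_role,
         col_events = col_events, role_markers = role_markers,
         missing_markers = missing_markers,
         female_markers = tolower(female_markers),
         male_markers = tolower(male_markers),
         event_sep = event_sep, date_format = date_format),
    class = "daen_dialect"
  )
}
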