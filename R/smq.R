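#' Canonical form of an event term
#'
#' Terms are matched exactly after case-folding and whitespace collapsing; no
#' stemming or fuzzy matching is performed, since standardized queries are
#' controlled vocabularies.
#'
#' @param x Character vector of terms.
#' @return Canonicalised character vector.
#' @export
canonical_term <- function(x) {
  tolower(gsub("\\s+", " ", trimws(x)))
}

#' Standardized-query term sets
#'
#' An `smq_definition` names a query (e.g. "drug abuse and dependence") and
#' carries its narrow and broad term sets. The broad set always contains the
#' narrow set: broad terms are the narrow terms plus additional related terms
#' that identify potential cases with less certainty. A query whose broad
#' scope adds nothing (narrow-only queries exist, e.g. for suicide and
#' self-injury) simply has `broad_terms` equal to `narrow_terms`.
#'
#' @param name Query label.
#' @param narrow Character vector of narrow-scope terms (at least one).
#' @param broad_additional Additional broad-scope terms; the broad set is the
#'   union of `narrow` and `broad_additional`.
#' @return An `smq_definition` object.
#' @export
#' @examples
#' q <- smq_definition("toy-withdrawal", "withdrawal syndrome", "rebound effect")
#' q$broad_terms
smq_definition <- function(name, narrow, broad_additional = character()) {
  narrow <- unique(canonical_term(narrow))
  narrow <- narrow[narrow != ""]
  if (!length(narrow)) {
    stop("query '", name, "' has an empty narrow term list", call. = FALSE)
  }
  broad <- union(narrow, canonical_term(broad_additional))
  broad <- broad[broad != ""]
  structure(list(name = name, narrow_terms = narrow, broad_terms = broad),
            class = "smq_definition")
}

#' @export
print.smq_definition <- function(x, ...) {
  cat("<smq_definition> ", x$name, ": ", length(x$narrow_terms),
      " narrow / ", length(x$broad_terms), " broad terms\n", sep = "")
  invisible(x)
}

#' Terms of a query at a given scope
#'
#' @param smq An [smq_definition()].
#' @param scope `"narrow"` or `"broad"`.
#' @return Character vector of canonical terms.
#' @export
smq_terms <- function(smq, scope = c("broad", "narrow")) {
  scope <- match.arg(scope)
  if (scope == "narrow") smq$narrow_terms else smq$broad_terms
}

#' Read standardized-query definitions from CSV
#'
#' Expects columns `query_name`, `term` and `scope`, with scope values
#' `narrow` or `broad_additional`. A term listed under both scopes is
#' accepted silently (union semantics). A small fictional fixture dictionary
#' ships with the package (see the example); it is a placeholder for licensed
#' MedDRA content and is meant to be replaced by real term lists.
#'
#' @param path CSV file path.
#' @return A named list of [smq_definition()] objects (class `smq_set`).
#' @export
#' @examples
#' path <- system.file("extdata", "smq_fictional.csv", package = "pvsignal")
#' smqs <- read_smq(path)
#' names(smqs)
read_smq <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                        show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("query_name", "term", "scope") %in% names(df)))
  bad <- setdiff(unique(df$scope), c("narrow", "broad_additional"))
  if (length(bad)) {
    stop("unknown scope value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  defs <- lapply(split(df, df$query_name), function(d) {
    smq_definition(d$query_name[1],
                   d$term[d$scope == "narrow"],
                   d$term[d$scope == "broad_additional"])
  })
  structure(defs[order(names(defs))], class = "smq_set")
}

#' Recode case events into query hits
#'
#' For every case and query, records a hit when any of the case's event terms
#' falls in the query's term set at the requested scope. Counting is at case
#' level: a case contributes at most one hit per query no matter how many of
#' its terms match (disproportionality denominators count cases, not events).
#' The result is independent of the order of a case's event terms, and hits
#' under narrow scope are always a subset of hits under broad scope.
#'
#' @param reports A [daen_reports()] collection.
#' @param smqs A list of [smq_definition()]s (distinct names).
#' @param scope `"broad"` (default, the primary analysis scope) or
#'   `"narrow"`.
#' @return A tibble with columns `case_id`, `query_name`, `scope` and
#'   `matched_terms` (list column, sorted canonical terms).
#' @export
map_cases <- function(reports, smqs, scope = c("broad", "narrow")) {
  scope <- match.arg(scope)
  nm <- vapply(smqs, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("query names must be distinct", call. = FALSE)
  ev <- tibble::tibble(case_id = reports$events$case_id,
                       term = canonical_term(reports$events$term))
  out <- lapply(smqs, function(q) {
    terms <- smq_terms(q, scope)
    m <- ev[ev$term %in% terms, , drop = FALSE]
    if (!nrow(m)) {
      return(tibble::tibble(case_id = character(), query_name = character(),
                            scope = character(), matched_terms = list()))
    }
    agg <- lapply(split(m$term, m$case_id), function(t) sort(unique(t)))
    tibble::tibble(case_id = names(agg), query_name = q$name, scope = scope,
                   matched_terms = unname(agg))
  })
  hits <- dplyr::bind_rows(out)
  dplyr::arrange(hits, .data$query_name, .data$case_id)
}
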