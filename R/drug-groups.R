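#' Drug groups
#'
#' A drug group collects the canonical active-ingredient names and trade-name
#' labels that should be analysed as a single exposure, e.g. grouping the
#' trade label "LYRICA" under the ingredient pregabalin, or pooling several
#' ingredients under a comparator-set label. Groups used as exposed and
#' comparator arms of one design must not share ingredients, which is
#' enforced at construction.
#'
#' @param name Group label (used as the canonical ingredient after
#'   [canonicalize_drugs()]).
#' @param ingredients Character vector of ingredient names belonging to the
#'   group (at least one).
#' @param trade_names Character vector of trade labels mapped into the group.
#' @return A `drug_group` list; `drug_groups()` returns a `drug_groups` list
#'   of them.
#' @export
#' @examples
#' g <- drug_groups(
#'   drug_group("pregabalin", "pregabalin", "lyrica"),
#'   drug_group("oxycodone", "oxycodone", c("endone", "oxycontin"))
#' )
#' names(g)
drug_group <- function(name, ingredients, trade_names = character()) {
  ingredients <- canonical_label(ingredients)
  trade_names <- canonical_label(trade_names)
  if (!length(ingredients)) stop("group '", name, "' has no ingredients",
                                 call. = FALSE)
  structure(list(name = name, ingredients = unique(ingredients),
                 trade_names = unique(trade_names)),
            class = "drug_group")
}

canonical_label <- function(x) {
  x <- tolower(trimws(x))
  x[x != ""]
}

#' @rdname drug_group
#' @param ... `drug_group` objects.
#' @export
drug_groups <- function(...) {
  groups <- list(...)
  if (length(groups) == 1 && is.list(groups[[1]]) &&
      !inherits(groups[[1]], "drug_group")) {
    groups <- groups[[1]]
  }
  stopifnot(all(vapply(groups, inherits, logical(1), "drug_group")))
  names(groups) <- vapply(groups, `[[`, character(1), "name")
  if (anyDuplicated(names(groups))) stop("duplicate group names", call. = FALSE)
  ing <- unlist(lapply(groups, `[[`, "ingredients"))
  if (anyDuplicated(ing)) {
    stop("groups share ingredient(s): ",
         paste(unique(ing[duplicated(ing)]), collapse = ", "), call. = FALSE)
  }
  structure(groups, class = "drug_groups")
}

#' Read drug groups from a CSV file
#'
#' Expects columns `name`, `ingredients` and (optionally) `trade_names`, the
#' latter two semicolon-separated.
#'
#' @param path CSV file path.
#' @return A [drug_groups()] collection.
#' @export
read_drug_groups <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                        show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("name", "ingredients") %in% names(df)))
  split_field <- function(x) {
    if (is.null(x) || is.na(x)) character() else trimws(strsplit(x, ";")[[1]])
  }
  drug_groups(lapply(seq_len(nrow(df)), function(i) {
    drug_group(df$name[i], split_field(df$ingredients[i]),
               if ("trade_names" %in% names(df)) split_field(df$trade_names[i])
               else character())
  }))
}

#' Relabel drug entries by group membership
#'
#' Every drug entry whose ingredient or trade name matches a group (matching
#' is case-insensitive after trimming) has its ingredient replaced by the
#' group's canonical name; non-matching entries pass through unchanged.
#' Roles are never altered, so the multiset of suspected / not-suspected /
#' interacting roles per case is invariant under this operation.
#'
#' @param reports A [daen_reports()] collection.
#' @param groups A [drug_groups()] collection with disjoint ingredient sets.
#' @return A new [daen_reports()] collection with canonicalised ingredients.
#' @export
canonicalize_drugs <- function(reports, groups) {
  stopifnot(inherits(groups, "drug_groups"))
  # one lookup over ingredient names and trade labels alike: the export's
  # ingredient field sometimes carries a trade label
  label_map <- unlist(unname(lapply(groups, function(g) {
    keys <- c(g$ingredients, g$trade_names)
    stats::setNames(rep(g$name, length(keys)), keys)
  })))
  dup <- duplicated(names(label_map))
  if (any(dup)) {
    clash <- names(label_map)[dup][
      label_map[names(label_map)[dup]] != label_map[dup]]
    if (length(clash)) {
      stop("label(s) mapped by two groups: ",
           paste(unique(clash), collapse = ", "), call. = FALSE)
    }
  }
  drugs <- reports$drugs
  by_ing <- unname(label_map[canonical_label_keep(drugs$ingredient)])
  by_trade <- unname(label_map[canonical_label_keep(drugs$trade_name)])
  conflict <- !is.na(by_ing) & !is.na(by_trade) & by_ing != by_trade
  if (any(conflict)) {
    i <- which(conflict)[1]
    stop("drug entry matches two groups: '", by_ing[i], "' and '",
         by_trade[i], "' (case ", drugs$case_id[i], ")", call. = FALSE)
  }
  new_ing <- dplyr::coalesce(by_ing, by_trade, drugs$ingredient)
  drugs$ingredient <- new_ing
  structure(list(cases = reports$cases, drugs = drugs,
                 events = reports$events),
            class = "daen_reports")
}

canonical_label_keep <- function(x) {
  out <- tolower(trimws(x))
  out[out == ""] <- NA
  out
}
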