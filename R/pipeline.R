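#' Study configuration
#'
#' Bundles everything [run_study()] needs: the study window, the exposed and
#' comparator drug groups, which queries to analyse and at what scope, the
#' error level and minimum-case rule, and which sensitivity analyses to run.
#'
#' @param window_start,window_end Study window (closed interval of report
#'   dates).
#' @param exposed Exposed drug-group name.
#' @param comparators Character vector of comparator drug-group names.
#' @param queries Optional character vector of query names (default: all
#'   queries supplied to [run_study()]).
#' @param scope Primary analysis scope, `"broad"` or `"narrow"`.
#' @param alpha Two-sided error level.
#' @param min_cases Minimum exposed event count for signal assessment.
#' @param sensitivity Named logical toggles: `per_comparator`, `narrow_only`,
#'   `single_suspected`, `subgroups`, `annual`.
#' @return A `study_config` object.
#' @export
#' @examples
#' study_config(exposed = "pregabalin",
#'              comparators = c("gabapentin", "duloxetine", "amitriptyline"))
study_config <- function(window_start = "2005-04-01",
                         window_end = "2024-12-31",
                         exposed, comparators, queries = NULL,
                         scope = c("broad", "narrow"),
                         alpha = 0.05, min_cases = 3,
                         sensitivity = list(per_comparator = TRUE,
                                            narrow_only = TRUE,
                                            single_suspected = TRUE,
                                            subgroups = TRUE,
                                            annual = TRUE)) {
  scope <- match.arg(scope)
  window_start <- as.Date(window_start); window_end <- as.Date(window_end)
  stopifnot(window_start <= window_end, alpha > 0, alpha < 1, min_cases >= 1)
  defaults <- list(per_comparator = TRUE, narrow_only = TRUE,
                   single_suspected = TRUE, subgroups = TRUE, annual = TRUE)
  sensitivity <- utils::modifyList(defaults, as.list(sensitivity))
  structure(list(window_start = window_start, window_end = window_end,
                 exposed = exposed, comparators = comparators,
                 queries = queries, scope = scope, alpha = alpha,
                 min_cases = as.integer(min_cases),
                 sensitivity = sensitivity),
            class = "study_config")
}

#' Read a study configuration from YAML
#'
#' @param path YAML file with fields matching the [study_config()] arguments.
#' @return A `study_config` object.
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(study_config, y)
}

config_error <- function(msg) {
  rlang::abort(msg, class = "pvsignal_config_error")
}

signal_row <- function(tab, query, comparator, alpha, min_cases, scope,
                       stratum = NA_character_) {
  s <- detect_signal(tab, alpha = alpha, min_cases = min_cases)
  dplyr::bind_cols(
    tibble::tibble(query_name = query, comparator = comparator,
                   scope = scope, stratum = stratum),
    as_tibble(s),
    tibble::tibble(ror_display = format_estimate(s$ror))
  )
}

#' Run the full disproportionality study
#'
#' Orchestrates the two-stage analysis: full-database disproportionality
#' from summary counts (when supplied), then active-comparator
#' disproportionality from case-level data against the grouped comparator
#' set, with per-comparator, narrow-scope, single-suspected, subgroup and
#' annual sensitivity analyses per the configured toggles. Every estimate in
#' the bundle is traceable to its 2x2 table (cells are carried alongside).
#'
#' @param config A [study_config()].
#' @param reports A [daen_reports()] collection (not yet canonicalised or
#'   window-filtered; both are applied here).
#' @param groups A [drug_groups()] collection resolving the exposed and
#'   comparator names.
#' @param smqs Query definitions (named list of [smq_definition()]s).
#' @param summary_counts Optional [summary_counts()] for the full-database
#'   stage and the proportion table.
#' @return A `pv_study` bundle: a list with elements `proportions`,
#'   `full_dataset`, `grouped`, `per_comparator`, `sensitivity`, `annual`
#'   and `meta`.
#' @export
run_study <- function(config, reports, groups, smqs, summary_counts = NULL) {
  stopifnot(inherits(config, "study_config"))
  group_names <- vapply(groups, `[[`, character(1), "name")
  query_names <- vapply(smqs, `[[`, character(1), "name")
  queries <- config$queries %||% query_names
  missing_groups <- setdiff(c(config$exposed, config$comparators), group_names)
  if (length(missing_groups)) {
    config_error(paste0("unresolved drug group(s): ",
                        paste(missing_groups, collapse = ", ")))
  }
  missing_queries <- setdiff(queries, query_names)
  if (length(missing_queries)) {
    config_error(paste0("unresolved query name(s): ",
                        paste(missing_queries, collapse = ", ")))
  }

  reports <- canonicalize_drugs(
    filter_window(reports, config$window_start, config$window_end), groups)
  hits <- list(broad = map_cases(reports, smqs, "broad"),
               narrow = map_cases(reports, smqs, "narrow"))
  primary_hits <- hits[[config$scope]]
  alpha <- config$alpha; mc <- config$min_cases

  # Table of per-drug event counts and proportions, flagged where the
  # proportion differs from the exposed drug (chi-square, no correction)
  all_drugs <- c(config$exposed, config$comparators)
  totals <- stats::setNames(
    vapply(all_drugs, function(g) {
      d <- design_spec(g, setdiff(all_drugs, g), queries[1],
                       scope = config$scope)
      sum(classify_exposure(reports, d)$arm == "exposed")
    }, numeric(1)), all_drugs)
  prop_rows <- lapply(queries, function(q) {
    counts <- vapply(all_drugs, function(g) {
      d <- design_spec(g, setdiff(all_drugs, g), q, scope = config$scope)
      tab <- build_table_cases(reports, primary_hits, d)
      tab$a
    }, numeric(1))
    p_flag <- vapply(all_drugs, function(g) {
      if (g == config$exposed || totals[[g]] == 0 ||
          totals[[config$exposed]] == 0) {
        return(NA_real_)
      }
      proportion_test(counts[[config$exposed]], totals[[config$exposed]],
                      counts[[g]], totals[[g]])
    }, numeric(1))
    tibble::tibble(query_name = q, drug = all_drugs, n = unname(counts),
                   total = unname(totals),
                   proportion = unname(counts / totals),
                   p_vs_exposed = unname(p_flag),
                   differs = !is.na(p_flag) & p_flag < alpha)
  })
  proportions <- dplyr::bind_rows(prop_rows)

  # stage 1: full-database comparator from summary counts
  full_dataset <- NULL
  if (!is.null(summary_counts)) {
    full_dataset <- dplyr::bind_rows(lapply(queries, function(q) {
      tab <- build_table_summary(summary_counts, config$exposed, q)
      signal_row(tab, q, "full_dataset", alpha, mc, config$scope)
    }))
  }

  # stage 2: active comparator (grouped set)
  grouped <- dplyr::bind_rows(lapply(queries, function(q) {
    d <- design_spec(config$exposed, config$comparators, q,
                     scope = config$scope)
    signal_row(build_table_cases(reports, primary_hits, d), q,
               "grouped", alpha, mc, config$scope)
  }))

  per_comparator <- NULL
  if (isTRUE(config$sensitivity$per_comparator)) {
    per_comparator <- dplyr::bind_rows(lapply(queries, function(q) {
      dplyr::bind_rows(lapply(config$comparators, function(cmp) {
        d <- design_spec(config$exposed, cmp, q, scope = config$scope)
        signal_row(build_table_cases(reports, primary_hits, d), q, cmp,
                   alpha, mc, config$scope)
      }))
    }))
  }

  sensitivity <- list()
  if (isTRUE(config$sensitivity$narrow_only)) {
    sensitivity$narrow_only <- dplyr::bind_rows(lapply(queries, function(q) {
      d <- design_spec(config$exposed, config$comparators, q,
                       scope = "narrow")
      signal_row(build_table_cases(reports, hits$narrow, d), q, "grouped",
                 alpha, mc, "narrow")
    }))
  }
  if (isTRUE(config$sensitivity$single_suspected)) {
    sensitivity$single_suspected <- dplyr::bind_rows(
      lapply(queries, function(q) {
        d <- design_spec(config$exposed, config$comparators, q,
                         scope = config$scope,
                         restrict_single_suspected = TRUE)
        signal_row(build_table_cases(reports, primary_hits, d), q, "grouped",
                   alpha, mc, config$scope, stratum = "single_suspected")
      }))
  }
  if (isTRUE(config$sensitivity$subgroups)) {
    strata <- c(
      lapply(names(age_bins()), function(b) list(label = paste0("age:", b),
                                                 age_bin = b)),
      lapply(c("female", "male"), function(s) list(label = paste0("sex:", s),
                                                   sex = s)),
      lapply(names(period_bins()), function(p) {
        list(label = paste0("period:", p), years = period_bins()[[p]])
      })
    )
    sensitivity$subgroups <- dplyr::bind_rows(lapply(queries, function(q) {
      dplyr::bind_rows(lapply(strata, function(st) {
        d <- design_spec(config$exposed, config$comparators, q,
                         scope = config$scope, age_bin = st$age_bin,
                         sex = st$sex, years = st$years)
        signal_row(build_table_cases(reports, primary_hits, d), q, "grouped",
                   alpha, mc, config$scope, stratum = st$label)
      }))
    }))
  }

  annual <- NULL
  if (isTRUE(config$sensitivity$annual)) {
    years <- seq(report_year(config$window_start),
                 report_year(config$window_end))
    annual <- dplyr::bind_rows(lapply(queries, function(q) {
      d <- design_spec(config$exposed, config$comparators, q,
                       scope = config$scope)
      s <- annual_series(reports, primary_hits, d, years, alpha = alpha,
                         min_cases = mc)
      dplyr::mutate(s, query_name = q, .before = 1)
    }))
  }

  meta <- list(
    package_version = as.character(utils::packageVersion("pvsignal")),
    config_hash = rlang::hash(config),
    window = c(format(config$window_start), format(config$window_end)),
    scope = config$scope, alpha = alpha, min_cases = mc,
    caveat = paste("Raw report counts must not be compared across drugs:",
                   "no prescribing denominator is applied; RORs/PRRs reflect",
                   "proportional reporting only and signals are",
                   "hypothesis-generating, not causal.")
  )
  structure(list(proportions = proportions, full_dataset = full_dataset,
                 grouped = grouped, per_comparator = per_comparator,
                 sensitivity = sensitivity, annual = annual, meta = meta),
            class = "pv_study")
}

#' @export
print.pv_study <- function(x, ...) {
  cat("<pv_study> scope:", x$meta$scope, "| window:",
      paste(x$meta$window, collapse = " to "), "\n")
  if (!is.null(x$full_dataset)) {
    cat("  full-database results:\n")
    for (i in seq_len(nrow(x$full_dataset))) {
      cat("   ", x$full_dataset$query_name[i], "ROR",
          x$full_dataset$ror_display[i],
          if (x$full_dataset$is_signal[i]) "*" else "", "\n")
    }
  }
  cat("  grouped active-comparator results:\n")
  for (i in seq_len(nrow(x$grouped))) {
    cat("   ", x$grouped$query_name[i], "ROR", x$grouped$ror_display[i],
        if (x$grouped$is_signal[i]) "*" else "", "\n")
  }
  invisible(x)
}

#' Annual disproportionality series
#'
#' One signal assessment per calendar year, each computed from that year's
#' reports only. Years with fewer than `min_cases` exposed event cases are
#' flagged unsupported and carry no estimate, matching the minimum-case rule.
#' The series serialises with the full-precision point estimate and bounds so
#' it can be plotted against a reference line at 1.
#'
#' @inheritParams build_table_cases
#' @param years Integer vector of calendar years.
#' @param alpha Two-sided error level.
#' @param min_cases Minimum exposed event count.
#' @return A tibble with columns `year`, `n_cases`, `supported`, `ror`,
#'   `ror_lower`, `ror_upper`, `is_signal`.
#' @export
annual_series <- function(reports, hits, design, years, alpha = 0.05,
                          min_cases = 3) {
  tabs <- annual_tables(reports, hits, design, years, min_cases = min_cases)
  rows <- lapply(seq_len(nrow(tabs)), function(i) {
    if (!tabs$supported[i]) {
      return(tibble::tibble(year = tabs$year[i], n_cases = tabs$n_cases[i],
                            supported = FALSE, ror = NA_real_,
                            ror_lower = NA_real_, ror_upper = NA_real_,
                            is_signal = FALSE))
    }
    s <- detect_signal(tabs$table[[i]], alpha = alpha, min_cases = min_cases)
    tibble::tibble(year = tabs$year[i], n_cases = tabs$n_cases[i],
                   supported = TRUE, ror = s$ror$point,
                   ror_lower = s$ror$lower, ror_upper = s$ror$upper,
                   is_signal = s$is_signal)
  })
  dplyr::bind_rows(rows)
}

#' Descriptive summary of one drug group's case reports
#'
#' Computes the descriptive statistics reported for each focal drug: case
#' count, age mean/SD and missingness, sex distribution, the top-k most
#' frequent event terms (ties broken lexicographically), events per case,
#' medicines per case (median and interquartile range), co-medication
#' frequencies and the suspected-role breakdown (sole suspected / one of
#' multiple suspected / part of a suspected interaction).
#'
#' @param reports A [daen_reports()] collection with canonicalised drugs.
#' @param group Drug-group name.
#' @param k Number of top event terms and co-medications to report.
#' @return A list of summary components; an empty group yields zero counts.
#' @export
descriptive_summary <- function(reports, group, k = 10) {
  susp <- reports$drugs[reports$drugs$role == "suspected", , drop = FALSE]
  ids <- unique(susp$case_id[susp$ingredient == group])
  sub <- subset_cases(reports, ids)
  n <- nrow(sub$cases)
  if (n == 0) {
    return(list(group = group, n_cases = 0,
                age = list(mean = NA_real_, sd = NA_real_, n_missing = 0),
                sex = c(female = 0, male = 0, missing = 0),
                top_terms = tibble::tibble(term = character(), n = integer()),
                events_per_case = list(mean = NA_real_, sd = NA_real_),
                medicines_per_case = list(median = NA_real_,
                                          iqr = c(NA_real_, NA_real_)),
                comedications = tibble::tibble(ingredient = character(),
                                               n = integer(),
                                               proportion = numeric()),
                roles = c(sole_suspected = 0, multiple_suspected = 0,
                          interaction = 0)))
  }
  age <- sub$cases$age_years
  term_tab <- table(sub$events$term)
  top <- tibble::tibble(term = names(term_tab), n = as.integer(term_tab))
  top <- dplyr::arrange(top, dplyr::desc(.data$n), .data$term)
  ev_per_case <- as.integer(table(factor(sub$events$case_id, levels = ids)))

  med_counts <- as.integer(table(factor(sub$drugs$case_id, levels = ids)))
  other <- sub$drugs[sub$drugs$ingredient != group, , drop = FALSE]
  other <- other[!duplicated(other[c("case_id", "ingredient")]), , drop = FALSE]
  co_tab <- table(other$ingredient)
  comeds <- tibble::tibble(ingredient = names(co_tab),
                           n = as.integer(co_tab))
  comeds <- dplyr::arrange(comeds, dplyr::desc(.data$n), .data$ingredient)
  comeds$proportion <- comeds$n / n

  interacting <- unique(sub$drugs$case_id[sub$drugs$role == "interacting"])
  susp_sub <- sub$drugs[sub$drugs$role == "suspected", , drop = FALSE]
  susp_sub <- susp_sub[!duplicated(susp_sub[c("case_id", "ingredient")]), ,
                       drop = FALSE]
  n_susp <- table(factor(susp_sub$case_id, levels = ids))
  is_inter <- ids %in% interacting
  sole <- sum(!is_inter & n_susp == 1)
  multi <- sum(!is_inter & n_susp > 1)

  list(
    group = group, n_cases = n,
    age = list(mean = mean(age, na.rm = TRUE),
               sd = stats::sd(age, na.rm = TRUE),
               n_missing = sum(is.na(age))),
    sex = c(female = sum(sub$cases$sex == "female"),
            male = sum(sub$cases$sex == "male"),
            missing = sum(sub$cases$sex == "missing")),
    top_terms = utils::head(top, k),
    events_per_case = list(mean = mean(ev_per_case), sd = stats::sd(ev_per_case)),
    medicines_per_case = list(median = stats::median(med_counts),
                              iqr = unname(stats::quantile(med_counts,
                                                           c(0.25, 0.75)))),
    comedications = utils::head(comeds, k),
    roles = c(sole_suspected = sole, multiple_suspected = multi,
              interaction = length(interacting))
  )
}

#' Write a study bundle to a directory of CSV/JSON tables
#'
#' Serialises every result table as CSV (full-precision values alongside the
#' display strings) plus a `run_log.json` carrying the package version,
#' configuration hash and the denominator caveat. Output is deterministic:
#' identical inputs produce byte-identical files.
#'
#' @param bundle A `pv_study` from [run_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "pv_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) {
    if (!is.null(df)) {
      readr::write_csv(df, file.path(dir, paste0(name, ".csv")),
                       progress = FALSE)
    }
  }
  wr(bundle$proportions, "proportions")
  wr(bundle$full_dataset, "full_dataset")
  wr(bundle$grouped, "grouped_comparator")
  wr(bundle$per_comparator, "per_comparator")
  wr(bundle$sensitivity$narrow_only, "sensitivity_narrow_only")
  wr(bundle$sensitivity$single_suspected, "sensitivity_single_suspected")
  wr(bundle$sensitivity$subgroups, "sensitivity_subgroups")
  wr(bundle$annual, "annual_series")
  jsonlite::write_json(bundle$meta, file.path(dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
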