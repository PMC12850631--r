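#' Convert case-level hit probabilities to per-term propensities
#'
#' The simulator samples event terms independently, so a query with `k`
#' terms at the chosen scope and a target case-level hit probability `p`
#' needs each term drawn with probability `1 - (1 - p)^(1/k)`; the chance of
#' at least one term then equals `p`.
#'
#' @param hit_probs Tibble with columns `group`, `query_name`, `p` giving the
#'   desired case-level hit probability per drug group and query (use group
#'   `"__background__"` for cases not suspected for any focal drug).
#' @param smqs A list of [smq_definition()]s.
#' @param scope Scope at which the probabilities are interpreted.
#' @return A tibble with columns `group`, `term`, `prob`.
#' @export
propensity_from_hits <- function(hit_probs, smqs, scope = "broad") {
  hit_probs <- tibble::as_tibble(hit_probs)
  stopifnot(all(c("group", "query_name", "p") %in% names(hit_probs)))
  nm <- vapply(smqs, `[[`, character(1), "name")
  rows <- lapply(seq_len(nrow(hit_probs)), function(i) {
    q <- smqs[[match(hit_probs$query_name[i], nm)]]
    if (is.null(q)) stop("unknown query: ", hit_probs$query_name[i],
                         call. = FALSE)
    terms <- smq_terms(q, scope)
    tibble::tibble(group = hit_probs$group[i], term = terms,
                   prob = 1 - (1 - hit_probs$p[i])^(1 / length(terms)))
  })
  dplyr::bind_rows(rows)
}

#' Simulation configuration
#'
#' Defines the generative model for synthetic spontaneous reports: the
#' probability that a case's primary suspected drug is each focal group (the
#' remainder are background cases suspected for a generic non-focal
#' medicine), pairwise co-suspect probabilities, per-term event propensities
#' conditional on the primary group, demographic models and the report-date
#' range. Defaults emulate the reporting structure of the Australian
#' database study population: focal-drug shares, per-query case-level
#' reporting proportions, age distribution (mean 55.5, SD 18.5, 36.5%
#' missing), sex mix and the 2005-2024 window.
#'
#' @param n_cases Number of reports to generate.
#' @param drug_mix Named probabilities that a case's primary suspected drug
#'   is each focal group; must sum to at most 1, remainder is background.
#' @param co_suspect Tibble with columns `primary`, `co`, `prob`: probability
#'   that a case with the given primary suspected drug also lists `co` as
#'   suspected.
#' @param event_propensity Tibble with columns `group`, `term`, `prob`: the
#'   probability that a case whose primary group is `group` reports `term`.
#' @param background_propensity Named per-term probabilities for background
#'   cases (and focal groups with no configured row for a term).
#' @param comed_probs Named probabilities of not-suspected co-medications.
#' @param age_mean,age_sd,age_missing Age model (normal, truncated at 0,
#'   rounded to whole years) and missingness fraction.
#' @param sex_probs Named probabilities for `female`, `male`, `missing`.
#' @param date_start,date_end Report-date range (uniform).
#' @param seed Master seed; per-component streams are derived from it so the
#'   draws for one component do not shift when another is added.
#' @return A `sim_config` object.
#' @export
sim_config <- function(n_cases = 20000,
                       drug_mix = c(pregabalin = 0.0044,
                                    gabapentin = 0.0009,
                                    duloxetine = 0.0022,
                                    amitriptyline = 0.0012),
                       co_suspect = default_co_suspect(),
                       event_propensity = NULL,
                       background_propensity = NULL,
                       comed_probs = c(paracetamol = 0.13, oxycodone = 0.11,
                                       diazepam = 0.08),
                       age_mean = 55.5, age_sd = 18.5, age_missing = 0.365,
                       sex_probs = c(female = 0.562, male = 0.397,
                                     missing = 0.041),
                       date_start = "2005-04-01", date_end = "2024-12-31",
                       seed = 1L) {
  stopifnot(n_cases >= 1, all(drug_mix >= 0), sum(drug_mix) <= 1,
            age_missing >= 0, age_missing < 1,
            all(sex_probs >= 0), abs(sum(sex_probs) - 1) < 1e-8)
  if (is.null(event_propensity)) {
    defaults <- default_propensities()
    event_propensity <- defaults$event[
      defaults$event$group %in% names(drug_mix), , drop = FALSE]
    if (is.null(background_propensity)) {
      background_propensity <- defaults$background
    }
  }
  event_propensity <- tibble::as_tibble(event_propensity)
  stopifnot(all(c("group", "term", "prob") %in% names(event_propensity)),
            all(event_propensity$prob >= 0 & event_propensity$prob <= 1))
  if (is.null(background_propensity)) background_propensity <- numeric()
  unknown <- setdiff(unique(event_propensity$group), names(drug_mix))
  if (length(unknown)) {
    stop("event_propensity references unknown drug group(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  event_propensity$term <- canonical_term(event_propensity$term)
  names(background_propensity) <- canonical_term(names(background_propensity))
  structure(list(n_cases = as.integer(n_cases), drug_mix = drug_mix,
                 co_suspect = tibble::as_tibble(co_suspect),
                 event_propensity = event_propensity,
                 background_propensity = background_propensity,
                 comed_probs = comed_probs, age_mean = age_mean,
                 age_sd = age_sd, age_missing = age_missing,
                 sex_probs = sex_probs, date_start = as.Date(date_start),
                 date_end = as.Date(date_end), seed = as.integer(seed)),
            class = "sim_config")
}

default_co_suspect <- function() {
  tibble::tibble(primary = "pregabalin",
                 co = c("amitriptyline", "oxycodone", "diazepam"),
                 prob = c(0.04, 0.05, 0.05))
}

# Case-level reporting proportions per focal drug and query, matching the
# published per-drug proportions for the four events of interest, spread
# over the fictional fixture term lists at broad scope.
default_propensities <- function() {
  smqs <- read_smq(system.file("extdata", "smq_fictional.csv",
                               package = "pvsignal"))
  hp <- tibble::tribble(
    ~group, ~query_name, ~p,
    "pregabalin",    "drug abuse and dependence",          418 / 2016,
    "gabapentin",    "drug abuse and dependence",          35 / 426,
    "duloxetine",    "drug abuse and dependence",          126 / 1008,
    "amitriptyline", "drug abuse and dependence",          167 / 573,
    "pregabalin",    "drug withdrawal",                    44 / 2016,
    "gabapentin",    "drug withdrawal",                    7 / 426,
    "duloxetine",    "drug withdrawal",                    76 / 1008,
    "amitriptyline", "drug withdrawal",                    7 / 573,
    "pregabalin",    "suicide and self-injury",            208 / 2016,
    "gabapentin",    "suicide and self-injury",            26 / 426,
    "duloxetine",    "suicide and self-injury",            124 / 1008,
    "amitriptyline", "suicide and self-injury",            45 / 573,
    "pregabalin",    "psychosis and psychotic disorders",  187 / 2016,
    "gabapentin",    "psychosis and psychotic disorders",  38 / 426,
    "duloxetine",    "psychosis and psychotic disorders",  61 / 1008,
    "amitriptyline", "psychosis and psychotic disorders",  53 / 573
  )
  bg <- tibble::tibble(group = "__background__",
                       query_name = unique(hp$query_name),
                       p = c(9116, 1553, 4423, 8121) / 460528)
  ev <- propensity_from_hits(hp, smqs, scope = "broad")
  bg_prop <- propensity_from_hits(bg, smqs, scope = "broad")
  list(event = ev,
       background = stats::setNames(bg_prop$prob, bg_prop$term))
}

# Independent per-component RNG streams derived from the master seed: the
# draws of one component are unchanged when another component is added.
stream_seed <- function(seed, component) {
  offsets <- c(drugs = 11L, co = 23L, events = 37L, age = 53L, sex = 67L,
               dates = 79L, comed = 97L)
  (seed * 1009L + offsets[[component]]) %% 2147483629L
}

with_stream <- function(seed, component, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(stream_seed(seed, component))
  expr
}

#' Generate a synthetic report collection with known ground truth
#'
#' Draws `n_cases` spontaneous reports: a primary suspected drug per case
#' from the configured mix (or a background medicine), pairwise co-suspect
#' drugs, event terms sampled independently per term with the propensity of
#' the case's primary group, not-suspected co-medications, and demographics
#' and report dates from their models. Cases that draw no event term receive
#' a neutral filler term (`"product quality issue"`, outside every query) so
#' that every report carries at least one event. Output is deterministic
#' given the seed.
#'
#' @param config A [sim_config()].
#' @param smqs Query definitions used to record planted ground truth
#'   (defaults to the fictional fixture set).
#' @return A list with elements `reports` (a [daen_reports()] collection) and
#'   `truth` (planted odds ratios per group/query/scope and the per-case
#'   latent hit indicators).
#' @export
#' @examples
#' sim <- simulate_reports(sim_config(n_cases = 200, seed = 42))
#' sim$reports
#' head(sim$truth$planted)
simulate_reports <- function(config,
                             smqs = read_smq(system.file("extdata",
                                                         "smq_fictional.csv",
                                                         package = "pvsignal"))) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_cases
  groups <- names(config$drug_mix)
  probs <- c(config$drug_mix, "__background__" = 1 - sum(config$drug_mix))

  primary <- with_stream(config$seed, "drugs",
                         sample(names(probs), n, replace = TRUE,
                                prob = unname(probs)))
  case_id <- sprintf("S%06d", seq_len(n))

  # co-suspect drugs by pairwise probability given the primary drug
  co_rows <- with_stream(config$seed, "co", {
    out <- list()
    cs <- config$co_suspect
    for (i in seq_len(nrow(cs))) {
      idx <- which(primary == cs$primary[i])
      if (!length(idx)) next
      take <- idx[stats::runif(length(idx)) < cs$prob[i]]
      if (length(take)) {
        out[[length(out) + 1]] <- tibble::tibble(case_id = case_id[take],
                                                 ingredient = cs$co[i])
      }
    }
    dplyr::bind_rows(out)
  })

  # event terms: independent Bernoulli per term, propensity keyed on the
  # primary suspected group (background propensity otherwise)
  all_terms <- union(unique(config$event_propensity$term),
                     names(config$background_propensity))
  ev_rows <- with_stream(config$seed, "events", {
    out <- vector("list", length(all_terms))
    ep <- config$event_propensity
    for (j in seq_along(all_terms)) {
      tm <- all_terms[j]
      p <- rep(config$background_propensity[tm], n)
      p[is.na(p)] <- 0
      rows <- ep[ep$term == tm, , drop = FALSE]
      if (nrow(rows)) {
        m <- match(primary, rows$group)
        hit_p <- rows$prob[m]
        p <- ifelse(is.na(hit_p), p, hit_p)
      }
      drawn <- stats::runif(n) < p
      if (any(drawn)) {
        out[[j]] <- tibble::tibble(case_id = case_id[drawn], term = tm)
      }
    }
    dplyr::bind_rows(out)
  })

  if (!nrow(ev_rows)) {
    ev_rows <- tibble::tibble(case_id = character(), term = character())
  }

  # every report must carry at least one event term
  empty <- setdiff(case_id, unique(ev_rows$case_id))
  if (length(empty)) {
    ev_rows <- dplyr::bind_rows(
      ev_rows, tibble::tibble(case_id = empty, term = "product quality issue"))
  }

  age <- with_stream(config$seed, "age", {
    a <- round(pmax(0, stats::rnorm(n, config$age_mean, config$age_sd)))
    a[stats::runif(n) < config$age_missing] <- NA
    a
  })
  sex <- with_stream(config$seed, "sex",
                     sample(names(config$sex_probs), n, replace = TRUE,
                            prob = unname(config$sex_probs)))
  dates <- with_stream(config$seed, "dates", {
    span <- as.integer(config$date_end - config$date_start)
    config$date_start + sample.int(span + 1L, n, replace = TRUE) - 1L
  })
  comed_rows <- with_stream(config$seed, "comed", {
    out <- list()
    for (cm in names(config$comed_probs)) {
      take <- which(stats::runif(n) < config$comed_probs[[cm]] &
                    primary != "__background__")
      if (length(take)) {
        out[[length(out) + 1]] <- tibble::tibble(case_id = case_id[take],
                                                 ingredient = cm)
      }
    }
    dplyr::bind_rows(out)
  })

  drugs <- tibble::tibble(
    case_id = case_id,
    ingredient = ifelse(primary == "__background__", "other medicine",
                        primary),
    trade_name = NA_character_,
    role = "suspected")
  if (nrow(co_rows)) {
    drugs <- dplyr::bind_rows(
      drugs, dplyr::mutate(co_rows, trade_name = NA_character_,
                           role = "suspected"))
  }
  if (nrow(comed_rows)) {
    drugs <- dplyr::bind_rows(
      drugs, dplyr::mutate(comed_rows, trade_name = NA_character_,
                           role = "not_suspected"))
  }

  cases <- tibble::tibble(case_id = case_id, report_date = dates,
                          age_years = as.numeric(age), sex = sex)
  reports <- daen_reports(cases, drugs, events = ev_rows)

  truth <- list(
    planted = planted_ror_table(config, smqs),
    latent = latent_hits(case_id, primary, ev_rows, smqs)
  )
  list(reports = reports, truth = truth)
}

latent_hits <- function(case_id, primary, ev_rows, smqs) {
  rows <- lapply(smqs, function(q) {
    res <- lapply(c("narrow", "broad"), function(sc) {
      ids <- unique(ev_rows$case_id[ev_rows$term %in% smq_terms(q, sc)])
      tibble::tibble(case_id = ids, query_name = q$name, scope = sc)
    })
    dplyr::bind_rows(res)
  })
  hits <- dplyr::bind_rows(rows)
  hits$primary <- primary[match(hits$case_id, case_id)]
  dplyr::arrange(hits, .data$scope, .data$query_name, .data$case_id)
}

#' Planted reporting odds ratio implied by a simulation configuration
#'
#' For a drug group and query, the case-level hit probability is
#' `1 - prod(1 - propensity)` over the query's terms at the chosen scope;
#' the planted odds ratio contrasts the exposed group's hit odds with the
#' comparator's: `[p1 / (1 - p1)] / [p0 / (1 - p0)]`.
#'
#' @param config A [sim_config()].
#' @param group Drug-group name (or `"__background__"`).
#' @param query Query name.
#' @param smqs Query definitions.
#' @param scope `"broad"` or `"narrow"`.
#' @param comparator Comparator group whose hit probability forms the
#'   denominator odds (default: background cases).
#' @return The planted odds ratio (positive ratio).
#' @export
planted_ror <- function(config, group, query,
                        smqs = read_smq(system.file("extdata",
                                                    "smq_fictional.csv",
                                                    package = "pvsignal")),
                        scope = "broad", comparator = "__background__") {
  p1 <- hit_probability(config, group, query, smqs, scope)
  p0 <- hit_probability(config, comparator, query, smqs, scope)
  (p1 / (1 - p1)) / (p0 / (1 - p0))
}

hit_probability <- function(config, group, query, smqs, scope) {
  nm <- vapply(smqs, `[[`, character(1), "name")
  q <- smqs[[match(query, nm)]]
  if (is.null(q)) stop("unknown query: ", query, call. = FALSE)
  terms <- smq_terms(q, scope)
  p <- vapply(terms, function(tm) {
    if (group == "__background__") {
      v <- config$background_propensity[tm]
      if (is.na(v)) 0 else unname(v)
    } else {
      rows <- config$event_propensity
      i <- rows$group == group & rows$term == tm
      if (any(i)) rows$prob[i][1] else {
        v <- config$background_propensity[tm]
        if (is.na(v)) 0 else unname(v)
      }
    }
  }, numeric(1))
  1 - prod(1 - p)
}

planted_ror_table <- function(config, smqs) {
  nm <- vapply(smqs, `[[`, character(1), "name")
  grid <- expand.grid(group = names(config$drug_mix), query = nm,
                      scope = c("narrow", "broad"),
                      stringsAsFactors = FALSE)
  grid$ror <- mapply(function(g, q, sc) {
    planted_ror(config, g, q, smqs, scope = sc)
  }, grid$group, grid$query, grid$scope)
  tibble::as_tibble(grid)
}
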