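#' Point estimate with a two-sided confidence interval
#'
#' Used for reporting odds ratios and proportional reporting ratios. A
#' not-estimable result (from a zero cell) carries `estimable = FALSE` and a
#' reason code instead of numbers.
#'
#' @param point,lower,upper Positive ratios with `lower <= point <= upper`.
#' @param alpha Two-sided error level.
#' @param estimable Logical.
#' @param reason Reason code when not estimable.
#' @return A `pv_estimate` object.
#' @keywords internal
pv_estimate <- function(point, lower, upper, alpha = 0.05, estimable = TRUE,
                        reason = NA_character_) {
  if (estimable) {
    stopifnot(point > 0, lower <= point, point <= upper)
  }
  structure(list(point = point, lower = lower, upper = upper, alpha = alpha,
                 estimable = estimable, reason = reason),
            class = "pv_estimate")
}

not_estimable <- function(reason, alpha = 0.05) {
  pv_estimate(NA_real_, NA_real_, NA_real_, alpha, estimable = FALSE,
              reason = reason)
}

#' Format a ratio estimate the way results tables print it
#'
#' Ratios display at 2 decimals, except a lower bound that exceeds 1 but
#' would round to 1.00, which displays at 3 decimals so that the
#' signal/no-signal status stays legible (e.g. "1.002").
#'
#' @param x A `pv_estimate`.
#' @return A character scalar like `"13.53 (12.12, 15.10)"`.
#' @export
format_estimate <- function(x) {
  if (!x$estimable) return(paste0("not estimable (", x$reason, ")"))
  fmt <- function(v, is_lower = FALSE) {
    s <- sprintf("%.2f", v)
    if (is_lower && v > 1 && s == "1.00") s <- sprintf("%.3f", v)
    s
  }
  paste0(fmt(x$point), " (", fmt(x$lower, is_lower = TRUE), ", ",
         fmt(x$upper), ")")
}

#' @export
print.pv_estimate <- function(x, ...) {
  cat("<pv_estimate> ", format_estimate(x), "\n", sep = "")
  invisible(x)
}

z_quantile <- function(alpha) stats::qnorm(1 - alpha / 2)

maybe_correct <- function(tab, correction) {
  cells <- unlist(tab[c("a", "b", "c", "d")])
  if (correction && any(cells == 0)) cells + 0.5 else cells
}

#' Reporting odds ratio with a Woolf confidence interval
#'
#' The reporting odds ratio is the cross-product ratio
#' `(a * d) / (b * c)` of a 2x2 exposure-by-event table of case counts. The
#' two-sided confidence interval is computed on the log scale (Woolf's
#' method): `exp(log(ROR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`. Values are
#' returned at full precision; display rounding is a formatting concern (see
#' [format_estimate()]).
#'
#' With any zero cell the estimate is flagged not estimable rather than
#' silently corrected; set `correction = TRUE` to opt in to the
#' Haldane-Anscombe 0.5 adjustment for exploratory use.
#'
#' @param table A [contingency_table()].
#' @param alpha Two-sided error level (default 0.05 for a 95% interval).
#' @param correction Apply a 0.5 continuity correction when a cell is zero.
#' @return A `pv_estimate`.
#' @export
#' @examples
#' ror(contingency_table(418, 1598, 8698, 449814))
ror <- function(table, alpha = 0.05, correction = FALSE) {
  stopifnot(inherits(table, "pv_table"))
  cells <- maybe_correct(table, correction)
  if (any(cells == 0)) return(not_estimable("zero_cell", alpha))
  a <- cells[["a"]]; b <- cells[["b"]]; c <- cells[["c"]]; d <- cells[["d"]]
  point <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- z_quantile(alpha)
  pv_estimate(point, exp(log(point) - z * se), exp(log(point) + z * se),
              alpha)
}

#' Proportional reporting ratio with a log-scale confidence interval
#'
#' The proportional reporting ratio compares the proportion of exposed cases
#' reporting the event with the comparator proportion:
#' `(a / (a + b)) / (c / (c + d))`, with interval
#' `exp(log(PRR) +/- z * sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d)))`. It
#' approximates the reporting odds ratio when the event is rare in both arms
#' and serves as a robustness check on it.
#'
#' @inheritParams ror
#' @return A `pv_estimate`.
#' @export
prr <- function(table, alpha = 0.05, correction = FALSE) {
  stopifnot(inherits(table, "pv_table"))
  cells <- maybe_correct(table, correction)
  if (cells[["a"]] == 0 || cells[["c"]] == 0) {
    return(not_estimable("zero_cell", alpha))
  }
  a <- cells[["a"]]; b <- cells[["b"]]; c <- cells[["c"]]; d <- cells[["d"]]
  point <- (a / (a + b)) / (c / (c + d))
  se <- sqrt(1 / a - 1 / (a + b) + 1 / c - 1 / (c + d))
  z <- z_quantile(alpha)
  pv_estimate(point, exp(log(point) - z * se), exp(log(point) + z * se),
              alpha)
}

#' Apply the signal-of-disproportionate-reporting rule
#'
#' A drug-event pair is flagged as a signal of disproportionate reporting
#' (SDR) when at least `min_cases` exposed cases report the event and the
#' lower bound of the reporting odds ratio's confidence interval exceeds 1.
#' An upper bound below 1 is annotated as decreased reporting: a lower
#' likelihood of the event being reported for the exposed drug than for the
#' comparator. Signals are hypothesis-generating, not evidence of causation.
#'
#' @inheritParams ror
#' @param min_cases Minimum exposed event count required to assess
#'   disproportionality (default 3).
#' @return A `pv_signal` object with elements `table`, `ror`, `prr`,
#'   `n_cases`, `is_signal` and `reasons`.
#' @export
#' @examples
#' detect_signal(contingency_table(418, 1598, 8698, 449814))
detect_signal <- function(table, alpha = 0.05, min_cases = 3,
                          correction = FALSE) {
  stopifnot(inherits(table, "pv_table"), min_cases >= 1)
  est_ror <- ror(table, alpha, correction)
  est_prr <- prr(table, alpha, correction)
  n <- table$a
  reasons <- character()
  if (n < min_cases) reasons <- c(reasons, "insufficient_cases")
  is_signal <- n >= min_cases && est_ror$estimable && est_ror$lower > 1
  if (is_signal) {
    reasons <- c(reasons, "signal")
  } else if (est_ror$estimable && est_ror$lower <= 1) {
    reasons <- c(reasons, "lower_ci_le_1")
    if (est_ror$point < 1 && est_ror$upper < 1) {
      reasons <- c(reasons, "decreased_reporting")
    }
  } else if (!est_ror$estimable) {
    reasons <- c(reasons, est_ror$reason)
  }
  structure(list(table = table, ror = est_ror, prr = est_prr, n_cases = n,
                 is_signal = is_signal, reasons = reasons),
            class = "pv_signal")
}

#' @export
print.pv_signal <- function(x, ...) {
  cat("<pv_signal> n =", x$n_cases, "| ROR", format_estimate(x$ror),
      "| PRR", format_estimate(x$prr),
      "|", if (x$is_signal) "SIGNAL" else "no signal",
      paste0("[", paste(x$reasons, collapse = ", "), "]"), "\n")
  invisible(x)
}

#' One-row tibble view of a signal result
#'
#' @param x A `pv_signal`.
#' @param ... Unused.
#' @return A tibble with the table cells, both estimates at full precision,
#'   the case count, the signal flag and reason codes.
#' @export
as_tibble.pv_signal <- function(x, ...) {
  tibble::tibble(
    a = x$table$a, b = x$table$b, c = x$table$c, d = x$table$d,
    n_cases = x$n_cases,
    ror = x$ror$point, ror_lower = x$ror$lower, ror_upper = x$ror$upper,
    prr = x$prr$point, prr_lower = x$prr$lower, prr_upper = x$prr$upper,
    is_signal = x$is_signal,
    reasons = paste(x$reasons, collapse = ",")
  )
}

#' Two-sided test for a difference between two reported proportions
#'
#' Pearson's chi-square test without continuity correction on the 2x2 table
#' `(a1, n1 - a1; a2, n2 - a2)`, as used to flag drug-level proportions that
#' differ from the exposed drug's proportion. Degenerate margins (the event
#' occurs in every case or in none, pooled over both groups) return p = 1.
#'
#' @param a1,n1 Events and total for the first group.
#' @param a2,n2 Events and total for the second group.
#' @return The two-sided p-value.
#' @export
#' @examples
#' proportion_test(418, 2016, 35, 426)
proportion_test <- function(a1, n1, a2, n2) {
  stopifnot(a1 >= 0, a2 >= 0, n1 > 0, n2 > 0, a1 <= n1, a2 <= n2)
  if ((a1 + a2) == 0 || (a1 + a2) == (n1 + n2)) return(1)
  m <- matrix(c(a1, n1 - a1, a2, n2 - a2), nrow = 2, byrow = TRUE)
  suppressWarnings(stats::chisq.test(m, correct = FALSE)$p.value)
}
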