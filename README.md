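# pvsignal

Disproportionality signal detection for spontaneous adverse-event reports.

`pvsignal` is an R package for pharmacovigilance analysts working with
public spontaneous-report databases such as Australia's Database of Adverse
Event Notifications (DAEN). It covers the full path from a raw case-report
export to signals of disproportionate reporting (SDRs): parsing and
normalising case reports, recoding adverse-event terms against Standardized
MedDRA Query (SMQ) style term sets, building 2×2 contingency tables under
full-database and active-comparator designs, and estimating reporting odds
ratios and proportional reporting ratios with confidence intervals and a
minimum-case signal rule. A synthetic report simulator with plantable effect
sizes makes every stage testable without access to a live database.

## The statistics

For a 2×2 table of case counts

|            | event | no event |
|------------|-------|----------|
| exposed    | a     | b        |
| comparator | c     | d        |

the **reporting odds ratio** is `ROR = (a·d)/(b·c)` with the Woolf
(log-scale) 95% confidence interval
`exp(ln ROR ± z₀.₉₇₅ · √(1/a + 1/b + 1/c + 1/d))`, and the **proportional
reporting ratio** is `PRR = [a/(a+b)] / [c/(c+d)]` with the analogous
log-scale interval. A drug–event pair is flagged as an SDR when at least 3
exposed cases report the event and the lower 95% bound of the ROR exceeds 1.
These are measures of *relative reporting*, not risk: no prescribing
denominator is involved, and a signal is hypothesis-generating, never causal
evidence.

Two comparator designs are supported. The *full-database* design compares an
exposed drug against all other drugs, built from published summary counts
with exposed cases removed from both comparator margins. The
*active-comparator* design restricts the comparator arm to drugs with
similar indications (reducing confounding by indication and channelling
bias) and is built from case-level data, with case-level counting: a report
listing several comparator drugs contributes one comparator case, and a
report suspected for both arms is assigned to the exposed arm only.

## Worked example

Full-database disproportionality from published summary counts:

```r
library(pvsignal)
counts <- read_summary_counts(
  system.file("extdata", "daen_summary_totals.csv", package = "pvsignal"),
  system.file("extdata", "daen_summary_events.csv", package = "pvsignal"))
tab <- build_table_summary(counts, "pregabalin", "drug abuse and dependence")
detect_signal(tab)
#> <pv_signal> n = 418 | ROR 13.53 (12.12, 15.10) | PRR 10.93 (10.01, 11.93) | SIGNAL [signal]
```

Of 2016 pregabalin reports, 418 involve an abuse/dependence event; the odds
of such an event are 13.5 times those in the rest of the database, with the
lower confidence bound (12.12) well above 1 — a strong SDR.

An end-to-end study on simulated reports (here with comparator-like event
propensities planted for all four drugs, so the grouped active-comparator
contrast is near null):

```r
sim <- simulate_reports(sim_config(n_cases = 5000, seed = 42,
  drug_mix = c(pregabalin = 0.25, gabapentin = 0.15, duloxetine = 0.15,
               amitriptyline = 0.15)))
smqs <- read_smq(system.file("extdata", "smq_fictional.csv", package = "pvsignal"))
groups <- read_drug_groups(system.file("extdata", "drug_groups.csv", package = "pvsignal"))
cfg <- study_config(exposed = "pregabalin",
                    comparators = c("gabapentin", "duloxetine", "amitriptyline"))
run_study(cfg, sim$reports, groups, smqs, summary_counts = counts)
#> <pv_study> scope: broad | window: 2005-04-01 to 2024-12-31
#>   full-database results:
#>     drug abuse and dependence ROR 13.53 (12.12, 15.10) *
#>     drug withdrawal ROR 6.76 (4.99, 9.15) *
#>     psychosis and psychotic disorders ROR 5.81 (4.99, 6.76) *
#>     suicide and self-injury ROR 12.40 (10.71, 14.36) *
#>   grouped active-comparator results:
#>     drug abuse and dependence ROR 1.09 (0.91, 1.30)
#>     drug withdrawal ROR 0.61 (0.39, 0.95)
#>     psychosis and psychotic disorders ROR 1.17 (0.93, 1.49)
#>     suicide and self-injury ROR 1.06 (0.84, 1.33)
```

The returned bundle also holds per-comparator sensitivity results,
narrow-scope / single-suspected / subgroup analyses, an annual ROR series,
and every underlying 2×2 table; `write_study_bundle()` serialises it to a
directory of CSV/JSON tables. The SMQ fixture shipped under `inst/extdata/`
is a small fictional term list — a placeholder for licensed MedDRA content,
designed to be replaced by real SMQ exports with the same CSV layout.

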