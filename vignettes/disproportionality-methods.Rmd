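---
title: "Disproportionality methods in pvsignal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality methods in pvsignal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvsignal)
```

## The problem

Spontaneous adverse-event databases collect voluntary, unverified reports of
suspected drug reactions. They have no denominator: we observe only what was
reported, not who was exposed. Disproportionality analysis asks whether a
drug–event pair is reported *more than its share*: whether the proportion of
reports mentioning the event among reports for the exposed drug exceeds the
proportion among comparator reports. `pvsignal` implements this for
DAEN-style exports: case-level reports carrying a case number, report date,
age, sex, drug entries with a suspected / not-suspected / interacting role,
and MedDRA-preferred-term-like event strings.

## Estimators and the signal rule

From a 2×2 table `(a, b; c, d)` of exposed/comparator × event/no-event
*case counts*, the package computes

* the reporting odds ratio `ROR = (a·d)/(b·c)` with the Woolf interval
  `exp(ln ROR ± z·√(1/a + 1/b + 1/c + 1/d))`, `z = qnorm(1 − α/2)`
  (1.959964 at α = 0.05), and
* the proportional reporting ratio `PRR = [a/(a+b)]/[c/(c+d)]` with
  `exp(ln PRR ± z·√(1/a − 1/(a+b) + 1/c − 1/(c+d)))` as a robustness
  companion; when events are rare in both arms the two agree closely.

A signal of disproportionate reporting requires `a ≥ min_cases` (default 3)
*and* a ROR lower bound above 1. An upper bound below 1 is annotated as
decreased reporting. Estimates with `a < min_cases` are still not computed
into signals; annual series flag such years as unsupported rather than
plotting unstable values.

Numerical choices worth stating explicitly:

* **Zero cells.** Any zero cell makes the ROR not-estimable (reason code
  `zero_cell`) rather than silently shifting the estimate; the
  Haldane–Anscombe 0.5 correction is available behind an explicit
  `correction = TRUE` flag for exploratory use only. The minimum-case rule
  already prevents zero `a` cells in signal assessment.
* **Rounding.** All computation and serialisation is at full double
  precision; ratios display at 2 decimals, except a lower bound that
  exceeds 1 but would display as 1.00, which displays at 3 decimals so the
  signal status stays visible (e.g. "1.002").
* **Proportion comparisons** between drugs use Pearson's chi-square without
  continuity correction; degenerate margins return p = 1. No multiplicity
  adjustment is applied across queries or subgroups — results tables are
  descriptive screens, and this is a documented caveat, not an oversight.

## Designs and counting rules

**Full-database design.** The comparator is every *other* drug in the
database. These tables are built from summary counts (total reports,
per-drug totals, per-drug and all-drug event counts), not case-level data,
because public databases publish whole-database figures only in summary
form: `a = n(exposed, event)`, `b = N(exposed) − a`, `c = n(all, event) − a`,
`d = N(total) − N(exposed) − c`. Exposed cases are removed from both
comparator margins, and the four cells always sum to the database total —
violations raise an inconsistency error naming the offending margin.

**Active-comparator design.** The comparator arm is a set of drugs with
similar indications, built from case-level reports. Counting is per case: a
report listing several comparator drugs counts once in the comparator arm.
A report suspected for both the exposed drug and a comparator is assigned to
the *exposed* arm and removed from the comparator arm. This was a genuinely
open design point — the alternative of dropping such overlap cases entirely
is equally defensible — but assigning them to the exposed arm guarantees no
case ever appears in both margins while keeping the exposed margin equal to
the count of exposed-suspected cases, which is how per-drug report totals
are published. Grouped-comparator estimates therefore need case-level data
and are not exactly derivable from per-drug summary tables; on non-overlapping
data they always lie inside the envelope of the per-comparator estimates
(a property the test suite verifies).

**Event recoding.** Event terms are matched to query term sets exactly,
after case-folding and whitespace collapsing — no stemming or fuzzy
matching, because standardized queries are controlled vocabularies and
fuzziness would inflate hits unpredictably. A case contributes at most one
hit per query however many of its terms match: all denominators count
cases, not events. The broad scope of a query is always a superset of its
narrow scope, so narrow-scope counts can never exceed broad-scope counts.
The shipped term lists are deliberately small and fictional (MedDRA is
licensed content); they use the real CSV layout so licensed lists drop in
unchanged. One shipped query ("suicide and self-injury") carries narrow
terms only, so its broad scope equals its narrow scope — a configuration
the real SMQ inventory contains.

**Strata.** Subgroup analyses use age bins 18–34, 35–44, 45–54, 55–64 and
>65, closed on the left and open on the right (18 ≤ age < 35, and >65 means
age ≥ 65 — the printed bins are contiguous, so one convention has to be
fixed); sexes female and male; and reporting periods 2005–2009, 2010–2014,
2015–2019, 2020–2024 or single calendar years derived from the report date.
Cases missing age or sex are excluded only from analyses stratified on that
variable, never from unstratified tables — age can be missing in a third of
reports, and dropping those globally would change every headline count.
Report dates are held at day precision; all period binning uses the calendar
year.

**Parsing conventions.** The export dialect (column names, role markers,
missing-value tokens, the event separator) is configurable via
`daen_dialect()`; in particular the marker text for the interacting role is
declarable because public exports do not standardise it. Rows sharing a case
number are merged by exact id only — no fuzzy record-linkage deduplication,
which is unspecifiable and risks silently dropping cases; conflicting report
dates within one case number are an error, not a guess. Sex values outside
female/male map to missing, as do unparseable or negative ages.

## The synthetic-report generator

`sim_config()` + `simulate_reports()` generate datasets with the structure
the analysis assumes: each case draws one primary suspected drug from a
configured mix (or a generic background medicine), optional co-suspect drugs
via pairwise probabilities, event terms sampled independently per term with
propensities keyed on the primary group, not-suspected co-medications,
normally distributed ages with a missing fraction, a categorical sex mix and
uniform report dates. Defaults encode the study conditions the package is
validated under: focal-drug shares and per-query case-level reporting
proportions taken from the published per-drug count tables, age mean 55.5
(SD 18.5) with 36.5% missing, 56.2% / 39.7% / 4.1% female/male/missing, and
the 1 April 2005 – 31 December 2024 window.

Because terms are independent Bernoulli draws, a query with terms
`p₁ … p_k` has case-level hit probability `1 − Π(1 − pᵢ)`, and
`propensity_from_hits()` inverts this to spread a target case-level
proportion across a query's terms. `planted_ror()` returns the implied true
odds ratio between any two groups in closed form, which is what the
recovery and coverage experiments compare estimates against. Seeding uses
one master seed from which per-component streams are derived, so adding a
component (say, co-medications) leaves the draws of every other component
unchanged — a property the test suite checks directly.

The generator deliberately does *not* model within-case term correlation
(unidentifiable from published tables and irrelevant to case-level hit
counting), reporting-delay dynamics, media-attention waves, or duplicate
submissions. Events depend only on the *primary* suspected drug, so
co-suspect drugs affect classification (multi-suspect restriction, overlap
handling) but not event propensities. Passing tests on this generator
therefore demonstrate correctness of the counting, estimation and decision
machinery under the stated model — not robustness to the reporting biases
of real spontaneous data, which no simulator grounded in published counts
alone could validate.

## Validation experiment sizes

The statistical property suite runs at sizes chosen to keep Monte-Carlo
error well inside the asserted bands: interval coverage on 2 000
two-binomial tables of 500 cases per arm at true odds ratios 0.5–5
(asserting 93–97% coverage); planted-effect recovery through the full
case-level pipeline at 50 000 cases per replicate, 20 replicates per planted
ratio in {0.5, 1, 2, 5, 13.5}, asserting the median estimate within 5% of
truth; and a null configuration (identical propensities in all arms, 4 000
cases, 200 replicates) asserting a per-query false-signal rate at or below
7.5% — about the nominal one-sided 2.5% plus Monte-Carlo slack and the
minimum-case rule's discreteness.

## Known limitations

* RORs and PRRs are reporting measures. Without prescribing denominators,
  raw counts must never be compared across drugs; the result bundle carries
  this caveat in its metadata.
* Only frequentist estimators are provided. Bayesian shrinkage (information
  component, EBGM) would stabilise small-count subgroups but is out of
  scope.
* The parser merges by exact case id; true duplicate *submissions* (same
  patient, different id) are assumed consolidated upstream.
* Death outcomes in public exports exist only as summary tables; the
  package tabulates user-supplied death counts verbatim and computes no
  statistics on them.
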