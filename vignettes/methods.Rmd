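---
title: "Methods: disproportionality screening, stratification and time-to-onset"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality screening, stratification and time-to-onset}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersignal)
```

## The screening model and its assumptions

Spontaneous reporting databases such as FAERS have no denominator: we never
observe how many patients took a drug, only how many adverse-event reports
mention it. Disproportionality analysis therefore compares, within the
database itself, how often a (drug, event) pair is reported against how
often it would be reported if drug and event were independent. For each
pair a 2×2 table of *report* counts is formed — `a` (suspect drug, suspect
event), `b` (other drugs, suspect event), `c` (suspect drug, other events),
`d` (other drugs, other events) — and four statistics are computed: the
reporting odds ratio (ROR), the proportional reporting ratio (PRR) with
Pearson's χ², the BCPNN information component with its posterior
mean/variance closed form (EIC, VIC, IC025), and the closed-form empirical
Bayes geometric mean (EBGM, EBGM05). Their positivity criteria — ROR CI
lower bound > 1 with a ≥ 3; PRR ≥ 2 with χ² ≥ 4 and a ≥ 3; IC025 > 0;
EBGM05 ≥ 2 — are combined conjunctively: only a pair flagged by **all
four** algorithms is a consensus-positive signal. The frequentist pair is
sensitive but false-positive prone; the Bayesian pair shrinks small counts
toward independence; the conjunction is deliberately conservative, which
our null-calibration runs confirm (measured consensus false-positive rate
effectively zero over replicate null databases).

The counting unit is the report, not the drug–event row: a report with
several PTs contributes to every term it mentions, but to each table cell
at most once. The comparator universe ("all other drugs") is every
deduplicated report whose primary-suspect drug is not the target —
including, for each study drug, the other study drug's reports. The
comparator is an explicit argument throughout, so a restricted background
is equally expressible.

Counts are assumed independent across reports; none of the statistics
model duplicate reporting, stimulated reporting, or confounding by
indication. Those caveats apply to any disproportionality analysis and are
why consensus positivity is a screening outcome, not a causal claim.

## Parameters that matter

- `min_a` (reports, default 3): the shared case-count gate for PT
  screening. SOC-level tables are enumerated from `min_a = 1` so
  sub-threshold organ classes remain visible in output tables.
- `z` and `z_ebgm` (default 1.96): interval quantiles. EBGM05 is
  conventionally described as a one-sided 95% bound, for which 1.645 would
  be the textbook choice; the default here is 1.96 because that is what
  the closed form as printed in FAERS analyses uses, and `z_ebgm = 1.645`
  is one argument away.
- BCPNN variance prefactor: the closed-form posterior variance is
  implemented with the prefactor `(1/ln 2)²`, the standard constant that
  converts the natural-log posterior variance to the log₂ scale. The
  vestigial "95% CI" expression sometimes printed alongside the BCPNN row
  plays no role: positivity is decided by `IC025 = EIC − 2√VIC`.
- Positivity thresholds (`ror_lower_min`, `prr_min`, `chisq_min`,
  `ic025_min`, `ebgm05_min`) are all overridable; loosening any of them can
  only enlarge the consensus-positive set (tested as a monotonicity
  property).
- `log_base` (default 10) for the stratum matrix: with the 0.01
  substitution a zero-count stratum cell is exactly −2, making the color
  scale interpretable; the base is a parameter, not a constant.

## Numerical choices and degenerate inputs

No continuity or Yates correction is applied anywhere: the printed χ² and
CI formulas contain none. A zero cell leaves ROR, the PRR interval and
EBGM05 *undefined* rather than corrected — the `a ≥ 3` gate makes the
`a = 0` case moot for positivity, and an undefined statistic is never
positive. The BCPNN component is defined for all non-negative cells,
including the all-zero table, where the shrinkage fixed point gives
EIC = 0 exactly. Statistics are computed in double precision and rounded
only at rendering (two decimals, comma thousands separators, en-dash
interval separator), matching conventional signal-table formatting.

One property worth stating precisely: ROR and PRR are strictly increasing
in `a` with `b`, `c`, `d` fixed, but EBGM and EIC are *not* — they are
relative-reporting ratios whose margins `(a+b)` and `(a+c)` grow with `a`,
and for `a` large against its margins an increment can lower them (e.g.
EBGM(11,10,10,10000) < EBGM(10,10,10,10000)). In the rare-event screening
regime (`b, c ≥ 2a`) strict monotonicity holds for all four, and that is
the regime the property tests assert.

In the stratum matrix, a PT×stratum cell whose ROR is 0 — in particular
`a = 0`, the PT never reported for the drug in that sex — is replaced by
0.01 before the log (−2 at base 10). The reverse degeneracy, an infinite
ROR from a zero *background* cell with `a > 0`, is not covered by that
substitution; those cells are recomputed with the Haldane–Anscombe +0.5
correction on all four cells so the matrix is finite everywhere. This is
the package's own choice for an otherwise undefined rendering input; it
affects display values only, never positivity.

Hierarchical clustering of the matrix uses Euclidean distance with average
linkage via `stats::hclust`. Rows are sorted by label before the distance
computation so ties break identically regardless of input order; the leaf
orders are therefore deterministic and permutation-invariant, and they are
part of the exported artifact (the rendered heatmap is just a view of
them).

## Deduplication, filtering and dates

FAERS re-emits updated cases under new primaryids sharing a caseid. The
published processing descriptions rarely say which version wins, so two
rules are applied in sequence and logged separately: byte-identical rows
collapse at parse time, and among several primaryids per caseid only the
numerically largest (the latest case version, per FDA guidance) is kept.
Deduplication is idempotent and commutes with primary-suspect filtering.

Keyword matching for the primary-suspect filter is case-insensitive
substring matching over both `drugname` and `prodname`, because FAERS drug
names are free text with dosage suffixes and brand/generic variation. Only
reports whose matching drug has role code PS are retained. A report
matching two canonical drugs is assigned to both analyses and logged.

Ages are normalised from FAERS unit codes (YR, MON, DY, ...) to years;
unknown units become missing. Dates are kept as raw YYYYMMDD strings:
empty means missing, 4- or 6-digit values are partial, and anything else
non-conforming is treated as partial (and logged) rather than guessed at.
Time-to-onset uses only full dates on both sides, requires a non-negative
interval, and bounds both dates to [1900-01-01, extraction date]; a 0-day
interval is kept because same-day infusion reactions are clinically real.
Exclusion reasons are assigned in a fixed precedence order
(missing event, missing start, partial, negative, out-of-range) and every
report appears exactly once across included and excluded tallies.

The group comparison behind the onset analysis is a two-sided Mann–Whitney
rank-sum test — chosen here as a documented stand-in where published
analyses report only "P > 0.05" without naming a test, and always reported
with its name in output. When both groups have ≤ 8 observations the
p-value is computed by exhaustive enumeration of all `choose(n1+n2, n1)`
assignments of pooled mid-ranks with the symmetric convention
`p = P(|U − E[U]| ≥ |u_obs − E[U]|)`, which handles ties exactly (fully
tied groups give p = 1, and [1,2,3] vs [10,20,30] gives 0.100). Larger
samples use the tie-corrected normal approximation without continuity
correction, which matches `wilcox.test(exact = FALSE, correct = FALSE)`.

## What the synthetic generator emulates — and what it does not

The generator produces a FAERS-dialect database with known ground truth.
Each case carries one primary-suspect drug (uniform over the drug
universe), zero to two concomitants, demographics with a female-leaning
sex mix (57% F among non-missing) and configurable missingness (defaults:
6.7% sex, 26% age, 15% missing and 5% partial dates, mirroring the
descriptive structure of the anti-amyloid extract), mostly-US reporting,
and event dates uniform over 2004-01-01 to 2024-06-30. PT occurrence is
independent Bernoulli per (report, PT) at rate `background_pt_rate / n_PT`,
multiplied by the planted relative risk for configured (drug, PT) pairs
and clipped to 1 — the simplest mechanism whose ground-truth relative risk
is exactly known. A report that samples no PT receives one uniformly
(FAERS cases always carry at least one reaction); at the default rate of 3
PTs per report over a 60-PT catalog this inflates the marginal mean by
under 2%. Therapy start dates are back-computed from per-drug
time-to-onset draws (log-normal by default, medians 33 days for lecanemab
and 146 for aducanumab with sdlog 1), so median-recovery targets are
planted quantities. A configurable fraction of cases (default 8%) is
re-emitted under a larger primaryid with only reporter occupation and
country perturbed — never the PT set — so deduplication correctness is
checkable against the manifest.

The generator deliberately does **not** model reporting dynamics (the
Weber effect, stimulated reporting after label changes), drug-name
misspellings beyond brand/generic pairs, correlated PT co-occurrence
(real syndromes), indication confounding, or OUTC/RPSR/INDI content.
Passing tests therefore demonstrate that the pipeline's arithmetic,
filtering and ranking behave correctly under known truth — not that any
specific real-world signal is valid.

## Genuinely open choices made here

- **Stratified comparator**: sex-stratified tables restrict *both* target
  and background to the stratum's sex — the standard stratified
  construction — rather than comparing a sex-restricted target against the
  full background.
- **Matrix row universe**: rows are the union of PTs consensus-positive in
  *any* drug×sex stratum (the per-stratum reading of a cross-stratum
  comparison figure); screening from the overall-positive set instead is a
  matter of passing those tables in.
- **Background universe**: taken as the full deduplicated remainder of the
  database; it is a function argument, so a restricted comparator is a
  one-line change.
- **Dedup precedence**: latest case version wins (largest primaryid), with
  exact-row collapse logged separately, since both readings of "remove
  duplicates by case ID and primary ID" are defensible.

## Problem sizes used in the tests

The test suite and the acceptance script use sizes chosen to make the
Monte-Carlo properties sharp at interactive runtimes: 1,000 random tables
for oracle equivalence, 2,000 binomial draws (expected cells ≥ 10) for CI
coverage, 20 replicate 50,000-case databases each for planted-signal
recovery (one pair at relative risk 10) and for null calibration, ~500
usable onset records per drug for median recovery, and a 4,000-case
complete-sex database for stratum additivity. The full suite runs in
about a minute on one core.

## Known limitations

The MGPS implementation is the closed-form relative-reporting EBGM with a
Wald-style lower bound, not the full DuMouchel two-component gamma-Poisson
prior fit; published EBGM values from full-prior implementations will
differ, most visibly at small counts. IC values cannot be validated
against published FAERS tables without the underlying cell counts. The
ingest layer normalises only the date and age quirks described above; it
does not attempt MedDRA LLT→PT coding (inputs are assumed PT-coded, as in
FAERS REAC), ISO country harmonisation, or drug-name standardisation
beyond case-insensitive substring matching.
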