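# faersignal

Disproportionality signal detection for spontaneous adverse-event reports,
built for FAERS-style quarterly data. The package grew out of
pharmacovigilance screening of the anti-amyloid antibodies for Alzheimer's
disease (lecanemab, aducanumab), where the questions of interest are which
adverse events are reported disproportionately often for a drug, whether
those signals differ between female and male patients, and how quickly
events set in after the start of therapy. Everything is exercised end to end
on a ground-truthed synthetic reporting database, so the whole pipeline is
testable without downloading the live FAERS extract.

It is aimed at pharmacovigilance analysts and biostatisticians who want the
standard screening machinery — case deduplication, primary-suspect
filtering, MedDRA aggregation, four signal algorithms under a consensus
rule, sex stratification, time-to-onset — as composable, tested R functions
rather than ad-hoc scripts.

## The statistics

For each (drug, term) pair a 2×2 report-count table is built:

|                | suspect event | other events |
|----------------|---------------|--------------|
| suspect drug   | a             | c            |
| all other drugs| b             | d            |

with N = a + b + c + d, and four algorithms are evaluated:

- **ROR** (reporting odds ratio): `ROR = ad/bc`,
  `95% CI = exp(ln ROR ± 1.96·√(1/a + 1/b + 1/c + 1/d))`;
  positive iff the CI lower bound > 1 and a ≥ 3.
- **PRR** (proportional reporting ratio): `PRR = [a/(a+b)] / [c/(c+d)]`
  with the Pearson χ² statistic (no continuity correction);
  positive iff PRR ≥ 2, χ² ≥ 4 and a ≥ 3.
- **BCPNN information component**: with shrinkage constant
  `γ = (N+2)² / [(a+b+1)(a+c+1)]`, the posterior mean
  `EIC = log₂[(a+1)(N+2)² / ((N+γ)(a+b+1)(a+c+1))]` and variance `VIC`
  give `IC025 = EIC − 2√VIC`; positive iff IC025 > 0.
- **MGPS** closed-form empirical Bayes geometric mean:
  `EBGM = aN / [(a+c)(a+b)]`,
  `EBGM05 = exp(ln EBGM − 1.96·√(1/a + 1/b + 1/c + 1/d))`;
  positive iff EBGM05 ≥ 2 and a > 0.

A pair is a **consensus-positive signal** only when all four criteria hold
simultaneously — the frequentist pair is sensitive, the Bayesian pair is
robust for rare events, and their conjunction is deliberately conservative.

Sex-stratified screening recomputes the PT-level tables within each
drug × sex stratum (both target and comparator restricted to the stratum)
and assembles a log₁₀(ROR) matrix over the union of stratum-positive PTs; a
stratum ROR of 0 (no case in the stratum) is replaced by 0.01 before the
log, so such cells are exactly −2. Time-to-onset is the calendar-day
interval from therapy start (START_DT) to event onset (EVENT_DT), with
missing, partial and implausible dates excluded for a recorded reason, and
groups compared by a two-sided Mann–Whitney test (exact enumeration for
small samples, tie-corrected normal approximation otherwise).

## Worked example

Simulate a 20,000-case reporting database (two target antibodies, eight
background drugs, two planted lecanemab associations at relative risks 10
and 5), ingest it exactly as FAERS files would be, and screen:

```r
library(faersignal)

cfg <- synthetic_config(n_cases = 20000, seed = 42)
ds  <- generate_dataset(cfg)

rs <- parse_faers_tables(ds) |>
  deduplicate() |>
  map_meddra(generate_meddra_dictionary(cfg))
target     <- filter_primary_suspect(rs)
background <- background_set(rs, target)

tabs <- enumerate_tables(target, background, "lecanemab",
                         level = "PT", min_a = 3)
sig <- screen_signals(tabs)
dplyr::select(sig, term, frequency, ror_ci, prr_chisq,
              ebgm_ebgm05, ic_ic025, consensus_positive)
```

```
  term   frequency ror_ci              prr_chisq       ebgm_ebgm05 ic_ic025     consensus_positive
1 PT_001       986 17.10 (15.30–19.11) 8.41 (3,723.82) 4.80 (4.30) 2.26 (2.13)  TRUE
2 PT_002       504 6.31 (5.58–7.14)    4.25 (1,061.67) 3.44 (3.04) 1.78 (1.62)  TRUE
3 PT_009       121 1.21 (0.99–1.47)    1.18 (3.56)     1.17 (0.96) 0.22 (-0.06) FALSE
...
```

The two planted pairs — and only they — come out consensus-positive:
PT_001 (planted at RR 10) reaches ROR 17.10 with CI (15.30, 19.11), EBGM
4.80 with lower bound 4.30 and IC025 2.13; every unplanted PT fails at
least one criterion. On a single table the same statistics are available
directly:

```r
disproportionality_stats(a = 20, b = 10, c = 10, d = 20)
#> ror 4.000  CI (1.367, 11.703)   prr 2.000  chisq 6.667
#> eic 0.392  ic025 -0.333         ebgm 1.333  ebgm05 0.456
#> consensus_positive FALSE   (ROR and PRR flag it; BCPNN and MGPS do not)

compare_tto(c(1, 2, 3), c(10, 20, 30))
#> statistic 0, p_value 0.1, Mann-Whitney (exact enumeration)
```

`run_pipeline(faers_run_config(...))` chains all stages (descriptive table,
SOC/PT screening per drug, stratified matrix with clustering order, onset
summaries and tests, JSON run manifest) into one reproducible run; a thin
command-line wrapper lives at `inst/cli/faersignal-pipeline.R`.

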