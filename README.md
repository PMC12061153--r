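# nhanesaudit

An audit pipeline for corpora of published single-factor association
studies built on cyclical health surveys such as NHANES.

The recent literature contains hundreds of formulaic papers each relating
one predictor (a biomarker, an index, an exposure) to one health
condition in the same survey database. Taken together, such studies form
an uncorrected multiple-testing sweep over a shared dataset, and the
freedom to pick a survey-year window invites selective analysis.
`nhanesaudit` is for meta-researchers, statistical reviewers, and
editors who want to re-analyze such a corpus quantitatively. It works on
a table of *published studies* (one CSV row per paper), not on survey
microdata.

## What it computes

**Evidence harmonization.** Every study's evidence becomes one two-sided
p-value. Reported p-values are taken as presented (entries censored as
"&lt;x" are resolved under a stated convention, default x itself). An
odds ratio with a (1 − α)-level CI [L, U] is inverted on the log scale:

    SE = (ln U − ln L) / (2 z_{1−α/2}),   z = ln(OR) / SE,
    p = 2 (1 − Φ(|z|)).

**Group-wise FDR re-correction.** Within each condition, the step-up
adjustment at rank k is

    p̃_(k) = min over j ≥ k of  m · c(m) · p_(j) / j,   capped at 1,

with c(m) = Σ_{i≤m} 1/i for Benjamini–Yekutieli (valid under arbitrary
dependence; the package default) and c(m) = 1 for Benjamini–Hochberg.
Implemented from first principles with the rank bookkeeping exposed, and
cross-checked in the tests against both a brute-force oracle and
`stats::p.adjust`.

**Association network.** The bipartite predictor–condition multigraph
(one edge per paper), degree tables, conditions with ≥ 4 papers, and
variables used as predictor in one study and outcome in another.
GraphML export for external layout tools.

**Window audit.** Each analyzed year range is compared with the survey
cycles actually released for that variable before publication (a
packaged availability calendar encodes the release history; the
2021–2023 cycle is absent because it was released only in late 2024).
Verdicts: `full`, `selective`, or `mismatch`.

**Synthetic corpora.** `generate_corpus()` draws corpora with known
ground truth (null/alternative mixture, rounded/censored reporting,
hub-skewed condition assignment, selective windows), and
`dredging_experiment()` contrasts uncorrected single-factor analysis
with joint correction across replicates.

## Worked example: the depression case study

Twenty-eight published studies each proposed a significant association
between some predictor and depression. Individually all 28 clear
p < 0.05; corrected jointly they do not:

```r
library(nhanesaudit)

tab2 <- read_corpus(nhanesaudit_example("table2_depression.csv"))
h    <- harmonize(tab2, convention = "at_bound")
dep  <- group_adjust(tab2, h, method = "BY")$depression

count_significant(dep)
#> [1] 13

head(dplyr::arrange(tibble::as_tibble(dep), rank), 15)
#>    study_id raw_p  rank adjusted_p significant
#>  1 38869164 0.001     1    0.00916 TRUE
#>  ...twelve "<0.001" entries share adjusted p 0.00916...
#> 13 28395506 0.002    13    0.0169  TRUE
#> 14 39029685 0.008    14    0.0586  FALSE
#> 15 38220117 0.008    15    0.0586  FALSE
```

So 13 of the 28 associations survive Benjamini–Yekutieli correction at
α = 0.05 with m = 28: the twelve censored "<0.001" entries (adjusted
0.009) and the p = 0.002 entry (adjusted 0.017). The first casualty is
p = 0.008 at adjusted 0.059. The survivor count is invariant to how the
censored entries are resolved anywhere in (0, 0.001].

The window audit on the 14 studies analyzing the systemic
immune-inflammation index (SII):

```r
sii <- read_corpus(nhanesaudit_example("table3_sii.csv"))
cal <- read_calendar(nhanesaudit_example("nhanes_calendar.csv"))
aud <- audit_windows(sii, cal)

table(aud$verdict)
#>      full selective
#>         3        11

aud[aud$study_id %in% c("38974989", "38027115"),
    c("study_id", "verdict", "coverage")]
#>   study_id verdict   coverage
#> 1 38974989 selective    0.727    # diabetes, analyzed 2003-2018 of 1999-2020
#> 2 38027115 selective    0.182    # diabetes, analyzed 2017-2020 of 1999-2020
```

Both diabetes studies used a strict subset of the 22 available years —
from the same database, in the same year, with different windows.

`run_audit()` chains all stages and writes `report.json`, `report.md`,
per-group FDR tables, the degree table, the GraphML graph and the
window-audit CSV. A thin command-line wrapper lives at
`inst/cli/nhanesaudit.R`.

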