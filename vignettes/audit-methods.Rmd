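---
title: "Auditing single-factor association corpora: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing single-factor association corpora: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nhanesaudit)
```

## The problem this package addresses

Cyclical public health surveys such as NHANES make it cheap to publish
*single-factor* association studies: one predictor (a biomarker, an index,
an exposure) regressed against one health condition, with covariate
adjustment but no joint modelling of competing predictors. When dozens of
such studies target the same condition over a short period, they
collectively perform a multiple-testing sweep that none of them corrects
for, and the freedom to choose a survey-year window invites selective
analysis. `nhanesaudit` re-analyzes a *corpus of published studies* — not
the survey microdata — along four axes:

1. **Evidence harmonization**: every study's reported evidence (a p-value,
   possibly censored as "<0.001", or an odds ratio with 95% CI) is reduced
   to a single two-sided p-value.
2. **Group-wise FDR re-correction**: the harmonized p-values for each
   condition are corrected jointly, as one research group investigating
   all those predictors together would have done.
3. **Association network**: the bipartite predictor–condition multigraph,
   whose degrees identify conditions studied as single-factor problems
   many times over, and variables used as predictor in one paper and as
   outcome in another.
4. **Window audit**: each study's analyzed year range compared with the
   survey cycles actually released for its variable before publication.

A synthetic corpus generator with recorded ground truth makes every stage
testable without any external download.

## Harmonizing odds-ratio evidence

For a study reporting an odds ratio $\mathrm{OR}$ with a
$(1-\alpha_{CI})$-level interval $[L, U]$, the standard error of the log
odds ratio is recovered from the interval width,

$$ SE = \frac{\ln U - \ln L}{2\, z_{1-\alpha_{CI}/2}}, \qquad
   z = \frac{\ln \mathrm{OR}}{SE}, \qquad
   p = 2\,(1 - \Phi(|z|)), $$

with $z_{0.975} \approx 1.959964$ for the default 95% interval. This
Wald-type inversion is the only reconstruction consistent with how such
intervals are produced in the source studies (exponentiated
$\widehat{\beta} \pm z \cdot SE$ from a logistic model). Two numerical
choices matter:

* $p$ is clamped at the smallest positive double rather than underflowing
  to zero, so downstream log-scale reporting is always defined;
* a zero-width interval is an error (no $SE$ is recoverable), as is an
  interval that fails to bracket the odds ratio — the latter indicates a
  transcription mistake and is never silently repaired.

Reported p-values are taken as presented. Entries censored as
"$<x$" must be mapped to a number before correction; the package's
default convention `at_bound` uses $x$ itself, which is the *largest*
(most conservative) admissible value. Because the adjusted rank of a
censored entry depends only weakly on its exact value, the survivor count
downstream is invariant to any choice in $(0, x]$ — a property the test
suite checks explicitly. The alternative `half_bound` ($x/2$) is provided
for sensitivity analysis.

## Step-up FDR correction

`fdr_adjust()` implements the step-up adjustment from first principles.
With $m$ hypotheses and sorted p-values $p_{(1)} \le \dots \le p_{(m)}$,
the candidate adjusted value at rank $k$ is

$$ \tilde p_{(k)} = \frac{m \, c(m)}{k} \, p_{(k)}, \qquad
   c(m) = \begin{cases} \sum_{i=1}^m 1/i & \text{Benjamini–Yekutieli} \\
                        1 & \text{Benjamini–Hochberg,} \end{cases} $$

followed by a cumulative minimum from rank $m$ downward and a cap at 1.
BY is the package default because the predictors in a survey-derived
corpus are arbitrarily correlated (many are functions of the same blood
panel); the harmonic constant buys validity under any dependence
structure. Design details:

* ties in the raw p-values keep input order in the sort, and the
  cumulative minimum guarantees tied raw p's receive identical adjusted
  p's regardless of tie order;
* significance is *strict*, `adjusted_p < alpha`, with `alpha = 0.05`
  default;
* `m` defaults to the group size. The true number of hypotheses a
  literature could have tested is unknowable, so an explicit `m` override
  is allowed and always inflates the correction;
* adjusted p-values are kept at full precision internally and rounded to
  3 decimals only in rendered reports.

`group_adjust()` partitions the corpus by normalized outcome label (or
predictor, or not at all) and applies the correction within each group
with $m$ equal to the group size.

On the packaged 28-study depression table, joint BY correction at
$\alpha = 0.05$ leaves 13 of 28 associations significant:

```{r depression}
tab2 <- read_corpus(nhanesaudit_example("table2_depression.csv"))
dep <- group_adjust(tab2, harmonize(tab2))$depression
count_significant(dep)
```

Three published adjusted cells in that table (printed 0.161) cannot be
reproduced from the printed raw p-values, which yield 0.163: the source
evidently corrected unrounded p-values it did not publish. The same
phenomenon appears for censored raw entries whose published adjusted
value exceeds the bound. The package reproduces every cell that is
computable from the printed inputs and documents the rest as
irreproducible rather than tuning inputs to match.

## The availability calendar and window audit

Survey variables enter and leave the questionnaire over time, so "the
full data" is variable-specific. The calendar maps each variable key to
released cycle spans with a release year; the packaged default encodes
one row per biennial cycle (1999–2000 through 2015–2016) plus the
combined pre-pandemic 2017–2020 release (released 2021), and omits the
2021–2023 cycle entirely, since it became public only in late 2024 —
after the publication window of the audited corpus.

Years are treated as plain integer sets, not cycle objects: the irregular
2017–2020 release and multi-span availabilities (e.g., a ferritin assay
collected 1999–2002, 2005–2010 and 2015–2020) make year sets the only
representation that handles all cases uniformly. Availability at
publication is the union of spans with `release_year < pub_year`
(strict): data released in the publication year itself are assumed
unavailable during the work. The verdicts are:

* **full** — every available year analyzed;
* **selective** — a strict subset analyzed, no out-of-range years; the
  pattern that, without stated justification, suggests post-hoc window
  shopping;
* **mismatch** — analyzed years outside availability (usually a
  transcription or key error; surfaced, never guessed away).

"Full" deliberately requires analyzed $\supseteq$ available rather than
mere span equality of endpoints, and partial overlap is always
"selective". On the packaged 14-study SII (systemic immune-inflammation
index) fixture this strict rule yields 3 full / 11 selective; the summary
the source of that table reports (4/10) implies a classification rule for
one study that is not stated anywhere, so the strict-rule output is
asserted in tests and the 4/10 split is documented as unreproducible. A
`justified_subset` column, when present, is carried through the audit so
flagged-but-justified studies can be reported separately — the tool
flags, humans judge.

## The synthetic corpus generator

`generate_corpus()` draws corpora from the process the audit implicitly
assumes, with every latent quantity recorded:

* **Mixture**: a proportion `pi0` of studies are true nulls (log OR = 0,
  p uniform); alternatives draw a true log odds ratio from
  $N(\mu_{\beta}, \sigma_{\beta})$, default $N(0.5, 0.2)$ — odds ratios
  around 1.6, typical of the single-factor literature.
* **Sampling noise**: each study has $SE \sim U(0.1, 0.3)$, the range
  implied by survey-sized logistic fits, and observes
  $\widehat{\ln OR} \sim N(\ln OR_{true}, SE)$.
* **Reporting**: half the studies report a p-value (rounded to 3
  decimals, censored to "<0.001" below the threshold), half an OR with
  95% CI rounded to 2 decimals — the mix seen in published tables.
  Rounding is applied *before* harmonization, deliberately reproducing at
  controllable severity the irreproducible-cell phenomenon above; with
  `round_digits_or = 12` the harmonized p recovers the exact p to 1e-6,
  which the tests assert. If rounding breaks the CI-brackets-OR
  invariant, the observation noise is redrawn: the generator never emits
  invalid records.
* **Structure**: studies hit conditions with Zipf($s$) weights
  (`hub_concentration`, default 1), predictors uniformly; defaults of 341
  studies, 138 conditions, 169 predictors match the scale of the audited
  corpus, and publication years use the observed 33/82/190 surge weights
  for 2022/2023/2024.
* **Windows**: a variable is drawn from the calendar's
  contiguous-availability variables; with probability `selective_prob`
  (default 10/14, the observed split in the windows case study) the
  analyzed window is a uniformly drawn strict contiguous sub-window,
  otherwise the full span. Restricting to contiguous variables makes the
  drawn selectivity indicator coincide exactly with the audit verdict —
  a multi-span availability can never be covered by one contiguous
  window, which would conflate generator intent with representational
  limits.

A single seeded RNG stream drives all draws; the seed is recorded in the
corpus provenance, identical seeds give bit-identical output, and the
caller's RNG state is restored afterwards.

What the generator does *not* emulate: survey microdata (weights, design
effects, within-cycle correlation), genuine between-study dependence
(each synthetic study is an independent draw), text-level features, or
the PRISMA screening process. Passing calibration tests therefore show
that the pipeline's statistics behave as designed under its stated
model — not that the model captures every property of the published
literature.

## The dredging experiment

`dredging_experiment()` contrasts the uncorrected single-factor reading
(each study judged at $\alpha$ alone) with joint group-wise correction,
across replicates. Per replicate it reports:

* `uncorrected_null_rejection_rate` — the fraction of true-null studies
  with harmonized $p < \alpha$, computed on the *harmonized* p-value so
  that reporting artifacts (rounding, censoring) are part of the
  pipeline being measured;
* `by_fdp` / `bh_fdp` — the realized false discovery proportion within
  each outcome group (0 for groups rejecting nothing), averaged over
  groups. The per-group scope matches the per-family guarantee the FDR
  theorems give; pooling rejection counts across 100+ independent
  families would instead measure a quantity no procedure controls
  (under a global null it collapses to 1 whenever any family rejects);
* `by_power` — jointly corrected detections over all non-null studies.

The calibration suite runs 200 replicates of 500 studies for each of
$\pi_0 = 1$ (type I calibration: the uncorrected rate must sit within 3
Monte-Carlo standard errors of $\alpha$) and $\pi_0 = 0.8$ (the mean
per-group FDP under BY must not exceed $\alpha$ beyond 3 MC SEs). These
sizes give Monte-Carlo standard errors of roughly 0.001–0.003 on the
rates, small enough that a miscalibrated implementation cannot hide, and
complete in a few minutes on one CPU core. Module-level tests use
smaller corpora (50–2,000 studies) chosen so each binomial tolerance is
still a 3-sigma band.

## Degenerate inputs and tie-breaking, in one place

* Empty corpus: valid everywhere a count is the answer; `median_span()`
  errors (no median of nothing).
* Records without evidence (window-only studies): accepted by
  `read_corpus()` and flagged by `has_evidence()`; `harmonize()` refuses
  them by name. Records with *both* evidence forms are rejected at read
  time — there is no principled way to prefer one.
* Label matching is exact after whitespace/case normalization; no fuzzy
  matching. A user-supplied synonym map handles known aliases, and its
  output is itself normalized so normalization stays idempotent.
* Degree tables sort by role then label; popularity tables break count
  ties by (start, end); `multifactorial_conditions()` breaks degree ties
  by label — every ordering in a report is deterministic.
* Condition degree counts *papers* (parallel edges) by default, matching
  the convention that node size reflects publication count; a
  distinct-partner variant is available because "number of associated
  predictors" is genuinely ambiguous between the two readings.

## Known limitations

* The OR/CI inversion assumes a symmetric Wald interval on the log scale;
  profile-likelihood or exact intervals from the source studies would
  yield slightly different implied standard errors. No correction is
  attempted.
* Censored p-values make exact reproduction of some published adjusted
  cells impossible in principle; the conventions bracket the answer.
* The window audit is evidence of *selectivity*, not of intent; release
  years in the calendar are data and can be refined without code changes.
* Affiliation and journal tallies depend on upstream transcription
  choices (first-author vs corresponding-author affiliation, journal
  renames); the package counts what the corpus file says.
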