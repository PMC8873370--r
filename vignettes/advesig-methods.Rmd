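---
title: "Methods: disproportionality signal detection and immune-infiltrate grade association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality signal detection and immune-infiltrate grade association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(advesig)
```

## Overview

`advesig` implements two complementary analysis strands around one question
— the role of inflammatory cells in breast cancer:

1. **Disproportionality analysis** of spontaneous adverse-drug-reaction
   (ADR) line listings for a class of anti-HER2 monoclonal antibodies
   (trastuzumab, trastuzumab emtansine, pertuzumab), using the Proportional
   Reporting Ratio (PRR) with the classical three-part signal rule, plus
   reaction-share summaries.
2. **Grade association** in a spontaneous canine model of mammary
   carcinoma: frequency tables of histotype and malignancy grade,
   per-field immune-infiltrate densities (CD68 macrophages, CD20
   B lymphocytes), between-grade two-sample tests computed from summary
   statistics, and serum neutrophil–lymphocyte (NLR) and
   platelet–lymphocyte (PLR) ratios.

Both strands are backed by seeded synthetic-data generators with known
ground truth, so every stage of the pipeline is testable offline, including
the operating characteristics (false-positive rate and power) of the signal
rule.

## The disproportionality model

A line listing is a one-row-per-(report, reaction) export: a report that
mentions several MedDRA preferred terms (PTs) spans several rows sharing a
`report_id`. For a drug of interest within an explicit drug class, the 2×2
table counts

* `a` — rows of the reaction of interest for the drug of interest,
* `b` — the same reaction for all other drugs in the class,
* `c` — all other reactions for the drug of interest,
* `d` — all other reactions for the other drugs,

and the PRR is

$$\mathrm{PRR} = \frac{a/(a+c)}{b/(b+d)}.$$

The counting unit is the (report, PT) row, matching dashboard tallies. The
signal rule declares a (drug, reaction) pair a signal when PRR ≥ 2, the
case count `a` is at least 3, and the Pearson χ² of the table is at least
4; a PRR exactly equal to 1 is never a signal. The PRR = 1 exclusion is
evaluated on the table's rational value (`a(b+d) = b(a+c)`), not on the
floating-point ratio, so exact proportionality is excluded even when the
float drifts.

```{r}
tab <- contingency_table(a = 286, b = 327, c = 337, d = 4230)
compute_prr(tab)
as.numeric(compute_chi2(tab))
```

This worked example uses the published blood-and-lymphatic-disorder counts
of the anti-HER2 class (platelet-count decrease under trastuzumab emtansine
against the two comparator antibodies, denominators 623, 3435 and 1122
reports). The class's headline screen-level PRR values cannot be recomputed
from published material because the full 2×2 marginals of the original
extraction were never printed; the printed per-drug counts above are the
reproducible quantity, and this package treats them as the worked example.

### Numerical choices

* **χ² variant.** Pearson without continuity correction by default; the
  Yates-corrected statistic (|ad−bc| reduced by N/2, floored at 0) is
  available via `yates = TRUE`. Classical PRR practice varies; the rule
  threshold applies to whichever variant the run configures.
* **Zero cells.** `b = 0` leaves the PRR undefined. The default policy is
  an explicit error (`strict`); `haldane` adds 0.5 to all four cells first.
  Silent corrections distort the PRR on near-degenerate tables, so the
  correction is opt-in. `prr_screen()` converts degenerate tables into
  flagged `NA` rows rather than failures.
* **Rounding.** Percentage shares use round-half-even (`round()`), the IEEE
  default. Some published percentage tables show truncation rather than
  rounding (e.g. 45/101 printed as 44.5% where half-even arithmetic gives
  44.6%); the package reproduces only arithmetic-consistent values and does
  not emulate truncation.
* **Label matching.** All text fields are compared case-insensitively after
  whitespace trimming.

## The synthetic line-listing generator

`pv_config()` + `simulate_line_listing()` define the generative model used
for validation:

* Exactly `totals[drug]` reports per drug (the volumes default to the
  scale of real per-drug report counts in this drug class, order 10³–10⁴).
* Each report draws each PT independently as Bernoulli(min(1, λ·p)), where
  p is the reaction's baseline probability and λ the injected signal
  multiplier (default 1). λ is the recoverable ground truth.
* At least one reaction per report is guaranteed: when every Bernoulli
  trial fails, one PT is drawn proportionally to the drug's reaction
  probabilities. This preserves within-drug reaction-share *ratios* — and
  therefore the PRR — exactly, but inflates the per-report marginal
  reporting proportion of each PT by the factor (1 + P₀/Σp), with P₀ the
  probability that all trials fail. Convergence of empirical proportions to
  configured probabilities therefore holds in the regime where P₀ ≈ 0
  (e.g. vocabularies containing a common background reaction); the tests
  exercise exactly that regime.
* Demographics (age band, sex, route, year, seriousness, outcome) are
  drawn from categorical distributions whose defaults emulate the study
  stratum: predominantly female, 18–64, years 2015–2020.
* With probability `duplicate_rate` a report is re-emitted under a fresh
  identifier immediately after its original, as an exact payload copy.

`expected_prr()` is the analytic oracle: the PRR implied by expected row
counts. With a homogeneous comparator pool the guarantee's inflation
factors cancel and the empirical PRR converges to this value; with
heterogeneous comparators (different P₀ per drug) the pooled comparator
share is mildly distorted, which matters only for null pairs far from the
signal threshold.

What the generator does **not** emulate: reporting dynamics over time,
under-reporting, co-medication structure, or free-text fields. Passing
recovery tests therefore shows the statistical machinery is correct under
independent per-PT reporting, not that real dashboards behave this way.

## De-duplication

Real duplicate exclusion is a manual, case-by-case judgement. The package
substitutes a deterministic key — (drug, PT, age band, sex, route, year,
seriousness), configurable — keeping the first occurrence in input order.
Two properties follow: the operation is idempotent, and every exact-copy
duplicate is removed. The price of determinism is over-collapse: the key
has finite cardinality, so on a dense listing genuinely distinct reports
collide and are removed too. On synthetic listings of ~10⁴ rows the key
space saturates and an injected five-fold signal can be flattened below
threshold. Consequently `run_config()` exposes both the key and a `dedup`
toggle, and listings known to be duplicate-free (e.g. generated with
`duplicate_rate = 0`) should be screened with `dedup = FALSE`. Real
exports, whose payload fields are far higher-cardinality, collide rarely.

## Operating characteristics

`operating_characteristics()` replays `simulate_line_listing()` +
`prr_screen()` over many replicates (per-replicate seeds drawn once from
the master seed) and reports, per (drug, reaction) pair: the configured λ,
the analytic `expected_prr`, the mean and Monte-Carlo standard error of
the estimated PRR, and the flag rate with its binomial standard error. For
injected pairs the flag rate is power; for λ = 1 pairs it is the
false-positive rate. The validation experiment shipped with the package
uses three drugs at 20,000 reports each, a six-PT vocabulary at baseline
probability 0.05, one injected λ = 5 pair, and 200 replicates (~40 s on
one CPU); at that scale power is essentially 1 and null flag rates
essentially 0.

## The grade-association strand

The canine cohort comprises 101 mammary carcinomas classified by histotype
(Goldschmidt system) and malignancy grade G1–G3 (Peña system).
Immunostained sections are counted over the first 10 fields encountered at
400× magnification, each field 0.1885 mm²; `density_from_fields()` converts
per-field counts into a per-field mean and a per-mm² density.

* **Units.** Published per-grade tables are ambiguous between per-field and
  per-case units. `summarize_by_grade()` reduces each case to the mean of
  its 10 field counts first, then summarises across cases — avoiding
  pseudo-replication of fields within a case. Standard deviations use the
  sample (n−1) denominator; a single-case grade reports `NA`.
* **Tests.** The published comparisons concern independent groups of
  unequal size (45 vs 22 cases), so tests are unpaired; the default is the
  Welch unequal-variance t-test with Welch–Satterthwaite degrees of
  freedom, with the classical pooled Student test as an option.
  `ttest_summary()` computes them directly from (n, mean, sd) so published
  summary tables can be re-tested without raw data; on raw data it agrees
  with `stats::t.test()` exactly.
* **Multiplicity.** No correction by default, mirroring the published
  analysis; `pairwise_grade_tests(p_adjust = ...)` enables Holm or
  Bonferroni.
* **Known inconsistency.** The published per-histotype grade cells do not
  sum to the printed grade totals (grade I cells sum to 50, total printed
  45). The totals row (45/34/22) is treated as authoritative for grade
  distributions; the discrepancy is reported, not resolved.

### The synthetic IHC generator

`ihc_config()` parameterises per-field counts per grade and marker by mean
and SD (the form in which the reference summaries are published). Fields
are drawn i.i.d. from a normal truncated below at 0, rounded to integers; a
negative-binomial option exists for overdispersed counts. Two consequences
are documented rather than hidden:

* Truncation at 0 biases the realised mean upward when mean/SD is small
  (about +0.7 cells at mean 6, SD 4.24); moment-convergence tests use
  configurations where the truncation mass is negligible.
* Because cases are summarised by their field means, across-case SDs in
  `summarize_by_grade()` shrink by ≈ √10 relative to the configured
  per-field SD. The generator reproduces configured *per-field* moments;
  between-case heterogeneity is not modelled. Grade separation achieved on
  synthetic cohorts is therefore easier than in real data, and passing
  tests validate the computation, not the biology.

Histotype labels are sampled from the empirical 101-case frequencies so
that generated cohorts exercise `aggregate_histotype_grade()` realistically.

## Problem sizes and determinism

Every simulation is driven by one seed per call (no global RNG state is
leaked), and identical configuration + seed reproduce byte-identical
outputs, including the TSV artifacts of `run_pipeline()`. The shipped
validation uses: convergence checks at 50,000 reports; de-duplication
ground truth at ~10⁴ rows; signal recovery at 3 × 20,000 reports × 200
replicates; IHC moment checks at 300–400 cases per grade. These sizes keep
the full suite under a minute while leaving Monte-Carlo error well inside
the asserted 3-standard-error bounds.

## Limitations

* The PRR is a reporting-disproportionality measure, not a risk estimate;
  no confidence intervals are provided (none are used by the signal rule).
* Other disproportionality statistics (ROR, EBGM, IC) are out of scope.
* The MedDRA hierarchy is modelled as flat PT/SOC labels.
* The deterministic duplicate key is a reproducible surrogate for manual
  curation, with the over-collapse behaviour described above.
* Serum reference summaries rest on 4 animals per grade; the NLR/PLR
  helpers propagate no uncertainty.
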