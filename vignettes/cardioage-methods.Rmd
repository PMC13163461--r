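---
title: "Estimating biological cardiovascular age from structured coronary CTA reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating biological cardiovascular age from structured coronary CTA reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardioage)
```

## The problem

Chronological age is the strongest conventional predictor of cardiovascular
risk, yet two 60-year-olds with the same risk-factor profile can carry very
different coronary disease burdens. A coronary CT angiography (CTA) report
already quantifies that burden: the Agatston calcium score (CAC), the
CAD-RADS stenosis severity category, high-risk anatomy, and left-ventricular
function. `cardioage` turns those report metrics into a *biological
cardiovascular age* (BioAGE) — an age in years at which the observed disease
burden would be typical — and evaluates how well that score discriminates
major adverse cardiovascular events (MACE: death, myocardial infarction,
late revascularization) against chronological age.

Because clinical report corpora cannot be redistributed, the package is
built around a synthetic cohort generator that emulates the cohort profile
of a single-centre symptomatic population (n = 346 included of 386
uploaded), so the entire pipeline — report text, parsing, scoring,
ROC evaluation — runs end-to-end with no external data.

## The scoring model

BioAGE is an additive points system on top of a CAC-based base age:

$$\mathrm{BioAGE} = 39 + 0.1 \cdot \mathrm{CAC} + \sum_k \Delta_k$$

with year increments $\Delta_k$ for:

| rule | default years |
|---|---|
| CAD-RADS 2 / 3 / 4a / 4b / 5 | +5 / +10 / +15 / +20 / +20 |
| multivessel disease (LAD, RCA and CX all > 50%) | +15 |
| proximal LAD lesion > 70% | +10 |
| soft plaque confined to RCA/CX | +5 |
| LVEF < 50% or elevated EDV/ESV (once) | +10 |
| any extracoronary finding (aortic ectasia/aneurysm, ...; once) | +5 |

Design choices where the framework leaves room:

* **Additive composition.** The worked reference case (CAC 215.3 AU,
  CAD-RADS 3, LVEF 77%) yields 39 + 21.53 + 10 = 70.53, displayed as
  71 years — consistent with base-plus-increments and inconsistent with
  averaging the components; `compose_bioage()` therefore adds.
* **CAD-RADS 4a/4b printed as a +15–20 range** resolve to 4a = +15,
  4b = +20; category 5 (occlusion, unstated) = +20, keeping the mapping
  monotone. Category 1 adds nothing.
* **Increments stack** across rule families; the per-rule ledger in every
  `bioage_estimate` makes the policy auditable, and every increment is
  configurable through `scoring_config()`.
* **Unstated magnitudes.** The EDV/ESV elevation thresholds (200 mL, 90 mL)
  and the extracoronary increment (+5) have no published values; the
  defaults are package choices, documented as such.
* **Display rounding** is nearest integer with halves away from zero; all
  statistics use the continuous total, so rounding never affects an AUC.
* **Plausibility bounds** default to [25, 105] years: they exclude the
  canonical failure examples (17 and 123 years) and contain the plausible
  published score range (39–95). Totals outside the bounds are excluded
  from evaluation but still count in the success-rate denominator.

A known limitation: the zero-burden case (CAC 0, CAD-RADS 0, LVEF 77%)
yields exactly 39 under this framework, while the reference description of
that case reports 42.5 years — evidence that the original LLM-based
estimator pooled components beyond its stated rule list. The rule list, not
that unexplained value, is what this package implements.

## Rule-based parsing instead of an LLM

The original extraction step was a commercial LLM at an unstated version
and temperature; `cardioage` replaces it with a deterministic lexicon
parser (`parse_report()`), because the downstream analysis depends on the
extracted metrics, not on the extractor's identity — and determinism makes
every number in this package reproducible. The parser applies, in order:
locale detection (keyword voting), CAC extraction, CAD-RADS extraction,
clause-level anatomy rules, LV function, extracoronary findings. A report
is *parsed* only when all three key metrics (CAC, CAD-RADS, LVEF) are
found; otherwise it fails with a typed reason (`missing_cac`,
`malformed_number`, `missing_cadrads`, `ambiguous_phrasing`,
`missing_function`), prioritized in the order a reader would re-query a
report. Numeric handling accepts decimal commas (always, when unambiguous)
and strips dot-grouped thousands separators under the German locale
("1.204,5" reads as 1204.5). When several CAD-RADS tokens appear, the
maximum category wins, mirroring per-vessel reporting conventions.
`matched_spans` records where in the text each field was found, the
package's analogue of senior-reader supervision: an audit trail instead of
a modeled reader.

## The synthetic cohort

`cohort_config()` defaults *are* the emulated study conditions:

* chronological age ~ Normal(58.5, 10.8²) truncated to [25, 81];
  39.6% women;
* CAD-RADS marginals 20.2 / 15.9 / 31.2 / 16.7 / 15.9%, with the lumped
  "4+5" share split 8.0 / 5.0 / 2.9% across 4a / 4b / 5 (a
  monotone-decreasing severity split; the source table does not separate
  them);
* CAC: zero-inflated log-normal per CAD-RADS stratum with log-means
  monotone in category, scaled at construction so E[CAC] = 108.6 AU
  analytically, hard-capped at 24,328 AU. The printed SD (263) is
  internally inconsistent with that maximum at n = 346 and is deliberately
  not matched;
* LVEF ~ Normal(69.7, 9.7²) truncated to [23, 86] (truncated mean 68.7; an
  optional `lvef_shift_cadrads4plus` models functional impairment in
  obstructive disease and defaults to 0 so the marginal stays at the
  published profile); EDV sex-specific, ESV derived as EDV·(1 − LVEF/100);
* high-risk plaque prevalence 25.4%;
* follow-up ~ Normal(4.2, 1.2²) truncated to [2, 6] years — the published
  4.2 ± 2.8 cannot live inside its own 2–6 year collection window, so the
  SD is shrunk to fit;
* MACE: a binary logistic model on the *true* BioAGE (matching the binary
  ROC evaluation; no competing risks or hazard realism — the event time is
  only used for censoring mechanics), event types fixed at the published
  2:5:22 death/MI/revascularization composition. The slope default 0.035
  per year is calibrated so the population AUC of true BioAGE for MACE is
  ≈ 0.77 with chronological age near 0.58 — the discrimination the score is
  meant to emulate; the intercept auto-calibrates by root-finding so the
  expected event rate equals `target_event_rate` (0.087).

Severity coupling uses a Gaussian copula: a latent atherosclerosis severity
correlated with age (ρ = 0.35) is cut at the category quantiles, so the
CAD-RADS (and high-risk plaque, ρ = 0.5) marginals are exact by
construction while severity still rises with age. This is why the
calibration tests can demand marginals within ±0.01 at n = 50,000.

Report text is rendered from templates (three phrase variants per section,
chosen deterministically by `style_seed`; German locale uses decimal
commas, RIVA/RCX vessel synonyms) under a round-trip contract:
`parse_report(render_report(m))` recovers `m` exactly at the declared
formatting precision (1 decimal). `inject_failures()` rewrites a seeded
subset with the documented failure modes (CAD-RADS token deleted,
stenosis phrased only as "Einengung"-style synonyms, calcium section
deleted). The default text-failure rate is 0.052: the emulated study's
10.4% total failure rate decomposes into half text-level failures and half
implausible scores, and the generator's heavy CAC tail produces the
implausible half (≈4–5%) by itself.

What the generator does **not** emulate: real report free text (negation,
typos, layout), between-reader style drift, informative censoring,
competing risks, or any correlation between parse failures and disease
severity. Passing tests therefore show that the method is implemented
correctly and behaves as designed under the emulated conditions — not that
the parser would achieve a 90% success rate on another hospital's corpus.

## Evaluation

`auc()` is the Mann–Whitney c-statistic (ties 0.5) computed via midranks;
`auc_ci_and_test()` adds the DeLong structural-components variance, a Wald
95% CI truncated to [0, 1] and a two-sided test of AUC = 0.5. The original
analysis names only a statistics product, not a CI method; DeLong is the
field-standard nonparametric choice, and its finite-sample size is itself
verified by simulation in the test suite (rejection rate within 5% ± 2%
over 3,000 null replicates with ≈30 events in 346; the test is mildly
liberal at that event count, with a true size near 6%). The p-values are read as tests against
chance discrimination (AUC = 0.5), the reading consistent with the
published non-significant chronological-age result.

Deviation statistics summarize |BioAGE − chronological age| (mean, SD,
median, IQR with linearly interpolated quantiles) plus the signed split —
the published deviation summaries are only coherent for absolute
deviations with the sign split reported separately, and that is what
`deviation_stats()` emits.

`batch_consistency()` evaluates cumulative prefixes of the cohort
(the published batch sizes 94, 149, 252, 346 are cumulative, although the
text calls them four separate groups; a disjoint-group mode is available
via `cumulative = FALSE`). Prefixes with a single outcome class are
flagged undefined rather than failing the whole table.

## The pipeline

`run_pipeline()` chains simulate → parse → score → evaluate. Excluded
records are retained with a typed `inclusion_status`, and the manifest
identities hold exactly on every run:

```
included = uploaded − parse failures − implausible scores
success_rate = included / uploaded
```

Outputs (`write_outputs()`) are a per-patient CSV with a fixed, documented
column order (`patient_csv_columns()`), an evaluation-summary JSON, a
manifest JSON and a plain-text log; cohorts travel as JSONL plus a
ground-truth CSV (`write_cohort()` / `read_cohort_jsonl()`). Everything is
deterministic given the configuration seed (the manifest timestamp is the
single intentionally non-reproducible field). A thin command-line wrapper
over these functions ships in `inst/cli/cardioage.R`.

```{r pipeline, eval = FALSE}
res <- run_pipeline(run_config(
  cohort = cohort_config(n_patients = 386, seed = 1),
  batch_sizes = c(94, 149, 252, 346)
))
res
```

## Problem sizes and numerical choices

The test suite exercises the oracle equivalences at 500 random AUC
datasets (n ≤ 30, exhaustive pair counting), 10,000 random metric sets
against a brute-force rule evaluator, 1,000 random metric sets × 2 locales
× 3 template styles for the parser round trip, 100 seeded cohorts of
n = 346 for signal recovery, 50,000-patient cohorts for marginal
calibration, and 3,000 null replicates for the test's type-I error —
sizes chosen so Monte-Carlo error is small relative to each tolerance.
Other numerical choices: truncated-normal draws use the inverse-CDF (so
the age uniform doubles as the copula's Gaussian age signal), the
auto-calibration root-find runs `uniroot` to tolerance 1e-10 on [−200,
200], display rounding is half-away-from-zero, and degenerate DeLong
variances (perfect separation) yield p = 0 with a point CI rather than an
error.
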