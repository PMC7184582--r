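---
title: "Case definitions, partial recording protocols and their performance: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Case definitions, partial recording protocols and their performance: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perioprp)
```

This vignette is the package's account of its science: the two case
definitions as implemented, the decisions taken where their published
wording is ambiguous, the performance battery, the synthetic-data model
and its calibration, and what the package's tests do and do not
demonstrate about real survey data.

## Data model

A chart collection is a long tibble with one row per (participant, tooth,
site). The analysed dentition is the 28 permanent teeth excluding third
molars, in FDI codes; each tooth has six probing sites (MB, B, DB, ML, L,
DL) carrying probing pocket depth (PPD) and clinical attachment loss
(CAL) in integer millimetres, with `NA` for a missing measurement —
distinct from 0 mm. Absent teeth keep their six rows with all-`NA`
measurements, so every participant occupies exactly 168 rows and round
trips through the CSV interchange format losslessly. NHANES-style sources
numbered in the Universal system are converted with `universal_to_fdi()`;
third molars map to an exclusion marker and are dropped on input.

Eligibility mirrors surveillance practice: age ≥ 30 years, no medical
exclusion from the periodontal exam, dentate, and complete periodontal
status. The published exclusion "non-complete periodontal status" is not
defined by its source; this package reads it as *every present tooth has
all six sites measured for both PPD and CAL*, which is what a completed
full-mouth protocol produces. The reading is deliberately strict and is
configurable (`require_complete = FALSE`) for partially recorded sources.
Participants failing several criteria are attributed, in the flow report,
to the first applicable reason in the fixed order age, medical exclusion,
incomplete status, edentulous.

## The two case definitions

Both engines are pure functions of (chart, site selector, parameters);
only measured sites inside the selector are consulted, and a missing
measurement never satisfies any criterion.

**2012 CDC/AAP (surveillance definition).** Interproximal sites only
(MB, DB, ML, DL):

* *severe*: ≥ 2 interproximal sites with CAL ≥ 6 mm on ≥ 2 distinct
  teeth **and** ≥ 1 interproximal site with PPD ≥ 5 mm;
* *moderate*: ≥ 2 interproximal sites with CAL ≥ 4 mm on ≥ 2 distinct
  teeth **or** ≥ 2 interproximal sites with PPD ≥ 5 mm on ≥ 2 distinct
  teeth;
* *mild*: ≥ 2 interproximal sites with CAL ≥ 3 mm **and** (≥ 2
  interproximal sites with PPD ≥ 4 mm on ≥ 2 distinct teeth or ≥ 1 site
  with PPD ≥ 5 mm);
* *none* otherwise. Stages are coded 0–3; a case is stage ≥ 1.

The "not on the same tooth" qualifier attaches to the thresholds exactly
as in the original definition: the mild rule's CAL pair may sit on one
tooth, its PPD ≥ 4 pair may not.

**2018 EFP/AAP.** A participant is a case when

* (a) interdental CAL is detectable at ≥ 2 **non-adjacent** teeth, or
* (b) at ≥ 2 teeth a mid (buccal/oral) site shows CAL ≥ 3 mm together
  with PPD > 3 mm at that same site.

Staging reads interdental CAL at the site of greatest loss: 1–2 mm mild,
3–4 mm moderate, ≥ 5 mm severe (stages III and IV are collapsed into
"severe", as the four-level surveillance coding requires).

Three clauses needed interpretation; each is a parameter or a documented
fixed choice:

* *Detectable interdental CAL* (pathway a) carries no printed threshold.
  The default is ≥ 1 mm, the smallest measurable loss on a whole-mm
  chart and the lower edge of the stage-1 band; `detectable_cal_mm`
  raises it.
* *Adjacency* is anatomical: two teeth are adjacent iff they occupy
  consecutive positions in their arch's sequence (right second molar
  through left second molar), regardless of whether intervening teeth
  are present. The central incisors across the midline are adjacent;
  teeth in different arches never are. This makes the predicate a fixed
  property of tooth coordinates rather than of each mouth.
* *Pathway (b) with no measurable interdental CAL* would otherwise leave
  a case unstaged; such cases are staged mild, preserving the invariant
  `is_case ⇔ stage ≥ 1`. Pathway (b) requires CAL and PPD at the *same
  site*, the stricter of the two possible readings.

Both engines are existential in the observed sites, hence monotone: if a
selector `S` is a subset of `T`, a case under `S` is a case under `T` and
its stage cannot decrease. Two consequences are load-bearing for the
analysis design. First, the full-mouth diagnosis is a well-defined
reference standard. Second, a partial protocol can never produce a false
positive against that reference, so its specificity is exactly 1. The
published comparison this package re-implements prints specificities
slightly below 100%, which cannot arise from monotone rule engines
evaluated on site subsets of the same examination; the mechanism behind
those cells is not described and is deliberately not imitated.

## Partial recording protocols

`make_protocol()` builds the five named full-mouth PRPs: the six Ramfjord
index teeth (16, 21, 24, 36, 41, 44) and the ten CPITN index teeth (17,
16, 11, 26, 27, 36, 37, 31, 46, 47), each on six-site circumferential
inspection; and MB-B, MB-B-DB and MB-B-DL site triples on all 28 teeth.
Missing index teeth contribute no evidence — classical CPITN substitution
rules are out of scope. Custom selectors support sensitivity analyses,
and protocols serialise to JSON for audit.

## Performance battery

All presence-level indicators are computed literally from the 2×2 table
of protocol diagnosis versus full-mouth reference. Design choices:

* *Empty denominators*: an indicator whose denominator is zero (e.g.
  sensitivity with no reference positives) is `NA`, never 0, and `NA`
  propagates through the evaluation tables.
* *Proportion CIs* are Wilson score intervals, chosen for stability at
  the extreme proportions (≈ 100%) that arise here. The DOR interval
  follows the log-scale formula `log DOR ± z·√(1/TP+1/TN+1/FP+1/FN)`,
  with the Haldane–Anscombe +0.5 correction to all four cells when any
  cell is zero (flagged in the output). Youden and AUC bounds are
  combined from the Wilson bounds of sensitivity and specificity; F1
  uses a Wilson interval with effective denominator TP + (FP+FN)/2; MCC
  uses the Fisher z transform. The published tables print CIs without
  naming methods, so these are package choices, stated here for
  auditability; no numerical comparison in the tests depends on them.
* *DOR scale*: the battery reports both `dor` and `log10_dor`. In the
  published table this package mirrors, the row labelled "DOR" is
  numerically consistent with log₁₀(DOR) implied by the printed
  sensitivity/specificity pairs (e.g. Se 87.1 / Sp 78.5 implies
  DOR ≈ 24.7 and log₁₀ ≈ 1.39, the printed value), not with DOR itself;
  exposing both scales lets either be checked.
* *Hard-label binary AUC*: a hard-label classifier yields a three-point
  ROC polygon whose trapezoidal area is (Se+Sp)/2 exactly; the package
  computes it as such, and one published AUC cell inconsistent with its
  own row's (Se+Sp)/2 is treated as unexplained rather than targeted.
* *Multiclass staging AUC*: the Hand–Till construction — the unweighted
  mean over unordered stage pairs, present in the reference, of the
  pairwise AUC restricted to that pair. With hard ordinal labels as
  scores, the pairwise AUC is the tie-corrected Mann–Whitney statistic;
  when predictions are binary within a pair it reduces exactly to the
  (Se+Sp)/2 of the pair's 2×2 table. Stage labels are ordinal, but no
  distance between stages enters the statistic. The implementation is
  cross-checked in the tests against an independent pairwise enumeration
  and against `pROC::multiclass.roc` on ordinal predictions.
* *Per-stage precision* is one-vs-rest positive predictive value of each
  predicted stage; the 2012 → 2018 staging cross-tab is emitted as a 4×4
  matrix plus a long edge list suitable for alluvial tools.

## Synthetic population model

The generator emulates the structure — not the demographics — of a
full-mouth surveillance examination, so the pipeline is exercised
end-to-end without survey data:

* a latent severity class per participant (`healthy`/`mild`/`moderate`/
  `severe`), default mixture 0.45/0.20/0.20/0.15;
* tooth retention: each of the 28 teeth is lost independently with
  probability `tooth_loss_base` (0.05) plus a class increment (0, 0.05,
  0.10, 0.25) — more severe disease, fewer teeth;
* site CAL: class mean plus a shared per-tooth Gaussian effect plus
  independent site noise (total SD 1.2 mm, half the variance in the
  tooth effect), rounded half-up to integer mm and truncated at 0. Class
  means (−2.0, 1.2, 2.8, 5.0 mm) are means of the latent Gaussian before
  truncation; the negative healthy mean encodes "mostly no measurable
  loss". With these defaults, at n = 2000 all four full-mouth 2012
  severity classes occur with frequency ≥ 5% (needed to exercise the
  multiclass AUC), full-mouth 2012 prevalence is ≈ 53% and 2018
  prevalence ≈ 74% — the 2018 definition's detectable-CAL rule flags
  most mouths with any interdental loss, as it does in adult survey
  populations;
* site PPD: `0.6·CAL` plus a pocket offset (mean 1.2, SD 0.8 mm),
  rounded and truncated to `[0, CAL + 3]` — pockets track attachment
  loss but cannot exceed it by more than a biologically plausible cap;
* optional missingness (`missing_rate`, default 0) blanks measured
  sites to exercise the incomplete-status screen.

The latent class only drives generation. Ground truth for every
performance number is the full-mouth rule-based diagnosis, mirroring the
use of the full-mouth examination as reference standard in the analysis
this package re-implements.

What the synthetic model does *not* emulate: demographic structure,
examiner effects and calibration drift, localized (single-sextant)
disease patterns, and the site-level spatial correlation of real mouths
beyond the shared tooth effect. Passing tests on synthetic data therefore
demonstrate correctness of the rules, the selectors and the metric layer
— e.g. sensitivities observed under each PRP on this generator are higher
than those published for NHANES, whose disease is more localized; the
package makes no claim of reproducing survey-level estimates, which would
require the survey data itself.

## Numerical and scale choices

Measurements are integers; all rule thresholds compare integers, so no
tolerance enters the engines. The strict CSV reader rejects non-integer
millimetre values; the lenient reader rounds half-up (the generator
rounds the same way). Classification and evaluation are deterministic and
invariant to row order; the generator is bit-reproducible from (config,
seed), with every stochastic step inside one seeded block.

Test and example problem sizes are chosen to keep the default suite
fast while leaving no branch unexercised: oracle equivalence against an
independently written brute-force rule checker runs on 10,000 random
small charts (≤ 6 teeth, the size at which exhaustive pair enumeration is
cheap); monotonicity and perfect-reference properties run on a
2,000-chart synthetic population, the same size used by the acceptance
script; the calibration check recovers the generator's realized
full-mouth 2018 prevalence across independent seeds within an exact
binomial 99% interval at n = 2000.

## Known limitations

* The 2018 implementation excludes grading (A–C), extent, the stage
  III/IV distinction and tooth-loss-based staging criteria — none enter
  the four-level surveillance comparison.
* Specificity of a PRP against its own full-mouth reference is 1 by
  construction (monotonicity); published sub-100% specificities for the
  same design are not reproducible from the stated rules, and the
  package reports the monotone result.
* Confidence intervals for Youden, F1, MCC and AUC are pragmatic
  constructions (above), not delta-method or bootstrap intervals.
* Score-based ROC curves, DeLong variance, survey weights and
  between-AUC hypothesis tests are out of scope.
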