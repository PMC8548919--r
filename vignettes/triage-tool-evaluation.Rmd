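---
title: "Evaluating major-incident triage tools against an intervention-based reference standard"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating major-incident triage tools against an intervention-based reference standard}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triageval)
```

## The problem

When a major incident produces more casualties than the available medical
resources can treat, first responders apply a *primary triage tool*: a
short, physiology-based decision algorithm that sorts casualties into
priority categories — P1 (Immediate: needs time-critical major
resuscitative or surgical intervention), P2 (Urgent), P3 (Delayed),
Expectant, and Dead. Children are a hard case: their normal vital signs
are age-dependent, so adult thresholds misfire, and dedicated paediatric
tools (the UK Paediatric Triage Tape, the US JumpSTART) add complexity of
their own.

A tool's worth is measured by how well it identifies the children who
actually needed a time-critical life-saving intervention (LSI). Because
real major incidents cannot be instrumented, trauma-registry populations
are used as surrogates: each registry child is assigned a *reference*
category from the interventions they actually received (Lerner's
consensus criteria, extended with paediatric fluid-resuscitation
measures), every tool is replayed against the child's first recorded
pre-hospital physiology, and tool-predicted P1 status is scored against
intervention-based P1 status.

`triageval` implements that whole design as a tested pipeline: a registry
data model, eleven tools encoded as declarative ordered-check rules, the
intervention-based reference classifier, the diagnostic-accuracy
statistics, and — because registry data are confidential — a synthetic
cohort generator so every stage is exercisable end-to-end.

## The surrogate mapping

Registries do not record the field observations the tools ask for, so
tool inputs are derived from recorded physiology by fixed surrogate
rules:

* all registry patients are assumed **non-ambulatory** (they were
  conveyed to hospital), so "walking" is always false and no tool can
  emit P3;
* **breathing** is false when a pre-hospital advanced airway was placed
  or the respiratory rate is below 4 /min (undetectable in the field);
* a **palpable radial pulse** is SBP ≥ 60 mmHg under 12 years, ≥ 90 mmHg
  from 12 years;
* GCS ≤ 8 is **unconscious**; GCS < 12 is **unresponsive to voice**;
  GCS-motor 6 means **obeys commands**; GCS-motor ≤ 3 maps to
  JumpSTART's "inappropriate response / unresponsive" branch;
* **catastrophic haemorrhage** (the opening check of BCD, MPTT-24 and
  NARU) has no registry surrogate; the check is *skipped*, implemented as
  a three-valued predicate whose `NA` result passes control to the next
  check;
* **capillary refill > 2 s** (MIMMS, NARU, START, PTT) is proxied by the
  absent-radial-pulse surrogate. This is a deliberate design choice — the
  least-assumption perfusion bridge — and it is isolated in a single
  derived flag so an alternative mapping is a one-line change.

## The rule engine

Each tool is an ordered list of `(predicate, outcome)` checks with a
default outcome, shipped in `inst/extdata/tools.yaml` and interpreted by
a small vectorised engine (`apply_tool()`). First match wins; ties cannot
arise. Encoding the trees as data rather than code makes every resolution
of an ambiguous published step explicit and overridable. Two resolutions
deserve note:

* sieve-family tools (BCD, MIMMS, NARU, MPTT, MPTT-24, START, MSTART,
  PTT, CareFlight) map "not breathing after airway opening" to Dead;
* JumpSTART's apnoea sequence (open airway, pulse check, five rescue
  breaths) is unobservable in a registry and collapses to: apnoeic and
  pulseless → Dead; apnoeic with a pulse → P1.

The PTT estimates thresholds from the child's length. Registries record
age, not tape length, so length is estimated from a bundled median
length-for-age table and mapped to the PTT's bands; the band thresholds
are transcribed from the published PTT reference card (the study this
package operationalises prints none) and live in the same YAML file.

The engine is verified against eleven independently hand-written
reference implementations (plain nested conditionals in the test suite)
on a boundary-dense discretized grid of roughly 750,000 physiology
combinations covering every threshold and both sides of it. A separate
reachability test constructs assessments directly (including walking
casualties and assessable catastrophic haemorrhage) and confirms every
branch of every tool can fire.

## The reference standard

A patient is reference-P1 when any of eight LSI criteria is met, each an
event kind with a time window anchored at ED arrival (minutes; negative =
pre-hospital): advanced airway within 4 h (pre-hospital counts),
haemorrhage-controlling / neurological / vascular surgery to head, neck
or torso within 4 h, chest tube within 2 h, limb-conserving surgery on a
pulseless limb within 4 h, IV vasopressors within 2 h, CPR within 4 h
(pre-hospital counts), escharotomy within 2 h, and "arrived in ED with
uncontrolled haemorrhage". The last is proxied paediatrically by a fluid
bolus of 20 ml/kg within an hour of arrival and/or any blood products
within that hour. Weight is estimated from sex-specific WHO medians up to
12 months and the field formula (age + 2) × 4 kg above.

Numerical choices, each configurable in `gold_standard_config()`:

* windows are **closed** at the stated bound ("within 2 h" admits an
  event at exactly 120 min);
* the fluid-bolus window is `[0, 60]` min — it is anchored at *arrival in
  ED*, so pre-hospital fluids do not count (unlike the airway and CPR
  windows, which explicitly include the pre-hospital phase);
* bolus volumes inside the window are **summed** by default (registries
  split boluses); `bolus_mode = "single"` restores one-event semantics;
* the weight formula uses completed years, the convention for that
  formula.

Dead and Expectant have no printed registry mapping, so both are
injectable predicates. The defaults — Dead: no recordable physiology
(RR 0, SBP 0, GCS 3) plus in-hospital death; Expectant: in-hospital death
with length of stay ≤ 2 days — are chosen to reproduce the published
outcome profile of those categories (universal mortality; Expectant
median LOS 1 day) and are documented as stand-ins. Precedence is total:
Dead > Expectant > P1 > P2; P3 is unreachable on registry cohorts, whose
inclusion criteria exclude minor injuries.

## The synthetic registry

Real registry data are confidential, so the generator
(`generate_cohort()`) is a first-class module whose defaults *are* the
study conditions: sex, age-subgroup, injury-type, mechanism and
reference-category proportions as listed in `generator_config()`, and an
LSI mix for P1 patients (airway-dominated, multiplicity 73.2% / 21.8% /
5.0% for one / two / three-plus criteria) matching the published
intervention ledger.

Construction guarantees **label recovery**: an intended-P1 record
receives at least one qualifying event placed strictly inside its
window; an intended-P2 record receives either no events or deliberate
decoys (events just outside their windows, boluses below threshold) that
must not qualify; Dead/Expectant records satisfy whatever death rules
the active reference configuration uses. `assign_category()` therefore
recovers the intended label for 100% of records — the central
cross-module test, asserted exactly at n = 10,000.

Free parameters the study does not constrain were fixed once and
documented here:

* physiology is drawn from age-conditional normal ranges (bundled
  APLS-style reference table) with category-conditional derangement —
  P1/Expectant/Dead get lower GCS, SBP pushed below the radial-pulse
  threshold with elevated probability, RR pushed outside 12–23 — so
  tools have non-trivial discriminative power. Only the *ordering* (P1
  more deranged than P2) is load-bearing for the tests; the shift sizes
  are stated config, not estimates of registry joint distributions.
* ISS cannot follow a single continuous law: the published summary has
  lower quartile = median = 9, the signature of a large atom at ISS 9
  (one AIS-3 injury). The generator therefore uses category-conditional
  discrete mixtures with an atom at 9, tuned to the published
  per-category medians/IQRs; the n = 10,000 cohort reproduces overall
  median 9 with lower quartile 9.
* Expectant length of stay is drawn from {1, 2} days so the default
  Expectant rule (death with LOS ≤ 2) recovers the label; the published
  Expectant IQR reaches 3 days, a known tension with the stand-in rule
  that disappears under a user-supplied rule.
* missingness injection is MCAR by default, with an `age_biased` mode
  (younger children more likely selected) mirroring the observation that
  excluded registry patients were younger.

What passing tests on this generator do **not** show: that the tools'
measured sensitivities on synthetic cohorts estimate their registry
sensitivities. The synthetic physiology-intervention joint distribution
is invented; the pipeline's correctness claims (engine equivalence, label
recovery, identity preservation, marginal calibration) are the tested
properties, not the clinical numbers.

## Statistics

Performance against the binary P1 standard: sensitivity, specificity,
under-triage = 100 − sensitivity, over-triage = 100 − PPV, and the
single-operating-point trapezoidal AUC — the area under the polyline
(0,0) → (1 − specificity, sensitivity) → (1,1), which reduces to
(sensitivity + specificity)/2 and is asserted against numeric
trapezoidal integration to 1e-12. Confidence intervals for proportions
use Newcombe's continuity-corrected Wilson score method (lower bound
exactly 0 at k = 0, upper exactly 1 at k = n). AUC comparison uses
DeLong's paired structural-components variance, verified against a
brute-force O(n²) kernel enumeration for n ≤ 30; with binary predictors
ties dominate and the function warns accordingly. Group contrasts
delegate to base R (chi-squared, Fisher exact, two-sample KS), with
Mood's median test composed as a 2×2 chi-squared on above/below the
pooled median, and Bonferroni adjustment over the mechanisms present for
the post-hoc mechanism cells (the family size is a documented choice:
the published analysis does not state one).

Two denominator policies are exposed because the published analysis does
not state how Dead/Expectant patients enter tool-performance
denominators: `p1_vs_p2_only` (default; they are dropped) and
`p1_vs_all_nonp1` (they count as gold-negative). With under 1% of
patients in those categories the difference is below printed precision.

Reports are stratified over: all < 16 years, all < 12, and the four
four-year subgroups, with half-open bounds (age 4.0 belongs to 4–<8).
PTT rows are computed only on its applicable ages (< 12 years); for all
other tools the four subgroup confusion matrices must sum to the overall
matrix, an identity `verify_bundle()` re-checks on every emitted bundle
along with the under-triage and AUC closed forms.

## Worked example

```{r example, eval = FALSE}
cfg <- run_config(
  mode = "synthetic",
  generator = generator_config(n_patients = 10000, seed = 1,
                               missingness_rate = 0),
  out_dir = "triageval-report")
bundle <- run_pipeline(cfg)
verify_bundle(bundle)

perf <- bundle$performance_primary
subset(perf, stratum == "<16",
       select = c(tool, sensitivity, specificity, under_triage,
                  over_triage, auc))
```

Problem sizes used throughout the package's own checks: the engine
equivalence grid is ~750,000 assessments; label recovery, marginal
calibration and report identities are asserted at n = 10,000; the
missing-data exclusion fraction at the full registry size n = 15,133.

## Limitations

* The Dead/Expectant reference rules are stand-ins behind a config seam.
* The capillary-refill and PTT-length surrogates are package choices
  where the published methods are silent; both are isolated in config.
* Synthetic cohorts calibrate marginals, not joint distributions; tool
  rankings on synthetic data are not evidence about real populations.
* The pipeline evaluates P1 prediction only; P3-level over-triage
  dynamics are out of scope, as are chemical/biological/radiological/
  nuclear criteria and the SALT and ASAV tools, which cannot be applied
  retrospectively to registry data.
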