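# triageval

Evaluation of major-incident (mass-casualty) primary triage tools in
children, against an intervention-based reference standard.

## What it does, and for whom

When casualties outnumber resources, first responders run a triage
sieve — a short physiology-based algorithm — to label each casualty
P1 (Immediate), P2 (Urgent), P3 (Delayed), Expectant or Dead. Which
sieve should a health system adopt for children? `triageval` is for
researchers and planners who answer that question with trauma-registry
data. It provides:

* **Eleven triage tools as data, not prose** — BCD Triage Sieve,
  CareFlight, JumpSTART, MIMMS Triage Sieve, MPTT, MPTT-24, MSTART,
  NARU Triage Sieve, Paediatric Triage Tape (PTT), RAMP and START —
  encoded as ordered `(predicate, outcome)` checks in a YAML registry,
  executed by a small first-match-wins engine, and verified against
  independent hand-coded references over an exhaustive discretized
  physiology grid.
* **Registry surrogates**: fixed mappings from recorded physiology to
  the field observations tools ask for (non-ambulatory assumption,
  RR < 4 = not breathing, SBP thresholds for the radial pulse, GCS 8/12
  consciousness thresholds, GCS-motor 6 = obeys commands).
* **An intervention-based reference standard** (Lerner's criteria with
  paediatric extensions): P1 = any of eight time-critical life-saving
  interventions within its window (advanced airway or CPR within 4 h
  including pre-hospital, torso/head/neck surgery within 4 h, chest
  tube, vasopressors or escharotomy within 2 h, limb-conserving surgery
  on a pulseless limb within 4 h, uncontrolled haemorrhage at arrival —
  proxied by a 20 ml/kg fluid bolus or blood products within an hour).
* **Diagnostic accuracy statistics**: sensitivity, specificity,
  under-triage (100 − sensitivity), over-triage (100 − PPV),
  single-operating-point trapezoidal AUC = (sensitivity +
  specificity)/2, Newcombe continuity-corrected Wilson intervals,
  DeLong's paired AUC comparison, chi-squared / Fisher / Mood's median /
  Kolmogorov-Smirnov group contrasts, stratified over four-year age
  subgroups.
* **A synthetic registry generator** so the entire pipeline is testable
  without confidential data: configured marginals (69.5% male, 27.1%
  reference-P1, ISS median 9 with an atom at 9, ...), age-conditional
  physiology with category-conditional derangement, and intervention
  timelines constructed so the reference classifier recovers the
  intended category of every record exactly.

## Worked example

```r
library(triageval)

cfg <- run_config(
  mode = "synthetic",
  generator = generator_config(n_patients = 10000, seed = 1),
  out_dir = "triageval-report")
bundle <- run_pipeline(cfg, quiet = TRUE)
verify_bundle(bundle)   # re-checks AUC/under-triage/aggregation identities

perf <- subset(bundle$performance_primary, stratum == "<16",
               select = c(tool, sensitivity, specificity, under_triage,
                          over_triage, auc))
perf[, 2:5] <- round(perf[, 2:5], 1); perf$auc <- round(perf$auc, 3)
print(perf, row.names = FALSE)
```

```
       tool sensitivity specificity under_triage over_triage   auc
        BCD        74.9        55.1         25.1        61.0 0.650
 CareFlight        65.4        89.3         34.6        29.8 0.774
  JumpSTART        69.7        85.6         30.3        34.9 0.776
      MIMMS        54.6        85.0         45.4        41.6 0.698
       MPTT        77.6        45.8         22.4        64.5 0.617
     MPTT24        75.2        54.1         24.8        61.4 0.646
     MSTART        68.5        83.5         31.5        38.5 0.760
       NARU        68.9        77.9         31.1        45.5 0.734
        PTT        60.3        82.6         39.7        42.6 0.715
       RAMP        68.5        89.3         31.5        28.9 0.789
      START        68.5        83.5         31.5        38.5 0.760
```

Each row is one tool replayed against every eligible child's first
pre-hospital physiology and scored against intervention-based P1
status on this synthetic cohort. Sensitivity is the percentage of
reference-P1 children the tool flags P1; under-triage is its
complement (missed children needing time-critical intervention);
over-triage is the share of tool-P1 calls that were not reference-P1;
the AUC column is the single-operating-point value (sensitivity +
specificity)/2 on the 0–1 scale. The PTT row is computed on under-12s
only, its applicable range. Note these numbers characterise the
synthetic cohort — the generator calibrates marginals, not the real
joint distribution of physiology and intervention — so they validate
the machinery, not clinical rankings.

The reference-category outcome table from the same run
(`bundle$gold_table$table`) shows the expected gradient — on this
cohort P1 children had 60.7% ICU admission and median ISS 17 versus
8.6% and ISS 9 for P2 — and `bundle$gold_table$p1_vs_p2` carries the
chi-squared / Mood's median contrasts.

A thin command-line wrapper is included:

```sh
Rscript inst/cli/triage-eval.R simulate --n 10000 --seed 1 --out cohort.csv
Rscript inst/cli/triage-eval.R run --n 10000 --seed 1 --out report/
Rscript inst/cli/triage-eval.R verify --bundle report/
```

## Package layout

* `R/cohort.R` — data model, CSV I/O, validation, eligibility filter,
  age subgroups
* `R/tools.R` — surrogate derivation, rule engine, PTT bands
* `R/gold.R` — weight estimation, LSI criteria, category assignment
* `R/performance.R` — confusion metrics, Wilson CC, trapezoidal AUC,
  DeLong, group tests
* `R/simulate.R` — synthetic registry generator, missingness injection
* `R/compare.R`, `R/pipeline.R` — cohort contrasts, stratified reports,
  end-to-end pipeline and bundle verifier
* `inst/extdata/` — tool definitions (YAML), WHO infant weight medians,
  length-for-age medians, paediatric vitals reference (all plain text)
* `vignettes/triage-tool-evaluation.Rmd` — the methods account: model,
  assumptions, parameter choices, limitations
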