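# Declarative definitions of the 11 major-incident primary triage tools.
#
# Each tool is an ordered list of checks; the first check whose predicate
# evaluates TRUE decides the category, otherwise the default applies.
# A predicate evaluating to NA (e.g. catastrophic haemorrhage, which has no
# registry surrogate and is never assessable) causes that check to be
# skipped. Published step order is preserved; branch outcomes not printed in
# the tools' summary descriptions are resolved from each tool's source
# publication: sieve-family tools map "not breathing after airway opening"
# to Dead; RAMP's "signs of obvious death" is encoded as not breathing AND
# no radial pulse; JumpSTART's apnoea sequence collapses to Dead when
# pulseless and P1 when a pulse is present (rescue-breath response is
# unobservable in a registry).
#
# rr_outside: triggers when rr < lo, or rr > hi (hi_op: gt) / rr >= hi
# (hi_op: ge). Comparators transcribe the printed wording exactly
# ("between 12 and 23" -> lo 12, hi 23 gt; "<10 or >=30" -> lo 10, hi 30 ge).

tools:
  BCD:
    name: Battlefield Casualty Drills Triage Sieve
    applicable_age: [0, 16]
    checks:
      - {predicate: catastrophic_haemorrhage, outcome: P1}
      - {predicate: walking, outcome: P3}
      - {predicate: not_breathing, outcome: Dead}
      - {predicate: not_responds_to_voice, outcome: P1}
      - {predicate: rr_outside, lo: 12, hi: 23, hi_op: gt, outcome: P1}
      - {predicate: hr_above, threshold: 100, op: gt, outcome: P1}
    default: P2

  CareFlight:
    name: CareFlight Triage
    applicable_age: [0, 16]
    checks:
      - {predicate: walking, outcome: P3}
      - predicate: all_of
        of:
          - {predicate: not_obeys_commands}
          - {predicate: not_breathing}
        outcome: Dead
      - {predicate: not_obeys_commands, outcome: P1}
      - {predicate: no_radial_pulse, outcome: P1}
    default: P2

  JumpSTART:
    name: JumpSTART
    applicable_age: [0, 16]
    checks:
      - {predicate: walking, outcome: P3}
      - predicate: all_of
        of:
          - {predicate: not_breathing}
          - {predicate: no_radial_pulse}
        outcome: Dead
      - {predicate: not_breathing, outcome: P1}
      - {predicate: rr_outside, lo: 15, hi: 45, hi_op: gt, outcome: P1}
      - {predicate: no_radial_pulse, outcome: P1}
      - {predicate: jumpstart_mental_immediate, outcome: P1}
    default: P2

  MIMMS:
    name: MIMMS Triage Sieve
    applicable_age: [0, 16]
    checks:
      - {predicate: walking, outcome: P3}
      - {predicate: not_breathing, outcome: Dead}
      - {predicate: rr_outside, lo: 10, hi: 30, hi_op: ge, outcome: P1}
      - {predicate: cap_refill_over_2s, outcome: P1}
    default: P2

  MPTT:
    name: Modified Physiological Triage Tool
    applicable_age: [0, 16]
    checks:
      - {predicate: walking, outcome: P3}
      - {predicate: not_breathing, outcome: Dead}
      - {predicate: rr_outside, lo: 12, hi: 22, hi_op: ge, outcome: P1}
      - {predicate: hr_above, threshold: 100, op: ge, outcome: P1}
      - {predicate: gcs_below, threshold: 14, outcome: P1}
    default: P2

  MPTT24:
    name: Modified Physiological Triage Tool 24
    applicable_age: [0, 16]
    checks:
      - {predicate: catastrophic_haemorrhage, outcome: P1}
      - {predicate: walking, outcome: P3}
      - {predicate: not_breathing, outcome: Dead}
      - {predicate: not_responds_to_voice, outcome: P1}
      - {predicate: rr_outside, lo: 12, hi: 24, hi_op: ge, outcome: P1}
      - {predicate: hr_above, threshold: 100, op: ge, outcome: P1}
    default: P2

  MSTART:
    name: Modified START
    applicable_age: [0, 16]
    checks:
      - {predicate: walking, outcome: P3}
      - {predicate: not_breathing, outcome: Dead}
      - {predicate: rr_outside, hi: 30, hi_op: gt, outcome: P1}
      - {predicate: no_radial_pulse, outcome: P1}
      - {predicate: not_obeys_commands, outcome: P1}
    default: P2

  NARU:
    name: NARU Triage Sieve
    applicable_age: [0, 16]
    checks:
      - {predicate: catastrophic_haemorrhage, outcome: P1}
      # "Are they injured?" is always yes for registry patients and is
      # omitted (it routes uninjured bystanders out of the sieve).
      - {predicate: walking, outcome: P3}
      - {predicate: not_breathing, outcome: Dead}
      - {predicate: unconscious, outcome: P1}
      - {predicate: rr_outside, lo: 10, hi: 30, hi_op: ge, outcome: P1}
      - predicate: any_of
        of:
          - {predicate: hr_above, threshold: 120, op: gt}
          - {predicate: cap_refill_over_2s}
        outcome: P1
    default: P2

  PTT:
    name: Paediatric Triage Tape
    applicable_age: [0, 12]
    checks:
      - {predicate: walking, outcome: P3}
      - {predicate: not_breathing, outcome: Dead}
      - {predicate: rr_outside_band, outcome: P1}
      - {predicate: cap_refill_over_2s, outcome: P1}
      - {predicate: hr_outside_band, outcome: P1}
    default: P2

  RAMP:
    name: Rapid Assessment of Mentation and Pulse
    applicable_age: [0, 16]
    checks:
      - predicate: all_of        # "signs of obvious death"
        of:
          - {predicate: not_breathing}
          - {predicate: no_radial_pulse}
        outcome: Dead
      - {predicate: not_obeys_commands, outcome: P1}
      - {predicate: no_radial_pulse, outcome: P1}
    default: P2

  START:
    name: Simple Triage and Rapid Treatment
    applicable_age: [0, 16]
    checks:
      - {predicate: walking, outcome: P3}
      - {predicate: not_breathing, outcome: Dead}
      - {predicate: rr_outside, hi: 30, hi_op: gt, outcome: P1}
      - {predicate: cap_refill_over_2s, outcome: P1}
      - {predicate: not_obeys_commands, outcome: P1}
    default: P2

# Length-banded normal ranges for the Paediatric Triage Tape. The study
# this package operationalises prints no band thresholds; these are a
# TRANSCRIPTION of the published PTT reference card (normal ranges
# inclusive; outside the range triggers P1). The >140 cm box carries the
# adult sieve thresholds (no bradycardia bound; pulse over 120 triggers).
ptt_bands:
  - {band_id: infant,      length_lo: 50,  length_hi: 80,  rr_lo: 20, rr_hi: 50, hr_lo: 90, hr_hi: 180}
  - {band_id: small_child, length_lo: 80,  length_hi: 100, rr_lo: 15, rr_hi: 40, hr_lo: 80, hr_hi: 160}
  - {band_id: child,       length_lo: 100, length_hi: 140, rr_lo: 10, rr_hi: 30, hr_lo: 70, hr_hi: 140}
  - {band_id: large_child, length_lo: 140, length_hi: 250, rr_lo: 10, rr_hi: 29, hr_lo: 0,  hr_hi: 120}
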