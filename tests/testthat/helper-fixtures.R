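# small hand-built cohort fixtures

make_patient <- function(patient_id = "p1", age_years = 10, sex = "male",
                         rr = 20, hr = 90, sbp = 110, gcs_total = 15,
                         gcs_motor = 6,
                         advanced_airway_prehospital = FALSE,
                         injury_type = "blunt",
                         mechanism = "vehicle_collision", iss = 9,
                         died_in_hospital = FALSE, icu_admission = FALSE,
                         los_days = 5) {
  data.frame(patient_id = patient_id, age_years = age_years, sex = sex,
             rr = rr, hr = hr, sbp = sbp, gcs_total = gcs_total,
             gcs_motor = gcs_motor,
             advanced_airway_prehospital = advanced_airway_prehospital,
             injury_type = injury_type, mechanism = mechanism, iss = iss,
             died_in_hospital = died_in_hospital,
             icu_admission = icu_admission, los_days = los_days,
             stringsAsFactors = FALSE)
}

make_event <- function(patient_id, kind, time_min, volume_ml = NA_real_) {
  data.frame(patient_id = patient_id, kind = kind, time_min = time_min,
             volume_ml = volume_ml, stringsAsFactors = FALSE)
}

small_cohort <- function() {
  patients <- rbind(
    make_patient("a", age_years = 10),
    make_patient("b", age_years = 5, sbp = 55, gcs_total = 7,
                 gcs_motor = 3),
    make_patient("c", age_years = 14, rr = 30, hr = 120)
  )
  events <- rbind(
    make_event("b", "advanced_airway", -10),
    make_event("b", "fluid_bolus", 30, 600)
  )
  triage_cohort(patients, events, provenance = "fixture")
}
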