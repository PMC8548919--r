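#' Reference-standard configuration
#'
#' Configures the intervention-based triage reference standard: the eight
#' Priority-1 life-saving-intervention criteria with their time windows
#' (minutes from ED arrival; windows are closed at the stated bound, and
#' the airway and CPR criteria also count pre-hospital events), the
#' paediatric uncontrolled-haemorrhage extensions (fluid bolus of
#' `fluid_bolus_ml_per_kg` within `haemorrhage_window_min` of arrival,
#' and/or blood products within the same window), and the injectable Dead
#' and Expectant rules. The default Dead rule is no recordable physiology
#' (RR 0, SBP 0, GCS 3) plus in-hospital death; the default Expectant rule
#' is in-hospital death within 2 days' length of stay. Both are explicit
#' stand-ins behind a config seam, since the exact registry mappings for
#' those two categories are a known unknown.
#'
#' @param fluid_bolus_ml_per_kg qualifying bolus volume per estimated kg
#'   (default 20).
#' @param haemorrhage_window_min window for the haemorrhage proxies
#'   (default 60).
#' @param bolus_mode `"sum"` (default: bolus volumes within the window are
#'   summed) or `"single"` (one event must reach the threshold alone).
#' @param dead_rule,expectant_rule predicates `function(patients_df)`
#'   returning a logical vector; `NULL` selects the defaults above.
#' @return object of class `gold_standard_config`.
#' @export
gold_standard_config <- function(fluid_bolus_ml_per_kg = 20,
                                 haemorrhage_window_min = 60,
                                 bolus_mode = c("sum", "single"),
                                 dead_rule = NULL,
                                 expectant_rule = NULL) {
  bolus_mode <- match.arg(bolus_mode)
  criteria <- data.frame(
    criterion_id = c("advanced_airway_4h", "surgery_head_neck_torso_4h",
                     "chest_tube_2h", "limb_surgery_pulseless_4h",
                     "vasopressors_2h", "cpr_4h", "escharotomy_2h"),
    kind = c("advanced_airway", "surgery_head_neck_torso", "chest_tube",
             "limb_conserving_surgery_pulseless", "iv_vasopressors",
             "cpr", "escharotomy"),
    window_min = c(240, 240, 120, 240, 120, 240, 120),
    includes_prehospital = c(TRUE, FALSE, FALSE, FALSE, FALSE, TRUE,
                             FALSE),
    stringsAsFactors = FALSE
  )
  if (is.null(dead_rule)) {
    dead_rule <- function(p) {
      !is.na(p$rr) & p$rr == 0 & !is.na(p$sbp) & p$sbp == 0 &
        !is.na(p$gcs_total) & p$gcs_total == 3 & p$died_in_hospital
    }
  }
  if (is.null(expectant_rule)) {
    expectant_rule <- function(p) p$died_in_hospital & p$los_days <= 2
  }
  structure(
    list(criteria = criteria,
         fluid_bolus_ml_per_kg = fluid_bolus_ml_per_kg,
         haemorrhage_window_min = haemorrhage_window_min,
         bolus_mode = bolus_mode,
         dead_rule = dead_rule,
         expectant_rule = expectant_rule,
         category_precedence = c("Dead", "Expectant", "P1", "P2", "P3")),
    class = "gold_standard_config"
  )
}

P1_CRITERION_IDS <- c(
  "advanced_airway_4h", "uncontrolled_haemorrhage_ed",
  "surgery_head_neck_torso_4h", "chest_tube_2h",
  "limb_surgery_pulseless_4h", "vasopressors_2h", "cpr_4h",
  "escharotomy_2h"
)

#' Estimate body weight from age
#'
#' Infants up to 12 months: sex-specific WHO median weight-for-age (bundled
#' monthly table, month rounded from fractional age). Over 12 months: the
#' field formula (age + 2) x 4 kg with age in completed years.
#'
#' @param age_years ages in `[0, 16)`.
#' @param sex `"male"`/`"female"`, recycled if length 1.
#' @return data.frame with `weight_kg` and `method`
#'   (`"who_lookup"`/`"formula"`).
#' @export
estimate_weight <- function(age_years, sex) {
  if (any(age_years < 0 | age_years >= 16)) {
    stop("domain error: age_years must be in [0, 16)")
  }
  if (length(sex) == 1) sex <- rep(sex, length(age_years))
  who <- utils::read.csv(extdata_path("who_weight_for_age_median.csv"),
                         comment.char = "#")
  infant <- age_years <= 1
  w <- numeric(length(age_years))
  if (any(infant)) {
    month <- pmin(12, pmax(0, round(age_years[infant] * 12)))
    col <- ifelse(sex[infant] == "male", "male_kg", "female_kg")
    w[infant] <- mapply(function(m, cl) who[[cl]][who$month == m],
                        month, col)
  }
  w[!infant] <- (floor(age_years[!infant]) + 2) * 4
  data.frame(weight_kg = w,
             method = ifelse(infant, "who_lookup", "formula"),
             stringsAsFactors = FALSE)
}

# logical matrix (patients x criteria) of satisfied P1 criteria
p1_criteria_matrix <- function(cohort, cfg = gold_standard_config()) {
  p <- cohort$patients
  e <- cohort$events
  if (nrow(e) && any(!(e$kind %in% EVENT_KINDS))) {
    stop("validation error: unknown event kind")
  }
  out <- matrix(FALSE, nrow = nrow(p), ncol = length(P1_CRITERION_IDS),
                dimnames = list(p$patient_id, P1_CRITERION_IDS))
  if (!nrow(e) || !nrow(p)) return(out)
  idx <- match(e$patient_id, p$patient_id)
  for (i in seq_len(nrow(cfg$criteria))) {
    cr <- cfg$criteria[i, ]
    hit <- e$kind == cr$kind & e$time_min <= cr$window_min &
      (cr$includes_prehospital | e$time_min >= 0)
    out[unique(idx[hit]), cr$criterion_id] <- TRUE
  }
  # uncontrolled haemorrhage on ED arrival: explicit flag, OR qualifying
  # fluid bolus volume within the window, OR any blood products within it
  wnd <- cfg$haemorrhage_window_min
  flag <- e$kind == "uncontrolled_haemorrhage_flag"
  blood <- e$kind == "blood_products" & e$time_min >= 0 & e$time_min <= wnd
  haem <- rep(FALSE, nrow(p))
  haem[unique(idx[flag | blood])] <- TRUE
  bolus <- e$kind == "fluid_bolus" & e$time_min >= 0 & e$time_min <= wnd
  if (any(bolus)) {
    threshold <- cfg$fluid_bolus_ml_per_kg *
      estimate_weight(p$age_years, p$sex)$weight_kg
    vol_by_patient <- if (cfg$bolus_mode == "sum") {
      tapply(e$volume_ml[bolus], idx[bolus], sum)
    } else {
      tapply(e$volume_ml[bolus], idx[bolus], max)
    }
    who <- as.integer(names(vol_by_patient))
    haem[who] <- haem[who] | vol_by_patient >= threshold[who]
  }
  out[, "uncontrolled_haemorrhage_ed"] <- haem
  out
}

#' Which Priority-1 criteria does each patient meet?
#'
#' @param cohort a `triage_cohort`.
#' @param cfg a [gold_standard_config()].
#' @return named list (by `patient_id`) of character vectors of satisfied
#'   criterion ids (empty vector = none).
#' @export
meets_p1_criteria <- function(cohort, cfg = gold_standard_config()) {
  m <- p1_criteria_matrix(cohort, cfg)
  apply(m, 1, function(row) P1_CRITERION_IDS[row], simplify = FALSE)
}

#' Assign intervention-based reference triage categories
#'
#' Evaluates the category rules in precedence order: Dead, then Expectant,
#' then P1 if any life-saving-intervention criterion is met, else P2.
#' P3 is unreachable for registry cohorts (registry inclusion criteria
#' guarantee at least moderate injury), mirroring the reference standard's
#' behaviour on such data.
#'
#' @param cohort a `triage_cohort`.
#' @param cfg a [gold_standard_config()].
#' @return factor of categories with levels [TRIAGE_CATEGORIES], named by
#'   `patient_id`.
#' @export
assign_category <- function(cohort, cfg = gold_standard_config()) {
  p <- cohort$patients
  dead <- cfg$dead_rule(p)
  expectant <- cfg$expectant_rule(p) & !dead
  p1 <- rowSums(p1_criteria_matrix(cohort, cfg)) > 0
  out <- rep("P2", nrow(p))
  out[p1] <- "P1"
  out[expectant] <- "Expectant"
  out[dead] <- "Dead"
  out <- factor(out, levels = TRIAGE_CATEGORIES)
  names(out) <- p$patient_id
  out
}

#' Secondary gold standards
#'
#' @param cohort a `triage_cohort`.
#' @param which `"mortality"` (in-hospital death) or `"iss_over_15"`
#'   (ISS strictly greater than 15).
#' @return logical vector named by `patient_id`.
#' @export
secondary_gold <- function(cohort, which = c("mortality", "iss_over_15")) {
  which <- match.arg(which)
  p <- cohort$patients
  out <- if (which == "mortality") p$died_in_hospital else p$iss > 15
  names(out) <- p$patient_id
  out
}

#' Priority-1 criterion breakdown
#'
#' Per-criterion counts among reference-P1 patients plus the
#' multiplicity distribution (how many criteria each P1 patient meets).
#'
#' @param cohort a `triage_cohort`.
#' @param cfg a [gold_standard_config()].
#' @return list with `by_criterion` (data.frame: criterion_id, n,
#'   pct_of_p1) and `multiplicity` (table of criteria counts per P1
#'   patient).
#' @export
p1_criterion_breakdown <- function(cohort, cfg = gold_standard_config()) {
  m <- p1_criteria_matrix(cohort, cfg)
  cat <- assign_category(cohort, cfg)
  m <- m[cat == "P1", , drop = FALSE]
  n_p1 <- nrow(m)
  by_criterion <- data.frame(
    criterion_id = P1_CRITERION_IDS,
    n = colSums(m),
    pct_of_p1 = if (n_p1) 100 * colSums(m) / n_p1 else NA_real_,
    row.names = NULL
  )
  list(by_criterion = by_criterion,
       multiplicity = table(criteria_met = rowSums(m)),
       n_p1 = n_p1)
}
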