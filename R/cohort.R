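#' Construct a triage cohort
#'
#' A cohort bundles one row per patient (demographics, first pre-hospital
#' physiology, injury descriptors and outcomes) with a long-format table of
#' timed intervention events keyed by `patient_id`. Event times are minutes
#' relative to ED arrival; negative times are pre-hospital.
#'
#' @param patients data.frame with columns `patient_id`, `age_years`, `sex`
#'   (`"male"`/`"female"`), `rr`, `hr`, `sbp`, `gcs_total`, `gcs_motor`
#'   (integer physiology, `NA` = missing, zeros are legal values),
#'   `advanced_airway_prehospital` (logical), `injury_type`
#'   (`"blunt"`/`"penetrating"`), `mechanism` (see [MECHANISMS]), `iss`
#'   (0--75), `died_in_hospital`, `icu_admission` (logical), `los_days`.
#' @param events data.frame with columns `patient_id`, `kind` (see
#'   [EVENT_KINDS]), `time_min`, `volume_ml` (`NA` except for
#'   `fluid_bolus`). May have zero rows.
#' @param provenance free-text origin note (source file or generator seed).
#' @param validate run [validate_cohort()] (default `TRUE`).
#'
#' @return An object of class `triage_cohort`: a list with elements
#'   `patients`, `events`, `provenance`.
#' @export
triage_cohort <- function(patients, events = NULL, provenance = "",
                          validate = TRUE) {
  if (is.null(events)) {
    events <- empty_events()
  }
  patients <- as.data.frame(patients, stringsAsFactors = FALSE)
  events <- as.data.frame(events, stringsAsFactors = FALSE)
  missing_cols <- setdiff(PATIENT_COLUMNS, names(patients))
  if (length(missing_cols)) {
    stop("cohort schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  missing_ev <- setdiff(EVENT_COLUMNS, names(events))
  if (length(missing_ev)) {
    stop("events schema error: missing column(s) ",
         paste(missing_ev, collapse = ", "))
  }
  patients <- patients[PATIENT_COLUMNS]
  events <- events[EVENT_COLUMNS]
  rownames(patients) <- NULL
  rownames(events) <- NULL
  obj <- structure(
    list(patients = patients, events = events,
         provenance = as.character(provenance)),
    class = "triage_cohort"
  )
  if (validate) validate_cohort(obj)
  obj
}

empty_events <- function() {
  data.frame(patient_id = character(), kind = character(),
             time_min = numeric(), volume_ml = numeric(),
             stringsAsFactors = FALSE)
}

#' @export
print.triage_cohort <- function(x, ...) {
  cat(sprintf("<triage_cohort> %d patients, %d intervention events\n",
              nrow(x$patients), nrow(x$events)))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  if (nrow(x$patients)) {
    cat(sprintf("  age median %.1f y; %.1f%% male; %.1f%% blunt\n",
                stats::median(x$patients$age_years),
                100 * mean(x$patients$sex == "male"),
                100 * mean(x$patients$injury_type == "blunt")))
  }
  invisible(x)
}

#' Number of patients in a cohort
#' @param cohort a `triage_cohort`.
#' @return integer count.
#' @export
n_patients <- function(cohort) nrow(cohort$patients)

#' Validate cohort invariants
#'
#' Hard errors: duplicated `patient_id`, out-of-range ISS/GCS/LOS, unknown
#' sex/injury-type/mechanism/event-kind levels, `volume_ml` present on a
#' non-bolus event (or absent on a bolus), non-finite event times, event
#' rows whose `patient_id` is not in the patient table. The GCS internal
#' consistency rule (motor <= total - 2, since eye and verbal contribute at
#' least 1 each) is surfaced as a warning only: registries contain
#' inconsistent rows and no cleaning rule is imposed.
#'
#' @param cohort a `triage_cohort`.
#' @return the cohort, invisibly.
#' @export
validate_cohort <- function(cohort) {
  p <- cohort$patients
  e <- cohort$events
  if (anyDuplicated(p$patient_id)) {
    stop("validation error: duplicated patient_id: ",
         paste(unique(p$patient_id[duplicated(p$patient_id)])[1:3],
               collapse = ", "))
  }
  bad_level <- function(x, levels) !is.na(x) & !(x %in% levels)
  checks <- list(
    "sex" = bad_level(p$sex, c("male", "female")),
    "injury_type" = bad_level(p$injury_type, c("blunt", "penetrating")),
    "mechanism" = bad_level(p$mechanism, MECHANISMS),
    "age_years" = !is.na(p$age_years) & p$age_years < 0,
    "iss" = !is.na(p$iss) & (p$iss < 0 | p$iss > 75),
    "gcs_total" = !is.na(p$gcs_total) & (p$gcs_total < 3 | p$gcs_total > 15),
    "gcs_motor" = !is.na(p$gcs_motor) & (p$gcs_motor < 1 | p$gcs_motor > 6),
    "los_days" = !is.na(p$los_days) & p$los_days < 0,
    "rr" = !is.na(p$rr) & p$rr < 0,
    "hr" = !is.na(p$hr) & p$hr < 0,
    "sbp" = !is.na(p$sbp) & p$sbp < 0
  )
  for (nm in names(checks)) {
    if (any(checks[[nm]])) {
      stop("validation error in field '", nm, "' for patient_id ",
           p$patient_id[which(checks[[nm]])[1]])
    }
  }
  inconsistent <- !is.na(p$gcs_motor) & !is.na(p$gcs_total) &
    p$gcs_motor > p$gcs_total - 2
  if (any(inconsistent)) {
    warning(sum(inconsistent),
            " record(s) with gcs_motor > gcs_total - 2 (kept as-is)")
  }
  if (nrow(e)) {
    if (any(bad_level(e$kind, EVENT_KINDS))) {
      stop("validation error: unknown event kind '",
           e$kind[which(bad_level(e$kind, EVENT_KINDS))[1]], "'")
    }
    if (any(!is.finite(e$time_min))) {
      stop("validation error: non-finite event time_min")
    }
    is_bolus <- e$kind == "fluid_bolus"
    if (any(is_bolus & is.na(e$volume_ml))) {
      stop("validation error: fluid_bolus event without volume_ml")
    }
    if (any(!is_bolus & !is.na(e$volume_ml))) {
      stop("validation error: volume_ml on a non-fluid_bolus event")
    }
    orphan <- !(e$patient_id %in% p$patient_id)
    if (any(orphan)) {
      stop("validation error: event for unknown patient_id ",
           e$patient_id[which(orphan)[1]])
    }
  }
  invisible(cohort)
}

#' Read a cohort from CSV
#'
#' Reads the documented cohort CSV dialect (one row per patient) plus an
#' optional companion long-format events CSV. Empty physiology cells become
#' `NA` (explicit missing), never zero; zero is a legal recorded value.
#'
#' @param path path to the patient CSV.
#' @param events_path path to the events CSV, or `NULL` for no events.
#' @param schema_version accepted schema version (currently `"1"`).
#' @return a [triage_cohort()].
#' @export
read_cohort <- function(path, events_path = NULL, schema_version = "1") {
  if (!identical(schema_version, "1")) {
    stop("unsupported schema_version: ", schema_version)
  }
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", na.strings = NULL)
  missing_cols <- setdiff(PATIENT_COLUMNS, names(raw))
  if (length(missing_cols)) {
    stop("cohort schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  num <- function(col, integerish = FALSE) {
    x <- raw[[col]]
    x[x == ""] <- NA_character_
    out <- suppressWarnings(as.numeric(x))
    bad <- !is.na(x) & is.na(out)
    if (any(bad)) {
      stop("row-level validation error: non-numeric '", col,
           "' for patient_id ", raw$patient_id[which(bad)[1]])
    }
    out
  }
  bool <- function(col) {
    x <- toupper(raw[[col]])
    out <- rep(NA, length(x))
    out[x %in% c("TRUE", "T", "1")] <- TRUE
    out[x %in% c("FALSE", "F", "0")] <- FALSE
    bad <- !is.na(raw[[col]]) & raw[[col]] != "" & is.na(out)
    if (any(bad)) {
      stop("row-level validation error: non-logical '", col,
           "' for patient_id ", raw$patient_id[which(bad)[1]])
    }
    out
  }
  patients <- data.frame(
    patient_id = raw$patient_id,
    age_years = num("age_years"),
    sex = raw$sex,
    rr = num("rr"),
    hr = num("hr"),
    sbp = num("sbp"),
    gcs_total = num("gcs_total"),
    gcs_motor = num("gcs_motor"),
    advanced_airway_prehospital = bool("advanced_airway_prehospital"),
    injury_type = raw$injury_type,
    mechanism = raw$mechanism,
    iss = num("iss"),
    died_in_hospital = bool("died_in_hospital"),
    icu_admission = bool("icu_admission"),
    los_days = num("los_days"),
    stringsAsFactors = FALSE
  )
  events <- empty_events()
  if (!is.null(events_path)) {
    if (!file.exists(events_path)) stop("file not found: ", events_path)
    eraw <- utils::read.csv(events_path, stringsAsFactors = FALSE,
                            colClasses = "character", na.strings = NULL)
    missing_ev <- setdiff(EVENT_COLUMNS, names(eraw))
    if (length(missing_ev)) {
      stop("events schema error: missing column(s) ",
           paste(missing_ev, collapse = ", "))
    }
    tm <- suppressWarnings(as.numeric(eraw$time_min))
    vol <- eraw$volume_ml
    vol[vol == ""] <- NA_character_
    events <- data.frame(
      patient_id = eraw$patient_id,
      kind = eraw$kind,
      time_min = tm,
      volume_ml = suppressWarnings(as.numeric(vol)),
      stringsAsFactors = FALSE
    )
  }
  triage_cohort(patients, events, provenance = path)
}

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort()]: missing values become empty cells, logicals
#' become `TRUE`/`FALSE`. Round-trips field-for-field.
#'
#' @param cohort a `triage_cohort`.
#' @param path output path for the patient CSV.
#' @param events_path output path for the events CSV, or `NULL` to skip.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, events_path = NULL) {
  utils::write.csv(cohort$patients, path, row.names = FALSE, na = "")
  if (!is.null(events_path)) {
    utils::write.csv(cohort$events, events_path, row.names = FALSE, na = "")
  }
  invisible(path)
}

#' Subset a cohort by a logical predicate on patients
#'
#' Keeps matching patients together with their events.
#'
#' @param cohort a `triage_cohort`.
#' @param keep logical vector of length `n_patients(cohort)`.
#' @return a `triage_cohort`.
#' @export
subset_cohort <- function(cohort, keep) {
  stopifnot(length(keep) == nrow(cohort$patients))
  p <- cohort$patients[keep, , drop = FALSE]
  e <- cohort$events[cohort$events$patient_id %in% p$patient_id, ,
                     drop = FALSE]
  triage_cohort(p, e, provenance = cohort$provenance, validate = FALSE)
}

#' Apply the study eligibility filter
#'
#' A record is included iff `age_years < 16` and all five required
#' pre-hospital physiology fields (`rr`, `hr`, `sbp`, `gcs_total`,
#' `gcs_motor`) are present; records missing any of them are excluded,
#' as are those aged 16 or over.
#'
#' @param cohort a `triage_cohort`.
#' @return list with elements `included` and `excluded` (both
#'   `triage_cohort`), partitioning the input.
#' @export
eligibility_filter <- function(cohort) {
  p <- cohort$patients
  complete <- rep(TRUE, nrow(p))
  for (f in REQUIRED_PHYSIOLOGY) complete <- complete & !is.na(p[[f]])
  eligible <- complete & !is.na(p$age_years) & p$age_years < 16
  list(
    included = subset_cohort(cohort, eligible),
    excluded = subset_cohort(cohort, !eligible)
  )
}

#' Breakdown of exclusions by missing physiology field
#'
#' Counts, per required physiology field, how many excluded records are
#' missing it (a record missing several fields contributes to each).
#'
#' @param excluded the excluded `triage_cohort` from [eligibility_filter()].
#' @return named integer vector over [REQUIRED_PHYSIOLOGY] plus `age_16_plus`.
#' @export
exclusion_breakdown <- function(excluded) {
  p <- excluded$patients
  out <- vapply(REQUIRED_PHYSIOLOGY, function(f) sum(is.na(p[[f]])),
                integer(1))
  c(out, age_16_plus = sum(!is.na(p$age_years) & p$age_years >= 16))
}

#' Assign the four-year age subgroup
#'
#' Half-open bands `[0,4)`, `[4,8)`, `[8,12)`, `[12,16)`: a boundary age
#' falls in the upper band (age 4.0 is "4-<8").
#'
#' @param age_years numeric vector, each in `[0, 16)`.
#' @return factor with levels [AGE_SUBGROUPS].
#' @export
assign_age_subgroup <- function(age_years) {
  if (any(is.na(age_years)) || any(age_years < 0) || any(age_years >= 16)) {
    stop("domain error: age_years must be in [0, 16)")
  }
  cut(age_years, breaks = c(0, 4, 8, 12, 16), labels = AGE_SUBGROUPS,
      right = FALSE, include.lowest = FALSE)
}
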