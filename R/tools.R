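#' Derive triage-tool inputs from registry records
#'
#' Maps each record's first pre-hospital physiology onto the assessment
#' features the tools consume, using the study's surrogate rules:
#' registry patients are assumed non-ambulatory (`walking` always `FALSE`);
#' a patient with a pre-hospital advanced airway, or a respiratory rate
#' below 4 (undetectable), is `breathing = FALSE`; a palpable radial pulse
#' is SBP >= 60 mmHg under 12 years and >= 90 mmHg at 12 years and over;
#' GCS <= 8 is unconscious and GCS < 12 unresponsive to voice; GCS motor 6
#' means able to obey commands; GCS motor <= 3 maps to JumpSTART's
#' "inappropriate response / unresponsive" immediate branch. Catastrophic
#' haemorrhage has no registry surrogate and is `NA` (unassessable), so
#' checks on it are skipped. Capillary refill over 2 s is proxied by the
#' absent-radial-pulse surrogate (perfusion surrogacy).
#'
#' @param cohort a `triage_cohort` whose records passed
#'   [eligibility_filter()] (all five physiology fields present).
#' @return data.frame, one row per patient: `patient_id`, `age_years`,
#'   `rr`, `hr`, `sbp`, `gcs_total`, `gcs_motor`, and the derived flags
#'   `walking`, `breathing`, `responds_to_voice`, `unconscious`,
#'   `obeys_commands`, `radial_pulse`, `cap_refill_over_2s`,
#'   `jumpstart_mental_immediate`, `catastrophic_haemorrhage` (logical
#'   `NA`).
#' @export
derive_tool_inputs <- function(cohort) {
  p <- cohort$patients
  for (f in REQUIRED_PHYSIOLOGY) {
    if (anyNA(p[[f]])) {
      stop("precondition error: missing '", f, "' for patient_id ",
           p$patient_id[which(is.na(p[[f]]))[1]],
           " (apply eligibility_filter first)")
    }
  }
  radial <- ifelse(p$age_years < 12, p$sbp >= 60, p$sbp >= 90)
  data.frame(
    patient_id = p$patient_id,
    age_years = p$age_years,
    rr = p$rr, hr = p$hr, sbp = p$sbp,
    gcs_total = p$gcs_total, gcs_motor = p$gcs_motor,
    walking = rep(FALSE, nrow(p)),
    breathing = !(p$advanced_airway_prehospital | p$rr < 4),
    responds_to_voice = p$gcs_total >= 12,
    unconscious = p$gcs_total <= 8,
    obeys_commands = p$gcs_motor == 6,
    radial_pulse = radial,
    cap_refill_over_2s = !radial,
    jumpstart_mental_immediate = p$gcs_motor <= 3,
    catastrophic_haemorrhage = rep(NA, nrow(p)),
    stringsAsFactors = FALSE
  )
}

PREDICATE_NAMES <- c(
  "catastrophic_haemorrhage", "walking", "not_breathing",
  "not_responds_to_voice", "unconscious", "not_obeys_commands",
  "no_radial_pulse", "cap_refill_over_2s", "jumpstart_mental_immediate",
  "rr_outside", "hr_above", "gcs_below", "rr_outside_band",
  "hr_outside_band", "all_of", "any_of"
)

#' Load the triage tool registry
#'
#' Parses a YAML tool-definition file (the bundled default encodes all 11
#' tools plus the PTT length bands) into a registry of ordered-check
#' decision algorithms. Errors on a missing tool, an unknown predicate
#' name, an invalid outcome, or malformed PTT bands (bands must tile the
#' supported length range without overlap).
#'
#' @param path path to a tool-definition YAML file; default the bundled
#'   registry.
#' @return object of class `tool_registry`: list with `tools` (named list
#'   of `tool_definition`) and `ptt_bands` (data.frame).
#' @export
load_tool_definitions <- function(path = NULL) {
  if (is.null(path)) path <- extdata_path("tools.yaml")
  spec <- yaml::read_yaml(path)
  if (is.null(spec$tools)) stop("config error: no 'tools' section")
  missing <- setdiff(TOOL_IDS, names(spec$tools))
  if (length(missing)) {
    stop("config error: missing tool(s): ", paste(missing, collapse = ", "))
  }
  validate_check <- function(chk, tool_id) {
    if (is.null(chk$predicate) || !(chk$predicate %in% PREDICATE_NAMES)) {
      stop("config error in ", tool_id, ": unknown predicate name '",
           chk$predicate, "'")
    }
    if (chk$predicate %in% c("all_of", "any_of")) {
      if (!length(chk$of)) {
        stop("config error in ", tool_id, ": empty composite predicate")
      }
      lapply(chk$of, validate_check, tool_id = tool_id)
    }
    invisible(chk)
  }
  tools <- lapply(names(spec$tools), function(id) {
    t <- spec$tools[[id]]
    if (!length(t$checks)) stop("config error in ", id, ": no checks")
    for (chk in t$checks) {
      validate_check(chk, id)
      if (!(chk$outcome %in% TRIAGE_CATEGORIES)) {
        stop("config error in ", id, ": invalid outcome '", chk$outcome, "'")
      }
    }
    if (!(t$default %in% TRIAGE_CATEGORIES)) {
      stop("config error in ", id, ": invalid default outcome")
    }
    structure(
      list(tool_id = id, name = t$name %||% id,
           applicable_age = as.numeric(t$applicable_age),
           checks = t$checks, default_outcome = t$default),
      class = "tool_definition"
    )
  })
  names(tools) <- names(spec$tools)
  bands <- do.call(rbind, lapply(spec$ptt_bands, as.data.frame))
  bands <- bands[order(bands$length_lo), ]
  if (any(bands$length_lo[-1] != bands$length_hi[-nrow(bands)])) {
    stop("config error: PTT bands must tile the length range without ",
         "overlap or gaps")
  }
  structure(list(tools = tools[TOOL_IDS], ptt_bands = bands),
            class = "tool_registry")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.tool_registry <- function(x, ...) {
  cat("<tool_registry>", length(x$tools), "tools:\n")
  for (t in x$tools) {
    cat(sprintf("  %-10s [%g, %g) y, %d checks, default %s\n", t$tool_id,
                t$applicable_age[1], t$applicable_age[2],
                length(t$checks), t$default_outcome))
  }
  invisible(x)
}

# Estimate tape length (cm) from age via the bundled median length-for-age
# reference; linear interpolation, constant beyond the table ends.
estimate_length_cm <- function(age_years) {
  tab <- utils::read.csv(extdata_path("length_for_age_median.csv"),
                         comment.char = "#")
  stats::approx(tab$age_years, tab$length_cm, xout = age_years,
                rule = 2)$y
}

#' PTT length band for a patient age
#'
#' Estimates length from age via the bundled median length-for-age table,
#' then selects the Paediatric Triage Tape band containing that length
#' (band intervals are `[lo, hi)`). Lengths outside the supported range are
#' clamped to the nearest band with a warning.
#'
#' @param age_years ages in years, each `< 12` (PTT applicability).
#' @param registry a `tool_registry` (for the band table); default bundled.
#' @return data.frame of band rows, one per input age.
#' @export
ptt_band_for <- function(age_years, registry = load_tool_definitions()) {
  if (any(age_years >= 12)) {
    stop("precondition error: PTT applies to ages under 12 years")
  }
  bands <- registry$ptt_bands
  len <- estimate_length_cm(age_years)
  idx <- findInterval(len, bands$length_lo)
  if (any(idx == 0)) {
    warning("estimated length below supported range; clamped to first band")
    idx[idx == 0] <- 1
  }
  too_long <- len >= bands$length_hi[nrow(bands)]
  if (any(too_long)) {
    warning("estimated length above supported range; clamped to last band")
    idx[too_long] <- nrow(bands)
  }
  out <- bands[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Evaluate one (possibly composite) predicate over an assessment
# data.frame; returns logical vector with NA meaning "not assessable,
# skip this check". `bands` is the per-row PTT band table or NULL.
eval_predicate <- function(chk, a, bands = NULL) {
  n <- nrow(a)
  switch(chk$predicate,
    catastrophic_haemorrhage = a$catastrophic_haemorrhage,
    walking = a$walking,
    not_breathing = !a$breathing,
    not_responds_to_voice = !a$responds_to_voice,
    unconscious = a$unconscious,
    not_obeys_commands = !a$obeys_commands,
    no_radial_pulse = !a$radial_pulse,
    cap_refill_over_2s = a$cap_refill_over_2s,
    jumpstart_mental_immediate = a$jumpstart_mental_immediate,
    rr_outside = {
      low <- if (!is.null(chk$lo)) a$rr < chk$lo else rep(FALSE, n)
      high <- if (!is.null(chk$hi)) {
        if (identical(chk$hi_op, "ge")) a$rr >= chk$hi else a$rr > chk$hi
      } else rep(FALSE, n)
      low | high
    },
    hr_above = {
      if (identical(chk$op, "ge")) a$hr >= chk$threshold
      else a$hr > chk$threshold
    },
    gcs_below = a$gcs_total < chk$threshold,
    rr_outside_band = {
      if (is.null(bands)) stop("PTT band predicate without band table")
      a$rr < bands$rr_lo | a$rr > bands$rr_hi
    },
    hr_outside_band = {
      if (is.null(bands)) stop("PTT band predicate without band table")
      a$hr < bands$hr_lo | a$hr > bands$hr_hi
    },
    all_of = {
      res <- rep(TRUE, n)
      for (sub in chk$of) res <- res & eval_predicate(sub, a, bands)
      res
    },
    any_of = {
      res <- rep(FALSE, n)
      for (sub in chk$of) res <- res | eval_predicate(sub, a, bands)
      res
    },
    stop("unknown predicate name '", chk$predicate, "'")
  )
}

#' Apply one triage tool to assessments
#'
#' Evaluates the tool's checks in order; the first matching predicate's
#' outcome is returned (first-match-wins), otherwise the default outcome.
#' Checks whose predicate is not assessable (`NA`, e.g. catastrophic
#' haemorrhage on registry surrogates) are skipped. Patients outside the
#' tool's applicable age get `NA` (inapplicable), which is distinct from
#' any triage category.
#'
#' @param tool a `tool_definition` from [load_tool_definitions()].
#' @param assessments data.frame from [derive_tool_inputs()] (or
#'   constructed directly with the same columns).
#' @param registry the `tool_registry` (needed for PTT band lookup).
#' @return character vector of categories (`NA` = inapplicable), named by
#'   `patient_id` when present.
#' @export
apply_tool <- function(tool, assessments,
                       registry = load_tool_definitions()) {
  stopifnot(inherits(tool, "tool_definition"))
  a <- assessments
  n <- nrow(a)
  applicable <- a$age_years >= tool$applicable_age[1] &
    a$age_years < tool$applicable_age[2]
  bands <- NULL
  uses_bands <- any(vapply(tool$checks, function(chk) {
    grepl("_band$", chk$predicate)
  }, logical(1)))
  if (uses_bands) {
    bands <- registry$ptt_bands[rep(1L, n), , drop = FALSE]
    if (any(applicable)) {
      suppressWarnings(
        bands[applicable, ] <- ptt_band_for(a$age_years[applicable],
                                            registry)
      )
    }
  }
  out <- rep(NA_character_, n)
  undecided <- applicable
  for (chk in tool$checks) {
    if (!any(undecided)) break
    trig <- eval_predicate(chk, a, bands)
    fire <- undecided & !is.na(trig) & trig
    out[fire] <- chk$outcome
    undecided <- undecided & !fire
  }
  out[undecided] <- tool$default_outcome
  if (!is.null(a$patient_id)) names(out) <- a$patient_id
  out
}

#' Apply all tools in a registry to a cohort
#'
#' @param cohort an eligible `triage_cohort`.
#' @param registry a `tool_registry`.
#' @return data.frame: `patient_id`, `age_years`, then one character
#'   column per tool (`NA` = tool inapplicable at that age, e.g. PTT at
#'   12 years and over). Deterministic: repeat runs are identical.
#' @export
apply_all_tools <- function(cohort, registry = load_tool_definitions()) {
  a <- derive_tool_inputs(cohort)
  out <- data.frame(patient_id = a$patient_id, age_years = a$age_years,
                    stringsAsFactors = FALSE)
  for (id in names(registry$tools)) {
    out[[id]] <- unname(apply_tool(registry$tools[[id]], a, registry))
  }
  out
}

#' Truth table of a tool over an assessment grid
#'
#' Enumerates a discretized grid of raw physiology, derives assessments
#' and returns the tool's decision for each cell; intended for review and
#' golden-file export of the encoded decision trees.
#'
#' @param tool_id a tool identifier from [TOOL_IDS].
#' @param registry a `tool_registry`.
#' @param ages,rr,hr,sbp,gcs_total,gcs_motor,airway grid margins.
#' @return data.frame of grid cells with a `category` column.
#' @export
tool_truth_table <- function(tool_id, registry = load_tool_definitions(),
                             ages = c(1, 6, 10, 14),
                             rr = c(0, 3, 4, 11, 12, 23, 24, 30, 31, 46),
                             hr = c(60, 100, 101, 121),
                             sbp = c(50, 60, 90),
                             gcs_total = c(3, 8, 11, 12, 14, 15),
                             gcs_motor = c(1, 3, 5, 6),
                             airway = c(FALSE, TRUE)) {
  grid <- expand.grid(age_years = ages, rr = rr, hr = hr, sbp = sbp,
                      gcs_total = gcs_total, gcs_motor = gcs_motor,
                      advanced_airway_prehospital = airway)
  grid$patient_id <- sprintf("g%06d", seq_len(nrow(grid)))
  a <- derive_inputs_from_raw(grid)
  grid$category <- unname(apply_tool(registry$tools[[tool_id]], a, registry))
  grid
}

# derive_tool_inputs over a bare data.frame of raw physiology (no cohort
# wrapper); shared by the truth-table export and grid-based tests.
derive_inputs_from_raw <- function(p) {
  radial <- ifelse(p$age_years < 12, p$sbp >= 60, p$sbp >= 90)
  data.frame(
    patient_id = p$patient_id %||% sprintf("r%06d", seq_len(nrow(p))),
    age_years = p$age_years,
    rr = p$rr, hr = p$hr, sbp = p$sbp,
    gcs_total = p$gcs_total, gcs_motor = p$gcs_motor,
    walking = rep(FALSE, nrow(p)),
    breathing = !(p$advanced_airway_prehospital | p$rr < 4),
    responds_to_voice = p$gcs_total >= 12,
    unconscious = p$gcs_total <= 8,
    obeys_commands = p$gcs_motor == 6,
    radial_pulse = radial,
    cap_refill_over_2s = !radial,
    jumpstart_mental_immediate = p$gcs_motor <= 3,
    catastrophic_haemorrhage = rep(NA, nrow(p)),
    stringsAsFactors = FALSE
  )
}
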