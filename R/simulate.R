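#' Synthetic registry generator configuration
#'
#' Defaults encode the marginal structure of the study cohort this package
#' emulates: 69.5% male; age subgroup weights 9.4 / 15.5 / 25.8 / 49.3%
#' over the four four-year bands; 95.4% blunt injury; mechanism mix
#' dominated by vehicle collisions (49.6%) and low falls (23.9%); intended
#' reference-category mix of 27.1% P1, 0.04% Dead, 0.58% Expectant, the
#' rest P2; ISS tuned to overall median 9, IQR (9, 17). Missingness is off
#' by default (included-cohort fixtures); [inject_missingness()] adds it.
#'
#' @param n_patients cohort size.
#' @param seed integer RNG seed.
#' @param p_male proportion male.
#' @param age_subgroup_weights length-4 proportions over [AGE_SUBGROUPS]
#'   (must sum to 1).
#' @param p_blunt proportion blunt injury.
#' @param mechanism_weights named proportions over [MECHANISMS]
#'   (normalised internally).
#' @param p_p1,p_dead,p_expectant intended category proportions
#'   (`p_p1 + p_dead + p_expectant <= 1`, remainder P2).
#' @param missingness_rate proportion of records given missing physiology
#'   at generation time (default 0).
#' @return object of class `generator_config`.
#' @export
generator_config <- function(n_patients = 1000,
                             seed = 1,
                             p_male = 0.695,
                             age_subgroup_weights =
                               c(0.094, 0.155, 0.258, 0.493),
                             p_blunt = 0.954,
                             mechanism_weights = c(
                               vehicle_collision = 0.496,
                               fall_under_2m = 0.239,
                               fall_over_2m = 0.130,
                               blows = 0.066,
                               stabbing = 0.026,
                               crush = 0.009,
                               shooting = 0.003,
                               blast = 0.001,
                               burn = 0.001,
                               other = 0.030),
                             p_p1 = 0.271,
                             p_dead = 0.0004,
                             p_expectant = 0.0058,
                             missingness_rate = 0) {
  check_prop <- function(x, nm) {
    if (any(is.na(x)) || any(x < 0 | x > 1)) {
      stop("configuration error in field '", nm, "': proportion outside ",
           "[0, 1]")
    }
  }
  if (length(n_patients) != 1 || is.na(n_patients) || n_patients < 0) {
    stop("configuration error in field 'n_patients'")
  }
  check_prop(p_male, "p_male"); check_prop(p_blunt, "p_blunt")
  check_prop(p_p1, "p_p1"); check_prop(p_dead, "p_dead")
  check_prop(p_expectant, "p_expectant")
  check_prop(missingness_rate, "missingness_rate")
  if (length(age_subgroup_weights) != 4 ||
      abs(sum(age_subgroup_weights) - 1) > 1e-9) {
    stop("configuration error in field 'age_subgroup_weights': must be 4 ",
         "proportions summing to 1")
  }
  if (p_p1 + p_dead + p_expectant > 1) {
    stop("configuration error: p_p1 + p_dead + p_expectant > 1")
  }
  if (!setequal(names(mechanism_weights), MECHANISMS)) {
    stop("configuration error in field 'mechanism_weights': must be named ",
         "over the mechanism vocabulary")
  }
  structure(
    list(n_patients = as.integer(n_patients), seed = as.integer(seed),
         p_male = p_male, age_subgroup_weights = age_subgroup_weights,
         p_blunt = p_blunt,
         mechanism_weights = mechanism_weights / sum(mechanism_weights),
         p_p1 = p_p1, p_dead = p_dead, p_expectant = p_expectant,
         missingness_rate = missingness_rate),
    class = "generator_config"
  )
}

# discrete ISS sampler: piecewise weights over blocks of ISS values, with
# the registry's large atom at ISS 9 (single AIS-3 injury pattern)
sample_iss <- function(n, category) {
  blocks <- switch(category,
    P2 = list(w = c(0.15, 0.45, 0.15, 0.10, 0.15),
              v = list(1:8, 9, 10:12, 13:17, 18:45)),
    P1 = list(w = c(0.13, 0.20, 0.15, 0.27, 0.15, 0.10),
              v = list(1:8, 9, 10:16, 17:26, 27:40, 41:66)),
    Expectant = list(w = c(0.25, 0.50, 0.25),
                     v = list(29:38, 39:45, 46:57)),
    Dead = list(w = c(0.5, 0.5), v = list(20:22, 23:26))
  )
  block <- sample.int(length(blocks$w), n, replace = TRUE,
                      prob = blocks$w)
  vapply(block, function(b) {
    vals <- blocks$v[[b]]
    if (length(vals) == 1) vals else sample(vals, 1)
  }, numeric(1))
}

vitals_reference <- function() {
  utils::read.csv(extdata_path("paediatric_vitals_reference.csv"),
                  comment.char = "#")
}

# LSI criterion mix among P1 patients (relative frequencies of the eight
# criteria) and the multiplicity split (one / two / three-plus criteria)
P1_CRITERION_WEIGHTS <- c(
  advanced_airway = 808, haemorrhage = 310, surgery = 169, chest_tube = 70,
  limb_surgery = 23, vasopressors = 6, cpr = 1, escharotomy = 1
)
P1_MULTIPLICITY <- c(`1` = 0.732, `2` = 0.218, `3` = 0.050)

#' Generate a synthetic registry cohort
#'
#' Draws a cohort whose marginals converge to the configured proportions
#' and whose intervention timelines are constructed so that
#' [assign_category()] under the given reference-standard configuration
#' recovers each record's intended category exactly: intended P1 records
#' receive one or more qualifying life-saving interventions inside their
#' time windows (criterion mix and multiplicity follow the configured
#' intervention profile), intended P2 records receive none (possibly
#' decoy events outside the windows or sub-threshold boluses), and
#' Dead/Expectant records satisfy the active death rules. Physiology is
#' age-conditional (bundled reference ranges) with category-conditional
#' derangement: lower GCS, SBP pushed below the radial-pulse surrogate
#' threshold, RR pushed outside normal, for P1/Expectant/Dead.
#'
#' @param config a [generator_config()].
#' @param gold_cfg the [gold_standard_config()] the labels must satisfy.
#' @return list: `cohort` (a `triage_cohort`), `intended` (factor of
#'   intended categories named by patient id).
#' @export
generate_cohort <- function(config = generator_config(),
                            gold_cfg = gold_standard_config()) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_patients
  if (n == 0) {
    empty <- triage_cohort(
      stats::setNames(
        as.data.frame(lapply(PATIENT_COLUMNS, function(x) character(0))),
        PATIENT_COLUMNS),
      provenance = sprintf("synthetic seed=%d n=0", config$seed),
      validate = FALSE)
    return(list(cohort = empty,
                intended = factor(character(0),
                                  levels = TRIAGE_CATEGORIES)))
  }
  set.seed(config$seed)
  ids <- sprintf("SYN%06d", seq_len(n))
  sex <- ifelse(stats::runif(n) < config$p_male, "male", "female")
  subgroup <- sample.int(4, n, replace = TRUE,
                         prob = config$age_subgroup_weights)
  age <- stats::runif(n, c(0, 4, 8, 12)[subgroup],
                      c(4, 8, 12, 16)[subgroup])
  mech <- sample(names(config$mechanism_weights), n, replace = TRUE,
                 prob = config$mechanism_weights)
  # stabbing/shooting are penetrating by definition; the residual
  # penetrating mass (to hit p_blunt exactly in expectation) is carried by
  # the "other" mechanism
  w <- config$mechanism_weights
  p_other_pen <- (1 - config$p_blunt - w[["stabbing"]] -
                    w[["shooting"]]) / w[["other"]]
  p_other_pen <- min(1, max(0, p_other_pen))
  penetrating <- mech %in% c("stabbing", "shooting") |
    (mech == "other" & stats::runif(n) < p_other_pen)
  injury_type <- ifelse(penetrating, "penetrating", "blunt")
  u <- stats::runif(n)
  intended <- ifelse(u < config$p_dead, "Dead",
              ifelse(u < config$p_dead + config$p_expectant, "Expectant",
              ifelse(u < config$p_dead + config$p_expectant + config$p_p1,
                     "P1", "P2")))

  vit <- vitals_reference()
  band <- findInterval(age, vit$age_lo)
  rnorm_pos <- function(mu, sd) pmax(0, round(stats::rnorm(n, mu, sd)))
  rr <- rnorm_pos(vit$rr_mean[band], vit$rr_sd[band])
  hr <- rnorm_pos(vit$hr_mean[band], vit$hr_sd[band])
  sbp <- rnorm_pos(vit$sbp_mean[band], vit$sbp_sd[band])
  gcs <- rep(15L, n)
  sick <- intended %in% c("P1", "Expectant", "Dead")

  # P2 background noise so specificity is below 1 for most tools
  is_p2 <- intended == "P2"
  n_p2 <- sum(is_p2)
  if (n_p2) {
    gcs_p2 <- sample(c(15, 14, 13, 12, 10, 7), n_p2, replace = TRUE,
                     prob = c(0.880, 0.060, 0.030, 0.015, 0.010, 0.005))
    gcs[is_p2] <- gcs_p2
    low_bp <- stats::runif(n_p2) < 0.05
    sbp[is_p2][low_bp] <- pmax(0, round(stats::rnorm(sum(low_bp),
      ifelse(age[is_p2][low_bp] < 12, 52, 80), 6)))
    der_rr <- stats::runif(n_p2) < 0.08
    rr[is_p2][der_rr] <- pmax(4, round(rr[is_p2][der_rr] *
      sample(c(0.45, 1.7), sum(der_rr), replace = TRUE)))
    hi_hr <- stats::runif(n_p2) < 0.12
    hr[is_p2][hi_hr] <- round(hr[is_p2][hi_hr] * 1.35)
  }

  # category-conditional derangement for P1
  is_p1 <- intended == "P1"
  n_p1 <- sum(is_p1)
  if (n_p1) {
    gcs_p1 <- sample(c(3, 5, 7, 8, 10, 11, 13, 14, 15), n_p1,
                     replace = TRUE,
                     prob = c(0.13, 0.08, 0.08, 0.06, 0.08, 0.07, 0.07,
                              0.08, 0.35))
    gcs[is_p1] <- gcs_p1
    shock <- stats::runif(n_p1) < 0.40
    sbp[is_p1][shock] <- pmax(0, round(stats::rnorm(sum(shock),
      ifelse(age[is_p1][shock] < 12, 48, 75), 9)))
    der <- stats::runif(n_p1)
    low <- der < 0.275
    high <- der >= 0.275 & der < 0.55
    rr[is_p1][low] <- sample(0:11, sum(low), replace = TRUE)
    rr[is_p1][high] <- round(rr[is_p1][high] * 1.8)
    hi_hr <- stats::runif(n_p1) < 0.5
    hr[is_p1][hi_hr] <- round(hr[is_p1][hi_hr] * 1.35)
  }

  is_exp <- intended == "Expectant"
  if (any(is_exp)) {
    gcs[is_exp] <- 3L
    rr[is_exp] <- sample(0:8, sum(is_exp), replace = TRUE)
    sbp[is_exp] <- pmax(30, round(stats::rnorm(sum(is_exp), 55, 12)))
    hr[is_exp] <- pmax(0, round(stats::rnorm(sum(is_exp), 150, 25)))
  }
  is_dead <- intended == "Dead"
  if (any(is_dead)) {
    gcs[is_dead] <- 3L
    rr[is_dead] <- 0L
    sbp[is_dead] <- 0L
    hr[is_dead] <- 0L
  }
  gcs <- pmin(15, pmax(3, gcs))
  # motor component consistent with total (motor <= total - 2 holds since
  # round(1 + (gcs-3)*5/12) <= gcs - 2 for gcs in 3..15)
  motor <- round(1 + (gcs - 3) * 5 / 12)
  motor[gcs == 15] <- 6

  died <- rep(FALSE, n)
  died[is_dead | is_exp] <- TRUE
  died[is_p1] <- stats::runif(n_p1) < 0.014
  died[is_p2] <- stats::runif(n_p2) < 0.0008
  icu <- rep(FALSE, n)
  icu[is_dead] <- stats::runif(sum(is_dead)) < 0.5
  icu[is_exp] <- stats::runif(sum(is_exp)) < 0.931
  icu[is_p1] <- stats::runif(n_p1) < 0.602
  icu[is_p2] <- stats::runif(n_p2) < 0.085
  los <- numeric(n)
  los[is_p2] <- stats::rlnorm(n_p2, log(5), 0.75)
  los[is_p1] <- stats::rlnorm(n_p1, log(7), 0.95)
  los[is_exp] <- sample(c(1, 2), sum(is_exp), replace = TRUE,
                        prob = c(0.7, 0.3))
  los[is_dead] <- stats::rlnorm(sum(is_dead), log(11), 0.4)
  # survivors of P1/P2 who died must not satisfy the Expectant rule
  fix <- (is_p1 | is_p2) & died
  los[fix] <- pmax(los[fix], 3)
  los <- round(los, 1)

  iss <- numeric(n)
  for (cat in c("P2", "P1", "Expectant", "Dead")) {
    k <- intended == cat
    if (any(k)) iss[k] <- sample_iss(sum(k), cat)
  }

  ev <- generate_events(ids, age, sex, intended, gold_cfg)
  airway_flag <- ids %in% ev$patient_id[ev$kind == "advanced_airway" &
                                          ev$time_min <= 0]

  # guard: a non-Dead record must never satisfy the default dead rule
  clash <- !is_dead & died & rr == 0 & sbp == 0 & gcs == 3
  sbp[clash] <- 40

  patients <- data.frame(
    patient_id = ids, age_years = age, sex = sex,
    rr = rr, hr = hr, sbp = sbp, gcs_total = gcs, gcs_motor = motor,
    advanced_airway_prehospital = airway_flag,
    injury_type = injury_type, mechanism = mech, iss = iss,
    died_in_hospital = died, icu_admission = icu, los_days = los,
    stringsAsFactors = FALSE
  )
  cohort <- triage_cohort(patients, ev,
                          provenance = sprintf("synthetic seed=%d n=%d",
                                               config$seed, n),
                          validate = FALSE)
  if (config$missingness_rate > 0) {
    cohort <- inject_missingness(cohort, config$missingness_rate,
                                 seed = config$seed + 1L)
  }
  intended <- factor(intended, levels = TRIAGE_CATEGORIES)
  names(intended) <- ids
  list(cohort = cohort, intended = intended)
}

# build the long-format event table for a generated cohort
generate_events <- function(ids, age, sex, intended, gold_cfg) {
  weight <- estimate_weight(age, sex)$weight_kg
  per_kg <- gold_cfg$fluid_bolus_ml_per_kg
  wnd <- gold_cfg$haemorrhage_window_min
  rows <- vector("list", length(ids))
  mult_k <- as.integer(names(P1_MULTIPLICITY))
  for (i in seq_along(ids)) {
    if (intended[i] == "P1") {
      k <- sample(mult_k, 1, prob = P1_MULTIPLICITY)
      picks <- sample(names(P1_CRITERION_WEIGHTS), k,
                      prob = P1_CRITERION_WEIGHTS)
      evs <- lapply(picks, function(pk) {
        switch(pk,
          advanced_airway = list("advanced_airway",
                                 stats::runif(1, -30, 240), NA),
          haemorrhage = {
            sub <- sample(c("flag", "bolus", "blood"), 1)
            if (sub == "flag") {
              list("uncontrolled_haemorrhage_flag", 0, NA)
            } else if (sub == "bolus") {
              list("fluid_bolus", stats::runif(1, 5, wnd),
                   round(per_kg * weight[i] * stats::runif(1, 1.0, 1.6)))
            } else {
              list("blood_products", stats::runif(1, 0, wnd), NA)
            }
          },
          surgery = list("surgery_head_neck_torso",
                         stats::runif(1, 10, 240), NA),
          chest_tube = list("chest_tube", stats::runif(1, 5, 120), NA),
          limb_surgery = list("limb_conserving_surgery_pulseless",
                              stats::runif(1, 10, 240), NA),
          vasopressors = list("iv_vasopressors",
                              stats::runif(1, 0, 120), NA),
          cpr = list("cpr", stats::runif(1, -20, 240), NA),
          escharotomy = list("escharotomy", stats::runif(1, 0, 120), NA)
        )
      })
    } else if (intended[i] == "P2") {
      # decoy events that must NOT qualify: outside windows or below the
      # bolus threshold
      if (stats::runif(1) < 0.15) {
        decoy <- sample(c("late_chest", "late_surgery", "small_bolus",
                          "late_blood", "late_airway"), 1)
        evs <- list(switch(decoy,
          late_chest = list("chest_tube", stats::runif(1, 125, 600), NA),
          late_surgery = list("surgery_head_neck_torso",
                              stats::runif(1, 245, 900), NA),
          small_bolus = list("fluid_bolus", stats::runif(1, 0, wnd),
                             round(per_kg * weight[i] *
                                     stats::runif(1, 0.1, 0.7))),
          late_blood = list("blood_products", stats::runif(1, 65, 300),
                            NA),
          late_airway = list("advanced_airway",
                             stats::runif(1, 245, 600), NA)
        ))
      } else evs <- list()
    } else if (intended[i] == "Expectant") {
      evs <- if (stats::runif(1) < 0.8) {
        list(list("advanced_airway", stats::runif(1, -30, 240), NA))
      } else list()
    } else {
      evs <- if (stats::runif(1) < 0.5) {
        list(list("cpr", stats::runif(1, -20, 240), NA))
      } else list()
    }
    if (length(evs)) {
      rows[[i]] <- data.frame(
        patient_id = ids[i],
        kind = vapply(evs, `[[`, "", 1),
        time_min = round(vapply(evs, function(e) as.numeric(e[[2]]),
                                0), 1),
        volume_ml = vapply(evs, function(e) as.numeric(e[[3]]), 0),
        stringsAsFactors = FALSE
      )
    }
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty_events())
  do.call(rbind, rows)
}

#' Blank physiology fields at random (missing-data injection)
#'
#' Selects each record independently with probability `rate` and blanks
#' one to three of the five required physiology fields, so the record
#' fails the eligibility filter. `mode = "age_biased"` makes younger
#' children more likely to be selected (selection probability scaled by
#' `(16 - age) / 16`, renormalised to the target rate), mirroring the
#' observation that excluded registry patients skew younger.
#'
#' @param cohort a `triage_cohort`.
#' @param rate selection probability in `[0, 1]`.
#' @param seed integer seed (selection is reproducible).
#' @param mode `"mcar"` (default) or `"age_biased"`.
#' @return a new `triage_cohort` with injected missingness.
#' @export
inject_missingness <- function(cohort, rate, seed = 1,
                               mode = c("mcar", "age_biased")) {
  mode <- match.arg(mode)
  if (rate < 0 || rate > 1) stop("rate must be in [0, 1]")
  if (rate == 0) return(cohort)
  p <- cohort$patients
  set.seed(seed)
  prob <- if (mode == "mcar") rep(rate, nrow(p)) else {
    w <- (16 - pmin(p$age_years, 16)) / 16
    pmin(1, rate * w / mean(w))
  }
  hit <- stats::runif(nrow(p)) < prob
  for (i in which(hit)) {
    fields <- sample(REQUIRED_PHYSIOLOGY, sample.int(3, 1))
    p[i, fields] <- NA
  }
  triage_cohort(p, cohort$events,
                provenance = paste0(cohort$provenance,
                                    sprintf(" +missing(rate=%g,seed=%d)",
                                            rate, seed)),
                validate = FALSE)
}

#' Marginal summary of a cohort
#'
#' Counts and percentages for sex, age subgroup, outcome at discharge,
#' injury type and mechanism, plus median (IQR) age and ISS — the layout
#' of a registry characteristics table.
#'
#' @param cohort a non-empty `triage_cohort`.
#' @return list with `counts` (data.frame: variable, level, n, pct) and
#'   `medians` (data.frame: variable, median, q1, q3).
#' @export
summarize_cohort <- function(cohort) {
  p <- cohort$patients
  if (!nrow(p)) stop("precondition error: empty cohort")
  count_block <- function(variable, x, levels) {
    tab <- table(factor(x, levels = levels))
    data.frame(variable = variable, level = names(tab),
               n = as.integer(tab),
               pct = round(100 * as.integer(tab) / nrow(p), 1),
               stringsAsFactors = FALSE)
  }
  in_range <- !is.na(p$age_years) & p$age_years < 16
  counts <- rbind(
    count_block("sex", p$sex, c("male", "female")),
    count_block("age_subgroup",
                as.character(assign_age_subgroup(
                  p$age_years[in_range])),
                AGE_SUBGROUPS),
    count_block("outcome",
                ifelse(p$died_in_hospital, "dead", "alive"),
                c("alive", "dead")),
    count_block("injury_type", p$injury_type, c("blunt", "penetrating")),
    count_block("mechanism", p$mechanism, MECHANISMS)
  )
  qs <- function(x) stats::quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE,
                                    type = 2)
  am <- qs(p$age_years); im <- qs(p$iss)
  medians <- data.frame(
    variable = c("age_years", "iss"),
    median = c(am[2], im[2]), q1 = c(am[1], im[1]), q3 = c(am[3], im[3]),
    row.names = NULL
  )
  list(counts = counts, medians = medians, n = nrow(p))
}
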