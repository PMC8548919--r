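#' Compare included and excluded patients
#'
#' Contrasts the two eligibility strata on demographics and outcomes in
#' the layout of an included-vs-excluded characteristics table: Fisher's
#' exact test for sex, mortality and injury type; two-sample
#' Kolmogorov-Smirnov for age and ISS; an overall chi-squared across
#' injury mechanisms followed, when significant, by per-mechanism post-hoc
#' 2x2 chi-squared tests with Bonferroni adjustment over the mechanisms
#' present. Mechanisms absent from both groups are dropped with a message.
#'
#' @param included,excluded non-empty `triage_cohort`s.
#' @param alpha significance threshold gating the post-hoc tests
#'   (default 0.05).
#' @return list with `overall` (data.frame: variable, test, statistic, p)
#'   and `mechanism_posthoc` (data.frame with Bonferroni-adjusted p per
#'   mechanism; zero rows when the overall test is not significant).
#' @export
compare_included_excluded <- function(included, excluded, alpha = 0.05) {
  pi <- included$patients
  pe <- excluded$patients
  if (!nrow(pi) || !nrow(pe)) {
    stop("precondition error: both groups must be non-empty")
  }
  two_by_two <- function(x_inc, x_exc) {
    rbind(included = table(factor(x_inc, c(FALSE, TRUE))),
          excluded = table(factor(x_exc, c(FALSE, TRUE))))
  }
  rows <- list()
  add <- function(variable, test, res) {
    rows[[length(rows) + 1]] <<- data.frame(
      variable = variable, test = test,
      statistic = res$statistic, p = res$p, stringsAsFactors = FALSE)
  }
  add("sex_male", "fisher",
      group_compare(two_by_two(pi$sex == "male", pe$sex == "male"),
                    kind = "fisher"))
  add("mortality", "fisher",
      group_compare(two_by_two(pi$died_in_hospital, pe$died_in_hospital),
                    kind = "fisher"))
  add("injury_type_blunt", "fisher",
      group_compare(two_by_two(pi$injury_type == "blunt",
                               pe$injury_type == "blunt"),
                    kind = "fisher"))
  add("age_years", "ks",
      group_compare(pi$age_years, pe$age_years, kind = "ks"))
  add("iss", "ks", group_compare(pi$iss, pe$iss, kind = "ks"))

  present <- MECHANISMS[MECHANISMS %in% c(pi$mechanism, pe$mechanism)]
  dropped <- setdiff(MECHANISMS, present)
  if (length(dropped)) {
    message("mechanism level(s) absent from both groups, dropped: ",
            paste(dropped, collapse = ", "))
  }
  mech_tab <- rbind(
    included = table(factor(pi$mechanism, present)),
    excluded = table(factor(pe$mechanism, present))
  )
  mech_overall <- if (length(present) >= 2) {
    group_compare(mech_tab, kind = "chi2")
  } else {
    list(statistic = NA_real_, p = NA_real_)  # single level: no contrast
  }
  add("mechanism", "chi2", mech_overall)
  posthoc <- data.frame(mechanism = character(), statistic = numeric(),
                        p_adjusted = numeric(), stringsAsFactors = FALSE)
  if (!is.na(mech_overall$p) && mech_overall$p < alpha) {
    fam <- length(present)
    posthoc <- do.call(rbind, lapply(present, function(m) {
      res <- group_compare(two_by_two(pi$mechanism == m,
                                      pe$mechanism == m),
                           kind = "chi2")
      data.frame(mechanism = m, statistic = res$statistic,
                 p_adjusted = min(1, res$p * fam),
                 stringsAsFactors = FALSE)
    }))
  }
  list(overall = do.call(rbind, rows), mechanism_posthoc = posthoc)
}

#' Outcome table by reference triage category
#'
#' Per category: n (%), mortality n (%), ICU admission n (%), length of
#' stay and ISS medians with IQR, plus the P1-vs-P2 contrasts (chi-squared
#' for mortality and ICU admission, Mood's median test for ISS and LOS).
#' A category absent from the cohort yields a row with n = 0.
#'
#' @param cohort a `triage_cohort`.
#' @param categories factor from [assign_category()], aligned with the
#'   cohort.
#' @return list with `table` (one row per category) and `p1_vs_p2`
#'   (data.frame: outcome, test, statistic, p).
#' @export
gold_outcome_table <- function(cohort, categories) {
  p <- cohort$patients
  stopifnot(length(categories) == nrow(p))
  qs <- function(x) stats::quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE,
                                    type = 2)
  tab <- do.call(rbind, lapply(TRIAGE_CATEGORIES, function(cat) {
    k <- categories == cat
    n <- sum(k)
    if (n == 0) {
      return(data.frame(category = cat, n = 0, pct = 0,
                        deaths = 0, mortality_pct = NA_real_,
                        icu = 0, icu_pct = NA_real_,
                        los_median = NA_real_, los_q1 = NA_real_,
                        los_q3 = NA_real_, iss_median = NA_real_,
                        iss_q1 = NA_real_, iss_q3 = NA_real_))
    }
    lq <- qs(p$los_days[k]); iq <- qs(p$iss[k])
    data.frame(
      category = cat, n = n, pct = round(100 * n / nrow(p), 2),
      deaths = sum(p$died_in_hospital[k]),
      mortality_pct = round(100 * mean(p$died_in_hospital[k]), 2),
      icu = sum(p$icu_admission[k]),
      icu_pct = round(100 * mean(p$icu_admission[k]), 2),
      los_median = lq[2], los_q1 = lq[1], los_q3 = lq[3],
      iss_median = iq[2], iss_q1 = iq[1], iss_q3 = iq[3],
      row.names = NULL
    )
  }))
  p1 <- categories == "P1"
  p2 <- categories == "P2"
  contrasts <- NULL
  if (any(p1) && any(p2)) {
    mk22 <- function(x) rbind(P1 = table(factor(x[p1], c(FALSE, TRUE))),
                              P2 = table(factor(x[p2], c(FALSE, TRUE))))
    contrasts <- rbind(
      data.frame(outcome = "mortality", test = "chi2",
                 as.data.frame(group_compare(mk22(p$died_in_hospital),
                                             kind = "chi2"))),
      data.frame(outcome = "icu_admission", test = "chi2",
                 as.data.frame(group_compare(mk22(p$icu_admission),
                                             kind = "chi2"))),
      data.frame(outcome = "iss", test = "mood_median",
                 as.data.frame(group_compare(p$iss[p1], p$iss[p2],
                                             kind = "mood_median"))),
      data.frame(outcome = "los_days", test = "mood_median",
                 as.data.frame(group_compare(p$los_days[p1],
                                             p$los_days[p2],
                                             kind = "mood_median")))
    )
  }
  list(table = tab, p1_vs_p2 = contrasts)
}

#' Stratified per-tool performance report
#'
#' One [metrics()] row per tool for each evaluation stratum: overall under
#' 16, overall under 12, and the four four-year age subgroups. Patients
#' for whom a tool is inapplicable (PTT at 12 years and over) are removed
#' from that tool's rows, so the tool is simply absent from strata wholly
#' outside its applicable age. A stratum with no gold-positives yields
#' undefined (NA) sensitivity, flagged in the `degenerate` column.
#'
#' @param predictions data.frame from [apply_all_tools()].
#' @param gold either a factor of reference categories (multi-category
#'   primary standard) or a logical vector (secondary binary standard),
#'   named by or aligned with `predictions$patient_id`.
#' @param policy denominator policy passed to [confusion()].
#' @return data.frame with columns `stratum`, `tool`, the [metrics()]
#'   columns, and `degenerate`.
#' @export
stratified_report <- function(predictions, gold,
                              policy = c("p1_vs_p2_only",
                                         "p1_vs_all_nonp1")) {
  policy <- match.arg(policy)
  if (!is.null(names(gold))) {
    if (!setequal(names(gold), predictions$patient_id)) {
      stop("alignment error: gold and predictions patient sets differ")
    }
    gold <- gold[predictions$patient_id]
  } else if (length(gold) != nrow(predictions)) {
    stop("alignment error: gold and predictions differ in length")
  }
  gold_cat <- if (is.logical(gold)) {
    ifelse(gold, "P1", "P2")  # binary secondary standard
  } else as.character(gold)
  age <- predictions$age_years
  strata <- list(
    "<16" = age < 16,
    "<12" = age < 12,
    "0-<4" = age < 4,
    "4-<8" = age >= 4 & age < 8,
    "8-<12" = age >= 8 & age < 12,
    "12-<16" = age >= 12 & age < 16
  )
  tools <- setdiff(names(predictions), c("patient_id", "age_years"))
  out <- list()
  for (s in names(strata)) {
    for (tl in tools) {
      keep <- strata[[s]] & !is.na(predictions[[tl]])
      if (!any(keep)) next
      cm <- confusion(predictions[[tl]][keep], gold_cat[keep], policy)
      row <- metrics(cm)
      row <- cbind(data.frame(stratum = s, tool = tl,
                              stringsAsFactors = FALSE),
                   row)
      row$degenerate <- row$n_gold_positive == 0 ||
        row$n_gold_negative == 0
      out[[length(out) + 1]] <- row
    }
  }
  do.call(rbind, out)
}
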