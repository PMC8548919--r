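#' Confusion matrix against a binary Priority-1 gold standard
#'
#' "Positive" means category P1 on both axes. Tool predictions other than
#' P1 (including tool-assigned Dead) count as test-negative. How reference
#' Dead/Expectant records enter the denominator is a policy choice:
#' `"p1_vs_p2_only"` drops them entirely, `"p1_vs_all_nonp1"` counts them
#' as gold-negative.
#'
#' @param predicted character/factor of predicted categories, named by
#'   patient id (or unnamed, aligned with `gold`). `NA` (tool inapplicable)
#'   rows must be removed beforehand.
#' @param gold character/factor of reference categories, same patients.
#' @param policy `"p1_vs_p2_only"` (default) or `"p1_vs_all_nonp1"`.
#' @return object of class `confusion_matrix`: list with integer `tp`,
#'   `fp`, `fn`, `tn` and the `policy`.
#' @export
confusion <- function(predicted, gold,
                      policy = c("p1_vs_p2_only", "p1_vs_all_nonp1")) {
  policy <- match.arg(policy)
  np <- names(predicted); ng <- names(gold)
  predicted <- stats::setNames(as.character(predicted), np)
  gold <- stats::setNames(as.character(gold), ng)
  if (length(predicted) != length(gold)) {
    stop("alignment error: predicted and gold differ in length")
  }
  if (!is.null(np) && !is.null(ng)) {
    if (!setequal(np, ng)) {
      stop("alignment error: patient present in one input only: ",
           paste(utils::head(c(setdiff(np, ng), setdiff(ng, np)), 3),
                 collapse = ", "))
    }
    predicted <- predicted[ng]
  }
  if (anyNA(predicted)) {
    stop("predicted contains NA; remove inapplicable records first")
  }
  if (policy == "p1_vs_p2_only") {
    keep <- !(gold %in% c("Dead", "Expectant"))
    predicted <- predicted[keep]
    gold <- gold[keep]
  }
  test_pos <- predicted == "P1"
  gold_pos <- gold == "P1"
  structure(
    list(tp = sum(test_pos & gold_pos), fp = sum(test_pos & !gold_pos),
         fn = sum(!test_pos & gold_pos), tn = sum(!test_pos & !gold_pos),
         policy = policy),
    class = "confusion_matrix"
  )
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> tp=%d fp=%d fn=%d tn=%d (%s)\n",
              x$tp, x$fp, x$fn, x$tn, x$policy))
  invisible(x)
}

#' Diagnostic accuracy metrics from a confusion matrix
#'
#' Sensitivity, specificity, under-triage (100 - sensitivity) and
#' over-triage (100 - positive predictive value), all as percentages, with
#' the single-operating-point AUC as a proportion. Undefined ratios (zero
#' denominators) are returned as `NA` rather than raising division faults.
#'
#' @param cm a `confusion_matrix`.
#' @param conf confidence level for the Wilson intervals (default 0.95).
#' @return one-row data.frame with columns `tp`, `fp`, `fn`, `tn`,
#'   `sensitivity`, `sens_lo`, `sens_hi`, `specificity`, `spec_lo`,
#'   `spec_hi`, `under_triage`, `over_triage`, `auc`, `auc_lo`, `auc_hi`,
#'   `n_gold_positive`, `n_gold_negative`. Percentages on 0--100, AUC on
#'   0--1; AUC interval by the single-predictor DeLong variance.
#' @export
metrics <- function(cm, conf = 0.95) {
  stopifnot(inherits(cm, "confusion_matrix"))
  npos <- cm$tp + cm$fn
  nneg <- cm$fp + cm$tn
  sens <- if (npos > 0) 100 * cm$tp / npos else NA_real_
  spec <- if (nneg > 0) 100 * cm$tn / nneg else NA_real_
  over <- if (cm$tp + cm$fp > 0) 100 * cm$fp / (cm$tp + cm$fp) else NA_real_
  sci <- if (npos > 0) wilson_ci(cm$tp, npos, conf, TRUE) else c(NA, NA)
  cci <- if (nneg > 0) wilson_ci(cm$tn, nneg, conf, TRUE) else c(NA, NA)
  auc <- if (npos > 0 && nneg > 0) {
    auc_trapezoid(sens / 100, spec / 100)
  } else NA_real_
  aci <- c(NA_real_, NA_real_)
  if (npos > 0 && nneg > 0) {
    v <- binary_auc_variance(cm)
    z <- stats::qnorm(1 - (1 - conf) / 2)
    aci <- pmin(1, pmax(0, auc + c(-1, 1) * z * sqrt(v)))
  }
  data.frame(
    tp = cm$tp, fp = cm$fp, fn = cm$fn, tn = cm$tn,
    sensitivity = sens, sens_lo = 100 * sci[1], sens_hi = 100 * sci[2],
    specificity = spec, spec_lo = 100 * cci[1], spec_hi = 100 * cci[2],
    under_triage = if (is.na(sens)) NA_real_ else 100 - sens,
    over_triage = over,
    auc = auc, auc_lo = aci[1], auc_hi = aci[2],
    n_gold_positive = npos, n_gold_negative = nneg
  )
}

# DeLong variance of the AUC of a single binary predictor, in closed form
# from the confusion counts. With 0/1 scores the placement value of a
# positive is (1+sp)/2 when scored 1 and (1-sp)/2 when scored 0 (midrank
# handling of ties), so the structural-component variance over positives is
# se(1-se)*sp^2, and symmetrically over negatives.
binary_auc_variance <- function(cm) {
  m <- cm$tp + cm$fn   # gold positives
  n <- cm$fp + cm$tn   # gold negatives
  se <- cm$tp / m      # P(score=1 | positive)
  sp <- cm$tn / n      # P(score=0 | negative)
  se * (1 - se) * sp^2 / m + sp * (1 - sp) * se^2 / n
}

#' Single-operating-point trapezoidal AUC
#'
#' Area under the ROC polyline through (0,0), (1 - specificity,
#' sensitivity), (1,1), which reduces in closed form to
#' (sensitivity + specificity) / 2.
#'
#' @param sensitivity,specificity proportions in `[0, 1]` (vectorised).
#' @return AUC as a proportion.
#' @export
auc_trapezoid <- function(sensitivity, specificity) {
  if (any(is.na(sensitivity)) || any(is.na(specificity)) ||
      any(sensitivity < 0 | sensitivity > 1) ||
      any(specificity < 0 | specificity > 1)) {
    stop("domain error: sensitivity and specificity must be in [0, 1]")
  }
  (sensitivity + specificity) / 2
}

#' Wilson score interval with continuity correction
#'
#' Newcombe's continuity-corrected Wilson score interval for a binomial
#' proportion. The lower bound is exactly 0 when `successes = 0` and the
#' upper bound exactly 1 when `successes = n`; bounds are clipped to
#' `[0, 1]`.
#'
#' @param successes number of successes, `0 <= successes <= n`.
#' @param n number of trials, positive.
#' @param conf confidence level (default 0.95).
#' @param continuity_correction apply the continuity correction (default
#'   `TRUE`; `FALSE` gives the plain Wilson score interval).
#' @return numeric length-2 vector `c(lower, upper)` on the proportion
#'   scale.
#' @export
wilson_ci <- function(successes, n, conf = 0.95,
                      continuity_correction = TRUE) {
  if (length(n) != 1 || n <= 0) stop("domain error: n must be positive")
  if (successes < 0 || successes > n) {
    stop("domain error: successes must be in [0, n]")
  }
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- successes / n
  if (continuity_correction) {
    lo <- if (successes == 0) 0 else {
      (2 * n * p + z^2 - 1 -
         z * sqrt(z^2 - 2 - 1 / n + 4 * p * (n * (1 - p) + 1))) /
        (2 * (n + z^2))
    }
    hi <- if (successes == n) 1 else {
      (2 * n * p + z^2 + 1 +
         z * sqrt(z^2 + 2 - 1 / n + 4 * p * (n * (1 - p) - 1))) /
        (2 * (n + z^2))
    }
  } else {
    centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
    lo <- centre - half
    hi <- centre + half
  }
  c(max(0, lo), min(1, hi))
}

# midrank-based structural components (positives: V10; negatives: V01)
delong_components <- function(scores, gold_pos) {
  x <- scores[gold_pos]
  y <- scores[!gold_pos]
  m <- length(x); n <- length(y)
  all_r <- rank(c(x, y), ties.method = "average")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  v10 <- (all_r[seq_len(m)] - rx) / n
  v01 <- 1 - (all_r[m + seq_len(n)] - ry) / m
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' DeLong comparison of two paired AUCs
#'
#' Compares the AUCs of two predictors scored on the same patients against
#' the same binary gold standard, using DeLong's structural-components
#' variance for paired ROC curves and a two-sided normal reference for the
#' difference. Binary 0/1 scores are admissible (the AUC then equals
#' (sensitivity + specificity)/2); ties dominate in that case and a warning
#' notes it.
#'
#' @param pred_a,pred_b numeric score vectors (higher = more positive).
#' @param gold logical (or 0/1) gold-positive indicator, both classes
#'   present.
#' @return list with `auc_a`, `auc_b`, `z`, `p`, `var_diff`.
#' @export
delong_compare <- function(pred_a, pred_b, gold) {
  gold <- as.logical(gold)
  if (length(pred_a) != length(gold) || length(pred_b) != length(gold)) {
    stop("alignment error: score and gold lengths differ")
  }
  if (!any(gold) || all(gold)) {
    stop("domain error: gold standard is degenerate (one class only)")
  }
  if (all(pred_a %in% 0:1) && all(pred_b %in% 0:1)) {
    warning("binary scores: DeLong comparison is dominated by ties",
            call. = FALSE)
  }
  ca <- delong_components(pred_a, gold)
  cb <- delong_components(pred_b, gold)
  m <- sum(gold); n <- sum(!gold)
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  d <- ca$auc - cb$auc
  z <- if (d == 0) 0 else if (var_diff <= 0) Inf * sign(d) else {
    d / sqrt(var_diff)
  }
  p <- if (is.infinite(z)) 0 else 2 * stats::pnorm(-abs(z))
  list(auc_a = ca$auc, auc_b = cb$auc, z = z, p = p, var_diff = var_diff)
}

#' Two-group comparison tests
#'
#' The group-difference tests used for cohort contrasts: chi-squared and
#' Fisher's exact test on 2x2 (or larger) contingency tables, Mood's median
#' test (chi-squared on the 2x2 table of counts above vs at-or-below the
#' pooled median), and the two-sample Kolmogorov-Smirnov test. Bonferroni
#' adjustment over post-hoc families is the caller's responsibility.
#'
#' @param x,y for `"mood_median"` and `"ks"`: numeric samples. For
#'   `"chi2"` and `"fisher"`: either two factor-like vectors (tabulated
#'   internally) or `x` a contingency matrix with `y` omitted.
#' @param kind one of `"chi2"`, `"fisher"`, `"mood_median"`, `"ks"`.
#' @return list with `statistic` and `p` (statistic is `NA` for Fisher).
#' @export
group_compare <- function(x, y = NULL,
                          kind = c("chi2", "fisher", "mood_median", "ks")) {
  kind <- match.arg(kind)
  if (kind %in% c("mood_median", "ks")) {
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (!length(x) || !length(y)) stop("domain error: empty group")
  }
  if (kind == "ks") {
    res <- suppressWarnings(stats::ks.test(x, y))
    return(list(statistic = unname(res$statistic), p = res$p.value))
  }
  if (kind == "mood_median") {
    med <- stats::median(c(x, y))
    tab <- rbind(c(sum(x > med), sum(x <= med)),
                 c(sum(y > med), sum(y <= med)))
    if (any(colSums(tab) == 0)) {
      # all observations on one side of the pooled median: no evidence
      return(list(statistic = 0, p = 1))
    }
    res <- suppressWarnings(stats::chisq.test(tab))
    return(list(statistic = unname(res$statistic), p = res$p.value))
  }
  tab <- if (is.matrix(x) || is.table(x)) as.matrix(x) else table(x, y)
  if (any(dim(tab) < 2)) stop("domain error: degenerate contingency table")
  if (kind == "fisher") {
    res <- stats::fisher.test(tab)
    return(list(statistic = NA_real_, p = res$p.value))
  }
  res <- suppressWarnings(stats::chisq.test(tab))
  list(statistic = unname(res$statistic), p = res$p.value)
}
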