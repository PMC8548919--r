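test_that("confusion counts partition the retained set under both policies", {
  gold <- c(rep("P1", 5), rep("P2", 8), "Dead", "Expectant")
  pred <- c(rep("P1", 3), rep("P2", 2), rep("P1", 2), rep("P2", 6),
            "P2", "P1")
  cm <- confusion(pred, gold, "p1_vs_p2_only")
  expect_equal(c(cm$tp, cm$fn, cm$fp, cm$tn), c(3, 2, 2, 6))
  expect_equal(cm$tp + cm$fp + cm$fn + cm$tn, 13)  # Dead/Expectant dropped
  cm2 <- confusion(pred, gold, "p1_vs_all_nonp1")
  expect_equal(cm2$tp + cm2$fp + cm2$fn + cm2$tn, 15)
  expect_equal(cm2$fp, 3)  # the Expectant predicted P1 becomes an FP
  # perfect agreement
  cm3 <- confusion(gold, gold, "p1_vs_all_nonp1")
  expect_equal(c(cm3$fp, cm3$fn), c(0, 0))
  # all gold-P1 predicted P2
  cm4 <- confusion(rep("P2", 10), rep("P1", 10))
  expect_equal(c(cm4$tp, cm4$fn), c(0, 10))
  # named inputs must cover the same patients
  expect_error(confusion(c(a = "P1"), c(b = "P1")), "alignment")
})

test_that("metrics arithmetic and undefined markers", {
  cm <- structure(list(tp = 100, fp = 30, fn = 50, tn = 70,
                       policy = "p1_vs_p2_only"),
                  class = "confusion_matrix")
  m <- metrics(cm)
  expect_equal(m$sensitivity, 100 * 100 / 150)
  expect_equal(round(m$sensitivity, 1), 66.7)
  expect_equal(m$under_triage, 100 - m$sensitivity)
  expect_equal(m$over_triage, 100 * 30 / 130)
  expect_equal(m$auc, (m$sensitivity + m$specificity) / 200)
  # no positive predictions -> over-triage undefined
  cm0 <- structure(list(tp = 0, fp = 0, fn = 5, tn = 5,
                        policy = "p1_vs_p2_only"),
                   class = "confusion_matrix")
  expect_true(is.na(metrics(cm0)$over_triage))
  expect_equal(metrics(cm0)$sensitivity, 0)
})

test_that("single-point trapezoidal AUC equals the closed form and the numeric rule", {
  skip_if_not_installed("pracma")
  cases <- rbind(c(0.404, 0.948), c(0.355, 0.935), c(1, 1), c(0.5, 0.5),
                 c(0, 1), c(0.757, 0.42))
  for (i in seq_len(nrow(cases))) {
    s <- cases[i, 1]; c2 <- cases[i, 2]
    numeric_area <- pracma::trapz(c(0, 1 - c2, 1), c(0, s, 1))
    expect_equal(auc_trapezoid(s, c2), numeric_area, tolerance = 1e-12)
    expect_equal(auc_trapezoid(s, c2), (s + c2) / 2, tolerance = 1e-12)
  }
  expect_error(auc_trapezoid(1.2, 0.5), "domain")
  # label swap: AUC(1-s, 1-c reversed roles) = 1 - AUC
  expect_equal(auc_trapezoid(1 - 0.948, 1 - 0.404),
               1 - auc_trapezoid(0.404, 0.948))
})

test_that("Wilson continuity-corrected interval behaves at boundaries and nests in n", {
  expect_equal(wilson_ci(0, 10)[1], 0)
  expect_equal(wilson_ci(10, 10)[2], 1)
  ci <- wilson_ci(5, 10)
  expect_equal(unname(ci[1] + ci[2]), 1, tolerance = 1e-12)  # symmetric about 0.5
  # contains the point estimate for all 0 < k < n
  for (n in c(7, 24, 311)) {
    for (k in c(1, floor(n / 3), n - 1)) {
      ci <- wilson_ci(k, n)
      expect_lt(ci[1], k / n)
      expect_gt(ci[2], k / n)
    }
  }
  # width shrinks monotonically in n at fixed k/n
  widths <- sapply(c(10, 100, 1000), function(n) {
    diff(wilson_ci(round(0.3 * n), n))
  })
  expect_true(all(diff(widths) < 0))
  # continuity correction widens the plain Wilson interval
  expect_gt(diff(wilson_ci(30, 100, continuity_correction = TRUE)),
            diff(wilson_ci(30, 100, continuity_correction = FALSE)))
  expect_error(wilson_ci(5, 0), "domain")
  expect_error(wilson_ci(11, 10), "domain")
})

test_that("DeLong comparison matches the brute-force structural components oracle", {
  set.seed(42)
  for (rep in 1:6) {
    n <- sample(8:30, 1)
    gold <- c(TRUE, FALSE, runif(n - 2) < 0.45)  # both classes guaranteed
    pred_a <- round(runif(n), 2)
    pred_b <- if (rep %% 2) round(runif(n), 2) else as.numeric(runif(n) < 0.5)
    got <- suppressWarnings(delong_compare(pred_a, pred_b, gold))
    want <- ref_delong(pred_a, pred_b, gold)
    expect_equal(got$auc_a, want$auc_a, tolerance = 1e-12)
    expect_equal(got$auc_b, want$auc_b, tolerance = 1e-12)
    expect_equal(got$var_diff, want$var_diff, tolerance = 1e-10)
  }
})

test_that("DeLong edge cases: identical predictors, perfect and constant", {
  gold <- c(rep(TRUE, 6), rep(FALSE, 10))
  a <- as.numeric(gold)
  res <- suppressWarnings(delong_compare(a, a, gold))
  expect_equal(res$z, 0)
  expect_equal(res$p, 1)
  res2 <- suppressWarnings(delong_compare(a, rep(1, 16), gold))
  expect_equal(res2$auc_a, 1)
  expect_equal(res2$auc_b, 0.5)
  expect_error(delong_compare(a, a, rep(TRUE, 16)), "degenerate")
  expect_warning(delong_compare(a, a, gold), "binary")
  # binary predictor AUC equals (sens + spec) / 2
  pred <- c(1, 1, 1, 0, 0, 0, 1, 1, rep(0, 8))
  sens <- mean(pred[gold] == 1); spec <- mean(pred[!gold] == 0)
  res3 <- suppressWarnings(delong_compare(pred, a, gold))
  expect_equal(res3$auc_a, (sens + spec) / 2)
})

test_that("group comparison tests match their independent definitions", {
  x <- c(1, 2, 3, 4, 5)
  res <- group_compare(x, x, kind = "ks")
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)
  # Fisher on a perfectly separated 2x2: exact hypergeometric value
  res <- group_compare(matrix(c(10, 0, 0, 10), 2), kind = "fisher")
  expect_equal(res$p, 2 * dhyper(10, 10, 10, 10), tolerance = 1e-12)
  expect_lt(res$p, 0.001)
  # Mood's median: equal medians, symmetric counts
  res <- group_compare(c(1, 2, 3, 4, 9), c(1, 2, 3, 4, 9),
                       kind = "mood_median")
  expect_gt(res$p, 0.99)
  # strong location shift is detected
  res <- group_compare(rnorm(200), rnorm(200, 3), kind = "mood_median")
  expect_lt(res$p, 1e-6)
  expect_error(group_compare(numeric(0), x, kind = "ks"), "empty")
})

test_that("stratified report handles degenerate predictors exactly", {
  gen <- generate_cohort(generator_config(n_patients = 400, seed = 5))
  gold <- assign_category(gen$cohort)
  ids <- gen$cohort$patients$patient_id
  base <- data.frame(patient_id = ids,
                     age_years = gen$cohort$patients$age_years,
                     stringsAsFactors = FALSE)
  # perfect predictor
  perfect <- base; perfect$Oracle <- as.character(gold)
  rep1 <- stratified_report(perfect, gold)
  expect_true(all(rep1$sensitivity == 100))
  expect_true(all(rep1$specificity == 100))
  expect_true(all(rep1$auc == 1))
  # constant-P1 predictor
  allp1 <- base; allp1$AllP1 <- "P1"
  rep2 <- stratified_report(allp1, gold)
  expect_true(all(rep2$sensitivity == 100))
  expect_true(all(rep2$specificity == 0))
  expect_true(all(rep2$auc == 0.5))
  # constant-P2 predictor
  allp2 <- base; allp2$AllP2 <- "P2"
  rep3 <- stratified_report(allp2, gold)
  expect_true(all(rep3$under_triage == 100))
  expect_true(all(is.na(rep3$over_triage)))
})
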