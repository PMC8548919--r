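# Independent hand-coded reference implementations of each triage tool,
# written directly as nested conditionals over raw physiology (not via the
# declarative engine). Used as the oracle for engine-equivalence tests.
# Inputs: data.frame d with age_years, rr, hr, sbp, gcs_total, gcs_motor,
# advanced_airway_prehospital. The surrogate mappings are recomputed here
# from first principles: non-ambulatory, breathing unless pre-hospital
# advanced airway or RR < 4, radial pulse at SBP >= 60 (<12 y) / >= 90
# (>= 12 y), unconscious GCS <= 8, voice-responsive GCS >= 12, obeys at
# motor 6, JumpSTART immediate at motor <= 3, capillary refill proxied by
# absent radial pulse, catastrophic haemorrhage never assessable.

ref_surrogates <- function(d) {
  list(
    breathing = !(d$advanced_airway_prehospital | d$rr < 4),
    radial = ifelse(d$age_years < 12, d$sbp >= 60, d$sbp >= 90),
    voice = d$gcs_total >= 12,
    unconscious = d$gcs_total <= 8,
    obeys = d$gcs_motor == 6,
    jump_mental = d$gcs_motor <= 3
  )
}

ref_BCD <- function(d) {
  s <- ref_surrogates(d)
  ifelse(!s$breathing, "Dead",
  ifelse(!s$voice, "P1",
  ifelse(d$rr < 12 | d$rr > 23, "P1",
  ifelse(d$hr > 100, "P1", "P2"))))
}

ref_CareFlight <- function(d) {
  s <- ref_surrogates(d)
  ifelse(!s$obeys & !s$breathing, "Dead",
  ifelse(!s$obeys, "P1",
  ifelse(!s$radial, "P1", "P2")))
}

ref_JumpSTART <- function(d) {
  s <- ref_surrogates(d)
  ifelse(!s$breathing & !s$radial, "Dead",
  ifelse(!s$breathing, "P1",
  ifelse(d$rr < 15 | d$rr > 45, "P1",
  ifelse(!s$radial, "P1",
  ifelse(s$jump_mental, "P1", "P2")))))
}

ref_MIMMS <- function(d) {
  s <- ref_surrogates(d)
  ifelse(!s$breathing, "Dead",
  ifelse(d$rr < 10 | d$rr >= 30, "P1",
  ifelse(!s$radial, "P1", "P2")))
}

ref_MPTT <- function(d) {
  s <- ref_surrogates(d)
  ifelse(!s$breathing, "Dead",
  ifelse(d$rr < 12 | d$rr >= 22, "P1",
  ifelse(d$hr >= 100, "P1",
  ifelse(d$gcs_total < 14, "P1", "P2"))))
}

ref_MPTT24 <- function(d) {
  s <- ref_surrogates(d)
  ifelse(!s$breathing, "Dead",
  ifelse(!s$voice, "P1",
  ifelse(d$rr < 12 | d$rr >= 24, "P1",
  ifelse(d$hr >= 100, "P1", "P2"))))
}

ref_MSTART <- function(d) {
  s <- ref_surrogates(d)
  ifelse(!s$breathing, "Dead",
  ifelse(d$rr > 30, "P1",
  ifelse(!s$radial, "P1",
  ifelse(!s$obeys, "P1", "P2"))))
}

ref_NARU <- function(d) {
  s <- ref_surrogates(d)
  ifelse(!s$breathing, "Dead",
  ifelse(s$unconscious, "P1",
  ifelse(d$rr < 10 | d$rr >= 30, "P1",
  ifelse(d$hr > 120 | !s$radial, "P1", "P2"))))
}

ref_RAMP <- function(d) {
  s <- ref_surrogates(d)
  ifelse(!s$breathing & !s$radial, "Dead",
  ifelse(!s$obeys, "P1",
  ifelse(!s$radial, "P1", "P2")))
}

ref_START <- function(d) {
  s <- ref_surrogates(d)
  ifelse(!s$breathing, "Dead",
  ifelse(d$rr > 30, "P1",
  ifelse(!s$radial, "P1",
  ifelse(!s$obeys, "P1", "P2"))))
}

# PTT: re-reads the bundled length reference directly and re-transcribes
# the band thresholds; NA for age >= 12 (inapplicable).
ref_PTT <- function(d) {
  s <- ref_surrogates(d)
  tab <- read.csv(system.file("extdata", "length_for_age_median.csv",
                              package = "triageval"), comment.char = "#")
  len <- approx(tab$age_years, tab$length_cm, xout = d$age_years,
                rule = 2)$y
  rr_lo <- ifelse(len < 80, 20, ifelse(len < 100, 15, 10))
  rr_hi <- ifelse(len < 80, 50, ifelse(len < 100, 40,
                                       ifelse(len < 140, 30, 29)))
  hr_lo <- ifelse(len < 80, 90, ifelse(len < 100, 80,
                                       ifelse(len < 140, 70, 0)))
  hr_hi <- ifelse(len < 80, 180, ifelse(len < 100, 160,
                                        ifelse(len < 140, 140, 120)))
  out <- ifelse(!s$breathing, "Dead",
         ifelse(d$rr < rr_lo | d$rr > rr_hi, "P1",
         ifelse(!s$radial, "P1",
         ifelse(d$hr < hr_lo | d$hr > hr_hi, "P1", "P2"))))
  out[d$age_years >= 12] <- NA
  out
}

REFERENCE_TOOLS <- list(
  BCD = ref_BCD, CareFlight = ref_CareFlight, JumpSTART = ref_JumpSTART,
  MIMMS = ref_MIMMS, MPTT = ref_MPTT, MPTT24 = ref_MPTT24,
  MSTART = ref_MSTART, NARU = ref_NARU, PTT = ref_PTT, RAMP = ref_RAMP,
  START = ref_START
)

# boundary-dense discretized physiology grid covering every tool threshold
# plus a cell on either side of it
make_physiology_grid <- function(
    rr = c(0, 3, 4, 9, 10, 11, 12, 14, 15, 21, 22, 23, 24, 29, 30, 31,
           40, 45, 46, 60),
    hr = c(0, 79, 80, 99, 100, 101, 120, 121, 160, 180),
    sbp = c(0, 59, 60, 61, 89, 90, 91),
    gcs = c(3, 7, 8, 9, 11, 12, 13, 14, 15),
    motor = 1:6,
    airway = c(FALSE, TRUE),
    ages = c(1, 2.5, 6, 10, 14)) {
  g <- expand.grid(age_years = ages, rr = rr, hr = hr, sbp = sbp,
                   gcs_total = gcs, gcs_motor = motor,
                   advanced_airway_prehospital = airway,
                   KEEP.OUT.ATTRS = FALSE)
  g$patient_id <- sprintf("g%07d", seq_len(nrow(g)))
  g
}

# brute-force O(n^2) DeLong structural-components oracle: explicit
# enumeration of the Mann-Whitney kernel over all positive/negative pairs,
# with loop-computed component variances and covariances
ref_delong <- function(pred_a, pred_b, gold) {
  gold <- as.logical(gold)
  psi <- function(x, y) if (x > y) 1 else if (x == y) 0.5 else 0
  comp <- function(scores) {
    x <- scores[gold]; y <- scores[!gold]
    m <- length(x); n <- length(y)
    v10 <- numeric(m); v01 <- numeric(n)
    for (i in seq_len(m)) {
      acc <- 0
      for (j in seq_len(n)) acc <- acc + psi(x[i], y[j])
      v10[i] <- acc / n
    }
    for (j in seq_len(n)) {
      acc <- 0
      for (i in seq_len(m)) acc <- acc + psi(x[i], y[j])
      v01[j] <- acc / m
    }
    list(v10 = v10, v01 = v01, auc = mean(v10))
  }
  ca <- comp(pred_a); cb <- comp(pred_b)
  m <- sum(gold); n <- sum(!gold)
  cv <- function(u, v) sum((u - mean(u)) * (v - mean(v))) / (length(u) - 1)
  var_diff <-
    (cv(ca$v10, ca$v10) + cv(cb$v10, cb$v10) - 2 * cv(ca$v10, cb$v10)) / m +
    (cv(ca$v01, ca$v01) + cv(cb$v01, cb$v01) - 2 * cv(ca$v01, cb$v01)) / n
  list(auc_a = ca$auc, auc_b = cb$auc, var_diff = var_diff)
}
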