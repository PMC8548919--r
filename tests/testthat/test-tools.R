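test_that("surrogate derivation follows the registry mapping rules", {
  patients <- rbind(
    make_patient("radial_child", age_years = 10, sbp = 65),
    make_patient("radial_teen", age_years = 13, sbp = 65),
    make_patient("apnoeic", rr = 3),
    make_patient("airway", advanced_airway_prehospital = TRUE, rr = 20),
    make_patient("gcs11", gcs_total = 11, gcs_motor = 5),
    make_patient("gcs8", gcs_total = 8, gcs_motor = 3)
  )
  a <- derive_tool_inputs(triage_cohort(patients))
  rownames(a) <- a$patient_id
  expect_false(any(a$walking))
  expect_true(all(is.na(a$catastrophic_haemorrhage)))
  expect_true(a["radial_child", "radial_pulse"])     # SBP 65 >= 60, <12 y
  expect_false(a["radial_teen", "radial_pulse"])     # SBP 65 < 90, >=12 y
  expect_false(a["apnoeic", "breathing"])            # RR < 4 undetectable
  expect_false(a["airway", "breathing"])             # pre-hospital airway
  expect_false(a["gcs11", "responds_to_voice"])      # GCS < 12
  expect_false(a["gcs11", "unconscious"])            # GCS > 8
  expect_true(a["gcs8", "unconscious"])
  expect_true(a["gcs8", "jumpstart_mental_immediate"])  # motor <= 3
  expect_true(a["radial_child", "obeys_commands"])      # motor 6
  expect_identical(a$cap_refill_over_2s, !a$radial_pulse)
  # missing physiology is a precondition violation
  expect_error(
    derive_tool_inputs(triage_cohort(make_patient(rr = NA))),
    "precondition")
})

test_that("tool registry loads, validates, and rejects broken configs", {
  reg <- load_tool_definitions()
  expect_s3_class(reg, "tool_registry")
  expect_setequal(names(reg$tools), TOOL_IDS)
  expect_equal(reg$tools$PTT$applicable_age, c(0, 12))
  expect_equal(reg$tools$BCD$applicable_age, c(0, 16))

  spec <- yaml::read_yaml(system.file("extdata", "tools.yaml",
                                      package = "triageval"))
  broken <- withr::local_tempfile(fileext = ".yaml")
  spec2 <- spec; spec2$tools$START <- NULL
  yaml::write_yaml(spec2, broken)
  expect_error(load_tool_definitions(broken), "START")

  spec3 <- spec
  spec3$tools$BCD$checks[[3]]$predicate <- "levitating"
  yaml::write_yaml(spec3, broken)
  expect_error(load_tool_definitions(broken), "levitating")

  spec4 <- spec
  spec4$ptt_bands[[2]]$length_lo <- 85
  yaml::write_yaml(spec4, broken)
  expect_error(load_tool_definitions(broken), "tile")
})

test_that("single-tool decisions match the published step logic", {
  reg <- load_tool_definitions()
  d <- rbind(
    make_patient("calm", rr = 18, hr = 90),                    # all normal
    make_patient("tachypnoea", rr = 30, hr = 90),
    make_patient("tachycardia", rr = 18, hr = 110),
    make_patient("gcs11", gcs_total = 11, gcs_motor = 5),
    make_patient("child_fast_rr", age_years = 6, rr = 50),
    make_patient("no_motor6", gcs_total = 14, gcs_motor = 5, rr = 25),
    make_patient("apnoea_pulse", rr = 0, sbp = 110),
    make_patient("apnoea_no_pulse", rr = 0, sbp = 40),
    make_patient("apnoea_unresponsive", rr = 0, sbp = 40, gcs_total = 3,
                 gcs_motor = 1)
  )
  a <- derive_tool_inputs(triage_cohort(d, validate = FALSE))
  tool <- function(id) {
    out <- apply_tool(reg$tools[[id]], a, reg)
    names(out) <- d$patient_id
    out
  }
  bcd <- tool("BCD")
  expect_equal(unname(bcd["calm"]), "P2")
  expect_equal(unname(bcd["tachypnoea"]), "P1")   # RR outside 12-23
  expect_equal(unname(bcd["tachycardia"]), "P1")  # HR more than 100
  expect_equal(unname(bcd["gcs11"]), "P1")        # no response to voice
  expect_equal(unname(bcd["apnoea_pulse"]), "Dead")

  cf <- tool("CareFlight")
  expect_equal(unname(cf["calm"]), "P2")          # obeys + radial pulse
  expect_equal(unname(cf["no_motor6"]), "P1")     # does not obey
  # obeying commands short-circuits the breathing check: pulseless -> P1
  expect_equal(unname(cf["apnoea_no_pulse"]), "P1")
  expect_equal(unname(cf["apnoea_unresponsive"]), "Dead")

  js <- tool("JumpSTART")
  expect_equal(unname(js["child_fast_rr"]), "P1") # RR > 45
  expect_equal(unname(js["apnoea_pulse"]), "P1")  # apnoeic with pulse
  expect_equal(unname(js["apnoea_no_pulse"]), "Dead")

  ms <- tool("MSTART")
  expect_equal(unname(ms["no_motor6"]), "P1")     # fails obey-commands
  expect_equal(unname(ms["calm"]), "P2")

  # MPTT flags RR 22 (threshold ">= 22") where BCD (12-23) does not
  rr22 <- derive_tool_inputs(triage_cohort(make_patient(rr = 22)))
  expect_equal(unname(apply_tool(reg$tools$MPTT, rr22, reg)), "P1")
  expect_equal(unname(apply_tool(reg$tools$BCD, rr22, reg)), "P2")
})

test_that("PTT band lookup estimates length from age and clamps", {
  reg <- load_tool_definitions()
  expect_equal(ptt_band_for(0.5, reg)$band_id, "infant")    # ~66 cm
  expect_equal(ptt_band_for(3, reg)$band_id, "small_child") # ~96 cm
  expect_equal(ptt_band_for(8, reg)$band_id, "child")       # ~128 cm
  expect_equal(ptt_band_for(11.8, reg)$band_id, "large_child")
  expect_error(ptt_band_for(13, reg), "under 12")
  # bands tile [50, 250): every age under 12 lands in exactly one band
  bands <- ptt_band_for(seq(0, 11.99, by = 0.1), reg)
  expect_false(anyNA(bands$band_id))
})

test_that("tool application is deterministic and marks inapplicability", {
  co <- generate_cohort(generator_config(n_patients = 150, seed = 2))$cohort
  reg <- load_tool_definitions()
  p1 <- apply_all_tools(co, reg)
  p2 <- apply_all_tools(co, reg)
  expect_identical(p1, p2)
  teen <- p1$age_years >= 12
  expect_true(all(is.na(p1$PTT[teen])))
  expect_false(anyNA(p1$PTT[!teen]))
  for (id in setdiff(TOOL_IDS, "PTT")) expect_false(anyNA(p1[[id]]))
  # empty cohort -> empty prediction table
  empty <- subset_cohort(co, rep(FALSE, 150))
  expect_equal(nrow(apply_all_tools(empty, reg)), 0)
})

test_that("declarative engine equals the hand-coded references on a thinned grid", {
  reg <- load_tool_definitions()
  g <- make_physiology_grid(
    rr = c(0, 3, 4, 11, 12, 14, 15, 21, 22, 23, 24, 29, 30, 31, 45, 46),
    hr = c(0, 79, 80, 100, 101, 120, 121, 161),
    sbp = c(0, 59, 60, 89, 90, 91),
    gcs = c(3, 8, 9, 11, 12, 13, 14, 15),
    motor = c(1, 3, 4, 6))
  a <- triageval:::derive_inputs_from_raw(g)
  for (id in TOOL_IDS) {
    got <- unname(apply_tool(reg$tools[[id]], a, reg))
    want <- unname(REFERENCE_TOOLS[[id]](g))
    expect_identical(got, want, label = paste("engine", id),
                     expected.label = paste("reference", id))
  }
})

test_that("no tool emits P3 on registry surrogates; BCD dominates CareFlight on the voice-negative slice", {
  reg <- load_tool_definitions()
  g <- make_physiology_grid(
    rr = c(0, 4, 12, 20, 30, 46), hr = c(80, 101, 121),
    sbp = c(0, 60, 90), gcs = c(3, 8, 11, 12, 15), motor = c(1, 3, 6))
  a <- triageval:::derive_inputs_from_raw(g)
  preds <- lapply(reg$tools, apply_tool, assessments = a, registry = reg)
  for (id in TOOL_IDS) {
    expect_false(any(preds[[id]] == "P3", na.rm = TRUE), label = id)
  }
  slice <- a$breathing & !a$responds_to_voice
  expect_true(all(preds$BCD[slice] == "P1"))
  expect_true(all(preds$CareFlight[slice] %in% c("P1", "P2")))
})

test_that("every check branch of every tool is reachable for some assessment", {
  reg <- load_tool_definitions()
  flags <- expand.grid(
    walking = c(TRUE, FALSE), breathing = c(TRUE, FALSE),
    radial_pulse = c(TRUE, FALSE), gcs_total = c(3, 8, 11, 13, 15),
    gcs_motor = c(1, 4, 6), rr = c(0, 8, 13, 18, 25, 35, 50),
    hr = c(60, 105, 130), cat3 = c("yes", "no", "na"),
    age_years = c(1, 2.5, 6, 10), KEEP.OUT.ATTRS = FALSE)
  a <- data.frame(
    patient_id = sprintf("f%05d", seq_len(nrow(flags))),
    age_years = flags$age_years, rr = flags$rr, hr = flags$hr,
    sbp = ifelse(flags$radial_pulse, 100, 0),
    gcs_total = flags$gcs_total, gcs_motor = flags$gcs_motor,
    walking = flags$walking, breathing = flags$breathing,
    responds_to_voice = flags$gcs_total >= 12,
    unconscious = flags$gcs_total <= 8,
    obeys_commands = flags$gcs_motor == 6,
    radial_pulse = flags$radial_pulse,
    cap_refill_over_2s = !flags$radial_pulse,
    jumpstart_mental_immediate = flags$gcs_motor <= 3,
    catastrophic_haemorrhage = c(yes = TRUE, no = FALSE,
                                 na = NA)[as.character(flags$cat3)],
    stringsAsFactors = FALSE)
  for (id in TOOL_IDS) {
    tool <- reg$tools[[id]]
    applicable <- a$age_years >= tool$applicable_age[1] &
      a$age_years < tool$applicable_age[2]
    bands <- reg$ptt_bands[rep(1L, nrow(a)), ]
    suppressWarnings(
      bands[applicable, ] <- ptt_band_for(
        pmin(a$age_years[applicable], 11.9), reg))
    undecided <- applicable
    for (k in seq_along(tool$checks)) {
      trig <- triageval:::eval_predicate(tool$checks[[k]], a, bands)
      fire <- undecided & !is.na(trig) & trig
      expect_true(any(fire),
                  label = sprintf("%s check %d (%s) reachable", id, k,
                                  tool$checks[[k]]$predicate))
      undecided <- undecided & !fire
    }
    expect_true(any(undecided),
                label = paste(id, "default branch reachable"))
  }
})
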