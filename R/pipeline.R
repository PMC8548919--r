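#' Pipeline run configuration
#'
#' @param mode `"synthetic"` (generate a cohort) or `"csv"` (read one).
#' @param generator a [generator_config()] (synthetic mode).
#' @param cohort_csv,events_csv input paths (csv mode).
#' @param gold_cfg a [gold_standard_config()].
#' @param tool_config path to a tool-definition YAML, `NULL` for bundled.
#' @param policy denominator policy for performance tables.
#' @param out_dir output directory for the report bundle.
#' @param seed integer seed (overrides the generator seed in synthetic
#'   mode so one knob controls the run).
#' @return list of class `run_config`.
#' @export
run_config <- function(mode = c("synthetic", "csv"),
                       generator = generator_config(),
                       cohort_csv = NULL, events_csv = NULL,
                       gold_cfg = gold_standard_config(),
                       tool_config = NULL,
                       policy = "p1_vs_p2_only",
                       out_dir = "triageval-report",
                       seed = NULL) {
  mode <- match.arg(mode)
  if (mode == "csv" && is.null(cohort_csv)) {
    stop("configuration error: csv mode requires cohort_csv")
  }
  if (!is.null(seed)) generator$seed <- as.integer(seed)
  structure(list(mode = mode, generator = generator,
                 cohort_csv = cohort_csv, events_csv = events_csv,
                 gold_cfg = gold_cfg, tool_config = tool_config,
                 policy = policy, out_dir = out_dir),
            class = "run_config")
}

#' Run the end-to-end evaluation pipeline
#'
#' Executes the full study pipeline: ingest or generate a cohort, apply
#' the eligibility filter, compare included vs excluded, derive tool
#' inputs and apply all tools, assign reference categories, and produce
#' stratified performance tables for the primary (intervention-based P1)
#' and both secondary (mortality, ISS > 15) standards. Writes a report
#' bundle of CSV tables plus a JSON manifest recording the seed and
#' configuration, and returns the bundle invisibly.
#'
#' @param cfg a [run_config()].
#' @param quiet suppress per-stage record-count messages.
#' @return (invisibly) list of class `report_bundle` with elements
#'   `cohort_summary`, `included_excluded`, `gold_table`, `p1_breakdown`,
#'   `performance_primary`, `performance_mortality`, `performance_iss`,
#'   `manifest`, plus the `included` cohort, `predictions` and `gold`
#'   categories for further analysis.
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  say <- function(...) if (!quiet) message("[triageval] ", ...)
  stage <- "ingest"
  bundle <- tryCatch({
    if (cfg$mode == "synthetic") {
      gen <- generate_cohort(cfg$generator, cfg$gold_cfg)
      cohort <- gen$cohort
      say(sprintf("generated %d synthetic records (seed %d)",
                  n_patients(cohort), cfg$generator$seed))
    } else {
      cohort <- read_cohort(cfg$cohort_csv, cfg$events_csv)
      say(sprintf("read %d records from %s", n_patients(cohort),
                  cfg$cohort_csv))
    }
    if (n_patients(cohort) == 0) stop("empty cohort")

    stage <- "eligibility_filter"
    split <- eligibility_filter(cohort)
    say(sprintf("eligibility: %d included, %d excluded",
                n_patients(split$included), n_patients(split$excluded)))
    if (n_patients(split$excluded) > 0) {
      say("exclusions by missing field: ",
          paste(names(exclusion_breakdown(split$excluded)),
                exclusion_breakdown(split$excluded),
                sep = "=", collapse = ", "))
    }
    if (n_patients(split$included) == 0) stop("no eligible records")

    stage <- "compare_included_excluded"
    cmp <- if (n_patients(split$excluded) > 0) {
      compare_included_excluded(split$included, split$excluded)
    } else NULL

    stage <- "apply_tools"
    registry <- load_tool_definitions(cfg$tool_config)
    predictions <- apply_all_tools(split$included, registry)
    say(sprintf("applied %d tools to %d patients",
                length(registry$tools), nrow(predictions)))

    stage <- "assign_category"
    gold <- assign_category(split$included, cfg$gold_cfg)
    say("reference categories: ",
        paste(names(table(gold)), table(gold), sep = "=",
              collapse = ", "))

    stage <- "reports"
    list(
      cohort_summary = summarize_cohort(split$included),
      included_excluded = cmp,
      gold_table = gold_outcome_table(split$included, gold),
      p1_breakdown = p1_criterion_breakdown(split$included, cfg$gold_cfg),
      performance_primary = stratified_report(predictions, gold,
                                              cfg$policy),
      performance_mortality = stratified_report(
        predictions, secondary_gold(split$included, "mortality"),
        cfg$policy),
      performance_iss = stratified_report(
        predictions, secondary_gold(split$included, "iss_over_15"),
        cfg$policy),
      included = split$included,
      excluded = split$excluded,
      predictions = predictions,
      gold = gold
    )
  }, error = function(e) {
    stop("pipeline aborted at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  })
  bundle$manifest <- list(
    package_version = as.character(utils::packageVersion("triageval")),
    mode = cfg$mode,
    seed = if (cfg$mode == "synthetic") cfg$generator$seed else NA,
    n_input = if (cfg$mode == "synthetic") cfg$generator$n_patients
              else NA,
    policy = cfg$policy,
    fluid_bolus_ml_per_kg = cfg$gold_cfg$fluid_bolus_ml_per_kg,
    haemorrhage_window_min = cfg$gold_cfg$haemorrhage_window_min
  )
  class(bundle) <- "report_bundle"
  if (!is.null(cfg$out_dir)) write_bundle(bundle, cfg$out_dir)
  invisible(bundle)
}

#' Write a report bundle to disk
#'
#' @param bundle a `report_bundle` from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, file) {
    utils::write.csv(df, file.path(dir, file), row.names = FALSE, na = "")
  }
  w(bundle$cohort_summary$counts, "cohort_summary_counts.csv")
  w(bundle$cohort_summary$medians, "cohort_summary_medians.csv")
  if (!is.null(bundle$included_excluded)) {
    w(bundle$included_excluded$overall, "included_excluded.csv")
    w(bundle$included_excluded$mechanism_posthoc,
      "included_excluded_mechanism_posthoc.csv")
  }
  w(bundle$gold_table$table, "gold_category_outcomes.csv")
  if (!is.null(bundle$gold_table$p1_vs_p2)) {
    w(bundle$gold_table$p1_vs_p2, "gold_p1_vs_p2_contrasts.csv")
  }
  w(bundle$p1_breakdown$by_criterion, "p1_criterion_breakdown.csv")
  w(bundle$performance_primary, "performance_primary.csv")
  w(bundle$performance_mortality, "performance_mortality.csv")
  w(bundle$performance_iss, "performance_iss.csv")
  jsonlite::write_json(bundle$manifest,
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Verify the analytic identities of a report bundle
#'
#' Machine-checks the internal consistencies every report must satisfy:
#' under-triage = 100 - sensitivity; AUC = (sensitivity + specificity) /
#' 200; confusion counts of the four age subgroups sum to the overall
#' under-16 counts for every tool applicable across the full range.
#'
#' @param bundle a `report_bundle`.
#' @param tol numeric tolerance (default 1e-9).
#' @return `TRUE` invisibly, or an error describing the first violated
#'   identity.
#' @export
verify_bundle <- function(bundle, tol = 1e-9) {
  for (nm in c("performance_primary", "performance_mortality",
               "performance_iss")) {
    perf <- bundle[[nm]]
    ok <- is.na(perf$sensitivity) |
      abs(perf$under_triage - (100 - perf$sensitivity)) < tol
    if (!all(ok)) stop("identity violated in ", nm,
                       ": under_triage != 100 - sensitivity")
    ok <- is.na(perf$auc) |
      abs(perf$auc - (perf$sensitivity + perf$specificity) / 200) < tol
    if (!all(ok)) stop("identity violated in ", nm,
                       ": auc != (sens + spec) / 200")
    sub <- c("0-<4", "4-<8", "8-<12", "12-<16")
    for (tl in unique(perf$tool)) {
      rows <- perf[perf$tool == tl, ]
      if (!all(sub %in% rows$stratum) || !("<16" %in% rows$stratum)) next
      for (cell in c("tp", "fp", "fn", "tn")) {
        total <- sum(rows[rows$stratum %in% sub, cell])
        if (total != rows[rows$stratum == "<16", cell]) {
          stop("identity violated in ", nm, ": subgroup ", cell,
               " counts for ", tl, " do not sum to the overall stratum")
        }
      }
    }
  }
  invisible(TRUE)
}

#' ISS distribution among tool-assigned P1 patients
#'
#' Box-plot utility: distribution of ISS among the patients each tool
#' labels P1.
#'
#' @param cohort an eligible `triage_cohort`.
#' @param predictions data.frame from [apply_all_tools()].
#' @param ... passed to [graphics::boxplot()].
#' @return (invisibly) the list of per-tool ISS vectors.
#' @export
plot_iss_by_tool <- function(cohort, predictions, ...) {
  tools <- setdiff(names(predictions), c("patient_id", "age_years"))
  iss <- cohort$patients$iss[match(predictions$patient_id,
                                   cohort$patients$patient_id)]
  groups <- lapply(tools, function(tl) {
    iss[!is.na(predictions[[tl]]) & predictions[[tl]] == "P1"]
  })
  names(groups) <- tools
  graphics::boxplot(groups, las = 2, ylab = "ISS",
                    main = "ISS among tool-assigned P1 patients", ...)
  graphics::abline(h = 15, lty = 3)
  invisible(groups)
}
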