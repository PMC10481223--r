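#' Configure an end-to-end pipeline run
#'
#' Bundles every tunable of the pipeline stages. With `simulate = TRUE`
#' (the default) the run starts by generating a synthetic cohort; otherwise
#' the three input CSV paths must point at existing files in the documented
#' schemas.
#'
#' @param simulate Generate the inputs with [simulate_cohort()]?
#' @param cohort A [cohort_config()] (used when `simulate = TRUE`).
#' @param model A [maturation_model()].
#' @param bins Reference-chart bins, as from [default_bins()].
#' @param min_n Minimum records per reference bin.
#' @param smooth Apply the day-matched smoothing windows.
#' @param level Percentile level used as the flagging threshold.
#' @param window Evaluation day window, half-open.
#' @param positive_class,reference_class Classes for [evaluate_threshold()].
#' @param day_ranges Day ranges for [compare_groups()].
#' @param readings_path,scans_path,standards_path Input CSVs (when
#'   `simulate = FALSE`).
#' @param seed Seed for every source of randomness in the run.
#' @return A validated `pipeline_config`.
#' @export
pipeline_config <- function(simulate = TRUE, cohort = cohort_config(),
                            model = maturation_model(),
                            bins = default_bins(), min_n = 5, smooth = TRUE,
                            level = 15, window = c(6, 21),
                            positive_class = "low_supply",
                            reference_class = "normal",
                            day_ranges = default_day_ranges(),
                            readings_path = NULL, scans_path = NULL,
                            standards_path = NULL, seed = 1) {
  stopifnot(inherits(cohort, "cohort_config"),
            inherits(model, "maturation_model"),
            length(window) == 2L, window[1] < window[2], min_n >= 1)
  structure(
    list(simulate = isTRUE(simulate), cohort = cohort, model = model,
         bins = bins, min_n = min_n, smooth = smooth, level = level,
         window = window, positive_class = positive_class,
         reference_class = reference_class, day_ranges = day_ranges,
         readings_path = readings_path, scans_path = scans_path,
         standards_path = standards_path, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

# stable hash of a pipeline config for output provenance
config_hash_ <- function(config) {
  x <- unclass(config)
  x$cohort <- unclass(x$cohort)
  x$model <- unclass(x$model)
  x$bins <- as.data.frame(x$bins)
  x$day_ranges <- as.data.frame(x$day_ranges)
  rlang::hash(x)
}

#' Run the full maturation-sensing pipeline
#'
#' Executes the stages in order -- simulate (optional), calibrate, compute
#' conductivity and MM%, classify, build the normative reference, flag and
#' evaluate -- writing each stage's artifact into `out_dir` along with a
#' `report.json` holding counts, the threshold evaluation, the group
#' comparison p-values and the config provenance hash. Row counts in and
#' out of every stage are logged to `run.log` (and `message()`d), so
#' filtered or rejected records are auditable. The report contains no
#' timestamps: rerunning the same config and seed reproduces it
#' byte-identically.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory for the run.
#' @param quiet Suppress progress messages.
#' @return The report, invisibly (a list mirroring `report.json`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  # pre-flight validation before anything is written
  if (!config$simulate) {
    paths <- c(readings = config$readings_path, scans = config$scans_path,
               standards = config$standards_path)
    if (any(vapply(paths, is.null, logical(1))) || !all(file.exists(paths))) {
      abort("Pre-flight: readings/scans/standards paths must exist when simulate = FALSE.",
            class = "milksense_validation_error")
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character()
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    if (!quiet) message(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(log_lines, file.path(out_dir, "run.log"))
      abort(sprintf("Stage '%s' failed: %s", name, conditionMessage(e)),
            class = "milksense_stage_error")
    })
  }

  # 1. inputs
  if (config$simulate) {
    cohort <- stage("simulate",
                    simulate_cohort(config$cohort, seed = config$seed))
    write_cohort(cohort, out_dir)
    readings <- cohort$readings
    scans <- cohort$scans
    standards <- cohort$standards
    say("simulate: %d readings, %d scan records, %d devices",
        nrow(readings), nrow(scans),
        dplyr::n_distinct(standards$device_id))
  } else {
    readings <- stage("read", read_readings(config$readings_path))
    scans <- stage("read", read_scan_records(config$scans_path))
    standards <- stage("read", readr::read_csv(config$standards_path,
                                               show_col_types = FALSE))
    say("read: %d readings (%d rejected), %d scan records (%d rejected)",
        nrow(readings), nrow(attr(readings, "rejects") %||% data.frame()),
        nrow(scans), nrow(scan_rejects(scans)))
  }

  # 2. per-device calibration
  store <- stage("calibrate", fit_calibration_store(standards))
  write_calibration_store(store, file.path(out_dir, "calibration.json"))
  say("calibrate: %d device calibrations fitted", length(store))

  # 3. conductivity + MM%
  cond <- stage("mm", {
    x <- process_readings(readings, store)
    add_mm(x, config$model)
  })
  readr::write_csv(cond, file.path(out_dir, "conductivity.csv"))
  say("mm: %d readings processed, %d non-physical", nrow(cond),
      sum(cond$quality == "nonphysical"))

  # 4. classification
  classified <- stage("classify", classify_scans(scans))
  readr::write_csv(classified, file.path(out_dir, "classified.csv"))
  class_n <- table(classified$class_label)
  say("classify: %s",
      paste(sprintf("%s=%d", names(class_n), class_n), collapse = ", "))

  # 5. normative reference from the normal class
  chart <- stage("build-ref", build_reference(
    classified[classified$class_label == "normal", , drop = FALSE],
    bins = config$bins, min_n = config$min_n, smooth = config$smooth
  ))
  write_reference_chart(chart, file.path(out_dir, "reference_chart.csv"))
  say("build-ref: %d/%d bins populated", sum(!is.na(chart$p50)),
      nrow(chart))

  # 6. flag + evaluate
  flagged <- stage("flag", flag_scans(classified, chart,
                                      level = config$level))
  readr::write_csv(flagged, file.path(out_dir, "flagged.csv"))
  ev <- stage("evaluate", evaluate_threshold(
    flagged, positive_class = config$positive_class,
    reference_class = config$reference_class, window = config$window
  ))
  cmp <- stage("evaluate", compare_groups(
    flagged, day_ranges = config$day_ranges,
    classes = intersect(c(config$reference_class, "bf_problems",
                          config$positive_class),
                        as.character(unique(flagged$class_label)))
  ))
  say("evaluate: sensitivity %.1f%%, specificity %.1f%%",
      ev$sensitivity, ev$specificity)

  report <- list(
    config_hash = config_hash_(config),
    seed = config$seed,
    counts = list(
      readings = nrow(readings), scans = nrow(scans),
      devices = length(store),
      by_class = as.list(setNames(as.integer(class_n), names(class_n))),
      nonphysical_readings = sum(cond$quality == "nonphysical"),
      populated_bins = sum(!is.na(chart$p50))
    ),
    threshold_evaluation = unclass(tidy(ev))[],
    anova = list(
      p_class = glance(cmp)$p_class,
      p_day_range = glance(cmp)$p_day_range,
      p_interaction = glance(cmp)$p_interaction
    )
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  readr::write_csv(tidy(cmp, "cells"),
                   file.path(out_dir, "group_comparison.csv"))
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(report)
}
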