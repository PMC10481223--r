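# shared fixture builders; everything is generated in code at test time

# minimal scan-record tibble with sensible defaults, overridable per field
make_scan <- function(...,
                      mother_id = "M1",
                      day_postpartum = 10,
                      mm_percent = 80,
                      breast_side = "left",
                      reporter = "provider",
                      feeding_status = "exclusive",
                      formula_fraction_daily = NA_real_,
                      formula_last_24h = FALSE,
                      problem_tags = "") {
  tibble::tibble(
    mother_id = mother_id, day_postpartum = day_postpartum,
    mm_percent = mm_percent, breast_side = breast_side,
    reporter = reporter, feeding_status = feeding_status,
    formula_fraction_daily = formula_fraction_daily,
    formula_last_24h = formula_last_24h, problem_tags = problem_tags,
    ...
  )
}

# flagged + classified records with a prescribed confusion structure
make_flagged <- function(n_pos, n_pos_below, n_ref = 0, n_ref_below = 0,
                         day = 10) {
  tibble::tibble(
    class_label = rep(c("low_supply", "normal"), c(n_pos, n_ref)),
    day_postpartum = day,
    flag = factor(
      c(rep(c("below", "at_or_above"), c(n_pos_below, n_pos - n_pos_below)),
        rep(c("below", "at_or_above"), c(n_ref_below, n_ref - n_ref_below))),
      levels = c("below", "at_or_above", "no_reference")
    )
  )
}

# scan-records CSV written to a temp file; rows as character vectors
write_scan_csv <- function(rows) {
  header <- paste("mother_id", "baby_birth", "scan_time", "breast_side",
                  "mm_percent", "reporter", "feeding_status",
                  "formula_fraction_daily", "formula_last_24h",
                  "problem_tags", sep = ",")
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(c(header, rows), path)
  path
}

# independent decision table for the breastfeeding classifier, hand-coded
# from the classification rules (kept deliberately separate from the
# vectorised implementation in the package)
oracle_classify <- function(reporter, feeding_status, formula_last_24h,
                            tags, frac) {
  supply <- c("latch_problem", "tongue_tie", "low_weight_gain",
              "slow_weight_gain", "low_milk_supply")
  b2set <- c("latch_problem", "tongue_tie", "low_weight_gain",
             "low_milk_supply")
  if (reporter == "provider" &&
      feeding_status %in% c("partial", "mostly_formula") &&
      formula_last_24h && length(intersect(tags, supply)) > 0) {
    return("low_supply")
  }
  if (reporter == "mother" &&
      any(c("low_milk_supply", "slow_weight_gain") %in% tags) &&
      !is.na(frac) && frac > 0.2) {
    return("low_supply")
  }
  if (feeding_status == "partial" && formula_last_24h &&
      length(tags) == 0) {
    return("bf_problems")
  }
  if (feeding_status == "predominant_80plus" &&
      length(intersect(tags, b2set)) > 0) {
    return("bf_problems")
  }
  if (feeding_status %in% c("exclusive", "full_breastfeeding",
                            "full_own_milk", "predominant_80plus") &&
      length(intersect(tags, supply)) == 0) {
    return("normal")
  }
  "unclassified"
}

# independent sort-and-interpolate quantile (the type-7 formula written out)
oracle_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  vapply(p, function(pp) {
    h <- 1 + (n - 1) * pp
    lo <- floor(h)
    hi <- ceiling(h)
    if (x[hi] == x[lo]) return(x[lo]) # tied order statistics
    (1 - (h - lo)) * x[lo] + (h - lo) * x[hi]
  }, numeric(1))
}
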