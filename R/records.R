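#' Scan-record vocabulary
#'
#' Enumerations used by the scan-record schema: feeding-status levels,
#' recognised problem tags, and the subset of tags treated as indicators of
#' ineffective breastfeeding and/or low milk supply. Breast and nipple pain
#' are recognised tags but are deliberately *not* supply-associated: they are
#' reported as separate conditions and do not trigger the supply rules.
#'
#' @name scan_vocabulary
#' @return Character vectors of levels.
NULL

#' @rdname scan_vocabulary
#' @export
feeding_levels <- function() {
  c("exclusive", "full_breastfeeding", "full_own_milk", "predominant_80plus",
    "partial", "mostly_formula")
}

#' @rdname scan_vocabulary
#' @export
problem_tag_levels <- function() {
  c("latch_problem", "tongue_tie", "low_weight_gain", "low_milk_supply",
    "slow_weight_gain", "breast_pain", "nipple_pain")
}

#' @rdname scan_vocabulary
#' @export
supply_tags <- function() {
  c("latch_problem", "tongue_tie", "low_weight_gain", "slow_weight_gain",
    "low_milk_supply")
}

# tags triggering the predominant-breastfeeding problems rule (B2); matches
# the tag families reported for the problems group
b2_tags_ <- function() {
  c("latch_problem", "tongue_tie", "low_weight_gain", "low_milk_supply")
}

class_levels_ <- c("normal", "low_supply", "bf_problems", "unclassified")

# split a semicolon-delimited tag cell into a character vector
split_tags_ <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  lapply(strsplit(x, ";", fixed = TRUE),
         function(t) trimws(t[nzchar(trimws(t))]))
}

#' Read scan records from CSV
#'
#' Expected header (exactly these columns, `formula_fraction_daily` may be
#' empty): `mother_id, baby_birth, scan_time, breast_side, mm_percent,
#' reporter, feeding_status, formula_fraction_daily, formula_last_24h,
#' problem_tags`. `problem_tags` is semicolon-delimited within the cell.
#' `day_postpartum` is computed as `(scan_time - baby_birth) / 24 h`.
#' Malformed rows (negative day postpartum, MM% outside [0, 100], unknown
#' enum levels or tags) are collected into a rejects table attached as the
#' `"rejects"` attribute -- they are reported, never silently dropped.
#'
#' @param path Path to the scan-records CSV.
#' @return A tibble of valid scan records with `day_postpartum` appended;
#'   rejected rows (with reasons) in `attr(, "rejects")`.
#' @seealso [scan_rejects()], [classify_scans()]
#' @export
read_scan_records <- function(path) {
  req <- c("mother_id", "baby_birth", "scan_time", "breast_side",
           "mm_percent", "reporter", "feeding_status",
           "formula_fraction_daily", "formula_last_24h", "problem_tags")
  hdr <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  missing <- setdiff(req, hdr)
  if (length(missing) > 0L) {
    abort(paste0("Scan-records CSV is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "milksense_schema_error")
  }
  x <- readr::read_csv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         mother_id = readr::col_character(),
                         baby_birth = readr::col_datetime(),
                         scan_time = readr::col_datetime(),
                         breast_side = readr::col_character(),
                         mm_percent = readr::col_double(),
                         reporter = readr::col_character(),
                         feeding_status = readr::col_character(),
                         formula_fraction_daily = readr::col_double(),
                         formula_last_24h = readr::col_logical(),
                         problem_tags = readr::col_character()
                       ))
  x$day_postpartum <-
    as.numeric(difftime(x$scan_time, x$baby_birth, units = "hours")) / 24
  tags <- split_tags_(x$problem_tags)
  bad_tag <- vapply(tags, function(t) any(!t %in% problem_tag_levels()),
                    logical(1))
  reason <- dplyr::case_when(
    is.na(x$day_postpartum) | x$day_postpartum < 0 ~ "negative day_postpartum",
    !is.finite(x$mm_percent) | x$mm_percent < 0 | x$mm_percent > 100 ~
      "mm_percent outside [0, 100]",
    !x$breast_side %in% c("left", "right") ~ "unknown breast_side",
    !x$reporter %in% c("provider", "mother") ~ "unknown reporter",
    !x$feeding_status %in% feeding_levels() ~ "unknown feeding_status",
    bad_tag ~ "unknown problem tag",
    TRUE ~ NA_character_
  )
  rejects <- tibble::tibble(row = which(!is.na(reason)),
                            reason = reason[!is.na(reason)])
  if (nrow(rejects) > 0L) {
    warn(sprintf("%d scan record(s) rejected; see scan_rejects().",
                 nrow(rejects)))
  }
  out <- x[is.na(reason), , drop = FALSE]
  attr(out, "rejects") <- rejects
  out
}

#' @rdname read_scan_records
#' @param records A tibble returned by [read_scan_records()].
#' @export
scan_rejects <- function(records) {
  attr(records, "rejects") %||% tibble::tibble(row = integer(),
                                               reason = character())
}

#' Validate scan records for internal consistency
#'
#' Checks the cross-field constraints of the scan-record model, e.g. that
#' exclusive or full breastfeeding does not co-occur with formula in the
#' prior 24 hours, and that a reported daily formula fraction agrees with the
#' feeding-status category (predominant means <= 20% formula; partial or
#' mostly-formula means > 20%).
#'
#' @param records A scan-record tibble.
#' @return A tibble with columns `row` and `conflict`; zero rows when the
#'   records are consistent.
#' @export
validate_scan_records <- function(records) {
  stopifnot(is.data.frame(records))
  fs <- records$feeding_status
  frac <- records$formula_fraction_daily
  f24 <- records$formula_last_24h
  no_formula_status <- fs %in% c("exclusive", "full_breastfeeding",
                                 "full_own_milk")
  checks <- list(
    "exclusive/full feeding with formula_last_24h = TRUE" =
      no_formula_status & !is.na(f24) & f24,
    "exclusive/full feeding with formula_fraction_daily > 0" =
      no_formula_status & !is.na(frac) & frac > 0,
    "formula_fraction_daily outside [0, 1]" =
      !is.na(frac) & (frac < 0 | frac > 1),
    "predominant_80plus with formula_fraction_daily > 0.2" =
      fs == "predominant_80plus" & !is.na(frac) & frac > 0.2,
    "partial/mostly_formula with formula_fraction_daily <= 0.2" =
      fs %in% c("partial", "mostly_formula") & !is.na(frac) & frac <= 0.2
  )
  out <- purrr::imap(checks, function(hit, label) {
    tibble::tibble(row = which(hit), conflict = label)
  })
  dplyr::arrange(dplyr::bind_rows(out), .data$row)
}

#' Classify scan records into breastfeeding status groups
#'
#' Retrospective three-way classification of each scan record into
#' `normal`, `low_supply` or `bf_problems` (else `unclassified`), from the
#' reported feeding exclusivity, recent formula use and problem tags.
#' The rules, applied with precedence low_supply > bf_problems > normal:
#'
#' * **L1** (provider-reported low supply): partial or mostly-formula
#'   feeding, formula in the prior 24 h, and at least one supply-associated
#'   tag ([supply_tags()]).
#' * **L2** (mother-reported low supply): a `low_milk_supply` or
#'   `slow_weight_gain` tag together with a daily formula fraction over 20%.
#' * **B1**: partial feeding (formula in the prior 24 h) with no problem
#'   tags at all.
#' * **B2**: predominant breastfeeding (>= 80% mother's milk) tagged with a
#'   latch problem, tongue tie, low weight gain or low milk supply.
#' * **N1** (normal): exclusive, full, full-own-milk or predominant feeding
#'   with no supply-associated tags.
#'
#' Records matching no rule are `unclassified`. Classification is total,
#' deterministic and independent of record order; repeated scans from one
#' mother are treated as independent records. Inconsistent records (see
#' [validate_scan_records()]) raise an error listing each conflict.
#'
#' @param records A scan-record tibble (see [read_scan_records()] for the
#'   schema).
#' @param formula_window_hours Length of the "recent formula" window the
#'   `formula_last_24h` field refers to. Metadata only -- recorded in the
#'   output attributes; the field itself is collected against this window.
#' @return `records` with `class_label` (factor) and `rule_fired` columns
#'   appended.
#' @examples
#' recs <- tibble::tibble(
#'   mother_id = "M1", day_postpartum = 5, mm_percent = 70,
#'   reporter = "provider", feeding_status = "exclusive",
#'   formula_fraction_daily = NA_real_, formula_last_24h = FALSE,
#'   problem_tags = ""
#' )
#' classify_scans(recs)$class_label
#' @export
classify_scans <- function(records, formula_window_hours = 24) {
  stopifnot(is.data.frame(records))
  req <- c("reporter", "feeding_status", "formula_fraction_daily",
           "formula_last_24h", "problem_tags")
  missing <- setdiff(req, names(records))
  if (length(missing) > 0L) {
    abort(paste0("`records` is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "milksense_schema_error")
  }
  conflicts <- validate_scan_records(records)
  if (nrow(conflicts) > 0L) {
    show <- utils::head(conflicts, 5L)
    abort(paste0(
      "Inconsistent scan record(s):\n",
      paste(sprintf("  row %d: %s", show$row, show$conflict),
            collapse = "\n"),
      if (nrow(conflicts) > 5L) sprintf("\n  ... and %d more",
                                        nrow(conflicts) - 5L) else ""
    ), class = "milksense_validation_error")
  }

  tags <- split_tags_(records$problem_tags)
  has_tag <- function(set) {
    vapply(tags, function(t) any(t %in% set), logical(1))
  }
  n_tags <- lengths(tags)
  fs <- records$feeding_status
  f24 <- !is.na(records$formula_last_24h) & records$formula_last_24h
  frac <- records$formula_fraction_daily
  normal_statuses <- c("exclusive", "full_breastfeeding", "full_own_milk",
                       "predominant_80plus")

  l1 <- records$reporter == "provider" &
    fs %in% c("partial", "mostly_formula") & f24 & has_tag(supply_tags())
  l2 <- records$reporter == "mother" &
    has_tag(c("low_milk_supply", "slow_weight_gain")) &
    !is.na(frac) & frac > 0.2
  b1 <- fs == "partial" & f24 & n_tags == 0L
  b2 <- fs == "predominant_80plus" & has_tag(b2_tags_())
  n1 <- fs %in% normal_statuses & !has_tag(supply_tags())

  label <- dplyr::case_when(
    l1 | l2 ~ "low_supply",
    b1 | b2 ~ "bf_problems",
    n1 ~ "normal",
    TRUE ~ "unclassified"
  )
  rule <- dplyr::case_when(
    l1 ~ "L1", l2 ~ "L2", b1 ~ "B1", b2 ~ "B2", n1 ~ "N1", TRUE ~ ""
  )
  out <- dplyr::mutate(tibble::as_tibble(records),
                       class_label = factor(label, levels = class_levels_),
                       rule_fired = rule)
  attr(out, "formula_window_hours") <- formula_window_hours
  out
}

#' Summarise classified records by class and problem tag
#'
#' Counts records per class and, within each class, the percentage of
#' tag-carrying records bearing each tag. A record with several tags
#' contributes to each of its tag rows, so percentages are computed over the
#' records in the class that carry at least one tag and need not sum to 100.
#'
#' @param records Classified records (from [classify_scans()]).
#' @return A `classification_summary`: list with `classes` (class, n) and
#'   `tags` (class, tag, n, pct) tibbles.
#' @export
classification_summary <- function(records) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) {
    out <- list(
      classes = tibble::tibble(class_label = factor(levels = class_levels_),
                               n = integer()),
      tags = tibble::tibble(class_label = character(), tag = character(),
                            n = integer(), pct = numeric())
    )
    return(structure(out, class = "classification_summary"))
  }
  if (!"class_label" %in% names(records)) {
    abort("`records` must be classified first (see classify_scans()).",
          class = "milksense_bad_input")
  }
  classes <- dplyr::count(records, .data$class_label, .drop = FALSE)
  tags <- split_tags_(records$problem_tags)
  tagged <- tibble::tibble(class_label = as.character(records$class_label),
                           tags = tags)
  tagged <- tagged[lengths(tagged$tags) > 0L, , drop = FALSE]
  if (nrow(tagged) == 0L) {
    tag_tbl <- tibble::tibble(class_label = character(), tag = character(),
                              n = integer(), pct = numeric())
  } else {
    denom <- dplyr::count(tagged, .data$class_label, name = "n_tagged")
    long <- tidyr::unnest(tagged, "tags")
    names(long)[names(long) == "tags"] <- "tag"
    tag_tbl <- dplyr::count(long, .data$class_label, .data$tag)
    tag_tbl <- dplyr::left_join(tag_tbl, denom, by = "class_label")
    tag_tbl <- dplyr::mutate(tag_tbl, pct = 100 * .data$n / .data$n_tagged)
    tag_tbl$n_tagged <- NULL
  }
  structure(list(classes = classes, tags = tag_tbl),
            class = "classification_summary")
}

#' @export
print.classification_summary <- function(x, ...) {
  cat("Records per class:\n")
  print(x$classes)
  if (nrow(x$tags) > 0L) {
    cat("\nTag composition (percent of tag-carrying records in class):\n")
    print(x$tags, n = 30)
  }
  invisible(x)
}
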