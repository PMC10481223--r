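#' Default day ranges for group comparison
#'
#' Early postpartum (`[0, 5)`), the window where group separation is
#' expected to be strongest (`[5, 20)`), and established lactation
#' (`[20, 60)`). Half-open ranges in days.
#'
#' @return A tibble with columns `range_start` and `range_end`.
#' @export
default_day_ranges <- function() {
  tibble::tibble(range_start = c(0, 5, 20), range_end = c(5, 20, 60))
}

#' Evaluate the below-threshold flag in a day window
#'
#' Day-matched threshold screening: among scans of the positive class inside
#' the day window, the sensitivity is the percentage flagged strictly below
#' the percentile line; among reference-class scans, the specificity is the
#' percentage *not* flagged below. Scans with no reference value
#' (`flag == "no_reference"`) are excluded from numerator and denominator and
#' their count is reported. Stored values keep full precision; printing
#' rounds to the nearest integer percent.
#'
#' @param records Classified and flagged scan records (columns `class_label`,
#'   `flag`, `day_postpartum`).
#' @param positive_class Class treated as positive (default `"low_supply"`).
#' @param reference_class Class used for specificity (default `"normal"`).
#' @param window Day window `c(start, end)`, half-open; the default
#'   `c(6, 21)` covers days 6-20 postpartum.
#' @return A `threshold_eval` object with counts, `sensitivity` and
#'   `specificity` in percent.
#' @examples
#' recs <- tibble::tibble(
#'   class_label = rep(c("low_supply", "normal"), c(135, 200)),
#'   day_postpartum = 10,
#'   flag = factor(rep(c("below", "at_or_above", "below", "at_or_above"),
#'                     c(110, 25, 20, 180)),
#'                 levels = c("below", "at_or_above", "no_reference"))
#' )
#' evaluate_threshold(recs)
#' @export
evaluate_threshold <- function(records, positive_class = "low_supply",
                               reference_class = "normal",
                               window = c(6, 21)) {
  stopifnot(is.data.frame(records),
            all(c("class_label", "flag", "day_postpartum") %in%
                  names(records)),
            length(window) == 2L, window[1] < window[2])
  inw <- records$day_postpartum >= window[1] &
    records$day_postpartum < window[2]
  w <- records[inw, , drop = FALSE]
  n_no_ref <- sum(w$flag == "no_reference")
  w <- w[w$flag != "no_reference", , drop = FALSE]
  pos <- w[w$class_label == positive_class, , drop = FALSE]
  ref <- w[w$class_label == reference_class, , drop = FALSE]
  if (nrow(pos) == 0L) {
    abort(sprintf(
      "Undefined sensitivity: no %s-class records in day window [%g, %g).",
      positive_class, window[1], window[2]),
      class = "milksense_undefined_sensitivity")
  }
  n_below <- sum(pos$flag == "below")
  n_ref_below <- sum(ref$flag == "below")
  structure(
    list(
      window = window,
      positive_class = positive_class,
      reference_class = reference_class,
      n_positive = nrow(pos),
      n_below = n_below,
      sensitivity = 100 * n_below / nrow(pos),
      n_reference = nrow(ref),
      n_reference_below = n_ref_below,
      specificity = if (nrow(ref) > 0L) 100 * (1 - n_ref_below / nrow(ref))
                    else NA_real_,
      n_no_reference = n_no_ref
    ),
    class = "threshold_eval"
  )
}

#' @export
print.threshold_eval <- function(x, ...) {
  cat(sprintf("Threshold evaluation, days [%g, %g)\n",
              x$window[1], x$window[2]))
  cat(sprintf("  Sensitivity (%s): %d%% (%d/%d below the line)\n",
              x$positive_class, round(x$sensitivity), x$n_below,
              x$n_positive))
  if (!is.na(x$specificity)) {
    cat(sprintf("  Specificity (%s): %d%% (%d/%d below the line)\n",
                x$reference_class, round(x$specificity),
                x$n_reference_below, x$n_reference))
  }
  if (x$n_no_reference > 0L) {
    cat(sprintf("  (%d scan(s) without reference excluded)\n",
                x$n_no_reference))
  }
  invisible(x)
}

#' @describeIn evaluate_threshold One-row tibble of counts and rates.
#' @param x A `threshold_eval`.
#' @param ... Unused.
#' @method tidy threshold_eval
#' @export
tidy.threshold_eval <- function(x, ...) {
  tibble::tibble(
    positive_class = x$positive_class,
    reference_class = x$reference_class,
    window_start = x$window[1], window_end = x$window[2],
    n_positive = x$n_positive, n_below = x$n_below,
    sensitivity = x$sensitivity,
    n_reference = x$n_reference, n_reference_below = x$n_reference_below,
    specificity = x$specificity,
    n_no_reference = x$n_no_reference
  )
}

#' @describeIn evaluate_threshold Same as `tidy()` (single-row summary).
#' @method glance threshold_eval
#' @export
glance.threshold_eval <- function(x, ...) tidy(x)

# assign records to half-open day ranges; NA outside all ranges
assign_range_ <- function(day, day_ranges) {
  labels <- sprintf("[%g,%g)", day_ranges$range_start, day_ranges$range_end)
  out <- rep(NA_character_, length(day))
  for (i in seq_len(nrow(day_ranges))) {
    hit <- day >= day_ranges$range_start[i] & day < day_ranges$range_end[i]
    out[hit] <- labels[i]
  }
  factor(out, levels = labels)
}

#' Compare MM% between breastfeeding classes across day ranges
#'
#' Two-way fixed-effects analysis of MM% with factors breastfeeding class
#' and day range: per-cell means, standard errors and counts; the two-factor
#' ANOVA for the class, range and interaction effects; and Tukey-adjusted
#' pairwise class contrasts computed within each day range (the posthoc for
#' the class-by-day interaction).
#'
#' @param records Classified scan records (`class_label`, `day_postpartum`,
#'   `mm_percent`).
#' @param day_ranges Day-range table as from [default_day_ranges()].
#' @param classes Classes to compare (>= 2).
#' @return A `group_comparison` object; see [tidy.group_comparison()] and
#'   [glance.group_comparison()].
#' @export
compare_groups <- function(records, day_ranges = default_day_ranges(),
                           classes = c("normal", "low_supply")) {
  stopifnot(is.data.frame(records),
            all(c("class_label", "day_postpartum", "mm_percent") %in%
                  names(records)))
  if (length(classes) < 2L) {
    abort("Need at least two classes to compare.",
          class = "milksense_bad_input")
  }
  d <- records[records$class_label %in% classes, , drop = FALSE]
  d$class_label <- factor(as.character(d$class_label), levels = classes)
  d$day_range <- assign_range_(d$day_postpartum, day_ranges)
  d <- d[!is.na(d$day_range), , drop = FALSE]
  if (dplyr::n_distinct(d$class_label) < 2L) {
    abort("Fewer than two classes present in the analyzed day ranges.",
          class = "milksense_bad_input")
  }
  # ranges with no records at all are dropped silently; ranges with data
  # but an empty/sparse class cell are dropped with a warning
  cell_n <- dplyr::count(d, .data$day_range, .data$class_label,
                         .drop = FALSE)
  per_range <- dplyr::summarise(dplyr::group_by(cell_n, .data$day_range),
                                total = sum(.data$n),
                                min_cell = min(.data$n), .groups = "drop")
  bad_ranges <- as.character(
    per_range$day_range[per_range$total > 0L & per_range$min_cell < 2L])
  if (length(bad_ranges) > 0L) {
    warn(paste0("Dropping day range(s) with empty/sparse cells: ",
                paste(bad_ranges, collapse = ", ")))
  }
  drop_ranges <- as.character(
    per_range$day_range[per_range$total == 0L | per_range$min_cell < 2L])
  if (length(drop_ranges) > 0L) {
    d <- d[!d$day_range %in% drop_ranges, , drop = FALSE]
    d$day_range <- droplevels(d$day_range)
  }
  if (nrow(d) == 0L || dplyr::n_distinct(d$day_range) == 0L) {
    abort("No day range has enough records in every class.",
          class = "milksense_bad_input")
  }

  cells <- dplyr::summarise(
    dplyr::group_by(d, .data$day_range, .data$class_label),
    n = dplyr::n(),
    mean_mm = mean(.data$mm_percent),
    se_mm = stats::sd(.data$mm_percent) / sqrt(dplyr::n()),
    .groups = "drop"
  )

  many_ranges <- dplyr::n_distinct(d$day_range) > 1L
  form <- if (many_ranges) mm_percent ~ class_label * day_range
          else mm_percent ~ class_label
  fit <- aov(form, data = d)
  an <- as.data.frame(summary(fit)[[1]])
  an$term <- trimws(rownames(an))
  anova_tbl <- tibble::tibble(
    term = an$term,
    df = an$Df, sumsq = an$`Sum Sq`, statistic = an$`F value`,
    p_value = an$`Pr(>F)`
  )

  pairwise <- purrr::map_dfr(levels(d$day_range), function(rg) {
    sub <- d[d$day_range == rg, , drop = FALSE]
    sub$class_label <- droplevels(sub$class_label)
    if (nlevels(sub$class_label) < 2L) return(NULL)
    tk <- TukeyHSD(aov(mm_percent ~ class_label, data = sub))$class_label
    tibble::tibble(
      day_range = rg,
      contrast = rownames(tk),
      estimate = tk[, "diff"],
      conf_low = tk[, "lwr"],
      conf_high = tk[, "upr"],
      adj_p_value = tk[, "p adj"]
    )
  })

  structure(
    list(cells = cells, anova = anova_tbl, pairwise = pairwise,
         classes = classes, day_ranges = day_ranges, n = nrow(d)),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s over %d day range(s), %d records\n",
              paste(x$classes, collapse = " vs "),
              dplyr::n_distinct(x$cells$day_range), x$n))
  print(x$cells)
  cat("\nANOVA:\n")
  print(x$anova)
  invisible(x)
}

#' Tidy a group comparison
#'
#' @param x A `group_comparison` from [compare_groups()].
#' @param type One of `"cells"` (per class-by-range mean, SE, n),
#'   `"pairwise"` (Tukey-adjusted class contrasts within each range) or
#'   `"anova"` (the two-factor ANOVA table).
#' @param ... Unused.
#' @return A tibble.
#' @method tidy group_comparison
#' @export
tidy.group_comparison <- function(x, type = c("cells", "pairwise", "anova"),
                                  ...) {
  type <- match.arg(type)
  x[[type]]
}

#' @describeIn tidy.group_comparison One-row model-level summary with the
#'   ANOVA p-values for class, day range and their interaction.
#' @method glance group_comparison
#' @export
glance.group_comparison <- function(x, ...) {
  p_of <- function(term) {
    hit <- x$anova$p_value[x$anova$term == term]
    if (length(hit) == 1L) hit else NA_real_
  }
  tibble::tibble(
    n = x$n,
    p_class = p_of("class_label"),
    p_day_range = p_of("day_range"),
    p_interaction = p_of("class_label:day_range")
  )
}

#' Per-day moving median of MM%
#'
#' For each day d in `days`, the median MM% of records with day postpartum
#' in `[d - window_days/2, d + window_days/2)`, optionally per class. Days
#' with no records give `NA`.
#'
#' @param records Scan records (`day_postpartum`, `mm_percent`, optionally
#'   `class_label`).
#' @param window_days Width of the centred window in days (default 2).
#' @param days Days to evaluate (default 0..20).
#' @param by_class Split by `class_label` when present (default `TRUE`).
#' @return A tibble with `day`, `n`, `median_mm` (and `class_label`).
#' @export
moving_median <- function(records, window_days = 2, days = 0:20,
                          by_class = TRUE) {
  stopifnot(is.data.frame(records),
            all(c("day_postpartum", "mm_percent") %in% names(records)))
  one <- function(df, cls) {
    purrr::map_dfr(days, function(d) {
      v <- df$mm_percent[df$day_postpartum >= d - window_days / 2 &
                           df$day_postpartum < d + window_days / 2]
      tibble::tibble(class_label = cls, day = d, n = length(v),
                     median_mm = if (length(v) > 0L) median(v) else NA_real_)
    })
  }
  if (by_class && "class_label" %in% names(records)) {
    cls <- sort(unique(as.character(records$class_label)))
    out <- purrr::map_dfr(cls, function(cl) {
      one(records[records$class_label == cl, , drop = FALSE], cl)
    })
  } else {
    out <- one(records, NA_character_)
    out$class_label <- NULL
  }
  out
}
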