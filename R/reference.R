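#' Default day-postpartum bins for the reference chart
#'
#' Daily bins over the first three weeks, where maturation changes fastest,
#' then coarser intervals: `[d, d+1)` for d = 0..20, followed by
#' `[21, 28)`, `[28, 35)`, `[35, 45)`, `[45, 60)` and `[60, Inf)`.
#' All bins are half-open `[start, end)`.
#'
#' @return A tibble with columns `bin_start` and `bin_end` (26 rows).
#' @export
default_bins <- function() {
  tibble::tibble(
    bin_start = c(0:20, 21, 28, 35, 45, 60),
    bin_end = c(1:21, 28, 35, 45, 60, Inf)
  )
}

# smoothing window bounds for one bin: +/- 24 h for the daily bins of the
# first 3 days, trailing -24 h extension for every later bin
window_bounds_ <- function(bin_start, bin_end, smooth = TRUE) {
  if (!smooth) {
    return(c(bin_start, bin_end))
  }
  lo <- max(bin_start - 1, 0)
  hi <- if (bin_start <= 2 && (bin_end - bin_start) <= 1) bin_end + 1
        else bin_end
  c(lo, hi)
}

#' Select the records feeding one reference bin
#'
#' Percentile bins borrow neighbouring records to smooth the sparse early
#' days: daily bins starting within the first 3 days use a +/- 24-hour
#' window around the bin, and every later bin is extended 24 hours backward
#' only (a trailing window, so a bin never borrows from days after it once
#' past the rapid-change period). Windows never reach below day 0.
#'
#' @param records A tibble with a `day_postpartum` column.
#' @param bin_start,bin_end Bin bounds in days (half-open `[start, end)`).
#' @param smooth Apply the smoothing windows? With `FALSE` the bin selects
#'   exactly `[bin_start, bin_end)`.
#' @return The subset of `records` feeding this bin.
#' @export
select_window <- function(records, bin_start, bin_end, smooth = TRUE) {
  stopifnot(is.data.frame(records), "day_postpartum" %in% names(records))
  w <- window_bounds_(bin_start, bin_end, smooth)
  records[records$day_postpartum >= w[1] & records$day_postpartum < w[2], ,
          drop = FALSE]
}

#' Build a day-postpartum normative MM% percentile chart
#'
#' Computes empirical MM% percentiles (by default the 15th, 50th and 85th)
#' per day bin from scans of the normal-breastfeeding reference population,
#' using linear interpolation between order statistics (the `type = 7`
#' quantile estimator) and the smoothing windows of [select_window()]. Bins
#' whose window selects fewer than `min_n` records get missing values rather
#' than unstable percentiles.
#'
#' @param records Normal-class scan records with `day_postpartum` and
#'   `mm_percent` columns. If a `class_label` column is present it must be
#'   entirely `"normal"`; filter first otherwise.
#' @param bins Bin table as from [default_bins()].
#' @param levels Percentile levels in percent (default `c(15, 50, 85)`).
#' @param min_n Minimum records per window before a bin's percentiles are
#'   emitted (default 5).
#' @param smooth Apply the day-matched smoothing windows (default `TRUE`).
#' @return A `reference_chart`: a tibble with `bin_start`, `bin_end`, `n`
#'   and one `p<level>` column per level, plus provenance attributes.
#' @examples
#' recs <- tibble::tibble(day_postpartum = runif(300, 0, 30),
#'                        mm_percent = pmin(100, runif(300, 50, 110)))
#' chart <- build_reference(recs)
#' lookup_reference(chart, day = 4.5, level = 15)
#' @export
build_reference <- function(records, bins = default_bins(),
                            levels = c(15, 50, 85), min_n = 5,
                            smooth = TRUE) {
  stopifnot(is.data.frame(records),
            all(c("day_postpartum", "mm_percent") %in% names(records)))
  if ("class_label" %in% names(records) &&
      !all(records$class_label == "normal")) {
    abort("Reference charts are built from normal-class records only; filter first.",
          class = "milksense_bad_input")
  }
  stopifnot(is.data.frame(bins),
            all(c("bin_start", "bin_end") %in% names(bins)),
            all(bins$bin_start < bins$bin_end),
            !is.unsorted(bins$bin_start))
  levels <- sort(levels)

  rows <- purrr::pmap(bins, function(bin_start, bin_end) {
    v <- select_window(records, bin_start, bin_end, smooth)$mm_percent
    n <- length(v)
    q <- if (n >= min_n) {
      quantile(v, probs = levels / 100, type = 7, names = FALSE)
    } else {
      rep(NA_real_, length(levels))
    }
    tibble::tibble(bin_start = bin_start, bin_end = bin_end, n = n,
                   !!!stats::setNames(as.list(q), paste0("p", levels)))
  })
  chart <- dplyr::bind_rows(rows)
  if (all(is.na(chart[[paste0("p", levels[1])]]))) {
    abort("Empty reference chart: no bin reached min_n records.",
          class = "milksense_empty_chart")
  }
  # percentile ordering must hold within every populated bin
  pc <- as.matrix(chart[paste0("p", levels)])
  ok <- apply(pc, 1L, function(r) all(is.na(r)) || !is.unsorted(r))
  stopifnot(all(ok))
  structure(
    chart,
    class = c("reference_chart", class(chart)),
    percentile_levels = levels,
    min_n = min_n,
    smooth = smooth,
    provenance = list(
      config_hash = rlang::hash(list(bins = as.data.frame(bins),
                                     levels = levels, min_n = min_n,
                                     smooth = smooth)),
      n_records = nrow(records)
    )
  )
}

#' Look up a reference percentile for a day postpartum
#'
#' Finds the unique bin containing each day (half-open bins, so day 21.0
#' falls in `[21, 28)`) and returns its percentile value; missing bins
#' propagate `NA`.
#'
#' @param chart A `reference_chart` from [build_reference()].
#' @param day Day(s) postpartum, >= 0.
#' @param level Percentile level, one of the chart's levels.
#' @return MM% values, same length as `day` (`NA` where the bin is missing).
#' @export
lookup_reference <- function(chart, day, level = 15) {
  stopifnot(inherits(chart, "reference_chart"))
  if (any(!is.finite(day)) || any(day < 0)) {
    abort("`day` must be finite and >= 0.", class = "milksense_bad_input")
  }
  levels <- attr(chart, "percentile_levels")
  if (!level %in% levels) {
    abort(sprintf("Level %s not in chart levels (%s).", level,
                  paste(levels, collapse = ", ")),
          class = "milksense_bad_input")
  }
  idx <- findInterval(day, chart$bin_start)
  idx[idx == 0L] <- NA_integer_ # day below the first bin start
  chart[[paste0("p", level)]][idx]
}

#' Flag scans against a day-matched percentile threshold
#'
#' Compares each scan's MM% with the reference percentile for its day
#' postpartum. The comparison is strict: a scan exactly on the threshold
#' line counts as `at_or_above`. Scans whose day falls in a bin without
#' reference values are flagged `no_reference`.
#'
#' @param records Scan records with `day_postpartum` and `mm_percent`.
#' @param chart A `reference_chart`.
#' @param level Percentile level used as threshold (default 15).
#' @return `records` with `reference_mm` and `flag` (factor with levels
#'   below / at_or_above / no_reference) appended.
#' @export
flag_scans <- function(records, chart, level = 15) {
  stopifnot(is.data.frame(records),
            all(c("day_postpartum", "mm_percent") %in% names(records)))
  ref <- lookup_reference(chart, records$day_postpartum, level)
  flag <- dplyr::case_when(
    is.na(ref) ~ "no_reference",
    records$mm_percent < ref ~ "below",
    TRUE ~ "at_or_above"
  )
  dplyr::mutate(tibble::as_tibble(records),
                reference_mm = ref,
                flag = factor(flag,
                              levels = c("below", "at_or_above",
                                         "no_reference")))
}

#' Serialize / restore a reference chart
#'
#' The chart table is written as CSV (columns `bin_start_day`,
#' `bin_end_day`, `n`, `p<level>`...) with a JSON sidecar (`<path>.json`)
#' holding the percentile levels, settings and provenance, including a
#' full-precision copy of the percentile values so the round trip is
#' bit-exact.
#'
#' @param chart A `reference_chart`.
#' @param path CSV path; the sidecar is written next to it as `<path>.json`.
#' @return `write_reference_chart()` returns `path` invisibly;
#'   `read_reference_chart()` returns the restored `reference_chart`.
#' @export
write_reference_chart <- function(chart, path) {
  stopifnot(inherits(chart, "reference_chart"))
  levels <- attr(chart, "percentile_levels")
  out <- tibble::as_tibble(chart)
  names(out)[names(out) == "bin_start"] <- "bin_start_day"
  names(out)[names(out) == "bin_end"] <- "bin_end_day"
  readr::write_csv(out, path)
  sidecar <- list(
    percentile_levels = levels,
    min_n = attr(chart, "min_n"),
    smooth = attr(chart, "smooth"),
    provenance = attr(chart, "provenance"),
    values = lapply(stats::setNames(nm = paste0("p", levels)),
                    function(cn) chart[[cn]])
  )
  # 17 significant digits so the sidecar restores doubles bit-exactly
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = I(17), na = "null")
  invisible(path)
}

#' @rdname write_reference_chart
#' @export
read_reference_chart <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  x <- readr::read_csv(path, show_col_types = FALSE,
                       col_types = readr::cols(.default = readr::col_double(),
                                               n = readr::col_integer()))
  names(x)[names(x) == "bin_start_day"] <- "bin_start"
  names(x)[names(x) == "bin_end_day"] <- "bin_end"
  levels <- as.numeric(side$percentile_levels)
  for (cn in paste0("p", levels)) { # sidecar copy is the bit-exact source
    v <- side$values[[cn]]
    if (is.list(v)) {
      v <- vapply(v, function(e) if (is.null(e)) NA_real_ else as.numeric(e),
                  numeric(1))
    }
    x[[cn]] <- as.numeric(v)
  }
  structure(
    x,
    class = c("reference_chart", class(x)),
    percentile_levels = levels,
    min_n = side$min_n,
    smooth = side$smooth,
    provenance = side$provenance
  )
}

#' @export
print.reference_chart <- function(x, ...) {
  lv <- attr(x, "percentile_levels")
  cat(sprintf("<reference_chart> %d bins, percentiles %s, built from %d records\n",
              nrow(x), paste0("p", lv, collapse = "/"),
              attr(x, "provenance")$n_records))
  NextMethod()
}

#' @describeIn build_reference Long-format tibble of the chart (one row per
#'   bin and percentile level).
#' @param x A `reference_chart`.
#' @param ... Unused.
#' @method tidy reference_chart
#' @export
tidy.reference_chart <- function(x, ...) {
  levels <- attr(x, "percentile_levels")
  out <- tidyr::pivot_longer(tibble::as_tibble(x),
                             cols = dplyr::all_of(paste0("p", levels)),
                             names_to = "level", values_to = "mm_percent")
  out$level <- as.integer(sub("^p", "", out$level))
  out
}
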