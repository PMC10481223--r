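test_that("default bins are daily for three weeks then coarser", {
  b <- default_bins()
  expect_equal(nrow(b), 26)
  expect_equal(c(b$bin_start[1], b$bin_end[1]), c(0, 1))
  expect_equal(b$bin_end[26], Inf)
  expect_true(all(b$bin_start < b$bin_end))
  # contiguous and ordered
  expect_equal(b$bin_start[-1], b$bin_end[-26])
})

test_that("smoothing windows are +/-24h early and trailing-only later", {
  recs <- tibble::tibble(day_postpartum = c(0.2, 2.5, 4.2, 6.1),
                         mm_percent = 1:4)
  # daily bin [1,2): +/- 24 h window [0, 3) includes day 2.5
  w <- select_window(recs, 1, 2)
  expect_setequal(w$day_postpartum, c(0.2, 2.5))
  # bin [5,6): trailing window [4, 6) includes 4.2, excludes 6.1
  w2 <- select_window(recs, 5, 6)
  expect_equal(w2$day_postpartum, 4.2)
  # window floor never goes below day 0
  expect_equal(window_bounds_(0, 1), c(0, 2))
  # smoothing off selects the bare bin
  expect_equal(nrow(select_window(recs, 1, 2, smooth = FALSE)), 0)
})

test_that("reference percentiles match a hand sort-and-interpolate", {
  recs <- tibble::tibble(day_postpartum = rep(10.5, 10),
                         mm_percent = seq(10, 100, by = 10))
  chart <- build_reference(recs, bins = tibble::tibble(bin_start = 10,
                                                       bin_end = 11))
  expect_equal(unname(unlist(chart[1, c("p15", "p50", "p85")])),
               oracle_quantile(seq(10, 100, by = 10), c(.15, .50, .85)))
  # a constant sample gives a flat triple
  recs2 <- tibble::tibble(day_postpartum = rep(3.5, 8), mm_percent = 70)
  chart2 <- build_reference(recs2, bins = tibble::tibble(bin_start = 3,
                                                         bin_end = 4))
  expect_equal(unname(unlist(chart2[1, c("p15", "p50", "p85")])),
               c(70, 70, 70))
})

test_that("bins below min_n get missing values; empty charts error", {
  recs <- tibble::tibble(day_postpartum = c(rep(0.5, 8), rep(10.5, 3)),
                         mm_percent = c(rnorm(8, 50, 5), 80, 85, 90))
  chart <- build_reference(recs, min_n = 5)
  expect_true(is.na(chart$p50[chart$bin_start == 10]))
  expect_equal(chart$n[chart$bin_start == 10], 3L)
  expect_false(is.na(chart$p50[chart$bin_start == 0]))
  expect_error(
    build_reference(tibble::tibble(day_postpartum = 1, mm_percent = 50)),
    class = "milksense_empty_chart")
  expect_error(
    build_reference(dplyr::mutate(recs, class_label = "low_supply")),
    class = "milksense_bad_input")
})

test_that("percentiles are ordered p15 <= p50 <= p85 on random data", {
  set.seed(123)
  for (i in 1:10) {
    recs <- tibble::tibble(
      day_postpartum = runif(400, 0, 80),
      mm_percent = pmin(pmax(rnorm(400, 70, 25), 0), 100)
    )
    chart <- build_reference(recs)
    ok <- !is.na(chart$p50)
    expect_true(all(chart$p15[ok] <= chart$p50[ok]))
    expect_true(all(chart$p50[ok] <= chart$p85[ok]))
  }
})

test_that("with smoothing disabled the chart equals a naive per-bin oracle", {
  set.seed(5)
  recs <- tibble::tibble(day_postpartum = runif(500, 0, 70),
                         mm_percent = runif(500, 0, 100))
  chart <- build_reference(recs, smooth = FALSE, min_n = 1)
  bins <- default_bins()
  for (i in seq_len(nrow(bins))) {
    v <- recs$mm_percent[recs$day_postpartum >= bins$bin_start[i] &
                           recs$day_postpartum < bins$bin_end[i]]
    if (length(v) == 0) next
    expect_identical(unname(unlist(chart[i, c("p15", "p50", "p85")])),
                     oracle_quantile(v, c(.15, .5, .85)))
  }
})

test_that("lookup uses half-open bins and propagates missing values", {
  recs <- tibble::tibble(day_postpartum = runif(2000, 0, 80),
                         mm_percent = runif(2000, 40, 100))
  chart <- build_reference(recs)
  expect_equal(lookup_reference(chart, 0.5, 50), chart$p50[1])
  # day exactly 21 falls in [21, 28), not [20, 21)
  expect_equal(lookup_reference(chart, 21, 50),
               chart$p50[chart$bin_start == 21])
  expect_equal(lookup_reference(chart, 400, 50), chart$p50[26])
  expect_error(lookup_reference(chart, -1), class = "milksense_bad_input")
  expect_error(lookup_reference(chart, 5, level = 40),
               class = "milksense_bad_input")
})

test_that("flagging is strict at the threshold and handles missing bins", {
  recs <- tibble::tibble(day_postpartum = rep(5.5, 20),
                         mm_percent = seq(20, 96, length.out = 20))
  chart <- build_reference(recs, bins = tibble::tibble(bin_start = c(5, 10),
                                                       bin_end = c(6, 11)))
  thr <- lookup_reference(chart, 5.5, 15)
  expect_true(is.na(lookup_reference(chart, 10.5, 15)))
  scans <- tibble::tibble(
    day_postpartum = c(5.2, 5.2, 5.2, 10.5),
    mm_percent = c(thr - 1, thr, thr + 1, 50)
  )
  fl <- flag_scans(scans, chart, level = 15)
  expect_equal(as.character(fl$flag),
               c("below", "at_or_above", "at_or_above", "no_reference"))
})

test_that("chart serialization round-trips bit-exactly", {
  set.seed(9)
  recs <- tibble::tibble(day_postpartum = runif(800, 0, 90),
                         mm_percent = runif(800, 0, 100))
  chart <- build_reference(recs)
  path <- withr::local_tempfile(fileext = ".csv")
  write_reference_chart(chart, path)
  back <- read_reference_chart(path)
  expect_identical(back$p15, chart$p15)
  expect_identical(back$p50, chart$p50)
  expect_identical(back$p85, chart$p85)
  expect_identical(back$n, chart$n)
  expect_identical(attr(back, "provenance")$config_hash,
                   attr(chart, "provenance")$config_hash)
  expect_identical(attr(back, "percentile_levels"),
                   attr(chart, "percentile_levels"))
})

test_that("tidy() pivots the chart into long percentile format", {
  recs <- tibble::tibble(day_postpartum = runif(300, 0, 30),
                         mm_percent = runif(300, 50, 100))
  chart <- build_reference(recs)
  long <- tidy(chart)
  expect_setequal(unique(long$level), c(15, 50, 85))
  expect_equal(nrow(long), 3 * nrow(chart))
})
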