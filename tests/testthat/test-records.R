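test_that("scan-records CSV parses, computes day postpartum, collects rejects", {
  path <- write_scan_csv(c(
    "M1,2020-01-01T00:00:00Z,2020-01-06T12:00:00Z,left,70.5,provider,exclusive,,FALSE,",
    "M1,2020-01-01T00:00:00Z,2020-01-07T00:00:00Z,right,72,provider,exclusive,,FALSE,breast_pain",
    "M2,2020-02-01T08:00:00Z,2020-02-03T08:00:00Z,left,40,mother,partial,0.5,TRUE,low_milk_supply;slow_weight_gain"
  ))
  x <- read_scan_records(path)
  expect_equal(nrow(x), 3)
  expect_equal(nrow(scan_rejects(x)), 0)
  expect_equal(x$day_postpartum, c(5.5, 6, 2))

  # scan before birth is rejected, not dropped silently
  path2 <- write_scan_csv(c(
    "M1,2020-01-10T00:00:00Z,2020-01-06T00:00:00Z,left,70,provider,exclusive,,FALSE,",
    "M1,2020-01-01T00:00:00Z,2020-01-06T00:00:00Z,left,70,provider,exclusive,,FALSE,"
  ))
  expect_warning(y <- read_scan_records(path2), "rejected")
  expect_equal(nrow(y), 1)
  expect_equal(scan_rejects(y)$reason, "negative day_postpartum")

  # empty file with header parses to an empty record set
  path3 <- write_scan_csv(character())
  z <- read_scan_records(path3)
  expect_equal(nrow(z), 0)

  # missing mandatory columns are named
  path4 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("mother_id,scan_time", "M1,2020-01-02T00:00:00Z"), path4)
  expect_error(read_scan_records(path4), "baby_birth",
               class = "milksense_schema_error")
})

test_that("classification follows the documented rules", {
  # exclusive feeding with no problems is normal
  r <- classify_scans(make_scan())
  expect_equal(as.character(r$class_label), "normal")
  expect_equal(r$rule_fired, "N1")

  # provider-reported partial feeding + recent formula + latch problem
  r <- classify_scans(make_scan(feeding_status = "partial",
                                formula_fraction_daily = 0.5,
                                formula_last_24h = TRUE,
                                problem_tags = "latch_problem"))
  expect_equal(as.character(r$class_label), "low_supply")
  expect_equal(r$rule_fired, "L1")

  # predominant breastfeeding tagged with tongue tie
  r <- classify_scans(make_scan(feeding_status = "predominant_80plus",
                                formula_fraction_daily = 0.1,
                                formula_last_24h = TRUE,
                                problem_tags = "tongue_tie"))
  expect_equal(as.character(r$class_label), "bf_problems")
  expect_equal(r$rule_fired, "B2")

  # partial feeding without any tagged problem
  r <- classify_scans(make_scan(feeding_status = "partial",
                                formula_fraction_daily = 0.5,
                                formula_last_24h = TRUE))
  expect_equal(as.character(r$class_label), "bf_problems")
  expect_equal(r$rule_fired, "B1")

  # mother-reported supply indicators with substantial formula
  r <- classify_scans(make_scan(reporter = "mother",
                                feeding_status = "mostly_formula",
                                formula_fraction_daily = 0.9,
                                formula_last_24h = TRUE,
                                problem_tags = "slow_weight_gain"))
  expect_equal(as.character(r$class_label), "low_supply")
  expect_equal(r$rule_fired, "L2")

  # pain tags alone never trigger the supply rules
  r <- classify_scans(make_scan(problem_tags = "breast_pain;nipple_pain"))
  expect_equal(as.character(r$class_label), "normal")
})

test_that("inconsistent records raise a validation error naming the conflict", {
  expect_error(
    classify_scans(make_scan(formula_last_24h = TRUE)),
    "formula_last_24h", class = "milksense_validation_error")
  expect_error(
    classify_scans(make_scan(feeding_status = "predominant_80plus",
                             formula_fraction_daily = 0.5,
                             formula_last_24h = TRUE)),
    class = "milksense_validation_error")
  v <- validate_scan_records(make_scan(feeding_status = "partial",
                                       formula_fraction_daily = 0.1,
                                       formula_last_24h = TRUE))
  expect_equal(nrow(v), 1)
  expect_match(v$conflict, "partial/mostly_formula")
})

test_that("classification is deterministic and order-invariant", {
  set.seed(7)
  recs <- dplyr::bind_rows(lapply(1:40, function(i) {
    make_scan(mother_id = sprintf("M%02d", i),
              reporter = sample(c("provider", "mother"), 1),
              feeding_status = sample(feeding_levels(), 1),
              formula_fraction_daily = NA_real_,
              formula_last_24h = FALSE,
              problem_tags = paste(sample(problem_tag_levels(),
                                          sample(0:2, 1)),
                                   collapse = ";"))
  }))
  a <- classify_scans(recs)
  perm <- sample(nrow(recs))
  b <- classify_scans(recs[perm, ])
  expect_equal(as.character(b$class_label), as.character(a$class_label)[perm])
  expect_equal(classify_scans(recs)$class_label, a$class_label)
})

test_that("classification summary tallies tags per class", {
  recs <- dplyr::bind_rows(
    make_scan(feeding_status = "predominant_80plus",
              formula_fraction_daily = 0.1, formula_last_24h = TRUE,
              problem_tags = "latch_problem"),
    make_scan(feeding_status = "predominant_80plus",
              formula_fraction_daily = 0.1, formula_last_24h = TRUE,
              problem_tags = "latch_problem;tongue_tie"),
    make_scan(feeding_status = "predominant_80plus",
              formula_fraction_daily = 0.1, formula_last_24h = TRUE,
              problem_tags = "latch_problem"),
    make_scan(feeding_status = "predominant_80plus",
              formula_fraction_daily = 0.1, formula_last_24h = TRUE,
              problem_tags = "tongue_tie"),
    make_scan(feeding_status = "partial", formula_fraction_daily = 0.5,
              formula_last_24h = TRUE),
    make_scan()
  )
  s <- classification_summary(classify_scans(recs))
  cls <- s$classes
  expect_equal(cls$n[cls$class_label == "bf_problems"], 5L)
  expect_equal(cls$n[cls$class_label == "normal"], 1L)
  # 4 tag-carrying bf_problems records: latch on 3 (75%), tongue on 2 (50%)
  tg <- s$tags[s$tags$class_label == "bf_problems", ]
  expect_equal(tg$pct[tg$tag == "latch_problem"], 75)
  expect_equal(tg$pct[tg$tag == "tongue_tie"], 50)

  # all-normal input has an empty tag table; empty input is empty
  s2 <- classification_summary(classify_scans(
    dplyr::bind_rows(lapply(1:10, function(i) make_scan()))))
  expect_equal(s2$classes$n[s2$classes$class_label == "normal"], 10L)
  expect_equal(nrow(s2$tags), 0)
  s3 <- classification_summary(make_scan()[0, ])
  expect_equal(nrow(s3$classes), 0)
})
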