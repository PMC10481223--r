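test_that("conductance converts through the cell constant", {
  expect_equal(conductance_to_conductivity(3.00), 3.00)
  expect_equal(conductance_to_conductivity(3.00, 1.1), 3.30)
  expect_error(conductance_to_conductivity(0), class = "milksense_bad_input")
  expect_error(conductance_to_conductivity(-1), class = "milksense_bad_input")
  expect_error(conductance_to_conductivity(3, cell_constant = 0),
               class = "milksense_bad_input")
})

test_that("temperature correction follows the linear compensation model", {
  expect_equal(temperature_correct(3.00, 25.0, 0.02), 3.00)
  expect_equal(temperature_correct(3.12, 27.0, 0.02), 3.00)
  expect_equal(temperature_correct(2.88, 23.0, 0.02), 3.00)
  # inverse of the forward distortion for any T in (10, 40)
  for (temp in seq(10.5, 39.5, by = 2.3)) {
    distorted <- 3.4 * (1 + 0.02 * (temp - 25))
    expect_equal(temperature_correct(distorted, temp, 0.02), 3.4,
                 tolerance = 1e-12)
  }
  expect_error(temperature_correct(3, -40, 0.02),
               class = "milksense_bad_input")
  expect_error(temperature_correct(3, 25, 0.5),
               class = "milksense_bad_input")
})

test_that("two-point calibration fit recovers an affine device response", {
  idn <- fit_calibration(
    data.frame(true_mS_cm = c(1.413, 12.88),
               measured_mS_cm = c(1.413, 12.88)), "dev")
  expect_equal(idn$gain, 1, tolerance = 1e-12)
  expect_equal(idn$offset, 0, tolerance = 1e-12)

  std <- data.frame(true_mS_cm = c(1.413, 12.88),
                    measured_mS_cm = 1.05 * c(1.413, 12.88) + 0.073)
  cal <- fit_calibration(std, "dev")
  expect_equal(cal$gain, 1.05, tolerance = 1e-9)
  expect_equal(cal$offset, 0.073, tolerance = 1e-9)
  # round trip through the fitted inverse map
  expect_lt(max(abs(apply_calibration(std$measured_mS_cm, cal) -
                      std$true_mS_cm)), 1e-9)

  expect_error(
    fit_calibration(data.frame(true_mS_cm = 1.413, measured_mS_cm = 1.5)),
    class = "milksense_insufficient_calibration")
  expect_error(
    fit_calibration(data.frame(true_mS_cm = c(1.413, 1.413),
                               measured_mS_cm = c(1.4, 1.5))),
    class = "milksense_insufficient_calibration")
})

test_that("calibration clamps non-physical values to zero with a warning", {
  cal <- fit_calibration(
    data.frame(true_mS_cm = c(1.413, 12.88),
               measured_mS_cm = 1.05 * c(1.413, 12.88) + 0.073), "dev")
  expect_equal(apply_calibration(3.223, cal), 3.0, tolerance = 1e-9)
  expect_warning(out <- apply_calibration(0.073, cal), "non-physical")
  expect_identical(out, 0)
})

test_that("random affine distortions are recovered from two standards", {
  set.seed(42)
  for (i in 1:20) {
    gain <- runif(1, 0.8, 1.2)
    offset <- runif(1, -0.5, 0.5)
    truth <- c(1.413, 12.88)
    cal <- fit_calibration(
      data.frame(true_mS_cm = truth,
                 measured_mS_cm = gain * truth + offset), "d")
    sigma <- runif(1, 2, 7)
    expect_equal(apply_calibration(gain * sigma + offset, cal), sigma,
                 tolerance = 1e-9)
  }
})

test_that("the full processing chain is monotone and inverts the device model", {
  std <- data.frame(device_id = "D1",
                    true_mS_cm = c(1.413, 12.88),
                    measured_mS_cm = 1.08 * c(1.413, 12.88) - 0.12)
  store <- fit_calibration_store(std)
  sigma <- seq(2, 7, by = 0.5)
  temp <- 31.7
  readings <- tibble::tibble(
    device_id = "D1",
    conductance_mS = (1.08 * sigma - 0.12) * (1 + 0.02 * (temp - 25)),
    temperature_C = temp
  )
  out <- process_readings(readings, store)
  expect_equal(out$conductivity_25C, sigma, tolerance = 1e-9)
  expect_true(all(diff(out$conductivity_25C) > 0))
  expect_true(all(out$quality == "ok"))
})

test_that("devices without a calibration fall back to identity", {
  readings <- tibble::tibble(device_id = c("known", "unknown"),
                             conductance_mS = c(3.6, 3.6),
                             temperature_C = c(25, 25))
  std <- data.frame(device_id = "known", true_mS_cm = c(1.413, 12.88),
                    measured_mS_cm = 1.2 * c(1.413, 12.88))
  out <- process_readings(readings, fit_calibration_store(std))
  expect_equal(out$conductivity_25C, c(3.6 / 1.2, 3.6))
})

test_that("calibration store serializes to JSON and restores equal fits", {
  std <- data.frame(
    device_id = rep(c("A", "B"), each = 2),
    true_mS_cm = rep(c(1.413, 12.88), 2),
    measured_mS_cm = c(1.02 * c(1.413, 12.88) + 0.05,
                       0.97 * c(1.413, 12.88) - 0.02)
  )
  store <- fit_calibration_store(std)
  path <- withr::local_tempfile(fileext = ".json")
  write_calibration_store(store, path)
  back <- read_calibration_store(path)
  expect_identical(names(back), names(store))
  for (id in names(store)) {
    expect_equal(back[[id]]$gain, store[[id]]$gain)
    expect_equal(back[[id]]$offset, store[[id]]$offset)
  }
})

test_that("readings CSV rejects out-of-range rows and flags odd volumes", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "device_id,timestamp,breast_side,conductance_mS,temperature_C,sample_volume_ml",
    "D1,2020-01-05T10:00:00Z,left,3.5,30,0.5",
    "D1,2020-01-05T10:05:00Z,right,-1,30,0.5",
    "D1,2020-01-05T10:10:00Z,left,3.2,55,0.5",
    "D1,2020-01-05T10:15:00Z,right,3.1,30,0.7"
  ), path)
  expect_warning(x <- read_readings(path), "sample volumes")
  expect_equal(nrow(x), 2)
  rej <- attr(x, "rejects")
  expect_setequal(rej$reason,
                  c("non-positive conductance", "temperature outside (0, 50) C"))
})
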