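#' Convert measured conductance to raw conductivity
#'
#' A two-electrode sample cell reports conductance in millisiemens; the cell
#' constant K (in 1/cm) is the geometric factor that converts this to
#' conductivity in mS/cm. The device modelled here uses K = 1, so the map is
#' the identity by default, but K is kept as an explicit parameter.
#'
#' @param conductance Measured conductance in mS. Must be strictly positive.
#' @param cell_constant Cell constant K in 1/cm (default 1).
#' @return Conductivity in mS/cm, same length as `conductance`.
#' @examples
#' conductance_to_conductivity(3.0)        # 3.0 mS/cm
#' conductance_to_conductivity(3.0, 1.1)   # 3.3 mS/cm
#' @export
conductance_to_conductivity <- function(conductance, cell_constant = 1) {
  if (!is.numeric(conductance) || any(!is.finite(conductance)) ||
      any(conductance <= 0)) {
    abort("`conductance` must be finite and > 0 (mS).",
          class = "milksense_bad_input")
  }
  if (length(cell_constant) != 1L || !is.finite(cell_constant) ||
      cell_constant <= 0) {
    abort("`cell_constant` must be a single positive number (1/cm).",
          class = "milksense_bad_input")
  }
  conductance * cell_constant
}

#' Temperature-correct conductivity to 25 degrees Celsius
#'
#' Electrolyte conductivity rises roughly linearly with temperature. The
#' standard linear compensation model is
#' `sigma_25 = sigma_T / (1 + alpha * (T - 25))`, with alpha about 2% per
#' degree C for dilute aqueous KCl-like electrolytes. At 25 C the input is
#' returned unchanged.
#'
#' @param conductivity Conductivity at the measurement temperature, mS/cm.
#' @param temperature Sample temperature in degrees Celsius.
#' @param temp_coefficient Linear temperature coefficient alpha, per degree C
#'   (default 0.020).
#' @return Conductivity referenced to 25 C, mS/cm.
#' @examples
#' temperature_correct(3.12, 27)  # 3.00
#' temperature_correct(2.88, 23)  # 3.00
#' @export
temperature_correct <- function(conductivity, temperature,
                                temp_coefficient = 0.020) {
  if (length(temp_coefficient) != 1L || !is.finite(temp_coefficient) ||
      temp_coefficient < 0 || temp_coefficient >= 0.1) {
    abort("`temp_coefficient` must be in [0, 0.1) per degree C.",
          class = "milksense_bad_input")
  }
  denom <- 1 + temp_coefficient * (temperature - 25)
  if (any(!is.finite(denom)) || any(denom <= 0)) {
    abort(
      "Temperature out of compensable range: 1 + alpha*(T - 25) must be > 0.",
      class = "milksense_bad_input"
    )
  }
  conductivity / denom
}

#' Fit a per-device calibration from standard-solution readings
#'
#' Each device is calibrated against conductivity standards (conventionally
#' the KCl 1.413 and 12.88 mS/cm points). The device response is modelled as
#' an affine measured-to-true map `measured = gain * true + offset`, fitted by
#' ordinary least squares; with exactly two distinct standards the fit is the
#' exact interpolant.
#'
#' @param standards A data frame with columns `true_mS_cm` and
#'   `measured_mS_cm`, one row per standard reading. At least two rows with
#'   distinct true values are required.
#' @param device_id Identifier of the device the standards were read on.
#' @param cell_constant Cell constant K of the device, 1/cm.
#' @param temp_coefficient Temperature coefficient used by this device's
#'   correction stage, per degree C.
#' @return A `device_calibration` object: gain, offset, cell constant,
#'   temperature coefficient and the standards used.
#' @seealso [apply_calibration()], [process_readings()]
#' @examples
#' std <- data.frame(true_mS_cm = c(1.413, 12.88),
#'                   measured_mS_cm = c(1.413, 12.88))
#' fit_calibration(std, "dev1")  # identity device: gain 1, offset 0
#' @export
fit_calibration <- function(standards, device_id = NA_character_,
                            cell_constant = 1, temp_coefficient = 0.020) {
  req <- c("true_mS_cm", "measured_mS_cm")
  if (!is.data.frame(standards) || !all(req %in% names(standards))) {
    abort("`standards` needs columns true_mS_cm and measured_mS_cm.",
          class = "milksense_bad_input")
  }
  tr <- standards$true_mS_cm
  ms <- standards$measured_mS_cm
  if (nrow(standards) < 2L || length(unique(tr)) < 2L) {
    abort(
      "Insufficient calibration: need >= 2 standards with distinct true values.",
      class = "milksense_insufficient_calibration"
    )
  }
  fit <- lm(ms ~ tr)
  gain <- unname(coef(fit)[2L])
  offset <- unname(coef(fit)[1L])
  if (!is.finite(gain) || gain <= 0) {
    abort("Fitted calibration gain must be > 0.",
          class = "milksense_invalid_calibration")
  }
  structure(
    list(
      device_id = device_id,
      gain = gain,
      offset = offset,
      cell_constant = cell_constant,
      temp_coefficient = temp_coefficient,
      standards = tibble::as_tibble(standards[req])
    ),
    class = "device_calibration"
  )
}

#' @export
print.device_calibration <- function(x, ...) {
  cat(sprintf(
    "<device_calibration %s>  gain = %.6g, offset = %.6g mS/cm, K = %g /cm\n",
    x$device_id, x$gain, x$offset, x$cell_constant
  ))
  invisible(x)
}

#' Apply a fitted calibration to raw conductivity values
#'
#' Inverts the fitted measured-to-true device map:
#' `true = (raw - offset) / gain`. Non-physical results (<= 0 mS/cm) are
#' returned as 0 with a warning rather than an error, so batch pipelines do
#' not abort on isolated bad readings; [process_readings()] records a quality
#' flag for such rows.
#'
#' @param raw Raw (uncalibrated) conductivity values, mS/cm.
#' @param cal A `device_calibration` from [fit_calibration()].
#' @return Calibrated conductivity, mS/cm.
#' @export
apply_calibration <- function(raw, cal) {
  stopifnot(inherits(cal, "device_calibration"))
  if (!is.finite(cal$gain) || cal$gain <= 0) {
    abort("Invalid calibration: gain must be > 0.",
          class = "milksense_invalid_calibration")
  }
  out <- (raw - cal$offset) / cal$gain
  bad <- out <= 0
  if (any(bad)) {
    warn(sprintf(
      "%d calibrated value(s) were non-physical (<= 0 mS/cm); returned as 0.",
      sum(bad)
    ))
    out[bad] <- 0
  }
  out
}

#' Fit calibrations for every device in a standards table
#'
#' @param standards A data frame with columns `device_id`, `true_mS_cm`,
#'   `measured_mS_cm` (several rows per device).
#' @inheritParams fit_calibration
#' @return A named list of `device_calibration` objects keyed by device id.
#' @export
fit_calibration_store <- function(standards, cell_constant = 1,
                                  temp_coefficient = 0.020) {
  stopifnot(is.data.frame(standards), "device_id" %in% names(standards))
  ids <- unique(standards$device_id)
  stats::setNames(
    lapply(ids, function(id) {
      fit_calibration(standards[standards$device_id == id, , drop = FALSE],
                      device_id = id, cell_constant = cell_constant,
                      temp_coefficient = temp_coefficient)
    }),
    ids
  )
}

#' Serialize / restore a calibration store
#'
#' The store is written as JSON keyed by device id, holding gain, offset,
#' cell constant, temperature coefficient and the standards used.
#'
#' @param store A named list of `device_calibration` objects.
#' @param path File path for the JSON store.
#' @return `write_calibration_store()` returns `path` invisibly;
#'   `read_calibration_store()` returns the restored named list.
#' @export
write_calibration_store <- function(store, path) {
  payload <- lapply(store, function(cal) {
    list(
      device_id = cal$device_id,
      gain = cal$gain,
      offset = cal$offset,
      cell_constant = cal$cell_constant,
      temp_coefficient = cal$temp_coefficient,
      standards = as.data.frame(cal$standards)
    )
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_calibration_store
#' @export
read_calibration_store <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  stats::setNames(
    lapply(payload, function(p) {
      structure(
        list(
          device_id = p$device_id,
          gain = p$gain,
          offset = p$offset,
          cell_constant = p$cell_constant,
          temp_coefficient = p$temp_coefficient,
          standards = tibble::as_tibble(p$standards)
        ),
        class = "device_calibration"
      )
    }),
    names(payload)
  )
}

#' Read raw sensor readings from CSV
#'
#' Expected columns: `device_id`, `timestamp` (ISO-8601), `breast_side`
#' (left/right), `conductance_mS`, `temperature_C`, and optionally
#' `sample_volume_ml`. Readings with non-positive conductance or a
#' temperature outside (0, 50) C are rejected with a reason; rejects are
#' attached as the `"rejects"` attribute. Sample volumes outside the
#' device-validated set {0.2, 0.5, 1, 2} ml raise a warning only.
#'
#' @param path Path to the readings CSV.
#' @return A tibble of valid readings.
#' @export
read_readings <- function(path) {
  req <- c("device_id", "timestamp", "breast_side", "conductance_mS",
           "temperature_C")
  x <- readr::read_csv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         device_id = readr::col_character(),
                         timestamp = readr::col_datetime(),
                         breast_side = readr::col_character(),
                         .default = readr::col_double()
                       ))
  missing <- setdiff(req, names(x))
  if (length(missing) > 0L) {
    abort(paste0("Readings CSV is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "milksense_schema_error")
  }
  reason <- dplyr::case_when(
    !is.finite(x$conductance_mS) | x$conductance_mS <= 0 ~
      "non-positive conductance",
    !is.finite(x$temperature_C) | x$temperature_C <= 0 |
      x$temperature_C >= 50 ~ "temperature outside (0, 50) C",
    !x$breast_side %in% c("left", "right") ~ "unknown breast_side",
    TRUE ~ NA_character_
  )
  if ("sample_volume_ml" %in% names(x)) {
    odd <- !is.na(x$sample_volume_ml) &
      !x$sample_volume_ml %in% c(0.2, 0.5, 1, 2)
    if (any(odd)) {
      warn(sprintf(
        "%d reading(s) have sample volumes outside the validated set {0.2, 0.5, 1, 2} ml.",
        sum(odd)
      ))
    }
  }
  rejects <- tibble::tibble(row = which(!is.na(reason)),
                            reason = reason[!is.na(reason)])
  out <- x[is.na(reason), , drop = FALSE]
  attr(out, "rejects") <- rejects
  out
}

#' Process raw readings into calibrated conductivity at 25 C
#'
#' Runs the full device chain on a readings table: conductance times the
#' cell constant, linear temperature correction to 25 C, then the per-device
#' calibration (inverse of the fitted measured-to-true map). Rows whose
#' calibrated value is non-physical (<= 0) are kept, set to 0 and flagged
#' `"nonphysical"` in the `quality` column.
#'
#' @param readings A tibble with columns `device_id`, `conductance_mS`,
#'   `temperature_C` (e.g. from [read_readings()] or [simulate_cohort()]).
#' @param calibrations A named list of `device_calibration` objects keyed by
#'   device id (see [fit_calibration_store()]), or `NULL` for an identity
#'   calibration on every device.
#' @param cell_constant,temp_coefficient Defaults used for devices without an
#'   entry in `calibrations`.
#' @return The input tibble with `conductivity_25C` (mS/cm) and `quality`
#'   (`"ok"` or `"nonphysical"`) columns appended.
#' @export
process_readings <- function(readings, calibrations = NULL,
                             cell_constant = 1, temp_coefficient = 0.020) {
  stopifnot(is.data.frame(readings))
  req <- c("device_id", "conductance_mS", "temperature_C")
  missing <- setdiff(req, names(readings))
  if (length(missing) > 0L) {
    abort(paste0("`readings` is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "milksense_schema_error")
  }
  n <- nrow(readings)
  gain <- rep(1, n)
  offset <- rep(0, n)
  kk <- rep(cell_constant, n)
  alpha <- rep(temp_coefficient, n)
  if (!is.null(calibrations)) {
    idx <- match(readings$device_id, names(calibrations))
    has <- !is.na(idx)
    gain[has] <- vapply(calibrations[idx[has]], `[[`, numeric(1), "gain")
    offset[has] <- vapply(calibrations[idx[has]], `[[`, numeric(1), "offset")
    kk[has] <- vapply(calibrations[idx[has]], `[[`, numeric(1),
                      "cell_constant")
    alpha[has] <- vapply(calibrations[idx[has]], `[[`, numeric(1),
                         "temp_coefficient")
  }
  raw <- readings$conductance_mS * kk
  at25 <- raw / (1 + alpha * (readings$temperature_C - 25))
  cond <- (at25 - offset) / gain
  quality <- ifelse(cond <= 0, "nonphysical", "ok")
  cond[cond <= 0] <- 0
  dplyr::mutate(tibble::as_tibble(readings),
                conductivity_25C = cond, quality = quality)
}
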