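#' Configure a synthetic breastfeeding cohort
#'
#' Parameters of the cohort generator. The defaults emulate the kind of
#' observational data set the analysis pipeline targets: 592 mothers, most
#' scanned by a lactation support provider at one or two home visits
#' concentrated in the first weeks postpartum, a small fraction
#' self-tracking at home with 8-42 scans, both breasts scanned per session,
#' and per-device affine response distortions calibrated away with two-point
#' KCl standards.
#'
#' Each breast's latent conductivity decays exponentially from the
#' colostrum anchor to the mature anchor,
#' `sigma(t) = sigma_mature + (sigma_colostrum - sigma_mature) *
#' exp(-max(t - onset, 0) / tau)`, with per-mother time constant `tau` and
#' onset delay drawn log-normally around class-specific defaults: normal
#' breastfeeding activates fastest, the mixed problems group slower, and
#' low supply slowest (`tau` 1.5 / 3 / 5 days, onset 0.5 / 1 / 2 days).
#'
#' @param n_mothers Number of mothers (default 592).
#' @param class_mix Named proportions over normal / low_supply / bf_problems
#'   (must sum to 1).
#' @param sigma_colostrum,sigma_mature Conductivity anchors, mS/cm; shared
#'   with the [maturation_model()] defaults.
#' @param tau_by_class Named decay time constants, days. The normal class
#'   must activate faster than low supply.
#' @param onset_by_class Named activation onset delays, days.
#' @param tau_sdlog,onset_sdlog Log-scale SD of the per-mother log-normal
#'   draws around the class defaults (individual variability).
#' @param breast_asymmetry_sd SD (days) of the per-breast onset jitter.
#' @param noise_cv Coefficient of variation of the multiplicative
#'   measurement noise on conductivity (default 0.05).
#' @param mother_mode_fraction Fraction of mothers self-tracking with their
#'   own device; the rest are scanned by providers.
#' @param provider_visits Possible numbers of provider visits per mother.
#' @param provider_day_meanlog,provider_day_sdlog Log-normal parameters of
#'   provider visit days postpartum.
#' @param mother_scans_range Range of total scans for self-tracking mothers.
#' @param day_range Simulated day-postpartum range.
#' @param n_devices Number of provider devices shared across provider-mode
#'   mothers (self-tracking mothers each get their own device).
#' @param device_gain_sd,device_offset_sd SD of per-device gain (around 1)
#'   and offset (around 0 mS/cm) distortions.
#' @param label_noise Fraction of scan records whose feeding metadata is
#'   re-drawn from a random other class (default 0; use to test classifier
#'   robustness).
#' @param shape MM% model shape used when computing the recorded scores.
#' @return A validated `cohort_config` list.
#' @seealso [simulate_cohort()]
#' @export
cohort_config <- function(n_mothers = 592,
                          class_mix = c(normal = 0.5, low_supply = 0.2,
                                        bf_problems = 0.3),
                          sigma_colostrum = 6, sigma_mature = 3,
                          tau_by_class = c(normal = 1.5, bf_problems = 3,
                                           low_supply = 5),
                          onset_by_class = c(normal = 0.5, bf_problems = 1,
                                             low_supply = 2),
                          tau_sdlog = 0.4, onset_sdlog = 0.4,
                          breast_asymmetry_sd = 0.3,
                          noise_cv = 0.05,
                          mother_mode_fraction = 37 / 592,
                          provider_visits = c(1, 2),
                          provider_day_meanlog = log(8),
                          provider_day_sdlog = 1,
                          mother_scans_range = c(8, 42),
                          day_range = c(0, 60),
                          n_devices = 30,
                          device_gain_sd = 0.05, device_offset_sd = 0.05,
                          label_noise = 0,
                          shape = "linear") {
  cls <- c("normal", "low_supply", "bf_problems")
  stopifnot(
    length(n_mothers) == 1L, n_mothers >= 1,
    setequal(names(class_mix), cls),
    abs(sum(class_mix) - 1) < 1e-8, all(class_mix >= 0),
    sigma_colostrum > sigma_mature, sigma_mature > 0,
    setequal(names(tau_by_class), cls), all(tau_by_class > 0),
    setequal(names(onset_by_class), cls), all(onset_by_class > 0),
    tau_by_class[["normal"]] < tau_by_class[["low_supply"]],
    tau_sdlog >= 0, onset_sdlog >= 0, breast_asymmetry_sd >= 0,
    noise_cv >= 0, noise_cv < 0.5,
    mother_mode_fraction >= 0, mother_mode_fraction <= 1,
    length(day_range) == 2L, day_range[1] >= 0, day_range[2] > day_range[1],
    n_devices >= 1, label_noise >= 0, label_noise <= 1
  )
  structure(
    list(
      n_mothers = as.integer(n_mothers), class_mix = class_mix[cls],
      sigma_colostrum = sigma_colostrum, sigma_mature = sigma_mature,
      tau_by_class = tau_by_class[cls], onset_by_class = onset_by_class[cls],
      tau_sdlog = tau_sdlog, onset_sdlog = onset_sdlog,
      breast_asymmetry_sd = breast_asymmetry_sd, noise_cv = noise_cv,
      mother_mode_fraction = mother_mode_fraction,
      provider_visits = provider_visits,
      provider_day_meanlog = provider_day_meanlog,
      provider_day_sdlog = provider_day_sdlog,
      mother_scans_range = mother_scans_range, day_range = day_range,
      n_devices = as.integer(n_devices),
      device_gain_sd = device_gain_sd, device_offset_sd = device_offset_sd,
      label_noise = label_noise, shape = shape
    ),
    class = "cohort_config"
  )
}

#' Latent conductivity trajectory
#'
#' Single-exponential approach from the colostrum anchor to the mature-milk
#' plateau, flat before the activation onset:
#' `sigma(t) = sigma_mature + (sigma_colostrum - sigma_mature) *
#' exp(-max(t - onset, 0) / tau)`.
#'
#' @param t Days postpartum.
#' @param tau Decay time constant, days.
#' @param onset Activation onset delay, days.
#' @param sigma_colostrum,sigma_mature Conductivity anchors, mS/cm.
#' @return Conductivity at 25 C, mS/cm.
#' @export
sigma_trajectory <- function(t, tau, onset, sigma_colostrum = 6,
                             sigma_mature = 3) {
  stopifnot(all(tau > 0), all(onset >= 0))
  sigma_mature + (sigma_colostrum - sigma_mature) *
    exp(-pmax(t - onset, 0) / tau)
}

# per-session feeding metadata consistent with one target class, built to
# invert the classifier's decision table
draw_feeding_ <- function(class_label, reporter) {
  pick <- function(x, prob = NULL) sample(x, 1L, prob = prob)
  if (class_label == "normal") {
    status <- pick(c("exclusive", "full_breastfeeding", "full_own_milk",
                     "predominant_80plus"), prob = c(0.55, 0.15, 0.1, 0.2))
    predom <- status == "predominant_80plus"
    tags <- if (runif(1) < 0.15) pick(c("breast_pain", "nipple_pain")) else ""
    list(feeding_status = status,
         formula_fraction_daily = if (predom) runif(1, 0.05, 0.2) else 0,
         formula_last_24h = predom,
         problem_tags = tags)
  } else if (class_label == "low_supply") {
    status <- pick(c("partial", "mostly_formula"), prob = c(0.7, 0.3))
    frac <- if (status == "partial") runif(1, 0.25, 0.8)
            else runif(1, 0.8, 0.95)
    tags <- if (reporter == "mother") {
      # mother-reported indirect indicators of low supply
      pick(c("low_milk_supply", "slow_weight_gain",
             "low_milk_supply;slow_weight_gain"))
    } else {
      pick(c("low_milk_supply", "low_weight_gain", "latch_problem",
             "low_milk_supply;slow_weight_gain", "tongue_tie"),
           prob = c(0.35, 0.25, 0.2, 0.1, 0.1))
    }
    list(feeding_status = status, formula_fraction_daily = frac,
         formula_last_24h = TRUE, problem_tags = tags)
  } else { # bf_problems
    if (runif(1) < 0.6) { # partial feeding, no tagged problems
      list(feeding_status = "partial",
           formula_fraction_daily = runif(1, 0.25, 0.8),
           formula_last_24h = TRUE, problem_tags = "")
    } else { # predominant breastfeeding tagged with problems
      tags <- pick(c("latch_problem", "tongue_tie", "low_weight_gain",
                     "low_milk_supply"), prob = c(0.41, 0.3, 0.23, 0.06))
      list(feeding_status = "predominant_80plus",
           formula_fraction_daily = runif(1, 0.02, 0.2),
           formula_last_24h = runif(1) < 0.5, problem_tags = tags)
    }
  }
}

#' Simulate a synthetic milk-sensing cohort
#'
#' Generates a complete synthetic data set: per-breast latent conductivity
#' trajectories with class-dependent activation kinetics, scan schedules for
#' provider visits and self-tracking mothers, device readings with
#' multiplicative measurement noise, forward temperature distortion and
#' per-device affine response, two-point KCl calibration standards per
#' device, scan records with MM% as the app pipeline would compute it, and
#' the ground truth. Feeding-status labels and problem tags are drawn so
#' that [classify_scans()] recovers the ground-truth class (unless
#' `label_noise > 0`). All randomness flows from `seed`; the same config and
#' seed reproduce the output exactly.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @return A `milk_cohort` list with tibbles `readings`, `scans`, `truth`
#'   and `standards`, plus the `config` and `seed`.
#' @examples
#' coh <- simulate_cohort(cohort_config(n_mothers = 20), seed = 1)
#' head(coh$scans)
#' @export
simulate_cohort <- function(config = cohort_config(), seed = 1) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(as.integer(seed))
  cfg <- config
  n <- cfg$n_mothers
  model <- maturation_model(cfg$sigma_colostrum, cfg$sigma_mature,
                            shape = cfg$shape)
  birth0 <- as.POSIXct("2020-01-01 00:00:00", tz = "UTC")

  mothers <- tibble::tibble(
    mother_id = sprintf("M%04d", seq_len(n)),
    class_label = sample(names(cfg$class_mix), n, replace = TRUE,
                         prob = cfg$class_mix),
    self_mode = runif(n) < cfg$mother_mode_fraction,
    tau = NA_real_, onset = NA_real_
  )
  mothers$reporter <- ifelse(mothers$self_mode, "mother", "provider")
  mothers$device_id <- ifelse(
    mothers$self_mode,
    sprintf("DM%04d", seq_len(n)),
    sprintf("DP%02d", sample.int(cfg$n_devices, n, replace = TRUE))
  )
  mothers$tau <- rlnorm(n, log(cfg$tau_by_class[mothers$class_label]),
                        cfg$tau_sdlog)
  mothers$onset <- rlnorm(n, log(cfg$onset_by_class[mothers$class_label]),
                          cfg$onset_sdlog)
  mothers$birth <- birth0 + runif(n, 0, 364) * 86400

  # per-device affine response distortion; standards are read noise-free so
  # a two-point fit recovers the distortion exactly
  device_ids <- unique(mothers$device_id)
  devices <- tibble::tibble(
    device_id = device_ids,
    gain = pmax(1 + rnorm(length(device_ids), 0, cfg$device_gain_sd), 0.5),
    offset = rnorm(length(device_ids), 0, cfg$device_offset_sd)
  )
  standards <- tidyr::crossing(devices,
                               true_mS_cm = c(1.413, 12.88))
  standards <- dplyr::mutate(
    standards,
    measured_mS_cm = .data$gain * .data$true_mS_cm + .data$offset
  )
  standards <- standards[, c("device_id", "true_mS_cm", "measured_mS_cm")]

  # scan sessions per mother
  sessions <- purrr::pmap_dfr(
    mothers[, c("mother_id", "self_mode")],
    function(mother_id, self_mode) {
      if (self_mode) {
        n_scans <- round(runif(1, cfg$mother_scans_range[1],
                               cfg$mother_scans_range[2]))
        k <- max(2L, ceiling(n_scans / 2))
        days <- cumsum(c(runif(1, 0.5, 2), 0.5 + rexp(k - 1L, 1 / 1.2)))
        days <- days[days <= cfg$day_range[2]]
      } else {
        k <- sample(cfg$provider_visits, 1L)
        days <- pmin(rlnorm(k, cfg$provider_day_meanlog,
                            cfg$provider_day_sdlog), cfg$day_range[2])
      }
      days <- days[days >= cfg$day_range[1]]
      if (length(days) == 0L) return(NULL)
      tibble::tibble(mother_id = mother_id,
                     session = seq_along(days), day = sort(days))
    }
  )
  sessions <- dplyr::left_join(sessions, mothers, by = "mother_id")

  # feeding metadata drawn per session (shared by both breasts); optional
  # label noise re-draws from a random other class
  eff_class <- sessions$class_label
  if (cfg$label_noise > 0) {
    flip <- runif(nrow(sessions)) < cfg$label_noise
    eff_class[flip] <- vapply(eff_class[flip], function(cl) {
      sample(setdiff(names(cfg$class_mix), cl), 1L)
    }, character(1))
  }
  feeding <- purrr::map2_dfr(eff_class, sessions$reporter, draw_feeding_)
  sessions <- dplyr::bind_cols(sessions, feeding)

  # expand to per-breast scan rows
  scans <- dplyr::bind_rows(
    dplyr::mutate(sessions, breast_side = "left"),
    dplyr::mutate(sessions, breast_side = "right")
  )
  scans <- dplyr::arrange(scans, .data$mother_id, .data$session,
                          .data$breast_side)
  side_key <- paste(scans$mother_id, scans$breast_side)
  jitter <- rnorm(dplyr::n_distinct(side_key), 0, cfg$breast_asymmetry_sd)
  names(jitter) <- unique(side_key)
  scans$onset_side <- pmax(scans$onset + jitter[side_key], 0)

  scans$sigma_true <- sigma_trajectory(scans$day, scans$tau,
                                       scans$onset_side,
                                       cfg$sigma_colostrum, cfg$sigma_mature)
  scans$sigma_noisy <- scans$sigma_true *
    (1 + rnorm(nrow(scans), 0, cfg$noise_cv))
  scans$sigma_noisy <- pmax(scans$sigma_noisy, 1e-6)
  scans$temperature_C <- runif(nrow(scans), 20, 37)

  scans <- dplyr::left_join(scans, devices, by = "device_id")
  alpha <- 0.020
  # forward device model, the exact inverse of the processing chain:
  # affine response on the 25 C conductivity scale, then temperature
  # distortion, then conductance through the K = 1 cell
  conduct <- (scans$gain * scans$sigma_noisy + scans$offset) *
    (1 + alpha * (scans$temperature_C - 25))
  scans$conductance_mS <- conduct
  scans$scan_time <- scans$birth + scans$day * 86400
  mm <- mm_from_conductivity(scans$sigma_noisy, model)
  scans$mm_percent <- mm$mm_percent

  readings <- tibble::tibble(
    device_id = scans$device_id,
    timestamp = scans$scan_time,
    breast_side = scans$breast_side,
    conductance_mS = scans$conductance_mS,
    temperature_C = scans$temperature_C,
    sample_volume_ml = 0.5
  )
  scan_records <- tibble::tibble(
    mother_id = scans$mother_id,
    baby_birth = scans$birth,
    scan_time = scans$scan_time,
    breast_side = scans$breast_side,
    mm_percent = scans$mm_percent,
    reporter = scans$reporter,
    feeding_status = scans$feeding_status,
    formula_fraction_daily = scans$formula_fraction_daily,
    formula_last_24h = scans$formula_last_24h,
    problem_tags = scans$problem_tags,
    day_postpartum = scans$day
  )
  truth <- dplyr::distinct(
    tibble::tibble(
      mother_id = scans$mother_id,
      breast_side = scans$breast_side,
      class_label = scans$class_label,
      tau = scans$tau,
      onset = scans$onset_side,
      device_id = scans$device_id
    )
  )
  structure(
    list(readings = readings, scans = scan_records, truth = truth,
         standards = standards, config = cfg, seed = as.integer(seed)),
    class = "milk_cohort"
  )
}

#' @export
print.milk_cohort <- function(x, ...) {
  cat(sprintf(
    "<milk_cohort> %d mothers, %d scan records, %d devices (seed %d)\n",
    x$config$n_mothers, nrow(x$scans),
    dplyr::n_distinct(x$standards$device_id), x$seed
  ))
  invisible(x)
}

#' Write a simulated cohort to CSV files
#'
#' Emits `readings.csv`, `scans.csv`, `truth.csv` and `standards.csv` in the
#' schemas consumed by [read_readings()], [read_scan_records()] and
#' [fit_calibration_store()]. Output is byte-identical across runs for the
#' same config and seed.
#'
#' @param cohort A `milk_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "milk_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(cohort$readings, file.path(dir, "readings.csv"))
  readr::write_csv(cohort$scans, file.path(dir, "scans.csv"))
  readr::write_csv(cohort$truth, file.path(dir, "truth.csv"))
  readr::write_csv(cohort$standards, file.path(dir, "standards.csv"))
  invisible(dir)
}
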