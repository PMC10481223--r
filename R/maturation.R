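#' Define a milk maturation (MM%) model
#'
#' MM% maps milk conductivity onto a 0-100 maturation scale spanning
#' colostrum (electrolyte-rich, high conductivity, MM% = 0) to fully mature
#' milk (low conductivity, MM% = 100). Because the commercial equation behind
#' the score is not public, this package uses a documented surrogate anchored
#' at two conductivities: `sigma_colostrum` maps to 0% and `sigma_mature` to
#' 100%. The default shape interpolates linearly between the anchors; a
#' logistic shape (rescaled so the anchors are still hit exactly) is
#' available for soft saturation near the extremes. All downstream logic
#' relies only on monotonicity and the [0, 100] range, not on the particular
#' anchor values.
#'
#' @param sigma_colostrum Conductivity anchor mapped to MM% = 0, mS/cm.
#' @param sigma_mature Conductivity anchor mapped to MM% = 100, mS/cm. Must
#'   be positive and below `sigma_colostrum`.
#' @param shape `"linear"` (default) or `"logistic"`.
#' @param logistic_steepness Steepness k of the logistic shape, per mS/cm
#'   (used only when `shape = "logistic"`).
#' @return A `maturation_model` object.
#' @examples
#' m <- maturation_model()
#' mm_from_conductivity(c(6, 4.5, 3), m)
#' @export
maturation_model <- function(sigma_colostrum = 6, sigma_mature = 3,
                             shape = c("linear", "logistic"),
                             logistic_steepness = 2) {
  shape <- match.arg(shape)
  if (!(sigma_colostrum > sigma_mature && sigma_mature > 0)) {
    abort("Need sigma_colostrum > sigma_mature > 0.",
          class = "milksense_bad_input")
  }
  if (logistic_steepness <= 0) {
    abort("`logistic_steepness` must be > 0.", class = "milksense_bad_input")
  }
  structure(
    list(sigma_colostrum = sigma_colostrum, sigma_mature = sigma_mature,
         shape = shape, logistic_steepness = logistic_steepness),
    class = "maturation_model"
  )
}

#' @export
print.maturation_model <- function(x, ...) {
  cat(sprintf(
    "<maturation_model> %s; 0%% at %.3g mS/cm, 100%% at %.3g mS/cm\n",
    x$shape, x$sigma_colostrum, x$sigma_mature
  ))
  invisible(x)
}

# unclipped forward map, strictly decreasing in sigma
mm_raw_ <- function(sigma, model) {
  sc <- model$sigma_colostrum
  sm <- model$sigma_mature
  if (model$shape == "linear") {
    100 * (sc - sigma) / (sc - sm)
  } else {
    k <- model$logistic_steepness
    mid <- (sc + sm) / 2
    l <- stats::plogis(-k * (sigma - mid))
    l0 <- stats::plogis(-k * (sc - mid))
    l1 <- stats::plogis(-k * (sm - mid))
    100 * (l - l0) / (l1 - l0)
  }
}

#' Compute MM% from calibrated conductivity
#'
#' Strictly decreasing in conductivity on the unclipped range (early,
#' electrolyte-rich milk conducts more and scores lower). Values falling
#' outside [0, 100] -- expected near the anchors under sensor noise -- are
#' clipped and flagged rather than rejected.
#'
#' @param conductivity Temperature-corrected, calibrated conductivity at
#'   25 C, mS/cm. Must be > 0.
#' @param model A [maturation_model()].
#' @return A tibble with columns `conductivity_25C`, `mm_percent` (in
#'   [0, 100]) and `clipped` (logical).
#' @seealso [conductivity_from_mm()] for the inverse map, [add_mm()] for the
#'   data-frame verb.
#' @export
mm_from_conductivity <- function(conductivity, model = maturation_model()) {
  stopifnot(inherits(model, "maturation_model"))
  if (any(!is.finite(conductivity)) || any(conductivity <= 0)) {
    abort("`conductivity` must be finite and > 0 mS/cm.",
          class = "milksense_bad_input")
  }
  raw <- mm_raw_(conductivity, model)
  tibble::tibble(
    conductivity_25C = conductivity,
    mm_percent = pmin(pmax(raw, 0), 100),
    clipped = raw < 0 | raw > 100
  )
}

#' Invert the MM% map
#'
#' Returns the conductivity whose (unclipped) MM% equals `mm_percent`;
#' the exact inverse of the forward map on (0, 100).
#'
#' @param mm_percent MM% values in [0, 100].
#' @param model A [maturation_model()].
#' @return Conductivity at 25 C, mS/cm.
#' @export
conductivity_from_mm <- function(mm_percent, model = maturation_model()) {
  stopifnot(inherits(model, "maturation_model"))
  if (any(!is.finite(mm_percent)) || any(mm_percent < 0 | mm_percent > 100)) {
    abort("`mm_percent` must lie in [0, 100].", class = "milksense_bad_input")
  }
  sc <- model$sigma_colostrum
  sm <- model$sigma_mature
  if (model$shape == "linear") {
    sc - mm_percent * (sc - sm) / 100
  } else {
    k <- model$logistic_steepness
    mid <- (sc + sm) / 2
    l0 <- stats::plogis(-k * (sc - mid))
    l1 <- stats::plogis(-k * (sm - mid))
    l <- l0 + mm_percent / 100 * (l1 - l0)
    mid - stats::qlogis(l) / k
  }
}

#' Add MM% columns to a conductivity table
#'
#' Data-frame verb around [mm_from_conductivity()]: appends `mm_percent` and
#' `mm_clipped` computed from a conductivity column.
#'
#' @param data A data frame holding calibrated conductivities.
#' @param model A [maturation_model()].
#' @param conductivity Tidy-selected column holding conductivity at 25 C
#'   (default `conductivity_25C`).
#' @return `data` as a tibble with `mm_percent` and `mm_clipped` appended.
#' @export
add_mm <- function(data, model = maturation_model(),
                   conductivity = conductivity_25C) {
  conductivity_25C <- NULL # quiet R CMD check; column resolved by tidy eval
  sigma <- dplyr::pull(data, {{ conductivity }})
  res <- mm_from_conductivity(sigma, model)
  dplyr::mutate(tibble::as_tibble(data),
                mm_percent = res$mm_percent, mm_clipped = res$clipped)
}
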