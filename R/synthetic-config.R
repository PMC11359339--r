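#' Configuration for the synthetic orchard-phenology generator
#'
#' Bundles every knob of the generator: the weather process per region, the
#' logistic budbreak response per cultivar, the flowering-date linear model,
#' and the survey design. Defaults emulate the two New Zealand growing
#' regions the pipeline targets: Kerikeri (warmer winters, less chilling) and
#' Te Puke (cooler winters, more chilling), with the 'Zesy002' cultivar
#' breaking bud and flowering earlier than 'Hayward'.
#'
#' The flowering day of a vine is generated from a linear predictor in
#' cultivar (`CV`, 1 = 'Hayward'), the vine's true growing-degree-day
#' accumulation at 5% budbreak (`BB`) and the degree-day accumulation on
#' 1 September (`DD`), plus Gaussian noise. `BB` and `DD` enter the linear
#' predictor scaled by `thermal_scale` (default 100 degree-days per unit), so
#' coefficients read as days per 100 degree-days.
#'
#' @param seed Integer seed; the whole dataset is a deterministic function of
#'   the configuration including this seed.
#' @param years Integer vector of calendar years to simulate.
#' @param n_orchards_per_region Orchards per region (>= 1).
#' @param n_vines_per_orchard Vines per orchard and cultivar (>= 1).
#' @param region_params Tibble with columns `region`, `mean_temp` (annual mean
#'   air temperature, deg C), `amplitude` (annual sinusoid amplitude, deg C;
#'   winter mean is `mean_temp - amplitude`), `latitude` (degrees, negative in
#'   the Southern Hemisphere).
#' @param cultivar_params Tibble with columns `cultivar`, `threshold`
#'   (logistic budbreak midpoint in degree-days from 1 July) and `slope`
#'   (logistic slope per degree-day).
#' @param flowering_coefficients Named numeric vector with elements
#'   `intercept`, `cv`, `bb`, `dd`, `cv_bb`, `bb_dd` (days; `bb`/`dd` per
#'   `thermal_scale` degree-days).
#' @param residual_sd Flowering-day residual standard deviation in days (> 0).
#' @param survey_interval_days Days between budbreak surveys; 3 or 4.
#' @param buds_per_vine Number of monitored buds per vine (>= 1).
#' @param bb_threshold_sd Per-vine standard deviation of the logistic budbreak
#'   midpoint (degree-days). Gives each vine its own true 5%-budbreak GDD, so
#'   stage-1 estimation error propagates realistically into stage 2.
#' @param diurnal_amplitude Amplitude of the diurnal temperature sinusoid
#'   (deg C).
#' @param noise_sd Stationary standard deviation of the AR(1) hourly
#'   temperature noise (deg C).
#' @param noise_rho AR(1) autocorrelation of the hourly noise.
#' @param thermal_scale Degree-days (and chilling hours) per covariate unit in
#'   the flowering model.
#' @param censor_flowering_to_survey If `TRUE`, the reported first-flowering
#'   day is rounded up to the next survey visit, emulating field detection at
#'   3-4 day intervals.
#'
#' @return An object of class `synthetic_config` (a named list).
#' @export
#' @examples
#' cfg <- synthetic_config(seed = 1, years = 2019:2020)
#' cfg$cultivar_params
synthetic_config <- function(seed = 1L,
                             years = 2007:2022,
                             n_orchards_per_region = 3L,
                             n_vines_per_orchard = 5L,
                             region_params = default_region_params(),
                             cultivar_params = default_cultivar_params(),
                             flowering_coefficients = default_flowering_coefficients(),
                             residual_sd = 4.5,
                             survey_interval_days = 4L,
                             buds_per_vine = 40L,
                             bb_threshold_sd = 25,
                             diurnal_amplitude = 4,
                             noise_sd = 2,
                             noise_rho = 0.95,
                             thermal_scale = 100,
                             censor_flowering_to_survey = FALSE) {
  cfg <- list(
    seed = as.integer(seed),
    years = as.integer(years),
    n_orchards_per_region = as.integer(n_orchards_per_region),
    n_vines_per_orchard = as.integer(n_vines_per_orchard),
    region_params = tibble::as_tibble(region_params),
    cultivar_params = tibble::as_tibble(cultivar_params),
    flowering_coefficients = flowering_coefficients,
    residual_sd = residual_sd,
    survey_interval_days = as.integer(survey_interval_days),
    buds_per_vine = as.integer(buds_per_vine),
    bb_threshold_sd = bb_threshold_sd,
    diurnal_amplitude = diurnal_amplitude,
    noise_sd = noise_sd,
    noise_rho = noise_rho,
    thermal_scale = thermal_scale,
    censor_flowering_to_survey = isTRUE(censor_flowering_to_survey)
  )
  class(cfg) <- "synthetic_config"
  validate_synthetic_config(cfg)
}

#' @rdname synthetic_config
#' @export
default_region_params <- function() {
  tibble::tibble(
    region = c("Kerikeri", "Te Puke"),
    mean_temp = c(15.5, 14.5),
    amplitude = c(4.0, 5.5),
    latitude = c(-35.22, -37.78)
  )
}

#' @rdname synthetic_config
#' @export
default_cultivar_params <- function() {
  tibble::tibble(
    cultivar = c("Zesy002", "Hayward"),
    threshold = c(240, 320),
    slope = c(0.05, 0.05)
  )
}

#' @rdname synthetic_config
#' @export
default_flowering_coefficients <- function() {
  reference_flowering_coefficients("full")
}

validate_synthetic_config <- function(cfg) {
  stopifnot(is.numeric(cfg$residual_sd))
  if (cfg$residual_sd <= 0 && !isTRUE(all.equal(cfg$residual_sd, 0))) {
    abort_phenocast("residual_sd must be >= 0", "phenocast_config_error")
  }
  if (!cfg$survey_interval_days %in% c(3L, 4L)) {
    abort_phenocast("survey_interval_days must be 3 or 4", "phenocast_config_error")
  }
  counts <- c(cfg$n_orchards_per_region, cfg$n_vines_per_orchard, cfg$buds_per_vine)
  if (any(counts < 1L)) {
    abort_phenocast("all counts must be >= 1", "phenocast_config_error")
  }
  if (!setequal(cfg$region_params$region, c("Kerikeri", "Te Puke"))) {
    abort_phenocast("regions must be exactly 'Kerikeri' and 'Te Puke'",
                    "phenocast_config_error")
  }
  if (!setequal(cfg$cultivar_params$cultivar, c("Hayward", "Zesy002"))) {
    abort_phenocast("cultivars must be exactly 'Hayward' and 'Zesy002'",
                    "phenocast_config_error")
  }
  needed <- c("intercept", "cv", "bb", "dd", "cv_bb", "bb_dd")
  if (!all(needed %in% names(cfg$flowering_coefficients))) {
    abort_phenocast(
      paste("flowering_coefficients must contain:", paste(needed, collapse = ", ")),
      "phenocast_config_error"
    )
  }
  cfg
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("<synthetic_config>\n")
  cat("  seed:", x$seed, " years:", paste(range(x$years), collapse = "-"), "\n")
  cat("  orchards/region:", x$n_orchards_per_region,
      " vines/orchard:", x$n_vines_per_orchard,
      " buds/vine:", x$buds_per_vine, "\n")
  cat("  survey interval:", x$survey_interval_days, "d  residual sd:",
      x$residual_sd, "d\n")
  invisible(x)
}
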