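#' Simulate an hourly temperature series for one region and year
#'
#' Generates a full calendar year of hourly temperatures as the sum of an
#' annual sinusoid (minimum in mid-July, Southern Hemisphere), a diurnal
#' sinusoid peaking at 14:00 local time, and AR(1) Gaussian noise. The series
#' is a deterministic function of `(config$seed, region, year)`, independent
#' of the order in which regions and years are generated.
#'
#' @param config A [synthetic_config()].
#' @param region Region label present in `config$region_params`.
#' @param year Calendar year (integer).
#' @return A tibble with columns `station_id`, `latitude`, `timestamp`
#'   (hourly POSIXct, UTC), `temp_c` — one row per hour of the year.
#' @export
#' @examples
#' w <- simulate_weather(synthetic_config(seed = 1), "Kerikeri", 2020)
#' nrow(w)  # 8784 (leap year)
simulate_weather <- function(config, region, year) {
  pars <- config$region_params[config$region_params$region == region, ]
  if (nrow(pars) != 1) {
    abort_phenocast(paste0("unknown region: '", region, "'"),
                    "phenocast_config_error")
  }
  year <- as.integer(year)
  t0 <- lubridate::make_datetime(year, 1, 1, 0, tz = "UTC")
  t1 <- lubridate::make_datetime(year, 12, 31, 23, tz = "UTC")
  ts <- seq(t0, t1, by = "hour")
  n <- length(ts)

  mean_fun <- weather_mean_function(ts, pars$mean_temp, pars$amplitude,
                                    config$diurnal_amplitude)

  noise <- withr::with_seed(sub_seed(config$seed, "weather", region, year), {
    simulate_ar1(n, config$noise_rho, config$noise_sd)
  })

  tibble::tibble(
    station_id = paste0(gsub(" ", "", region), "_AWS"),
    latitude = pars$latitude,
    timestamp = ts,
    temp_c = mean_fun + noise
  )
}

# Deterministic seasonal + diurnal mean temperature at the given timestamps.
# Annual minimum on day-of-year 196 (mid-July); diurnal maximum at 14:00.
weather_mean_function <- function(timestamps, mean_temp, amplitude,
                                  diurnal_amplitude) {
  d <- lubridate::yday(timestamps) + lubridate::hour(timestamps) / 24
  h <- lubridate::hour(timestamps)
  annual <- mean_temp - amplitude * cos(2 * pi * (d - 196) / 365.25)
  diurnal <- diurnal_amplitude * cos(2 * pi * (h - 14) / 24)
  annual + diurnal
}

# Stationary AR(1) series with autocorrelation rho and marginal sd sigma.
simulate_ar1 <- function(n, rho, sigma) {
  if (sigma == 0 || n == 0) return(numeric(n))
  innov <- rnorm(n, 0, sigma * sqrt(1 - rho^2))
  innov[1] <- rnorm(1, 0, sigma)
  as.numeric(stats::filter(innov, rho, method = "recursive"))
}
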