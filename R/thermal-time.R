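#' Growing-degree-day accumulation from hourly temperatures
#'
#' Daily degree-day contribution = `max(0, mean(hourly temps) - base_temp)`;
#' the running sum starts at `season_start` (1 July by default, matching the
#' Southern Hemisphere growing season). Negative daily contributions are
#' clipped at zero by default (the usual GDD convention); set `clip = FALSE`
#' to allow them.
#'
#' @param weather Tibble with `timestamp` (POSIXct or Date-time) and `temp_c`
#'   columns, at most one record per hour.
#' @param season_start Date the accumulation starts (inclusive).
#' @param base_temp Base temperature in deg C (default 7).
#' @param through Last date (inclusive); defaults to the last full day in
#'   `weather`.
#' @param clip Clip negative daily contributions at zero (default `TRUE`).
#' @param max_missing_frac A day with more than this fraction of its 24 hours
#'   missing raises a data-quality error listing the dates (default 0.25).
#' @return Tibble with one row per day: `date`, `gdd_daily`, `gdd_cum`.
#' @export
#' @examples
#' cfg <- synthetic_config(seed = 1)
#' w <- simulate_weather(cfg, "Kerikeri", 2020)
#' gdd <- accumulate_gdd(w, season_start = as.Date("2020-07-01"))
#' tail(gdd, 2)
accumulate_gdd <- function(weather, season_start = NULL, base_temp = 7,
                           through = NULL, clip = TRUE,
                           max_missing_frac = 0.25) {
  daily <- daily_means(weather, max_missing_frac)
  season_start <- as.Date(season_start %||% default_season_start(daily$date))
  through <- as.Date(through %||% max(daily$date))
  daily <- dplyr::filter(daily, .data$date >= season_start, .data$date <= through)
  if (nrow(daily) == 0) {
    abort_phenocast("weather does not cover the requested GDD window",
                    "phenocast_data_error")
  }
  contrib <- daily$mean_temp - base_temp
  if (clip) contrib <- pmax(0, contrib)
  tibble::tibble(
    date = daily$date,
    gdd_daily = contrib,
    gdd_cum = cumsum(contrib)
  )
}

#' Chilling-unit accumulation from hourly temperatures
#'
#' Counts hourly records at or below `threshold` deg C (inclusive) from
#' `year_start` (1 January by default) and reports the running count per day.
#'
#' @inheritParams accumulate_gdd
#' @param year_start Date the count starts (inclusive).
#' @param threshold Chilling threshold in deg C (default 7; hours with
#'   `temp_c <= threshold` count).
#' @return Tibble with one row per day: `date`, `cu_daily`, `cu_cum`.
#' @export
accumulate_cu <- function(weather, year_start = NULL, threshold = 7,
                          through = NULL, max_missing_frac = 0.25) {
  check_hourly(weather)
  # reuse daily QC from daily_means, then count on the raw records
  daily <- daily_means(weather, max_missing_frac)
  year_start <- as.Date(year_start %||% min(daily$date))
  through <- as.Date(through %||% max(daily$date))
  rec <- tibble::tibble(
    date = as.Date(weather$timestamp, tz = "UTC"),
    chill = weather$temp_c <= threshold
  )
  rec <- dplyr::filter(rec, .data$date >= year_start, .data$date <= through)
  if (nrow(rec) == 0) {
    abort_phenocast("weather does not cover the requested CU window",
                    "phenocast_data_error")
  }
  rec |>
    dplyr::summarise(cu_daily = sum(.data$chill), .by = "date") |>
    dplyr::arrange(.data$date) |>
    dplyr::mutate(cu_cum = cumsum(.data$cu_daily))
}

#' Astronomical daylength
#'
#' Hours between sunrise and sunset using the standard refraction-corrected
#' solar geometry (zenith 90.833 degrees), via [geosphere::daylength()].
#'
#' @param latitude Latitude in degrees, negative in the Southern Hemisphere;
#'   `abs(latitude)` must be below the polar circle (66.5).
#' @param date Date (or anything coercible via `as.Date`). Vectorised over
#'   both arguments.
#' @return Daylength in hours, in `[0, 24]`.
#' @export
#' @examples
#' daylength(-38, as.Date("2020-09-21"))  # ~12 h near the equinox
daylength <- function(latitude, date) {
  if (any(abs(latitude) >= 66.5)) {
    abort_phenocast("latitude must satisfy |latitude| < 66.5 (no polar day/night)",
                    "phenocast_domain_error")
  }
  geosphere::daylength(latitude, as.Date(date))
}

#' Per-day thermal summary (GDD, CU, daylength)
#'
#' Convenience wrapper combining [accumulate_gdd()], [accumulate_cu()] and
#' [daylength()] into the per-day covariate table the flowering pipeline
#' consumes. GDD accumulates from `season_start` (1 July), CU from 1 January
#' of the same calendar year; days before `season_start` carry `NA` GDD.
#'
#' @inheritParams accumulate_gdd
#' @param cu_threshold Chilling threshold in deg C.
#' @return Tibble with `date`, `gdd_cum`, `cu_cum`, `daylength`.
#' @export
thermal_summary <- function(weather, season_start = NULL, base_temp = 7,
                            cu_threshold = 7, through = NULL) {
  lat <- weather$latitude[1] %||% NA_real_
  cu <- accumulate_cu(weather, threshold = cu_threshold, through = through)
  gdd <- accumulate_gdd(weather, season_start = season_start,
                        base_temp = base_temp, through = through)
  out <- dplyr::left_join(
    dplyr::select(cu, "date", "cu_cum"),
    dplyr::select(gdd, "date", "gdd_cum"),
    by = "date"
  )
  out$daylength <- if (is.na(lat)) NA_real_ else daylength(lat, out$date)
  dplyr::select(out, "date", "gdd_cum", "cu_cum", "daylength")
}

# --- internals ---------------------------------------------------------------

check_hourly <- function(weather) {
  assert_columns(weather, c("timestamp", "temp_c"), "weather")
  ts <- weather$timestamp
  if (is.unsorted(as.numeric(ts), strictly = TRUE)) {
    abort_phenocast("weather timestamps must be strictly increasing",
                    "phenocast_data_error")
  }
  if (any(weather$temp_c < -30 | weather$temp_c > 50, na.rm = TRUE)) {
    abort_phenocast("temperatures outside the sanity bound [-30, 50] deg C",
                    "phenocast_data_error")
  }
  invisible(weather)
}

daily_means <- function(weather, max_missing_frac = 0.25) {
  check_hourly(weather)
  daily <- weather |>
    dplyr::mutate(date = as.Date(.data$timestamp, tz = "UTC")) |>
    dplyr::summarise(
      mean_temp = mean(.data$temp_c, na.rm = TRUE),
      n_hours = sum(!is.na(.data$temp_c)),
      .by = "date"
    ) |>
    dplyr::arrange(.data$date)
  bad <- daily$date[daily$n_hours < 24 * (1 - max_missing_frac)]
  if (length(bad) > 0) {
    abort_phenocast(
      paste0("day(s) with > ", round(100 * max_missing_frac),
             "% missing hours: ", paste(format(bad), collapse = ", ")),
      "phenocast_data_error"
    )
  }
  daily
}

# Season runs 1 July -> 30 June; pick the 1 July at or before the last date.
default_season_start <- function(dates) {
  last <- max(dates)
  yr <- lubridate::year(last) - (lubridate::month(last) < 7)
  as.Date(paste0(yr, "-07-01"))
}
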