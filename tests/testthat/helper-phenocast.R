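# Shared fixtures, built in code.

# Small configuration that keeps generator-backed tests fast.
tiny_config <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(seed = seed, years = 2019:2021,
         n_orchards_per_region = 1, n_vines_per_orchard = 3),
    list(...)
  )
  do.call(synthetic_config, args)
}

# Hourly weather at a constant temperature for `days` full days.
constant_weather <- function(temp, days = 10, start = "2020-07-01",
                             latitude = -38) {
  t0 <- lubridate::as_datetime(paste(start, "00:00:00"), tz = "UTC")
  ts <- seq(t0, t0 + lubridate::dhours(days * 24 - 1), by = "hour")
  tibble::tibble(station_id = "const", latitude = latitude,
                 timestamp = ts, temp_c = temp)
}

# Survey panel whose counts sit exactly on a logistic curve.
logistic_survey <- function(intercept, slope, total_buds = 1000,
                            gdd = seq(0, 1000, by = 25)) {
  tibble::tibble(
    vine_id = "toy",
    gdd_cum = gdd,
    broken_buds = round(total_buds * plogis(intercept + slope * gdd)),
    total_buds = total_buds
  )
}

# Independent per-record oracles for the thermal accumulators.
naive_gdd <- function(weather, season_start, base_temp = 7) {
  dates <- as.Date(weather$timestamp, tz = "UTC")
  days <- sort(unique(dates[dates >= as.Date(season_start)]))
  cum <- 0
  out <- numeric(length(days))
  for (i in seq_along(days)) {
    temps <- weather$temp_c[dates == days[i]]
    cum <- cum + max(0, mean(temps) - base_temp)
    out[i] <- cum
  }
  tibble::tibble(date = days, gdd_cum = out)
}

naive_cu <- function(weather, through, threshold = 7) {
  dates <- as.Date(weather$timestamp, tz = "UTC")
  sum(weather$temp_c[dates <= as.Date(through)] <= threshold)
}
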