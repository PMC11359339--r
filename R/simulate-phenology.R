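#' Simulate one vine's budbreak survey and first-flowering day
#'
#' Each of the vine's `buds_per_vine` buds breaks independently when the
#' season's growing-degree-day accumulation crosses a logistic threshold:
#' bud `i` breaks at GDD `G_i ~ Logistic(midpoint, 1/slope)`, so the expected
#' proportion broken at accumulation `g` is `plogis(slope * (g - midpoint))`.
#' Surveys record the cumulative count every `survey_interval_days` from
#' 1 July to 31 December. The vine's true `BB` is the GDD at which its own
#' logistic curve crosses 5% (`midpoint + qlogis(0.05)/slope`). The
#' first-flowering day is the flowering linear predictor evaluated at
#' `(CV, BB/thermal_scale, DD/thermal_scale)` plus `N(0, residual_sd)` noise,
#' rounded to the nearest day and kept inside the September-December window
#' `[244, 366]`.
#'
#' @param config A [synthetic_config()].
#' @param weather Hourly weather tibble covering 1 July-31 December of the
#'   vine's season (see [simulate_weather()]).
#' @param cultivar `'Hayward'` or `'Zesy002'`.
#' @param vine_id Label used in outputs and error messages.
#' @param gdd Optional precomputed daily GDD table for this weather series
#'   (as returned by [accumulate_gdd()] from 1 July); computed on the fly
#'   when `NULL`.
#' @return A list with elements `survey` (tibble: `vine_id`, `cultivar`,
#'   `survey_date`, `gdd_cum`, `broken_buds`, `total_buds`), `flowering_doy`
#'   (integer day of year) and `truth` (one-row tibble with the vine's true
#'   midpoint, slope, `bb_true` and `dd_sep1`).
#' @export
simulate_vine_phenology <- function(config, weather, cultivar,
                                    vine_id = "vine_1", gdd = NULL) {
  pars <- config$cultivar_params[config$cultivar_params$cultivar == cultivar, ]
  if (nrow(pars) != 1) {
    abort_phenocast(paste0("unknown cultivar: '", cultivar, "'"),
                    "phenocast_config_error")
  }
  year <- lubridate::year(max(weather$timestamp))
  season_start <- as.Date(paste0(year, "-07-01"))
  season_end <- as.Date(paste0(year, "-12-31"))
  if (is.null(gdd)) {
    gdd <- accumulate_gdd(weather, season_start = season_start,
                          through = min(season_end, as.Date(max(weather$timestamp), tz = "UTC")))
  }
  dd_sep1 <- gdd$gdd_cum[gdd$date == as.Date(paste0(year, "-09-01"))]
  if (length(dd_sep1) != 1) {
    abort_phenocast("weather must cover 1 September of the season",
                    "phenocast_data_error")
  }

  seed <- sub_seed(config$seed, "vine", vine_id, cultivar, year)
  withr::with_seed(seed, {
    midpoint <- pars$threshold + rnorm(1, 0, config$bb_threshold_sd)
    bud_gdd <- rlogis(config$buds_per_vine, midpoint, 1 / pars$slope)
    noise <- rnorm(1, 0, config$residual_sd)
  })

  bb_true <- midpoint + qlogis(0.05) / pars$slope
  if (bb_true < 0 || bb_true > max(gdd$gdd_cum)) {
    abort_phenocast(
      paste0("vine '", vine_id, "': 5% budbreak GDD (", round(bb_true, 1),
             ") falls outside the season's GDD range [0, ",
             round(max(gdd$gdd_cum), 1), "]"),
      "phenocast_generation_error"
    )
  }

  survey_dates <- seq(season_start, max(gdd$date),
                      by = paste(config$survey_interval_days, "days"))
  survey_gdd <- gdd$gdd_cum[match(survey_dates, gdd$date)]
  broken <- vapply(survey_gdd, function(g) sum(bud_gdd <= g), integer(1))

  survey <- tibble::tibble(
    vine_id = vine_id,
    cultivar = cultivar,
    survey_date = survey_dates,
    gdd_cum = survey_gdd,
    broken_buds = broken,
    total_buds = config$buds_per_vine
  )

  scale <- config$thermal_scale
  lp <- flowering_linear_predictor(
    config$flowering_coefficients,
    cv = as.integer(cultivar == "Hayward"),
    bb = bb_true / scale,
    dd = dd_sep1 / scale
  )
  fday <- round(lp + noise)
  if (config$censor_flowering_to_survey) {
    survey_doys <- doy(survey_dates)
    later <- survey_doys[survey_doys >= fday]
    if (length(later) > 0) fday <- min(later)
  }
  fday <- as.integer(min(max(fday, 244L), 366L))

  list(
    survey = survey,
    flowering_doy = fday,
    truth = tibble::tibble(
      vine_id = vine_id, cultivar = cultivar, year = as.integer(year),
      midpoint = midpoint, slope = pars$slope,
      bb_true = bb_true, dd_sep1 = dd_sep1, linear_predictor = lp
    )
  )
}

#' Simulate a complete multi-year, multi-orchard phenology dataset
#'
#' Drives [simulate_weather()] and [simulate_vine_phenology()] over every
#' region, orchard, year, cultivar and vine in the configuration. Both
#' cultivars are planted in every orchard. The result is byte-identical for
#' identical configurations.
#'
#' @param config A [synthetic_config()].
#' @return A list of class `synthetic_dataset`:
#' \describe{
#'   \item{weather}{tibble of hourly records for all region-years, with
#'     `region` and `year` columns.}
#'   \item{surveys}{tibble of budbreak survey rows (`orchard`, `region`,
#'     `cultivar`, `year`, `row`, `bay`, `vine_id`, `survey_date`, `gdd_cum`,
#'     `broken_buds`, `total_buds`).}
#'   \item{flowering}{tibble with one row per vine (`vine_id`, ...,
#'     `first_flower_doy`).}
#'   \item{truth}{the generating parameters, including each vine's true
#'     5%-budbreak GDD, for recovery tests.}
#'   \item{config}{the configuration used.}
#' }
#' @export
#' @examples
#' cfg <- synthetic_config(seed = 1, years = 2019:2020,
#'                         n_orchards_per_region = 1, n_vines_per_orchard = 2)
#' ds <- simulate_dataset(cfg)
#' dplyr::count(ds$flowering, region, cultivar)
simulate_dataset <- function(config) {
  regions <- config$region_params$region
  cultivars <- config$cultivar_params$cultivar

  weather <- purrr::map(regions, function(rg) {
    purrr::map(config$years, function(yr) {
      dplyr::mutate(simulate_weather(config, rg, yr),
                    region = rg, year = as.integer(yr))
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()

  grid <- tidyr::expand_grid(
    region = regions,
    orchard_i = seq_len(config$n_orchards_per_region),
    year = config$years,
    cultivar = cultivars,
    vine_i = seq_len(config$n_vines_per_orchard)
  ) |>
    dplyr::mutate(
      orchard = paste0(substr(gsub(" ", "", .data$region), 1, 2), "_O",
                       .data$orchard_i),
      row = paste0("R", (.data$vine_i - 1) %/% 2 + 1),
      bay = paste0("B", (.data$vine_i - 1) %% 2 + 1),
      vine_id = paste(.data$orchard, .data$cultivar, .data$year,
                      paste0("V", .data$vine_i), sep = "_")
    )

  gdd_tables <- weather |>
    dplyr::group_by(.data$region, .data$year) |>
    dplyr::group_split() |>
    purrr::map(function(w) {
      key <- paste(w$region[1], w$year[1])
      gdd <- accumulate_gdd(w, season_start = as.Date(paste0(w$year[1], "-07-01")))
      stats::setNames(list(gdd), key)
    }) |>
    purrr::list_flatten()

  sims <- purrr::pmap(
    list(grid$region, grid$year, grid$cultivar, grid$vine_id),
    function(rg, yr, cv, vid) {
      w <- weather[weather$region == rg & weather$year == yr, ]
      simulate_vine_phenology(config, w, cv, vine_id = vid,
                              gdd = gdd_tables[[paste(rg, yr)]])
    }
  )

  surveys <- purrr::map2(sims, seq_len(nrow(grid)), function(s, i) {
    dplyr::mutate(s$survey,
                  orchard = grid$orchard[i], region = grid$region[i],
                  year = grid$year[i], row = grid$row[i], bay = grid$bay[i])
  }) |>
    purrr::list_rbind() |>
    dplyr::select("orchard", "region", "cultivar", "year", "row", "bay",
                  "vine_id", "survey_date", "gdd_cum", "broken_buds",
                  "total_buds")

  flowering <- grid |>
    dplyr::mutate(first_flower_doy = purrr::map_int(sims, "flowering_doy")) |>
    dplyr::select("orchard", "region", "cultivar", "year", "row", "bay",
                  "vine_id", "first_flower_doy")

  truth <- purrr::map(sims, "truth") |>
    purrr::list_rbind() |>
    dplyr::left_join(
      dplyr::select(grid, "vine_id", "orchard", "region", "row", "bay"),
      by = "vine_id"
    )

  structure(
    list(weather = weather, surveys = surveys, flowering = flowering,
         truth = truth, config = config),
    class = "synthetic_dataset"
  )
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("<synthetic_dataset>\n")
  cat("  vines:", nrow(x$flowering),
      " survey rows:", nrow(x$surveys),
      " weather rows:", nrow(x$weather), "\n")
  cat("  years:", paste(range(x$config$years), collapse = "-"), "\n")
  invisible(x)
}
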