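#' Pipeline configuration
#'
#' Validates and bundles everything [run_pipeline()] needs: either a
#' synthetic-data configuration or paths to weather/phenology CSVs, the
#' thermal-time parameters, the train/test year split, the candidate grid,
#' the cross-validation fold count and the interval level.
#'
#' @param synthetic A [synthetic_config()], or `NULL` when reading files.
#' @param weather_csv,phenology_csv Input paths (ignored when `synthetic` is
#'   given).
#' @param base_temp GDD base temperature (deg C).
#' @param cu_threshold Chilling threshold (deg C).
#' @param metric_month,metric_day Date (month, day) on which DD/CU/DL are
#'   read for the flowering covariates (default 1 September).
#' @param train_years,test_years Disjoint year vectors; by default the last
#'   three configured years are held out (mirroring a 2007-2019 train /
#'   2020-2022 test split).
#' @param candidates Candidate grid ([candidate_specs()]).
#' @param k Cross-validation folds.
#' @param level Prediction-interval level in (0, 1).
#' @param seed Seed for fold assignment and the classifiers.
#' @param thermal_scale Degree-days per flowering covariate unit.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = synthetic_config(),
                            weather_csv = NULL, phenology_csv = NULL,
                            base_temp = 7, cu_threshold = 7,
                            metric_month = 9, metric_day = 1,
                            train_years = NULL, test_years = NULL,
                            candidates = candidate_specs(),
                            k = 5, level = 0.99, seed = 1,
                            thermal_scale = 100) {
  if (is.null(synthetic) && (is.null(weather_csv) || is.null(phenology_csv))) {
    abort_phenocast("either `synthetic` or both CSV paths are required",
                    "phenocast_config_error")
  }
  if (!is.null(synthetic)) {
    years <- synthetic$years
    test_years <- test_years %||% utils::tail(sort(years), 3)
    train_years <- train_years %||% setdiff(years, test_years)
  }
  if (is.null(train_years) || is.null(test_years)) {
    abort_phenocast("train_years and test_years are required for file input",
                    "phenocast_config_error")
  }
  if (length(intersect(train_years, test_years)) > 0) {
    abort_phenocast("train_years and test_years must be disjoint",
                    "phenocast_config_error")
  }
  if (level <= 0 || level >= 1) {
    abort_phenocast("level must lie in (0, 1)", "phenocast_config_error")
  }
  structure(
    list(synthetic = synthetic, weather_csv = weather_csv,
         phenology_csv = phenology_csv, base_temp = base_temp,
         cu_threshold = cu_threshold, metric_month = metric_month,
         metric_day = metric_day, train_years = as.integer(train_years),
         test_years = as.integer(test_years), candidates = candidates,
         k = as.integer(k), level = level, seed = as.integer(seed),
         thermal_scale = thermal_scale),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields map directly onto [pipeline_config()] arguments; a
#' `synthetic:` block maps onto [synthetic_config()] arguments.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
pipeline_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  syn <- NULL
  if (!is.null(y$synthetic)) {
    syn_args <- y$synthetic
    for (f in c("region_params", "cultivar_params")) {
      if (!is.null(syn_args[[f]])) {
        syn_args[[f]] <- dplyr::bind_rows(syn_args[[f]])
      }
    }
    if (!is.null(syn_args$flowering_coefficients)) {
      syn_args$flowering_coefficients <- unlist(syn_args$flowering_coefficients)
    }
    syn <- do.call(synthetic_config, syn_args)
  }
  args <- y[setdiff(names(y), "synthetic")]
  do.call(pipeline_config, c(list(synthetic = syn), args))
}

#' Build flowering covariate records from surveys, flowering and thermal data
#'
#' Joins the stage-1 budbreak estimates with the 1 September thermal
#' covariates into the vine-year record table of the stage-2 regression:
#' `CV` (1 = 'Hayward'), `BB`, `DD`, `CU` (all divided by `thermal_scale`),
#' `DL` (hours), plus metadata and the response. Vines whose budbreak
#' estimate is flagged are dropped.
#'
#' @param budbreak A [estimate_budbreak()] table.
#' @param flowering Per-vine first-flowering tibble.
#' @param thermal Per region-year [thermal_summary()] rows with `region` and
#'   `year` columns.
#' @param metric_month,metric_day Covariate date (default 1 September).
#' @param thermal_scale Degree-days (and hours) per covariate unit.
#' @return Tibble of flowering records.
#' @export
build_flowering_records <- function(budbreak, flowering, thermal,
                                    metric_month = 9, metric_day = 1,
                                    thermal_scale = 100) {
  metric <- thermal |>
    dplyr::filter(lubridate::month(.data$date) == metric_month,
                  lubridate::mday(.data$date) == metric_day) |>
    dplyr::select("region", "year", "gdd_cum", "cu_cum", "daylength")
  ok <- dplyr::filter(budbreak, .data$flag %in% c("ok", "beyond_observed"))
  dropped <- nrow(budbreak) - nrow(ok)
  if (dropped > 0) {
    rlang::warn(paste(dropped, "vine(s) dropped (degenerate or extrapolated budbreak)"))
  }
  ok |>
    dplyr::select(dplyr::any_of(c("vine_id", "cultivar", "region", "orchard",
                                  "year", "row", "bay", "gdd_at_5pct"))) |>
    dplyr::inner_join(
      dplyr::select(flowering, "vine_id", "first_flower_doy"),
      by = "vine_id"
    ) |>
    dplyr::inner_join(metric, by = c("region", "year")) |>
    dplyr::mutate(
      CV = as.integer(.data$cultivar == "Hayward"),
      BB = .data$gdd_at_5pct / thermal_scale,
      DD = .data$gdd_cum / thermal_scale,
      CU = .data$cu_cum / thermal_scale,
      DL = .data$daylength
    ) |>
    dplyr::select(dplyr::any_of(c("vine_id", "cultivar", "region", "orchard",
                                  "year", "row", "bay")),
                  "CV", "BB", "DD", "CU", "DL", "first_flower_doy")
}

#' Run the full flowering-prediction pipeline
#'
#' Synthetic-or-file ingest, then: thermal summaries per region-year ->
#' per-vine budbreak estimation -> flowering covariate records -> candidate
#' model comparison on the year split with stepwise refinement -> k-fold
#' cross-validation of the final model -> presence/absence classification ->
#' region-by-cultivar ANOVA summaries. Reruns with the same configuration
#' are identical.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, every output table is
#'   written as CSV and a small run log is recorded.
#' @return List of class `pipeline_result`: `records`, `budbreak`,
#'   `year_split` (see [evaluate_year_split()]), `cv`, `classification`,
#'   `anova_mean`, `anova_range`, `strata`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  if (!is.null(config$synthetic)) {
    ds <- simulate_dataset(config$synthetic)
    weather <- ds$weather
    surveys <- ds$surveys
    flowering <- ds$flowering
  } else {
    weather <- read_weather_csv(config$weather_csv)
    phen <- read_phenology_csv(config$phenology_csv)
    surveys <- phen$surveys
    flowering <- phen$flowering
  }

  thermal <- weather |>
    dplyr::group_by(.data$region, .data$year) |>
    dplyr::group_modify(function(w, key) {
      thermal_summary(w, season_start = as.Date(paste0(key$year, "-07-01")),
                      base_temp = config$base_temp,
                      cu_threshold = config$cu_threshold)
    }) |>
    dplyr::ungroup()

  if (!"gdd_cum" %in% names(surveys)) {
    surveys <- surveys |>
      dplyr::left_join(
        dplyr::select(thermal, "region", "year", survey_date = "date",
                      "gdd_cum"),
        by = c("region", "year", "survey_date")
      )
  }

  budbreak <- estimate_budbreak(surveys)
  records <- build_flowering_records(
    budbreak, flowering, thermal,
    metric_month = config$metric_month, metric_day = config$metric_day,
    thermal_scale = config$thermal_scale
  )

  year_split <- evaluate_year_split(records, config$train_years,
                                    config$test_years,
                                    candidates = config$candidates,
                                    level = config$level)
  cv <- kfold_cv(records, year_split$final_fit$design, k = config$k,
                 seed = config$seed)

  inst <- build_classification_instances(records)
  train_inst <- dplyr::filter(inst, .data$year %in% config$train_years)
  test_inst <- dplyr::filter(inst, .data$year %in% config$test_years)
  classifiers <- fit_flower_classifiers(train_inst, seed = config$seed)
  classification <- confusion_table(classifiers, test_inst)

  strata <- stratum_summaries(records)
  anova_mean <- anova_two_way(strata, "mean_doy")
  anova_range <- anova_two_way(strata, "range_days")

  result <- structure(
    list(records = records, budbreak = budbreak, thermal = thermal,
         year_split = year_split, cv = cv, classification = classification,
         anova_mean = anova_mean, anova_range = anova_range, strata = strata,
         config = config),
    class = "pipeline_result"
  )
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat("  records:", nrow(x$records), " final model:",
      x$year_split$final_fit$design$label, "\n")
  cat("  final coverage:",
      round(coverage_percent(x$year_split$final_predictions), 1), "%\n")
  invisible(x)
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    readr::write_csv(df, file.path(out_dir, paste0(name, ".csv")))
  }
  w(result$records, "flowering_records")
  w(result$budbreak, "budbreak_estimates")
  w(result$year_split$comparison, "model_comparison")
  w(result$year_split$final_predictions, "final_predictions")
  w(result$cv, "cross_validation")
  w(result$classification$cells, "classification_cells")
  w(result$classification$summary, "classification_summary")
  w(result$strata, "strata")
  w(tidy(result$anova_mean), "anova_mean_doy")
  w(tidy(result$anova_range), "anova_range")
  writeLines(
    c(paste("seed:", result$config$seed),
      paste("R:", as.character(getRversion())),
      paste("phenocast:", as.character(utils::packageVersion("phenocast")))),
    file.path(out_dir, "run_log.txt")
  )
  invisible(out_dir)
}

# --- CSV readers/writers -----------------------------------------------------

#' Read and write weather and phenology CSVs
#'
#' `write_weather_csv()` emits `station_id,latitude,timestamp,temp_c`
#' (ISO-8601 timestamps, plus `region`/`year` when present);
#' `write_phenology_csv()` emits the survey table and the per-vine flowering
#' table to two files. The readers invert them, validating the schema.
#'
#' @param weather,surveys,flowering Tibbles as produced by
#'   [simulate_dataset()].
#' @param path,survey_path,flowering_path File paths.
#' @return Readers return tibbles (`read_phenology_csv()` a list of two);
#'   writers return the path invisibly.
#' @name phenology_io
NULL

#' @rdname phenology_io
#' @export
write_weather_csv <- function(weather, path) {
  readr::write_csv(weather, path)
  invisible(path)
}

#' @rdname phenology_io
#' @export
read_weather_csv <- function(path) {
  w <- readr::read_csv(path, show_col_types = FALSE)
  assert_columns(w, c("station_id", "latitude", "timestamp", "temp_c"),
                 "weather CSV")
  w$timestamp <- lubridate::as_datetime(w$timestamp, tz = "UTC")
  # a file may hold several stations; validate each series separately
  keys <- w[intersect(c("station_id", "region", "year"), names(w))]
  for (g in split(w, keys, drop = TRUE)) check_hourly(g)
  w
}

#' @rdname phenology_io
#' @export
write_phenology_csv <- function(surveys, flowering, survey_path,
                                flowering_path) {
  readr::write_csv(surveys, survey_path)
  readr::write_csv(flowering, flowering_path)
  invisible(c(survey_path, flowering_path))
}

#' @rdname phenology_io
#' @export
read_phenology_csv <- function(survey_path, flowering_path) {
  surveys <- readr::read_csv(survey_path, show_col_types = FALSE)
  flowering <- readr::read_csv(flowering_path, show_col_types = FALSE)
  assert_columns(surveys,
                 c("orchard", "region", "cultivar", "year", "vine_id",
                   "survey_date", "broken_buds", "total_buds"),
                 "survey CSV")
  assert_columns(flowering,
                 c("orchard", "region", "cultivar", "year", "vine_id",
                   "first_flower_doy"),
                 "flowering CSV")
  list(surveys = surveys, flowering = flowering)
}
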