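#' Build vine-date classification instances
#'
#' Expands flowering records into one instance per vine per survey date
#' between 1 September and 31 December: the label is whether the vine has
#' begun flowering by that date, the numeric predictors are the degree-day
#' and chilling-unit covariates. Two predictor modes are supported:
#' `"on_sep1"` (DD and CU frozen at their 1 September values — the default)
#' and `"since_sep1"` (accumulation from 1 September up to the instance
#' date, which requires a per-day `thermal` table).
#'
#' @param flowering Tibble with one row per vine: `vine_id`, `region`,
#'   `cultivar`, `year`, `first_flower_doy`, and (for `"on_sep1"`) `DD` and
#'   `CU` columns.
#' @param mode `"on_sep1"` or `"since_sep1"`.
#' @param thermal For `"since_sep1"`: per-day thermal summaries with columns
#'   `region`, `year`, `date`, `gdd_cum`, `cu_cum`.
#' @param interval_days Spacing of the instance date grid (default 4).
#' @return Tibble of instances: `vine_id`, `region`, `cultivar`, `year`,
#'   `date_doy`, `DD`, `CU`, `flowering` (0/1).
#' @export
build_classification_instances <- function(flowering,
                                           mode = c("on_sep1", "since_sep1"),
                                           thermal = NULL, interval_days = 4) {
  mode <- match.arg(mode)
  assert_columns(flowering,
                 c("vine_id", "region", "cultivar", "year", "first_flower_doy"),
                 "flowering")
  doys <- seq(244, 365, by = interval_days)  # 1 Sep .. late Dec
  inst <- flowering |>
    dplyr::select(dplyr::any_of(c("vine_id", "region", "cultivar", "year",
                                  "first_flower_doy", "DD", "CU"))) |>
    tidyr::expand_grid(date_doy = doys) |>
    dplyr::mutate(flowering = as.integer(.data$date_doy >= .data$first_flower_doy))
  if (mode == "on_sep1") {
    assert_columns(inst, c("DD", "CU"), "flowering (mode 'on_sep1')")
  } else {
    if (is.null(thermal)) {
      abort_phenocast("mode 'since_sep1' requires a `thermal` table",
                      "phenocast_config_error")
    }
    thermal <- thermal |>
      dplyr::mutate(date_doy = doy(.data$date)) |>
      dplyr::select("region", "year", "date_doy", "gdd_cum", "cu_cum")
    sep1 <- thermal |>
      dplyr::filter(.data$date_doy == 244) |>
      dplyr::select("region", "year", gdd_sep1 = "gdd_cum", cu_sep1 = "cu_cum")
    inst <- inst |>
      dplyr::select(-dplyr::any_of(c("DD", "CU"))) |>
      dplyr::inner_join(thermal, by = c("region", "year", "date_doy")) |>
      dplyr::inner_join(sep1, by = c("region", "year")) |>
      dplyr::mutate(DD = .data$gdd_cum - .data$gdd_sep1,
                    CU = .data$cu_cum - .data$cu_sep1) |>
      dplyr::select(-"gdd_cum", -"cu_cum", -"gdd_sep1", -"cu_sep1")
  }
  dplyr::select(inst, "vine_id", "region", "cultivar", "year", "date_doy",
                "DD", "CU", "flowering")
}

#' Fit the flowering presence/absence classifiers
#'
#' Fits a logistic regression and a random forest (500 trees, seeded) to
#' vine-date instances. Numeric predictors are scaled and centered using
#' training-set statistics, which are stored and re-applied to any test set.
#' Orchard is never used as a predictor.
#'
#' @param train Instances from [build_classification_instances()], both
#'   classes present.
#' @param predictors Predictor columns (numeric ones are standardised;
#'   character ones become factors).
#' @param n_trees Random-forest size.
#' @param seed Seed for the forest's bootstrap resampling.
#' @return Object of class `flowering_classifiers`: `logistic` (glm),
#'   `forest` (randomForest), `scaling` (per-predictor mean/sd), `predictors`.
#' @export
fit_flower_classifiers <- function(train,
                                   predictors = c("DD", "CU", "cultivar", "region"),
                                   n_trees = 500, seed = 1) {
  assert_columns(train, c(predictors, "flowering"), "train")
  if (length(unique(train$flowering)) < 2) {
    abort_phenocast("training data contain a single class", "phenocast_data_error")
  }
  num <- predictors[vapply(train[predictors], is.numeric, logical(1))]
  scaling <- lapply(train[num], function(x) list(center = mean(x), scale = sd(x)))
  design <- apply_scaling(train, predictors, scaling)
  design$flowering <- factor(train$flowering, levels = c(0, 1))

  fml <- stats::as.formula(paste("flowering ~", paste(predictors, collapse = " + ")))
  logistic <- glm(fml, data = design, family = binomial())
  forest <- withr::with_seed(as.integer(seed %% 2147483647), {
    randomForest::randomForest(fml, data = design, ntree = n_trees)
  })
  structure(
    list(logistic = logistic, forest = forest, scaling = scaling,
         predictors = predictors),
    class = "flowering_classifiers"
  )
}

# Standardise numeric predictors with stored statistics; idempotent only when
# statistics are re-derived, so always apply the stored training stats.
apply_scaling <- function(data, predictors, scaling) {
  out <- tibble::as_tibble(data[predictors])
  for (v in names(scaling)) {
    s <- scaling[[v]]
    out[[v]] <- (out[[v]] - s$center) / (if (s$scale > 0) s$scale else 1)
  }
  for (v in setdiff(predictors, names(scaling))) {
    out[[v]] <- factor(out[[v]])
  }
  out
}

#' Predict flowering presence from fitted classifiers
#'
#' @param object A `flowering_classifiers` fit.
#' @param newdata Instances to classify.
#' @param ... Unused.
#' @return `newdata` with `pred_logistic` and `pred_forest` columns (0/1).
#' @export
predict.flowering_classifiers <- function(object, newdata, ...) {
  design <- apply_scaling(newdata, object$predictors, object$scaling)
  p_log <- predict(object$logistic, newdata = design, type = "response")
  dplyr::mutate(
    tibble::as_tibble(newdata),
    pred_logistic = as.integer(p_log >= 0.5),
    pred_forest = as.integer(as.character(predict(object$forest, newdata = design)))
  )
}

#' Confusion breakdown per region and cultivar
#'
#' The four prediction-by-outcome cells as percentages of instances within
#' each region x cultivar stratum (cells sum to 100 per stratum and model),
#' plus overall accuracy, sensitivity and specificity per model.
#'
#' @param fitted A `flowering_classifiers` object.
#' @param test Labelled instances.
#' @return List with `cells` (tibble: `region`, `cultivar`, `prediction`,
#'   `flowering`, `pct_logistic`, `pct_forest`, `n`) and `summary` (tibble:
#'   per model accuracy/sensitivity/specificity in percent).
#' @export
confusion_table <- function(fitted, test) {
  pred <- predict(fitted, test)
  strata <- dplyr::count(pred, .data$region, .data$cultivar, name = "n_stratum")
  empty <- strata$n_stratum == 0
  if (any(empty)) rlang::warn("empty region x cultivar stratum omitted")

  cell_grid <- tidyr::expand_grid(prediction = 0:1, flowering = 0:1)
  cells <- purrr::pmap(strata, function(region, cultivar, n_stratum) {
    sub <- pred[pred$region == region & pred$cultivar == cultivar, ]
    purrr::pmap(cell_grid, function(prediction, flowering) {
      tibble::tibble(
        region = region, cultivar = cultivar,
        prediction = prediction, flowering = flowering,
        pct_logistic = 100 * mean(sub$pred_logistic == prediction &
                                    sub$flowering == flowering),
        pct_forest = 100 * mean(sub$pred_forest == prediction &
                                  sub$flowering == flowering),
        n = n_stratum
      )
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()

  summarise_model <- function(p) {
    tp <- sum(p == 1 & pred$flowering == 1)
    tn <- sum(p == 0 & pred$flowering == 0)
    fp <- sum(p == 1 & pred$flowering == 0)
    fn <- sum(p == 0 & pred$flowering == 1)
    tibble::tibble(
      accuracy = 100 * (tp + tn) / length(p),
      sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
      specificity = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_
    )
  }
  summary <- dplyr::bind_rows(
    dplyr::mutate(summarise_model(pred$pred_logistic), model = "logistic"),
    dplyr::mutate(summarise_model(pred$pred_forest), model = "random_forest")
  ) |> dplyr::relocate("model")

  list(cells = cells, summary = summary)
}
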