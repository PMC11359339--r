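#' Compare the candidate flowering models on a year-based train/test split
#'
#' Fits every candidate with full interactions on the training years, then
#' predicts the test years with 99% prediction intervals and reports, per
#' candidate: training AIC and R^2, the minimum and maximum interval width
#' over the test set, and the percentage of observed flowering days falling
#' inside their own interval. The AIC-best full-interaction candidate is then
#' refined by stepwise AIC ([stepwise_refine()]) and reported as an
#' additional `"<label>_1"` row — the final model of the pipeline.
#'
#' @param records Vine-year records with the candidate predictors, a `year`
#'   column and the response.
#' @param train_years,test_years Disjoint, non-empty integer vectors.
#' @param candidates Candidate grid (default [candidate_specs()]).
#' @param level Prediction-interval level.
#' @param response Response column name.
#' @return List of class `year_split_eval`: `comparison` (tibble, one row per
#'   candidate plus the refined final model), `best_label`, `final_fit` (the
#'   refined `flowering_fit`), `final_predictions`.
#' @export
evaluate_year_split <- function(records, train_years, test_years,
                                candidates = candidate_specs(), level = 0.99,
                                response = "first_flower_doy") {
  records <- tibble::as_tibble(records)
  assert_columns(records, c("year", response), "records")
  if (length(train_years) == 0 || length(test_years) == 0) {
    abort_phenocast("train_years and test_years must both be non-empty",
                    "phenocast_config_error")
  }
  if (length(intersect(train_years, test_years)) > 0) {
    abort_phenocast("train_years and test_years must be disjoint",
                    "phenocast_config_error")
  }
  train <- dplyr::filter(records, .data$year %in% train_years)
  test <- dplyr::filter(records, .data$year %in% test_years)
  if (nrow(train) == 0 || nrow(test) == 0) {
    abort_phenocast("empty train or test split", "phenocast_data_error")
  }
  if ("cultivar" %in% names(records)) {
    missing_cv <- setdiff(unique(test$cultivar), unique(train$cultivar))
    if (length(missing_cv) > 0) {
      rlang::warn(paste("test-only cultivar(s) excluded:",
                        paste(missing_cv, collapse = ", ")))
      test <- dplyr::filter(test, !.data$cultivar %in% missing_cv)
    }
  }

  eval_one <- function(fit, label) {
    pred <- predict_with_interval(fit, test, level = level)
    tibble::tibble(
      model = label,
      interval_min = min(pred$interval_width),
      interval_max = max(pred$interval_width),
      coverage_pct = coverage_percent(pred),
      aic = fit$aic,
      r_squared = fit$r_squared
    )
  }

  fits <- purrr::map(candidates$label, function(lb) {
    fit_flowering_model(train, lb, response = response)
  })
  rows <- purrr::map2(fits, candidates$label, eval_one)

  aics <- vapply(fits, `[[`, numeric(1), "aic")
  best_i <- which.min(aics)
  final_fit <- stepwise_refine(fits[[best_i]])
  final_pred <- predict_with_interval(final_fit, test, level = level)
  rows <- c(rows, list(eval_one(final_fit, final_fit$design$label)))

  structure(
    list(
      comparison = purrr::list_rbind(rows),
      best_label = candidates$label[best_i],
      final_fit = final_fit,
      final_predictions = final_pred
    ),
    class = "year_split_eval"
  )
}

#' @export
print.year_split_eval <- function(x, ...) {
  cat("<year_split_eval> best full-interaction candidate:", x$best_label, "\n")
  print(x$comparison)
  invisible(x)
}

#' @param x A `year_split_eval`.
#' @param ... Unused.
#' @rdname evaluate_year_split
#' @method tidy year_split_eval
#' @export
tidy.year_split_eval <- function(x, ...) x$comparison

#' K-fold cross-validation of a flowering model
#'
#' Randomly partitions the records into `k` folds (seeded), refits the model
#' on each training complement (so each training set holds `(k-1)/k` of the
#' data — 80% at the default `k = 5`) and scores the held-out fold.
#'
#' @param records Vine-year records.
#' @param design Candidate label, formula or [build_design()] result.
#' @param k Number of folds (default 5); must not exceed the record count.
#' @param seed Seed for the fold assignment.
#' @param response Response column name.
#' @return One-row tibble with mean and min-max range of the held-out RMSE,
#'   R^2 (squared correlation of observed and predicted) and MAE; the
#'   per-fold tibble is attached as attribute `"folds"`.
#' @export
kfold_cv <- function(records, design, k = 5, seed = 1,
                     response = "first_flower_doy") {
  records <- tibble::as_tibble(records)
  n <- nrow(records)
  if (k > n) abort_phenocast("k cannot exceed the number of records",
                             "phenocast_config_error")
  folds <- withr::with_seed(as.integer(seed %% 2147483647), {
    sample(rep(seq_len(k), length.out = n))
  })
  per_fold <- purrr::map(seq_len(k), function(i) {
    fit <- fit_flowering_model(records[folds != i, ], design, response = response)
    held <- records[folds == i, ]
    pred <- predict(fit$model, newdata = held)
    obs <- held[[response]]
    r2 <- if (sd(pred) == 0 || sd(obs) == 0) NA_real_ else stats::cor(obs, pred)^2
    tibble::tibble(fold = i, n_train = sum(folds != i), n_test = nrow(held),
                   rmse = rmse(obs, pred), r_squared = r2, mae = mae(obs, pred))
  }) |> purrr::list_rbind()
  out <- tibble::tibble(
    k = k,
    rmse_mean = mean(per_fold$rmse), rmse_min = min(per_fold$rmse),
    rmse_max = max(per_fold$rmse),
    r2_mean = mean(per_fold$r_squared), r2_min = min(per_fold$r_squared),
    r2_max = max(per_fold$r_squared),
    mae_mean = mean(per_fold$mae), mae_min = min(per_fold$mae),
    mae_max = max(per_fold$mae)
  )
  attr(out, "folds") <- per_fold
  out
}

#' Within-orchard analysis: does row/bay position help?
#'
#' For records from a single repeatedly-sampled orchard with row and bay
#' labels, fits each candidate twice — once with row and bay added as
#' categorical main effects, once without — on the training years, and
#' reports the interval widths, coverage, AIC and R^2 of both versions side
#' by side. Row/bay levels present only in the test years are pooled into
#' `"other"` with a warning.
#'
#' @inheritParams evaluate_year_split
#' @param refine_best Also report the stepwise-refined best candidate per
#'   inclusion mode (default `TRUE`).
#' @return Tibble: one row per candidate x {included, excluded}, columns
#'   `model`, `row_bay`, `interval_min`, `interval_max`, `coverage_pct`,
#'   `aic`, `r_squared`.
#' @export
positional_analysis <- function(records, train_years, test_years,
                                candidates = candidate_specs(), level = 0.99,
                                refine_best = TRUE,
                                response = "first_flower_doy") {
  records <- tibble::as_tibble(records)
  assert_columns(records, c("row", "bay", "year", response), "records")
  if ("orchard" %in% names(records) &&
      length(unique(records$orchard)) > 1) {
    abort_phenocast("positional analysis expects records from a single orchard",
                    "phenocast_config_error")
  }
  if (length(unique(records$year)) < 2) {
    abort_phenocast("positional analysis needs records from >= 2 years",
                    "phenocast_data_error")
  }
  train <- dplyr::filter(records, .data$year %in% train_years)
  test <- dplyr::filter(records, .data$year %in% test_years)

  # pool unseen positional levels so prediction never hits a novel factor level
  for (v in c("row", "bay")) {
    train[[v]] <- as.character(train[[v]])
    test[[v]] <- as.character(test[[v]])
    unseen <- setdiff(unique(test[[v]]), unique(train[[v]]))
    if (length(unseen) > 0) {
      rlang::warn(paste0("test-only ", v, " level(s) pooled into 'other': ",
                         paste(unseen, collapse = ", ")))
      test[[v]][test[[v]] %in% unseen] <- "other"
      train[[v]] <- factor(train[[v]], levels = c(unique(train[[v]]), "other"))
      # 'other' absent from training: drop those test rows with a warning
      keep <- test[[v]] != "other"
      test <- test[keep, ]
    }
    levs <- unique(as.character(train[[v]]))
    train[[v]] <- factor(as.character(train[[v]]), levels = levs)
    test[[v]] <- factor(as.character(test[[v]]), levels = levs)
  }

  single_level <- vapply(c("row", "bay"), function(v) {
    length(levels(train[[v]])) < 2
  }, logical(1))
  extra_terms <- c("row", "bay")[!single_level]

  eval_mode <- function(extra, mode_label) {
    fits <- purrr::map(candidates$label, function(lb) {
      design <- build_design(train, lb, extra = extra, response = response)
      fit_flowering_model(train, design, response = response)
    })
    rows <- purrr::map2(fits, candidates$label, function(fit, lb) {
      pred <- predict_with_interval(fit, test, level = level)
      tibble::tibble(
        model = lb, row_bay = mode_label,
        interval_min = min(pred$interval_width),
        interval_max = max(pred$interval_width),
        coverage_pct = coverage_percent(pred),
        aic = fit$aic, r_squared = fit$r_squared
      )
    })
    if (refine_best) {
      best <- which.min(vapply(fits, `[[`, numeric(1), "aic"))
      refined <- stepwise_refine(fits[[best]])
      pred <- predict_with_interval(refined, test, level = level)
      rows <- c(rows, list(tibble::tibble(
        model = refined$design$label, row_bay = mode_label,
        interval_min = min(pred$interval_width),
        interval_max = max(pred$interval_width),
        coverage_pct = coverage_percent(pred),
        aic = refined$aic, r_squared = refined$r_squared
      )))
    }
    purrr::list_rbind(rows)
  }

  dplyr::bind_rows(
    eval_mode(extra_terms, "included"),
    eval_mode(character(), "excluded")
  ) |>
    dplyr::arrange(.data$model, dplyr::desc(.data$row_bay))
}
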