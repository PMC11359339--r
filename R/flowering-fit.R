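#' Fit a flowering-date regression by ordinary least squares
#'
#' @param records Training data frame (rows = vine-year records) holding the
#'   design's predictors and the response.
#' @param design A [build_design()] result, a candidate label (expanded with
#'   full interactions), or a formula.
#' @param response Response column, used when `design` is a label.
#' @return Object of class `flowering_fit`: the underlying `lm` plus the
#'   design, training metrics (AIC under the Gaussian likelihood, R^2, RMSE,
#'   MAE) and the training predictor ranges (used to flag extrapolation at
#'   prediction time).
#' @export
#' @examples
#' cfg <- synthetic_config(seed = 1)
#' rec <- simulate_flowering_records(300, seed = 2)
#' fit <- fit_flowering_model(rec, "CV.BB.DD")
#' glance(fit)
fit_flowering_model <- function(records, design, response = "first_flower_doy") {
  if (inherits(design, "formula")) {
    design <- structure(
      list(formula = design,
           label = paste(deparse(design[[3]]), collapse = ""),
           terms = c("(Intercept)",
                     attr(stats::terms(design, data = records), "term.labels")),
           predictors = all.vars(design[[3]])),
      class = "flowering_design"
    )
  } else if (!inherits(design, "flowering_design")) {
    design <- build_design(records, design, response = response)
  }
  records <- tibble::as_tibble(records)
  model <- lm(design$formula, data = records)
  p <- length(coef(model))
  if (nrow(records) <= p) {
    abort_phenocast("need more records than model terms", "phenocast_data_error")
  }
  if (any(is.na(coef(model)))) {
    abort_phenocast(
      paste("rank-deficient design; collinear term(s):",
            paste(names(coef(model))[is.na(coef(model))], collapse = ", ")),
      "phenocast_fit_error"
    )
  }
  obs <- stats::model.response(stats::model.frame(model))
  fitted <- stats::fitted(model)
  num <- design$predictors[vapply(records[design$predictors], is.numeric, logical(1))]
  ranges <- lapply(records[num], range)
  structure(
    list(
      model = model, design = design, n = nrow(records),
      aic = AIC(model),
      r_squared = summary(model)$r.squared,
      rmse = rmse(obs, fitted),
      mae = mae(obs, fitted),
      sigma = summary(model)$sigma,
      training_ranges = ranges
    ),
    class = "flowering_fit"
  )
}

#' @export
print.flowering_fit <- function(x, ...) {
  cat("<flowering_fit> ", x$design$label, "\n", sep = "")
  cat("  n = ", x$n, ", AIC = ", round(x$aic, 1),
      ", R^2 = ", round(x$r_squared, 3),
      ", RMSE = ", round(x$rmse, 2), " d\n", sep = "")
  invisible(x)
}

#' @rdname fit_flowering_model
#' @param x A `flowering_fit`.
#' @param ... Unused.
#' @method tidy flowering_fit
#' @export
tidy.flowering_fit <- function(x, ...) {
  s <- summary(x$model)$coefficients
  tibble::tibble(
    term = rownames(s),
    estimate = s[, "Estimate"],
    std.error = s[, "Std. Error"],
    statistic = s[, "t value"],
    p.value = s[, "Pr(>|t|)"]
  )
}

#' @rdname fit_flowering_model
#' @method glance flowering_fit
#' @export
glance.flowering_fit <- function(x, ...) {
  tibble::tibble(
    label = x$design$label, n = x$n, aic = x$aic,
    r_squared = x$r_squared, rmse = x$rmse, mae = x$mae, sigma = x$sigma
  )
}

#' Refine a flowering fit by bidirectional stepwise AIC
#'
#' Starting from a (typically full-interaction) fit, repeatedly adds or drops
#' single terms to lower the AIC, never retaining an interaction without its
#' marginal terms, until no single-term move improves. The refined model's
#' AIC is never above the starting model's.
#'
#' @param fit A [fit_flowering_model()] result.
#' @return A new `flowering_fit` for the refined term set; its design carries
#'   the suffix `"_1"` on the label.
#' @export
stepwise_refine <- function(fit) {
  records <- tibble::as_tibble(fit$model$model)
  refined <- run_stepaic(stats::formula(fit$model), records)
  terms <- attr(stats::terms(refined), "term.labels")
  design <- structure(
    list(formula = stats::formula(refined),
         label = paste0(fit$design$label, "_1"),
         terms = c("(Intercept)", terms),
         predictors = fit$design$predictors),
    class = "flowering_design"
  )
  response <- as.character(stats::formula(refined)[[2]])
  out <- fit_flowering_model(records, design, response = response)
  out$training_ranges <- fit$training_ranges
  out
}

# stepAIC re-evaluates the model call in its caller's frame, so run it from a
# frame where the data are bound to a stable name.
run_stepaic <- function(fml, data) {
  environment(fml) <- environment()
  model <- lm(fml, data = data)
  MASS::stepAIC(model, direction = "both", trace = 0)
}

#' Predict flowering days with 99% prediction intervals
#'
#' Point predictions from the fitted coefficients, with prediction standard
#' error `sqrt(se_mean^2 + sigma^2)` (the standard error of the estimated
#' mean plus the residual variance) and interval
#' `prediction +/- z * se`, where `z` is the standard-normal critical value
#' ([interval_critical_value()]; 2.576 at the default 99% level). Records
#' whose numeric predictors fall far outside the training range (beyond one
#' full training span past either end, i.e. outside 3x the training span)
#' are flagged as extrapolation.
#'
#' @param fit A `flowering_fit`.
#' @param new_records Data frame of records to predict; if it contains the
#'   response column, observed values and an `inside` flag are included.
#' @param level Interval level (default 0.99).
#' @return Tibble of class `flowering_predictions`: per record
#'   `predicted_doy`, `lower`, `upper`, `interval_width`, `extrapolation`,
#'   and when observed: `observed_doy`, `inside`. Coverage percentage and
#'   min/max width are attached as attributes and via [coverage_percent()].
#' @export
predict_with_interval <- function(fit, new_records, level = 0.99) {
  new_records <- tibble::as_tibble(new_records)
  assert_columns(new_records, fit$design$predictors, "new_records")
  z <- interval_critical_value(level)
  pr <- predict(fit$model, newdata = new_records, se.fit = TRUE)
  se_pred <- sqrt(pr$se.fit^2 + fit$sigma^2)
  extrap <- rep(FALSE, nrow(new_records))
  for (v in names(fit$training_ranges)) {
    rg <- fit$training_ranges[[v]]
    span <- diff(rg)
    extrap <- extrap | new_records[[v]] < rg[1] - span |
      new_records[[v]] > rg[2] + span
  }
  if (any(extrap)) {
    rlang::warn(paste0(sum(extrap),
                       " record(s) lie far outside the training predictor range"))
  }
  pred <- as.numeric(pr$fit)
  out <- tibble::tibble(
    predicted_doy = pred,
    se = se_pred,
    lower = pred - z * se_pred,
    upper = pred + z * se_pred,
    interval_width = 2 * z * se_pred,
    extrapolation = extrap
  )
  response <- as.character(stats::formula(fit$model)[[2]])
  if (response %in% names(new_records)) {
    out$observed_doy <- new_records[[response]]
    out$inside <- out$observed_doy >= out$lower & out$observed_doy <= out$upper
  }
  meta <- intersect(c("vine_id", "region", "cultivar", "orchard", "year"),
                    names(new_records))
  out <- dplyr::bind_cols(new_records[meta], out)
  class(out) <- c("flowering_predictions", class(out))
  out
}

#' Coverage percentage of a prediction table
#'
#' @param predictions A [predict_with_interval()] result with observed values.
#' @return Percentage (0-100) of observations inside their own interval.
#' @export
coverage_percent <- function(predictions) {
  if (!"inside" %in% names(predictions)) {
    abort_phenocast("predictions carry no observed values", "phenocast_data_error")
  }
  100 * mean(predictions$inside)
}

#' Simulate flowering records directly from a coefficient set
#'
#' Draws vine-level covariates (`CV ~ Bernoulli(0.5)`, `BB ~ N(2, 0.5)`,
#' `DD ~ N(3, 1)`, in hundreds of degree-days) and generates the response
#' from [flowering_linear_predictor()] plus Gaussian noise. This bypasses the
#' weather/budbreak stages and is the correctly-specified test bed for the
#' stage-2 regression properties (coefficient recovery, interval coverage,
#' candidate selection).
#'
#' @param n Number of records.
#' @param coefficients Generating coefficients
#'   (default [reference_flowering_coefficients()]`("full")`).
#' @param residual_sd Noise standard deviation in days (default 4).
#' @param seed Optional seed.
#' @param bb_mean,bb_sd,dd_mean,dd_sd Covariate distribution parameters.
#' @return Tibble with `CV`, `BB`, `DD`, `CU`, `DL`, `first_flower_doy` (the
#'   response is left unrounded: these records feed regression property
#'   checks, not the survey emulator). `CU` and `DL` are independent noise
#'   covariates so that candidate sets containing them are misspecified by
#'   construction.
#' @export
simulate_flowering_records <- function(n,
                                       coefficients = reference_flowering_coefficients("full"),
                                       residual_sd = 4, seed = NULL,
                                       bb_mean = 2, bb_sd = 0.5,
                                       dd_mean = 3, dd_sd = 1) {
  gen <- function() {
    cv <- stats::rbinom(n, 1, 0.5)
    bb <- rnorm(n, bb_mean, bb_sd)
    dd <- rnorm(n, dd_mean, dd_sd)
    tibble::tibble(
      CV = cv, BB = bb, DD = dd,
      CU = rnorm(n, 4, 1), DL = rnorm(n, 11, 0.3),
      first_flower_doy = flowering_linear_predictor(coefficients, cv, bb, dd) +
        rnorm(n, 0, residual_sd)
    )
  }
  if (is.null(seed)) gen() else withr::with_seed(as.integer(seed %% 2147483647), gen())
}
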