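#' Reference flowering-model coefficient sets
#'
#' Two calibrated final models for the first-flowering day of kiwifruit,
#' expressed as named coefficient vectors over the hierarchical predictors:
#' `CV` (cultivar indicator, 1 = 'Hayward'), `BB` (growing-degree-day
#' accumulation at predicted 5% budbreak, per 100 degree-days) and `DD`
#' (degree-day accumulation on 1 September, per 100 degree-days).
#'
#' * `"full"` — the full-dataset model
#'   `312.7 + 15.1 CV + 10.9 BB - 3.3 DD - 3.5 CV:BB + 1.0 BB:DD`,
#'   used as the generating truth of [synthetic_config()].
#' * `"single_orchard"` — the single-orchard (row/bay subset) model
#'   `471.2 + 32.1 CV + 0.09 BB - 0.61 DD - 0.06 CV:BB` (no BB:DD term).
#'
#' @param which `"full"` or `"single_orchard"`.
#' @return Named numeric vector with elements `intercept`, `cv`, `bb`, `dd`,
#'   `cv_bb`, `bb_dd` (days).
#' @seealso [flowering_linear_predictor()]
#' @export
#' @examples
#' reference_flowering_coefficients("full")
reference_flowering_coefficients <- function(which = c("full", "single_orchard")) {
  which <- match.arg(which)
  switch(which,
    full = c(intercept = 312.7, cv = 15.1, bb = 10.9, dd = -3.3,
             cv_bb = -3.5, bb_dd = 1.0),
    single_orchard = c(intercept = 471.2, cv = 32.1, bb = 0.09, dd = -0.61,
                       cv_bb = -0.06, bb_dd = 0.0)
  )
}

#' Evaluate a flowering-date linear predictor
#'
#' Computes `intercept + cv*CV + bb*BB + dd*DD + cv_bb*CV*BB + bb_dd*BB*DD`
#' for coefficient vectors in the layout of
#' [reference_flowering_coefficients()]. This is the deterministic core both
#' of the synthetic generator and of predictions from the reference models.
#'
#' @param coefficients Named numeric vector (`intercept`, `cv`, `bb`, `dd`,
#'   `cv_bb`, `bb_dd`).
#' @param cv Cultivar indicator, 0 ('Zesy002') or 1 ('Hayward'). Vectorised.
#' @param bb 5%-budbreak degree days, in coefficient units (per 100
#'   degree-days under the defaults). Vectorised.
#' @param dd Degree days on 1 September, same units. Vectorised.
#' @return Numeric vector of predicted first-flowering days of year.
#' @export
#' @examples
#' flowering_linear_predictor(reference_flowering_coefficients("full"),
#'                            cv = 0, bb = 0, dd = 0)  # 312.7
flowering_linear_predictor <- function(coefficients, cv, bb, dd) {
  co <- coefficients
  unname(co[["intercept"]] + co[["cv"]] * cv + co[["bb"]] * bb +
           co[["dd"]] * dd + co[["cv_bb"]] * cv * bb + co[["bb_dd"]] * bb * dd)
}

#' Predict flowering day from a reference coefficient set
#'
#' Tidy wrapper around [flowering_linear_predictor()]: takes a data frame of
#' vine records and appends the point prediction of the chosen reference
#' model.
#'
#' @param records Data frame with columns `CV`, `BB`, `DD` (covariate units as
#'   in [reference_flowering_coefficients()]).
#' @param which Which reference model; see
#'   [reference_flowering_coefficients()].
#' @return `records` as a tibble with a `predicted_doy` column appended.
#' @export
predict_reference_flowering <- function(records, which = c("full", "single_orchard")) {
  assert_columns(records, c("CV", "BB", "DD"), "records")
  co <- reference_flowering_coefficients(match.arg(which))
  dplyr::mutate(
    tibble::as_tibble(records),
    predicted_doy = flowering_linear_predictor(co, .data$CV, .data$BB, .data$DD)
  )
}

#' Normal critical value for a two-sided prediction interval
#'
#' Standard-normal quantile for the given two-sided level, rounded to three
#' decimals so the conventional 99% value is exactly 2.576.
#'
#' @param level Interval level in (0, 1); default 0.99.
#' @return Scalar critical value.
#' @export
#' @examples
#' interval_critical_value(0.99)  # 2.576
interval_critical_value <- function(level = 0.99) {
  if (!is.numeric(level) || level <= 0 || level >= 1) {
    abort_phenocast("level must lie in (0, 1)", "phenocast_config_error")
  }
  round(qnorm((1 + level) / 2), 3)
}
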