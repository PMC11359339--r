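#' Fit the three candidate budbreak curves for one vine
#'
#' Fits, against growing-degree-day accumulation, (1) a binomial GLM for the
#' proportion of buds broken (logit link, weights = total buds), (2) a
#' Poisson log-linear model for the broken-bud count, and (3) a quadratic
#' least-squares model for the count. Each fit reports its AIC and an r^2
#' defined as the squared Pearson correlation between observed and fitted
#' budbreak proportions (so the three families are comparable on one scale).
#'
#' @param survey Tibble for a single vine with columns `gdd_cum`,
#'   `broken_buds`, `total_buds`; at least 4 observations, cumulative counts
#'   non-decreasing.
#' @return A list of class `budbreak_fits` with elements `binomial`,
#'   `poisson`, `polynomial` (each a list: `family`, `model`, `aic`,
#'   `r_squared`, `n_params`) and `vine_id` if present in `survey`.
#'   Degenerate panels (all-zero or all-saturated counts) raise a condition
#'   of class `phenocast_degenerate_fit`.
#' @export
#' @examples
#' sv <- tibble::tibble(
#'   gdd_cum = seq(50, 500, by = 50),
#'   broken_buds = round(40 * plogis(0.03 * (gdd_cum - 250))),
#'   total_buds = 40
#' )
#' fits <- fit_budbreak_curves(sv)
#' sapply(fits[c("binomial", "poisson", "polynomial")], `[[`, "aic")
fit_budbreak_curves <- function(survey) {
  assert_columns(survey, c("gdd_cum", "broken_buds", "total_buds"), "survey")
  validate_budbreak_survey(survey)
  y <- survey$broken_buds
  n <- survey$total_buds
  g <- survey$gdd_cum
  if (all(y == 0) || all(y == n)) {
    abort_phenocast(
      paste0("degenerate budbreak panel (",
             if (all(y == 0)) "no buds ever broke" else "all buds broken at every survey",
             ")"),
      "phenocast_degenerate_fit"
    )
  }
  prop <- y / n

  # near-complete panels routinely trigger the harmless 0/1 fitted-probability
  # warning; muffle just that one
  bin <- withCallingHandlers(
    glm(cbind(y, n - y) ~ g, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  poi <- glm(y ~ g, family = poisson())
  pol <- lm(y ~ g + I(g^2))

  mk <- function(family, model, fitted_prop, n_params) {
    r2 <- if (sd(fitted_prop) == 0 || sd(prop) == 0) 0 else
      stats::cor(prop, fitted_prop)^2
    list(family = family, model = model, aic = AIC(model),
         r_squared = r2, n_params = n_params,
         total_buds = utils::tail(n, 1))
  }

  out <- list(
    binomial = mk("binomial", bin, stats::fitted(bin), 2L),
    poisson = mk("poisson", poi, stats::fitted(poi) / n, 2L),
    polynomial = mk("polynomial", pol, stats::fitted(pol) / n, 3L),
    vine_id = if ("vine_id" %in% names(survey)) survey$vine_id[1] else NA_character_,
    survey = survey
  )
  class(out) <- "budbreak_fits"
  out
}

validate_budbreak_survey <- function(survey) {
  if (nrow(survey) < 4) {
    abort_phenocast("at least 4 survey observations are required per vine",
                    "phenocast_data_error")
  }
  if (is.unsorted(survey$gdd_cum)) {
    abort_phenocast("gdd_cum must be non-decreasing", "phenocast_data_error")
  }
  if (is.unsorted(survey$broken_buds)) {
    abort_phenocast("broken_buds must be non-decreasing (cumulative counts)",
                    "phenocast_data_error")
  }
  if (any(survey$broken_buds > survey$total_buds)) {
    abort_phenocast("broken_buds cannot exceed total_buds", "phenocast_data_error")
  }
  invisible(survey)
}

#' Select the best budbreak curve family by AIC
#'
#' Returns the minimum-AIC fit among the families in a [fit_budbreak_curves()]
#' result. Ties are broken toward the family with fewer parameters, then
#' toward the binomial.
#'
#' @param fits A `budbreak_fits` object (or a list of >= 2 per-family fits).
#' @return The selected per-family fit (list with `family`, `model`, `aic`,
#'   `r_squared`).
#' @export
select_best_family <- function(fits) {
  fam <- fits[intersect(c("binomial", "poisson", "polynomial"), names(fits))]
  fam <- fam[!vapply(fam, is.null, logical(1))]
  if (length(fam) < 2) {
    abort_phenocast("at least 2 successful fits are required for selection",
                    "phenocast_data_error")
  }
  aic <- vapply(fam, `[[`, numeric(1), "aic")
  npar <- vapply(fam, `[[`, numeric(1), "n_params")
  is_bin <- as.integer(names(fam) != "binomial")
  ord <- order(aic, npar, is_bin)
  fam[[ord[1]]]
}

#' Invert a fitted budbreak curve at the 5% level
#'
#' Finds the smallest GDD at which the fitted expected budbreak proportion
#' reaches `level` times the vine's final observed budbreak proportion
#' (default) or `level` times 1 (i.e. of all monitored buds) when
#' `basis = "total_buds"`. The crossing is located by bisection to 0.01
#' degree-days after bracketing on a dense grid, which also makes the
#' non-monotone quadratic family safe (the smallest crossing is returned).
#'
#' @param fit A per-family fit from [fit_budbreak_curves()] /
#'   [select_best_family()].
#' @param survey The vine's survey tibble (for the final observed proportion
#'   and the GDD search range).
#' @param level Fraction of the target budbreak (default 0.05).
#' @param basis `"final_budbreak"` (5% of the vine's own final budbreak) or
#'   `"total_buds"` (5% of all monitored buds).
#' @param tol Bisection tolerance in degree-days.
#' @return A list with `gdd_at_5pct` (NA when the curve never reaches the
#'   level within 1.5x the maximum observed GDD, in which case
#'   `flag = "extrapolated"`), `target` (the proportion sought) and `flag`.
#' @export
invert_at_5pct <- function(fit, survey, level = 0.05,
                           basis = c("final_budbreak", "total_buds"),
                           tol = 0.01) {
  basis <- match.arg(basis)
  final_prop <- utils::tail(survey$broken_buds, 1) / utils::tail(survey$total_buds, 1)
  target <- level * switch(basis, final_budbreak = final_prop, total_buds = 1)
  gmax <- 1.5 * max(survey$gdd_cum)

  f <- function(g) predict_budbreak_proportion(fit, g) - target

  grid <- seq(0, gmax, length.out = 512)
  vals <- f(grid)
  if (vals[1] >= 0) {
    return(list(gdd_at_5pct = 0, target = target, flag = "at_origin"))
  }
  cross <- which(vals[-1] >= 0 & vals[-length(vals)] < 0)
  if (length(cross) == 0) {
    return(list(gdd_at_5pct = NA_real_, target = target, flag = "extrapolated"))
  }
  lo <- grid[cross[1]]
  hi <- grid[cross[1] + 1]
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  gdd <- (lo + hi) / 2
  flag <- if (gdd > max(survey$gdd_cum)) "beyond_observed" else "ok"
  list(gdd_at_5pct = gdd, target = target, flag = flag)
}

# Expected budbreak proportion of a per-family fit at GDD g (vectorised).
predict_budbreak_proportion <- function(fit, g) {
  nd <- data.frame(g = g)
  switch(fit$family,
    binomial = as.numeric(predict(fit$model, nd, type = "response")),
    poisson = as.numeric(predict(fit$model, nd, type = "response")) / fit$total_buds,
    polynomial = as.numeric(predict(fit$model, nd)) / fit$total_buds,
    abort_phenocast(paste0("unknown family: ", fit$family), "phenocast_config_error")
  )
}

#' Estimate GDD at 5% budbreak for every vine in a survey table
#'
#' Stage 1 of the hierarchy: groups the survey table by vine, fits the three
#' candidate curve families, selects by AIC and inverts the winner at the 5%
#' level. Vines with degenerate panels or extrapolated inversions are kept in
#' the output with an explanatory `flag` and `NA` estimate.
#'
#' @param surveys Survey tibble as produced by [simulate_dataset()] (columns
#'   `vine_id`, `cultivar`, `region`, `year`, `gdd_cum`, `broken_buds`,
#'   `total_buds`, plus any metadata columns, which are carried through).
#' @inheritParams invert_at_5pct
#' @return Tibble of class `budbreak_estimates`, one row per vine: metadata,
#'   `family`, `aic`, `r_squared`, `gdd_at_5pct`, `flag`.
#' @export
estimate_budbreak <- function(surveys, level = 0.05,
                              basis = c("final_budbreak", "total_buds")) {
  basis <- match.arg(basis)
  assert_columns(surveys, c("vine_id", "gdd_cum", "broken_buds", "total_buds"),
                 "surveys")
  meta_cols <- intersect(
    c("vine_id", "cultivar", "region", "orchard", "year", "row", "bay"),
    names(surveys)
  )
  out <- surveys |>
    dplyr::group_by(dplyr::across(dplyr::all_of(meta_cols))) |>
    dplyr::group_modify(function(sv, key) {
      res <- tryCatch({
        fits <- fit_budbreak_curves(
          dplyr::mutate(sv, vine_id = key$vine_id[1])
        )
        best <- select_best_family(fits)
        best$total_buds <- sv$total_buds[1]
        inv <- invert_at_5pct(best, sv, level = level, basis = basis)
        tibble::tibble(
          family = best$family, aic = best$aic, r_squared = best$r_squared,
          gdd_at_5pct = inv$gdd_at_5pct, flag = inv$flag
        )
      }, phenocast_degenerate_fit = function(e) {
        tibble::tibble(family = NA_character_, aic = NA_real_,
                       r_squared = NA_real_, gdd_at_5pct = NA_real_,
                       flag = "degenerate")
      })
      res
    }) |>
    dplyr::ungroup()
  class(out) <- c("budbreak_estimates", class(out))
  out
}
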