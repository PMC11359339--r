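#' Per-stratum flowering summaries (mean and range)
#'
#' Aggregates vine-level first-flowering days into orchard-year-cultivar
#' strata: the stratum mean and the stratum range (max - min). Single-vine
#' strata have no range and are excluded from the range table with a
#' warning. These stratum-level values are the analysis units of
#' [anova_two_way()].
#'
#' @param flowering Tibble with `first_flower_doy` and the grouping columns.
#' @param keys Stratum-defining columns.
#' @return Tibble per stratum: keys, `n_vines`, `mean_doy`, `range_days`
#'   (NA for single-vine strata).
#' @export
stratum_summaries <- function(flowering,
                              keys = c("orchard", "year", "cultivar", "region")) {
  assert_columns(flowering, c(keys, "first_flower_doy"), "flowering")
  out <- flowering |>
    dplyr::summarise(
      n_vines = dplyr::n(),
      mean_doy = mean(.data$first_flower_doy),
      range_days = ifelse(dplyr::n() >= 2,
                          max(.data$first_flower_doy) - min(.data$first_flower_doy),
                          NA_real_),
      .by = dplyr::all_of(keys)
    )
  if (any(out$n_vines < 2)) {
    rlang::warn(paste(sum(out$n_vines < 2),
                      "single-vine stratum(-a) have no range and carry NA"))
  }
  out
}

#' Stratum flowering range (max - min first-flowering day)
#'
#' @inheritParams stratum_summaries
#' @return Tibble per stratum with `range_days`; single-vine strata are
#'   dropped with a warning.
#' @export
flowering_range <- function(flowering,
                            keys = c("orchard", "year", "cultivar", "region")) {
  out <- stratum_summaries(flowering, keys)
  dplyr::filter(dplyr::select(out, -"mean_doy"), !is.na(.data$range_days))
}

#' Two-way region-by-cultivar ANOVA on a stratum-level response
#'
#' Fits `response ~ region * cultivar` on stratum-level values (one value per
#' orchard-year-cultivar stratum) and reports Type-II F tests for region,
#' cultivar and their interaction, alongside group means with standard
#' errors. A term whose sum of squares is exactly zero reports F = 0.
#'
#' @param strata Stratum-level tibble (see [stratum_summaries()]) with
#'   `region` and `cultivar` columns.
#' @param response Column to analyse (e.g. `"mean_doy"` or `"range_days"`).
#' @return List of class `anova_result`: `table` (tibble: `term`, `sumsq`,
#'   `df`, `df_resid`, `statistic`, `p.value`) and `group_means` (tibble:
#'   `region`, `cultivar`, `mean`, `se`, `n`).
#' @export
anova_two_way <- function(strata, response = "mean_doy") {
  assert_columns(strata, c("region", "cultivar", response), "strata")
  strata <- dplyr::filter(tibble::as_tibble(strata),
                          !is.na(.data[[response]]))
  grid <- dplyr::count(strata, .data$region, .data$cultivar)
  full <- tidyr::expand_grid(region = unique(strata$region),
                             cultivar = unique(strata$cultivar))
  missing_cells <- dplyr::anti_join(full, grid, by = c("region", "cultivar"))
  if (nrow(missing_cells) > 0) {
    abort_phenocast(
      paste0("empty region x cultivar cell(s): ",
             paste(missing_cells$region, missing_cells$cultivar,
                   sep = ":", collapse = ", ")),
      "phenocast_data_error"
    )
  }
  if (any(grid$n < 2)) {
    abort_phenocast("each region x cultivar cell needs >= 2 observations",
                    "phenocast_data_error")
  }
  dat <- dplyr::mutate(strata,
                       region = factor(.data$region),
                       cultivar = factor(.data$cultivar))
  # a factor observed at a single level carries no contrast; drop it
  active <- c("region", "cultivar")[c(nlevels(dat$region) > 1,
                                      nlevels(dat$cultivar) > 1)]
  if (length(active) == 0) {
    abort_phenocast("need at least two groups in region or cultivar",
                    "phenocast_data_error")
  }
  fml <- stats::as.formula(paste(response, "~", paste(active, collapse = " * ")))
  fit <- lm(fml, data = dat)
  # car::Anova refuses an exactly-zero residual sum of squares (e.g. constant
  # responses); sequential SS coincide there, and our zero-SS guard below
  # turns the undefined F ratios into 0
  a2 <- tryCatch(car::Anova(fit, type = 2),
                 error = function(e) suppressWarnings(stats::anova(fit)))
  df_resid <- a2[["Df"]][rownames(a2) == "Residuals"]
  ss_resid <- a2[["Sum Sq"]][rownames(a2) == "Residuals"]
  terms <- setdiff(rownames(a2), "Residuals")
  ss <- a2[["Sum Sq"]][match(terms, rownames(a2))]
  # sums of squares indistinguishable from zero at the response's scale give
  # an undefined F ratio; report F = 0 (no evidence of an effect)
  ss_zero <- ss <= 1e-12 * (sum(dat[[response]]^2) + 1)
  tab <- tibble::tibble(
    term = terms,
    sumsq = ss,
    df = a2[["Df"]][match(terms, rownames(a2))],
    df_resid = df_resid,
    statistic = ifelse(ss_zero, 0, a2[["F value"]][match(terms, rownames(a2))]),
    p.value = ifelse(ss_zero, 1, a2[["Pr(>F)"]][match(terms, rownames(a2))])
  )
  means <- dat |>
    dplyr::summarise(
      mean = mean(.data[[response]]),
      se = sd(.data[[response]]) / sqrt(dplyr::n()),
      n = dplyr::n(),
      .by = c("region", "cultivar")
    )
  structure(list(table = tab, group_means = means, model = fit),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat("<anova_result>\n")
  print(x$table)
  invisible(x)
}

#' @param x An `anova_result`.
#' @param ... Unused.
#' @rdname anova_two_way
#' @method tidy anova_result
#' @export
tidy.anova_result <- function(x, ...) x$table
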