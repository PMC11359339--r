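test_that("logistic counts are won by the binomial family", {
  sv <- logistic_survey(-6, 0.02, total_buds = 40,
                        gdd = seq(50, 700, by = 40))
  fits <- fit_budbreak_curves(sv)
  expect_lt(fits$binomial$aic, fits$poisson$aic)
  expect_lt(fits$binomial$aic, fits$polynomial$aic)
  expect_equal(select_best_family(fits)$family, "binomial")
})

test_that("perfectly linear counts give a quadratic fit with r^2 = 1", {
  sv <- tibble::tibble(gdd_cum = seq(100, 500, by = 50),
                       broken_buds = seq(2, 34, by = 4),
                       total_buds = 40)
  fits <- fit_budbreak_curves(sv)
  expect_equal(fits$polynomial$r_squared, 1, tolerance = 1e-9)
})

test_that("AIC selection breaks ties toward parsimony, then binomial", {
  mk <- function(family, aic, n_params) {
    list(family = family, aic = aic, n_params = n_params)
  }
  fits <- list(binomial = mk("binomial", 6.4, 2),
               poisson = mk("poisson", 30, 2),
               polynomial = mk("polynomial", 25, 3))
  expect_equal(select_best_family(fits)$family, "binomial")
  fits$binomial$aic <- 25   # tie with polynomial: fewer parameters wins
  expect_equal(select_best_family(fits)$family, "binomial")
  fits$poisson$aic <- 25    # three-way numeric tie: binomial preferred
  expect_equal(select_best_family(fits)$family, "binomial")
  expect_error(select_best_family(list(binomial = fits$binomial)),
               class = "phenocast_data_error")
})

test_that("inversion matches the closed-form logit solution", {
  sv <- logistic_survey(-10, 0.02, total_buds = 1e6,
                        gdd = seq(0, 1000, by = 20))
  fits <- fit_budbreak_curves(sv)
  best <- select_best_family(fits)
  inv <- invert_at_5pct(best, sv)
  final_prop <- tail(sv$broken_buds, 1) / tail(sv$total_buds, 1)
  b <- coef(best$model)
  closed_form <- (qlogis(0.05 * final_prop) - b[1]) / b[2]
  expect_equal(inv$gdd_at_5pct, unname(closed_form), tolerance = 0.05)
  # against the analytic curve itself: (logit(0.05) + 10) / 0.02
  expect_equal(inv$gdd_at_5pct, (qlogis(0.05) + 10) / 0.02, tolerance = 1)
})

test_that("bisection agrees with a dense grid search and is self-consistent", {
  withr::local_seed(42)
  for (i in 1:20) {
    b0 <- runif(1, -12, -4)
    b1 <- runif(1, 0.01, 0.05)
    sv <- logistic_survey(b0, b1, total_buds = 500,
                          gdd = seq(0, 900, by = 30))
    best <- fit_budbreak_curves(sv)$binomial
    inv <- invert_at_5pct(best, sv)
    # dense-grid oracle at 0.01 degree-day resolution
    target <- inv$target
    grid <- seq(0, 1.5 * max(sv$gdd_cum), by = 0.01)
    p <- plogis(coef(best$model)[1] + coef(best$model)[2] * grid)
    oracle <- grid[which(p >= target)[1]]
    expect_equal(inv$gdd_at_5pct, oracle, tolerance = 0.02)
    # evaluating the fitted curve at the estimate recovers the target level
    p_at <- unname(plogis(coef(best$model)[1] + coef(best$model)[2] * inv$gdd_at_5pct))
    expect_equal(p_at, target, tolerance = 1e-3)
  }
})

test_that("a curve that never reaches the 5% level is flagged", {
  # fitted curve stays near zero over 1.5x the observed GDD range while the
  # vine's final observed budbreak (hence the 5% target) is high
  g <- seq(0, 400, by = 40)
  flatfit <- list(
    family = "binomial",
    model = glm(cbind(y, n - y) ~ g,
                family = binomial(),
                data = data.frame(g = g, y = round(1e6 * plogis(-14 + 0.005 * g)),
                                  n = 1e6)),
    total_buds = 40
  )
  sv <- tibble::tibble(gdd_cum = g, broken_buds = c(rep(0L, 10), 40L),
                       total_buds = 40L)
  inv <- invert_at_5pct(flatfit, sv)
  expect_true(is.na(inv$gdd_at_5pct))
  expect_equal(inv$flag, "extrapolated")
})

test_that("degenerate panels are excluded with a reason", {
  flat <- tibble::tibble(gdd_cum = c(100, 200, 300, 400),
                         broken_buds = 0L, total_buds = 40L)
  expect_error(fit_budbreak_curves(flat), class = "phenocast_degenerate_fit")

  surveys <- dplyr::bind_rows(
    dplyr::mutate(logistic_survey(-6, 0.02, 40, seq(50, 700, 50)),
                  vine_id = "good", cultivar = "Hayward",
                  region = "Te Puke", year = 2020L),
    dplyr::mutate(flat, vine_id = "flat", cultivar = "Hayward",
                  region = "Te Puke", year = 2020L)
  )
  est <- estimate_budbreak(surveys)
  expect_equal(nrow(est), 2)
  expect_equal(est$flag[est$vine_id == "flat"], "degenerate")
  expect_true(is.na(est$gdd_at_5pct[est$vine_id == "flat"]))
  expect_equal(est$family[est$vine_id == "good"], "binomial")
})

test_that("survey invariants are enforced before fitting", {
  sv <- logistic_survey(-6, 0.02, 40, seq(50, 700, 50))
  expect_error(fit_budbreak_curves(sv[1:3, ]), class = "phenocast_data_error")
  bad <- sv
  bad$broken_buds[3] <- bad$broken_buds[5]  # breaks monotonicity
  expect_error(fit_budbreak_curves(bad), class = "phenocast_data_error")
})

test_that("more buds per vine sharpen the 5%-budbreak estimate", {
  est_err <- function(buds) {
    cfg <- synthetic_config(seed = 11, years = 2020,
                            n_orchards_per_region = 1,
                            n_vines_per_orchard = 15,
                            buds_per_vine = buds)
    ds <- simulate_dataset(cfg)
    est <- estimate_budbreak(ds$surveys)
    joined <- dplyr::inner_join(est, ds$truth, by = "vine_id")
    median(abs(joined$gdd_at_5pct - joined$bb_true), na.rm = TRUE)
  }
  expect_lt(est_err(80), est_err(10))
})
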