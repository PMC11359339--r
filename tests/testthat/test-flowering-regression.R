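test_that("design expansion produces the factorial and refined term sets", {
  rec <- simulate_flowering_records(20, seed = 1)
  d2 <- build_design(rec, "CV.BB")
  expect_setequal(d2$terms, c("(Intercept)", "CV", "BB", "CV:BB"))
  d3 <- build_design(rec, "CV.BB.DD")
  expect_length(d3$terms, 8)
  expect_true("CV:BB:DD" %in% d3$terms)
  dref <- build_design(rec, "CV.BB.DD", interactions = "refined",
                       terms = c("CV", "BB", "DD", "CV:BB", "BB:DD"))
  expect_setequal(dref$terms,
                  c("(Intercept)", "CV", "BB", "DD", "CV:BB", "BB:DD"))
  expect_error(build_design(rec[, c("CV", "first_flower_doy")], "CV.BB"),
               class = "phenocast_schema_error")
})

test_that("a noiseless linear response is interpolated exactly", {
  rec <- simulate_flowering_records(100, residual_sd = 1e-9, seed = 2)
  fit <- suppressWarnings(fit_flowering_model(rec, "CV.BB.DD"))
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_lt(fit$rmse, 1e-6)
})

test_that("OLS coefficients solve the normal equations on a hand dataset", {
  rec <- tibble::tibble(
    CV = c(0, 1, 0, 1, 1),
    BB = c(1.0, 2.0, 1.5, 2.5, 3.0),
    first_flower_doy = c(310, 332, 315, 334, 340)
  )
  fit <- fit_flowering_model(rec, build_design(rec, "CV.BB",
                                               interactions = "refined",
                                               terms = c("CV", "BB")))
  X <- cbind(1, rec$CV, rec$BB)
  beta <- solve(t(X) %*% X, t(X) %*% rec$first_flower_doy)
  expect_equal(unname(coef(fit$model)), as.numeric(beta), tolerance = 1e-10)
})

test_that("rank deficiency is reported with the offending term", {
  rec <- simulate_flowering_records(50, seed = 3)
  rec$DD <- rec$BB  # perfectly collinear
  expect_error(fit_flowering_model(rec, build_design(rec, "CV.BB.DD",
                                                     interactions = "refined",
                                                     terms = c("CV", "BB", "DD"))),
               regexp = "DD", class = "phenocast_fit_error")
})

test_that("generating coefficients are recovered within their standard errors", {
  truth <- reference_flowering_coefficients("full")
  term_map <- c("(Intercept)" = "intercept", CV = "cv", BB = "bb", DD = "dd",
                "CV:BB" = "cv_bb", "BB:DD" = "bb_dd")
  hits <- 0; total <- 0
  for (s in 1:20) {
    rec <- simulate_flowering_records(500, residual_sd = 4, seed = 100 + s)
    fit <- fit_flowering_model(rec, build_design(
      rec, "CV.BB.DD", interactions = "refined",
      terms = c("CV", "BB", "DD", "CV:BB", "BB:DD")))
    tt <- tidy(fit)
    for (i in seq_len(nrow(tt))) {
      expected <- truth[[term_map[[tt$term[i]]]]]
      hits <- hits + (abs(tt$estimate[i] - expected) <= 3 * tt$std.error[i])
      total <- total + 1
    }
  }
  expect_gte(hits / total, 0.95)
})

test_that("stepwise refinement drops an absent three-way interaction", {
  # AIC keeps a null term whenever its deviance contribution exceeds 2, which
  # happens with probability P(chi2_1 > 2) ~ 0.157; so the drop rate should
  # sit near 84%, and well above chance
  dropped <- 0
  worse <- 0
  for (s in 1:50) {
    rec <- simulate_flowering_records(200, residual_sd = 4, seed = 200 + s)
    full <- fit_flowering_model(rec, "CV.BB.DD")
    refined <- stepwise_refine(full)
    dropped <- dropped + !("CV:BB:DD" %in% refined$design$terms)
    worse <- worse + (refined$aic > full$aic + 1e-8)
  }
  expect_gte(dropped, 37)  # ~84% expected; binomial(50, 0.843) > 37 w.p. ~0.98
  expect_equal(worse, 0)   # AIC never increases
})

test_that("an already-minimal model is a stepwise fixed point", {
  withr::local_seed(7)
  rec <- tibble::tibble(CV = rep(0:1, 50), BB = rnorm(100, 2, 0.5))
  rec$first_flower_doy <- 300 + 20 * rec$CV + 8 * rec$BB + rnorm(100, 0, 0.5)
  fit <- fit_flowering_model(rec, build_design(rec, "CV.BB",
                                               interactions = "refined",
                                               terms = c("CV", "BB")))
  refined <- stepwise_refine(fit)
  expect_setequal(refined$design$terms, fit$design$terms)
  expect_equal(refined$aic, fit$aic)
})

test_that("prediction intervals carry the 2.576 normal critical value", {
  expect_equal(interval_critical_value(0.99), 2.576)
  expect_error(interval_critical_value(1.2), class = "phenocast_config_error")

  rec <- simulate_flowering_records(400, residual_sd = 4, seed = 5)
  fit <- fit_flowering_model(rec, "CV.BB.DD")
  new <- simulate_flowering_records(50, residual_sd = 4, seed = 6)
  pred <- predict_with_interval(fit, new)
  expect_true(all(pred$lower < pred$predicted_doy &
                    pred$predicted_doy < pred$upper))
  expect_equal(pred$interval_width, pred$upper - pred$lower)
  # width floor: 2 * z * sigma-hat when the mean is precisely estimated
  expect_true(all(pred$interval_width >= 2 * 2.576 * fit$sigma - 1e-9))
})

test_that("a degenerate noise-free fit has zero-width intervals", {
  rec <- simulate_flowering_records(100, residual_sd = 0, seed = 8)
  fit <- suppressWarnings(fit_flowering_model(rec, build_design(rec, "CV.BB.DD",
                                               interactions = "refined",
                                               terms = c("CV", "BB", "DD",
                                                         "CV:BB", "BB:DD"))))
  pred <- predict_with_interval(fit, rec[1:10, ])
  expect_lt(max(pred$interval_width), 1e-6)
})

test_that("the reference model evaluates to its intercept at zero covariates", {
  zero <- tibble::tibble(CV = 0, BB = 0, DD = 0)
  expect_equal(predict_reference_flowering(zero, "full")$predicted_doy, 312.7)
  expect_equal(predict_reference_flowering(zero, "single_orchard")$predicted_doy,
               471.2)
})

test_that("OLS with intercept predicts the mean response at mean covariates", {
  # exact identity for a main-effects design (interaction columns would need
  # their own column means, not products of means)
  rec <- simulate_flowering_records(300, residual_sd = 4, seed = 9)
  fit <- fit_flowering_model(rec, build_design(rec, "CV.BB.DD",
                                               interactions = "refined",
                                               terms = c("CV", "BB", "DD")))
  at_mean <- predict(fit$model, newdata = tibble::tibble(
    CV = mean(rec$CV), BB = mean(rec$BB), DD = mean(rec$DD)))
  expect_equal(unname(at_mean), mean(rec$first_flower_doy), tolerance = 1e-8)
})

test_that("99% intervals cover about 99% of correctly specified test data", {
  train <- simulate_flowering_records(500, residual_sd = 4, seed = 10)
  test <- simulate_flowering_records(1000, residual_sd = 4, seed = 11)
  fit <- fit_flowering_model(train, "CV.BB.DD")
  cov <- coverage_percent(predict_with_interval(fit, test))
  expect_gte(cov, 96)
  expect_lte(cov, 100)
})

test_that("k-fold cross-validation uses 80% training folds and recovers sigma", {
  rec <- simulate_flowering_records(100, residual_sd = 1e-9, seed = 12)
  cv0 <- suppressWarnings(kfold_cv(rec, "CV.BB.DD", k = 5, seed = 1))
  folds <- attr(cv0, "folds")
  expect_equal(folds$n_train, rep(80, 5))
  expect_lt(cv0$rmse_mean, 1e-6)

  rec <- simulate_flowering_records(1000, residual_sd = 4, seed = 13)
  cv <- kfold_cv(rec, "CV.BB.DD", k = 5, seed = 1)
  expect_equal(cv$rmse_mean, 4, tolerance = 0.1)
  expect_true(cv$rmse_min <= cv$rmse_mean && cv$rmse_mean <= cv$rmse_max)
  expect_error(kfold_cv(rec[1:3, ], "CV.BB.DD", k = 5), class = "phenocast_config_error")
})

test_that("the year split selects the generating candidate and refines it", {
  rec <- simulate_flowering_records(600, residual_sd = 4, seed = 14)
  rec$year <- rep(2015:2020, each = 100)
  rec$cultivar <- ifelse(rec$CV == 1, "Hayward", "Zesy002")
  ys <- evaluate_year_split(rec, 2015:2018, 2019:2020)
  expect_equal(ys$best_label, "CV.BB.DD")
  expect_equal(nrow(ys$comparison), 10)
  full_aic <- ys$comparison$aic[ys$comparison$model == "CV.BB.DD"]
  refined_aic <- ys$comparison$aic[ys$comparison$model == "CV.BB.DD_1"]
  expect_lte(refined_aic, full_aic + 1e-8)
  expect_true(all(ys$comparison$coverage_pct >= 0 &
                    ys$comparison$coverage_pct <= 100))
  expect_error(evaluate_year_split(rec, 2015:2019, 2019:2020),
               class = "phenocast_config_error")
})

test_that("test-only cultivars are excluded with a warning", {
  rec <- simulate_flowering_records(200, residual_sd = 4, seed = 15)
  rec$year <- rep(c(2018, 2019), each = 100)
  rec$cultivar <- ifelse(rec$CV == 1, "Hayward", "Zesy002")
  rec$cultivar[rec$year == 2019][1:5] <- "Zes003"
  expect_warning(
    ys <- evaluate_year_split(rec, 2018, 2019,
                              candidates = candidate_specs()[3, ]),
    regexp = "Zes003"
  )
  expect_equal(nrow(ys$final_predictions), 95)
})
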