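test_that("weather series covers every hour of the year and is seed-reproducible", {
  cfg <- tiny_config()
  w_leap <- simulate_weather(cfg, "Kerikeri", 2020)
  w_common <- simulate_weather(cfg, "Kerikeri", 2019)
  expect_equal(nrow(w_leap), 8784)
  expect_equal(nrow(w_common), 8760)
  expect_false(any(duplicated(w_leap$timestamp)))

  again <- simulate_weather(cfg, "Kerikeri", 2020)
  expect_identical(w_leap, again)
  other_seed <- simulate_weather(tiny_config(seed = 2), "Kerikeri", 2020)
  expect_false(identical(w_leap$temp_c, other_seed$temp_c))

  expect_error(simulate_weather(cfg, "Gisborne", 2020), class = "phenocast_config_error")
})

test_that("zero noise reduces the series to the annual + diurnal sinusoids", {
  cfg <- tiny_config(noise_sd = 0)
  w <- simulate_weather(cfg, "Te Puke", 2019)
  pars <- cfg$region_params[cfg$region_params$region == "Te Puke", ]
  d <- lubridate::yday(w$timestamp) + lubridate::hour(w$timestamp) / 24
  h <- lubridate::hour(w$timestamp)
  expected <- pars$mean_temp - pars$amplitude * cos(2 * pi * (d - 196) / 365.25) +
    cfg$diurnal_amplitude * cos(2 * pi * (h - 14) / 24)
  expect_equal(w$temp_c, expected, tolerance = 1e-12)
  # coldest day lands mid-July, warmest around mid-January
  daily <- tapply(w$temp_c, as.Date(w$timestamp, tz = "UTC"), mean)
  expect_equal(lubridate::month(as.Date(names(daily)[which.min(daily)])), 7)
})

test_that("Te Puke accumulates more winter chilling than Kerikeri", {
  cu <- sapply(1:10, function(s) {
    cfg <- tiny_config(seed = s)
    k <- simulate_weather(cfg, "Kerikeri", 2020)
    t <- simulate_weather(cfg, "Te Puke", 2020)
    c(naive_cu(k, "2020-08-31"), naive_cu(t, "2020-08-31"))
  })
  expect_gt(mean(cu[2, ]), mean(cu[1, ]))
})

test_that("vine surveys are monotone, bounded, and on the requested date grid", {
  cfg <- tiny_config(survey_interval_days = 3)
  w <- simulate_weather(cfg, "Kerikeri", 2020)
  sim <- simulate_vine_phenology(cfg, w, "Hayward", vine_id = "v1")
  sv <- sim$survey
  expect_true(all(diff(sv$broken_buds) >= 0))
  expect_true(all(sv$broken_buds <= sv$total_buds))
  expect_true(all(diff(as.integer(sv$survey_date)) == 3))
  expect_equal(sv$survey_date[1], as.Date("2020-07-01"))
  expect_true(sim$flowering_doy >= 244 && sim$flowering_doy <= 366)
})

test_that("an effectively infinite logistic slope gives a step at the threshold", {
  cfg <- tiny_config(bb_threshold_sd = 0,
                     cultivar_params = tibble::tibble(
                       cultivar = c("Zesy002", "Hayward"),
                       threshold = c(240, 320), slope = c(1e6, 1e6)))
  w <- simulate_weather(cfg, "Kerikeri", 2020)
  sim <- simulate_vine_phenology(cfg, w, "Zesy002", vine_id = "v1")
  sv <- sim$survey
  expect_setequal(unique(sv$broken_buds), c(0, cfg$buds_per_vine))
  # the jump happens at the first survey whose GDD is at or past the midpoint
  first_full <- min(which(sv$broken_buds == cfg$buds_per_vine))
  expect_gte(sv$gdd_cum[first_full], 240)
  expect_lt(sv$gdd_cum[first_full - 1], 240)
  # and the true 5% GDD collapses onto the threshold
  expect_equal(sim$truth$bb_true, 240, tolerance = 1e-3)
})

test_that("zero residual sd makes the flowering day the rounded linear predictor", {
  cfg <- tiny_config(residual_sd = 1e-12)
  w <- simulate_weather(cfg, "Te Puke", 2020)
  sim <- simulate_vine_phenology(cfg, w, "Hayward", vine_id = "v9")
  expect_equal(sim$flowering_doy, round(sim$truth$linear_predictor))
})

test_that("a budbreak threshold outside the season's GDD range is rejected", {
  cfg <- tiny_config(bb_threshold_sd = 0,
                     cultivar_params = tibble::tibble(
                       cultivar = c("Zesy002", "Hayward"),
                       threshold = c(240, 99999), slope = c(0.05, 0.05)))
  w <- simulate_weather(cfg, "Kerikeri", 2020)
  expect_error(simulate_vine_phenology(cfg, w, "Hayward", vine_id = "vX"),
               regexp = "vX", class = "phenocast_generation_error")
})

test_that("the full dataset is reproducible and respects its invariants", {
  cfg <- tiny_config(seed = 5)
  ds1 <- simulate_dataset(cfg)
  ds2 <- simulate_dataset(cfg)
  expect_identical(ds1$surveys, ds2$surveys)
  expect_identical(ds1$flowering, ds2$flowering)
  expect_identical(ds1$weather, ds2$weather)

  expect_true(all(ds1$flowering$first_flower_doy >= 244 &
                    ds1$flowering$first_flower_doy <= 366))
  mono <- ds1$surveys |>
    dplyr::summarise(ok = !is.unsorted(broken_buds), .by = vine_id)
  expect_true(all(mono$ok))

  # Hayward flowers later than Zesy002 by design
  offs <- ds1$flowering |>
    dplyr::summarise(m = mean(first_flower_doy), .by = cultivar)
  expect_gt(offs$m[offs$cultivar == "Hayward"],
            offs$m[offs$cultivar == "Zesy002"] + 10)
})

test_that("configuration invariants are enforced", {
  expect_error(tiny_config(survey_interval_days = 5), class = "phenocast_config_error")
  expect_error(tiny_config(residual_sd = -1), class = "phenocast_config_error")
  expect_error(tiny_config(n_vines_per_orchard = 0), class = "phenocast_config_error")
  bad_regions <- default_region_params()
  bad_regions$region <- c("Kerikeri", "Motueka")
  expect_error(tiny_config(region_params = bad_regions),
               class = "phenocast_config_error")
})
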