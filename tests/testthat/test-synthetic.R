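test_that("generated weather satisfies physical constraints across seeds", {
  for (s in c(1, 17, 4242)) {
    w <- generate_daily_weather(weather_gen_params(seed = s),
                                "2008-03-01", 900)
    expect_true(all(w$TM < w$TX))
    expect_true(all(w$P >= 0))
    expect_true(all(w$RH >= 0 & w$RH <= 100))
    expect_true(all(w$SR > 0))
    expect_equal(nrow(w), 900)
  }
})

test_that("weather generation is bit-identical given the same seed", {
  p <- weather_gen_params(seed = 99)
  expect_identical(generate_daily_weather(p, "2007-01-01", 500),
                   generate_daily_weather(p, "2007-01-01", 500))
  p2 <- weather_gen_params(seed = 100)
  expect_false(identical(generate_daily_weather(p, "2007-01-01", 500)$TX,
                         generate_daily_weather(p2, "2007-01-01", 500)$TX))
})

test_that("noise-free degenerate weather collapses to the harmonic", {
  p <- weather_gen_params(noise_sd = list(tx = 0, dr = 0, rh = 0, sr = 0),
                          ar1_coef = 0, precip_wet_prob = 0, seed = 1)
  w <- generate_daily_weather(p, "2007-01-01", 730)
  doy <- as.integer(format(w$date, "%j"))
  expect_equal(w$TX, tx_seasonal_mean(p, doy), tolerance = 1e-12)
  expect_true(all(w$P == 0))
  expect_equal(w$TX - w$TM,
               pmax(p$dr_min, p$dr_mean + p$dr_seasonal_amp *
                      cos(2 * pi * (doy - p$tx_seasonal_phase) / 365.25)),
               tolerance = 1e-12)
})

test_that("long-run TX mean and anomaly autocorrelation match the generator", {
  p <- weather_gen_params(seed = 7)
  w <- generate_daily_weather(p, "2005-01-01", 3650)
  expect_lt(abs(mean(w$TX) - p$tx_mean), 0.5)
  anom <- w$TX - tx_seasonal_mean(p, as.integer(format(w$date, "%j")))
  r1 <- cor(anom[-1], anom[-length(anom)])
  expect_lt(abs(r1 - p$ar1_coef), 0.05)
})

test_that("generator parameters are validated", {
  expect_error(weather_gen_params(ar1_coef = 1), "ar1_coef")
  expect_error(weather_gen_params(tx_mean = NaN), "non-finite")
  expect_error(weather_gen_params(precip_wet_prob = 1.3), "probability")
  expect_error(generate_daily_weather(weather_gen_params(), n_days = 0),
               "n_days")
})

test_that("cropping events respect the window, cycle bounds and cultivars", {
  w <- tiny_weather(1500, seed = 3)
  ev <- generate_cropping_events(w, 500, seed = 21)
  expect_equal(nrow(ev), 500)
  expect_true(all(ev$harvest_date <= max(w$date)))
  expect_true(all(ev$sowing_date >= min(w$date)))
  cyc <- as.integer(ev$harvest_date - ev$sowing_date)
  expect_true(all(cyc >= 100 & cyc <= 160))
  ## zero-sd cycle pins harvest at sowing + mean
  ev1 <- generate_cropping_events(w, 1, cycle_days_mean = 126,
                                  cycle_days_sd = 0, seed = 5)
  expect_equal(as.integer(ev1$harvest_date - ev1$sowing_date), 126)
  ## window overflow rejected
  expect_error(generate_cropping_events(w, 5,
                                        sowing_window = c(max(w$date) - 10,
                                                          max(w$date))),
               "coverage")
})

test_that("cultivar sampling follows the requested probabilities", {
  w <- tiny_weather(1500, seed = 3)
  prof <- cultivar_profiles()[1:2, ]
  ev <- generate_cropping_events(w, 2000, cultivars = prof,
                                 cultivar_probs = c(0.7, 0.3), seed = 31)
  prop <- mean(ev$cultivar == prof$cultivar[1])
  expect_lt(abs(prop - 0.7), 0.03)
})

test_that("ground-truth yield arithmetic is exact", {
  row <- data.frame(Cultivar = "F60", TM_Avg_REP = 22.7, SR_Accu_RIP = 0)
  resp <- ground_truth_response(base_yield = 6000,
                                cultivar_effects = c(F60 = 0),
                                driver_terms = list(
                                  list(indicator = "TM_Avg_REP",
                                       form = "hinge", coef = -300,
                                       breakpoint = 22.7)),
                                noise_sd = 0)
  expect_equal(ground_truth_yield(row, resp), 6000)
  row$TM_Avg_REP <- 24.7
  expect_equal(ground_truth_yield(row, resp), 6000 - 600)
  ## below the breakpoint the hinge contributes nothing
  row$TM_Avg_REP <- 20
  expect_equal(ground_truth_yield(row, resp), 6000)
  expect_error(ground_truth_response(driver_terms = list(
    list(indicator = "NOT_AN_INDICATOR", form = "linear", coef = 1))),
    "unknown indicator")
})

test_that("noise-free yields are an exact function of the indicators", {
  sim <- simulate_indicator_dataset(n_events = 120, target_r2 = NULL,
                                    response = ground_truth_response(noise_sd = 0),
                                    n_days = 900, seed = 13)
  recomputed <- pmax(sim$response$yield_floor,
                     ground_truth_signal(sim$indicators, sim$response))
  expect_identical(sim$indicators$Yield, recomputed)
})

test_that("noise calibration hits the requested population R-squared", {
  sim <- simulate_indicator_dataset(n_events = 400, target_r2 = 0.35,
                                    n_days = 1000, seed = 29)
  r2 <- cor(sim$signal, sim$indicators$Yield)^2
  expect_lt(abs(r2 - 0.35), 0.08)
})

test_that("missingness injection is MCAR at the requested rate", {
  w <- tiny_weather(3650, seed = 2)
  g0 <- inject_missingness(w, 0, seed = 1)
  expect_identical(g0$series, w)
  g <- inject_missingness(w, 0.1, seed = 4)
  for (v in c("TX", "TM", "P", "RH", "SR")) {
    expect_lt(abs(mean(g$mask[[v]]) - 0.1), 0.02)
    ## observed cells untouched; masked truth + observed = original
    expect_identical(g$series[[v]][!g$mask[[v]]], w[[v]][!g$mask[[v]]])
    expect_true(all(is.na(g$series[[v]][g$mask[[v]]])))
    merged <- ifelse(g$mask[[v]], g$truth[[v]], g$series[[v]])
    expect_identical(merged, w[[v]])
  }
  expect_error(inject_missingness(w, 1), "rates")
})

test_that("regime mixtures tag events with their generating regime", {
  mix <- generate_regime_mixture(k = 2, events_per_regime = c(7, 11),
                                 seed = 5)
  expect_equal(as.integer(table(mix$events$regime)), c(7, 11))
  expect_length(mix$bundles, 18)
  one <- generate_regime_mixture(k = 1, events_per_regime = 5, seed = 6)
  expect_true(all(one$events$regime == 1))
  p <- weather_gen_params(seed = 1)
  expect_warning(generate_regime_mixture(k = 2, params_list = list(p, p),
                                         events_per_regime = 3, seed = 7),
                 "identical")
})
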