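test_that("raw harvest records are standardized, de-duplicated and screened", {
  raw <- data.frame(
    locality = c("Saldana", "saldaña", "Saldana", "Saldana", "Saldana"),
    cultivar = c("f-733", "F733", "F 733", "F60", "F60"),
    sowing_date = c(NA, NA, NA, "2013-06-01", "2013-09-01"),
    harvest_date = c("2013-06-30", "2013-06-30", "2013-07-15",
                     "2013-10-01", "2013-08-01"),
    rend = c(6000, 6000, 5500, -10, 4500))
  out <- standardize_records(raw, column_map = c(yield = "rend"),
                             cultivar_aliases = c("f-733" = "F733"),
                             locality_aliases = c("saldaña" = "SALDANA"))
  ## alias + normalization makes rows 1 and 2 duplicates -> one survivor
  expect_equal(nrow(out$records), 2)
  expect_true(all(out$records$cultivar %in% c("F733")))
  reasons <- out$removed$reason
  expect_true(any(grepl("duplicate", reasons)))
  expect_true(any(grepl("non-positive", reasons)))
  expect_true(any(grepl("sowing on or after harvest", reasons)))
  expect_error(standardize_records(raw[, -5]), "mandatory")
})

test_that("sowing dates are estimated by locality cycle length", {
  rec <- data.frame(locality = c("Saldana", "Villavicencio", "Saldana"),
                    sowing_date = as.Date(c(NA, NA, "2013-01-15")),
                    harvest_date = as.Date(c("2013-06-30", "2014-05-08",
                                             "2013-05-20")))
  est <- estimate_sowing_date(rec)
  expect_equal(est$sowing_date[1], as.Date("2013-02-24"))   # -126 days
  expect_equal(est$sowing_date[2], as.Date("2013-12-31"))   # -128 days
  expect_equal(est$sowing_date[3], as.Date("2013-01-15"))   # unchanged
  expect_equal(est$sowing_estimated, c(TRUE, TRUE, FALSE))
  rec$locality <- "Elsewhere"
  rec$sowing_date <- as.Date(NA)
  expect_error(estimate_sowing_date(rec), "no cycle length")
  est2 <- estimate_sowing_date(rec, default_cycle = 120)
  expect_equal(est2$sowing_date, rec$harvest_date - 120)
})

test_that("growth-stage splitting scales profiles with largest remainder", {
  prof <- data.frame(cultivar = "X", veg_days = 55, rep_days = 36,
                     rip_days = 35, reference_cycle = 126)
  s0 <- split_growth_stages("2013-01-01", as.Date("2013-01-01") + 126, prof)
  expect_equal(unname(s0$lengths), c(55, 36, 35))
  s1 <- split_growth_stages("2013-01-01", as.Date("2013-01-01") + 140, prof)
  ## raw scaled durations (61.11, 40.00, 38.89) -> (61, 40, 39)
  expect_equal(unname(s1$lengths), c(61, 40, 39))
  expect_equal(s1$panicle_initiation, as.Date("2013-01-01") + 61)
  expect_equal(s1$heading, as.Date("2013-01-01") + 101)
  expect_error(split_growth_stages("2013-01-01", "2013-02-01", prof),
               "implausible")
})

test_that("stage lengths sum to the cycle over cycles 100-160 and profiles", {
  profs <- rbind(cultivar_profiles(),
                 data.frame(cultivar = c("A", "B"),
                            veg_days = c(40, 70), rep_days = c(50, 26),
                            rip_days = c(36, 30), reference_cycle = 126))
  sow <- as.Date("2012-02-01")
  for (i in seq_len(nrow(profs))) {
    for (cyc in 100:160) {
      s <- split_growth_stages(sow, sow + cyc, profs[i, ])
      expect_identical(sum(s$lengths), as.integer(cyc))
      expect_true(s$panicle_initiation > sow && s$heading < sow + cyc)
    }
  }
})

test_that("weather windows are inclusive slices and gaps exclude events", {
  w <- tiny_weather(700, seed = 9)
  ev <- generate_cropping_events(w, 3, cycle_days_mean = 126,
                                 cycle_days_sd = 0, seed = 10)
  e <- attach_weather_window(ev[1, ], w)
  expect_s3_class(e, "cropping_event")
  expect_equal(nrow(e$window), 127)
  dates <- seq(e$sowing_date, e$harvest_date, by = "day")
  expect_equal(e$window$date, dates)
  expect_equal(e$window$TX, w$TX[match(dates, w$date)])
  wg <- w
  wg$TX[w$date == ev$sowing_date[2] + 30] <- NA
  expect_error(attach_weather_window(ev[2, ], wg), "not completely covered")
  expect_error(attach_weather_window(ev[3, ], w[1:10, ]),
               "not completely covered")
})

test_that("stage indicators match their stated definitions on fixtures", {
  w <- tiny_weather(700, seed = 12)
  ev <- generate_cropping_events(w, 1, cycle_days_mean = 126,
                                 cycle_days_sd = 0, seed = 3)
  e <- attach_weather_window(ev[1, ], w)
  idx <- w$date >= e$sowing_date & w$date < e$stages$panicle_initiation
  ## hand-planted exceedances in the vegetative window
  e$window$TX[1:4] <- c(30, 36, 34, 38)
  e$window$TX[5:sum(idx)] <- 30
  row <- compute_stage_indicators(e)
  expect_equal(row$TX_35_Freq_VEG, 2 / sum(idx))
  ## constant precipitation in the reproductive stage
  rep_idx <- e$window$date >= e$stages$panicle_initiation &
    e$window$date < e$stages$heading
  e$window$P[rep_idx] <- 5
  row <- compute_stage_indicators(e)
  expect_equal(row$P_Accu_REP, 5 * sum(rep_idx))
  expect_equal(row$P_10_Freq_REP, 0)
})

test_that("vectorized indicators equal the brute-force daily loop", {
  w <- tiny_weather(1200, seed = 14)
  ev <- generate_cropping_events(w, 100, seed = 15)
  for (j in seq_len(nrow(ev))) {
    e <- attach_weather_window(ev[j, ], w)
    row <- compute_stage_indicators(e)
    oracle <- indicators_by_loop(e)
    expect_equal(unlist(row[indicator_names()]), oracle, tolerance = 1e-12)
  }
})

test_that("indicator invariants hold on generated tables", {
  sim <- simulate_indicator_dataset(n_events = 150, n_days = 900, seed = 18)
  tab <- sim$indicators
  expect_identical(setdiff(names(tab), c("event_id", "Cultivar", "Yield")),
                   indicator_names())
  for (s in c("VEG", "REP", "RIP")) {
    expect_true(all(tab[[paste0("TM_Avg_", s)]] <=
                      tab[[paste0("TA_Avg_", s)]]))
    expect_true(all(tab[[paste0("TA_Avg_", s)]] <=
                      tab[[paste0("TX_Avg_", s)]]))
    expect_true(all(tab[[paste0("DR_Avg_", s)]] >= 0))
    expect_true(all(tab[[paste0("P_Accu_", s)]] >= 0))
    expect_true(all(tab[[paste0("SR_Accu_", s)]] >= 0))
  }
  freqs <- tab[grep("_Freq_", names(tab))]
  expect_true(all(freqs >= 0 & freqs <= 1))
})

test_that("indicators are invariant to weather-window row order", {
  w <- tiny_weather(700, seed = 19)
  ev <- generate_cropping_events(w, 1, seed = 20)
  e <- attach_weather_window(ev[1, ], w)
  ref <- compute_stage_indicators(e)
  set.seed(1)
  e$window <- e$window[sample(nrow(e$window)), ]
  expect_equal(compute_stage_indicators(e), ref, ignore_attr = TRUE)
})

test_that("table cleaning drops degenerate columns and fenced rows", {
  sim <- simulate_indicator_dataset(n_events = 200, n_days = 1000, seed = 23)
  tab <- sim$indicators
  cl0 <- clean_indicator_table(tab)
  expect_equal(nrow(cl0$removed_rows), 0)
  ## plant a constant column and a wild yield
  tab2 <- tab
  tab2$RH_Avg_VEG <- 80
  tab2$Yield[7] <- 10 * quantile(tab$Yield, 0.99)
  cl <- clean_indicator_table(tab2)
  expect_true("RH_Avg_VEG" %in% cl$removed_columns$column)
  expect_false("RH_Avg_VEG" %in% names(cl$table))
  expect_true(tab2$event_id[7] %in% cl$removed_rows$event_id)
  expect_error(clean_indicator_table(tab2[0, ]))
})
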