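stations <- data.frame(
  station_id = c("at_crop", "near", "far", "high"),
  latitude_deg = c(3.90, 3.95, 4.00, 3.90),
  longitude_deg = c(-75.00, -75.00, -75.00, -75.01),
  altitude_m = c(320, 340, 330, 420))

test_that("station screening applies the <10 km and +/-50 m rules", {
  sel <- select_stations(stations, 3.90, -75.00, 320)
  expect_equal(sel$station_id[1], "at_crop")
  expect_lt(sel$dist_km[1], 1e-6)
  ## 4.00 deg lat is ~11 km away -> excluded at the default threshold
  expect_false("far" %in% sel$station_id)
  expect_false("high" %in% sel$station_id)       # 100 m altitude offset
  expect_true("near" %in% sel$station_id)        # ~5.6 km
  expect_error(select_stations(stations, 10, -75, 320), "no eligible")
})

test_that("great-circle distances agree with a hand haversine", {
  d_pkg <- select_stations(stations, 3.90, -75.00, 340,
                           max_dist_km = 1000, alt_tol_m = 1000)
  d_hand <- haversine_km(stations$latitude_deg, stations$longitude_deg,
                         3.90, -75.00)
  expect_equal(sort(d_pkg$dist_km), sort(d_hand), tolerance = 0.1 / 5)
})

make_hourly <- function(n_days, seed = 1) {
  set.seed(seed)
  time <- seq(as.POSIXct("2012-01-01 00:00", tz = "UTC"),
              by = "hour", length.out = n_days * 24)
  df <- data.frame(time = time,
                   temp = 25 + 5 * sin(2 * pi * (0:(n_days * 24 - 1)) / 24) +
                     rnorm(n_days * 24),
                   P = rgamma(n_days * 24, 0.1, scale = 4),
                   RH = pmin(100, pmax(0, rnorm(n_days * 24, 80, 8))),
                   SR = pmax(0, rnorm(n_days * 24, 20, 8)))
  ## knock out random hours so completeness varies by day
  for (v in c("temp", "P", "RH", "SR"))
    df[[v]][runif(nrow(df)) < 0.15] <- NA
  df
}

test_that("hourly aggregation follows the strict >80% completeness rule", {
  time <- seq(as.POSIXct("2012-01-01 00:00", tz = "UTC"), by = "hour",
              length.out = 24)
  h <- data.frame(time = time, temp = c(20:27, rep(25, 16)))
  agg <- aggregate_hourly_to_daily(h)
  expect_equal(agg$TX, 27)
  expect_equal(agg$TM, 20)
  ## 19 of 24 valid hours (79%) -> missing; 20 (83%) -> present
  h19 <- h; h19$temp[1:5] <- NA
  expect_true(is.na(aggregate_hourly_to_daily(h19)$TX))
  h20 <- h; h20$temp[1:4] <- NA
  expect_false(is.na(aggregate_hourly_to_daily(h20)$TX))
  hd <- rbind(h, h[1, ])
  expect_error(aggregate_hourly_to_daily(hd), "duplicate")
})

test_that("hourly aggregation matches a per-day brute-force loop", {
  h <- make_hourly(30, seed = 77)
  fast <- aggregate_hourly_to_daily(h)
  slow <- hourly_daily_by_loop(h)
  expect_equal(fast$date, slow$date)
  for (v in c("TX", "TM", "P", "RH", "SR"))
    expect_equal(fast[[v]], slow[[v]], tolerance = 1e-12)
})

test_that("daily QC flags range, consistency and flatline violations", {
  w <- tiny_weather(200, seed = 15)
  w$TX[5] <- 50                      # out of range
  w$TM[9] <- w$TX[9] + 5             # internal inconsistency
  w$RH[20:26] <- 77.7                # 7-day flatline
  qc <- qc_daily(w)
  expect_true(is.na(qc$series$TX[5]))
  expect_true(is.na(qc$series$TX[9]) && is.na(qc$series$TM[9]))
  expect_true(all(is.na(qc$series$RH[20:26])))
  expect_equal(qc$report["TX", "range"], 1)
  expect_equal(qc$report["TM", "consistency"], 1)
  expect_equal(qc$report["RH", "flatline"], 7)
  ## a clean generated series carries no flags
  qc0 <- qc_daily(tiny_weather(300, seed = 16))
  expect_equal(sum(qc0$report$set_missing), 0)
})

test_that("extraterrestrial radiation matches FAO-56 anchors", {
  ## equinox at the equator: declination ~ 0, closed form (24*60/pi)*Gsc*dr
  doy_eq <- 81
  dr <- 1 + 0.033 * cos(2 * pi * doy_eq / 365)
  closed <- 24 * 60 / pi * 0.0820 * dr
  expect_equal(extraterrestrial_radiation(0, doy_eq, unit = "MJ"), closed,
               tolerance = 0.01)
  ## published worked example: 20 S, 3 September -> 32.2 MJ m-2 day-1
  expect_equal(extraterrestrial_radiation(-20, 246, unit = "MJ"), 32.2,
               tolerance = 0.2)
  ## hemispheric symmetry half a year apart (days chosen where the
  ## Earth-Sun distance factor is near its annual mean, so the geometric
  ## symmetry is not masked by orbital eccentricity)
  for (lat in c(10, 35, 55)) {
    a <- extraterrestrial_radiation(lat, 100)
    b <- extraterrestrial_radiation(-lat, 100 + 182)
    expect_lt(abs(a - b) / a, 0.02)
  }
  expect_error(extraterrestrial_radiation(70, 100), "polar")
  expect_error(extraterrestrial_radiation(0, 400), "day_of_year")
})

test_that("Angstrom-Prescott limits and monotonicity hold", {
  lat <- 4.2; doy <- 150
  ra <- extraterrestrial_radiation(lat, doy)
  N <- daylength(lat, doy)
  expect_equal(solar_from_sunshine(0, lat, doy), 0.25 * ra)
  expect_equal(solar_from_sunshine(N, lat, doy), 0.75 * ra)
  expect_equal(solar_from_sunshine(N / 2, lat, doy), (0.25 + 0.25) * ra)
  sr <- solar_from_sunshine(seq(0, N, length.out = 25), lat, doy)
  expect_true(all(diff(sr) > 0))
  expect_warning(out <- solar_from_sunshine(N + 2, lat, doy), "clipped")
  expect_equal(out, 0.75 * ra)
})

test_that("station merge is primary-first with full coverage union", {
  w <- tiny_weather(120, seed = 33)
  primary <- w[1:80, ]
  secondary <- w[60:120, ]
  secondary$TX <- secondary$TX + 0.5   # small disagreement, within tolerance
  m <- merge_station_series(primary, secondary)
  expect_equal(m$date, w$date)
  expect_equal(m$TX[1:80], primary$TX)                 # primary wins overlap
  expect_equal(m$TX[81:120], secondary$TX[22:61])
  expect_true(!anyNA(m$TX))
  prov <- attr(m, "provenance")
  expect_true(all(prov[1:80, "TX"] == "primary"))
  ## conflicting overlap beyond tolerance is logged, primary kept
  secondary$TX <- secondary$TX + 5
  m2 <- merge_station_series(primary, secondary)
  expect_gt(nrow(attr(m2, "conflicts")), 0)
  expect_equal(m2$TX[60:80], primary$TX[60:80])
})

test_that("TA and DR derivation keeps TA between TM and TX", {
  s <- data.frame(TX = c(30, 25), TM = c(20, 25))
  d <- derive_ta_dr(s)
  expect_equal(d$TA, c(25, 25))
  expect_equal(d$DR, c(10, 0))
  lit <- derive_ta_dr(s, ta_formula = "paper_literal")
  expect_equal(lit$TA, c(5, 0))
  w <- derive_ta_dr(tiny_weather(500, seed = 8))
  expect_true(all(w$TM <= w$TA & w$TA <= w$TX))
})

test_that("VAR gap filling is identity without gaps and mask-exact with", {
  w <- tiny_weather(600, seed = 41)
  expect_identical(impute_var_temperature_precip(w)[c("TX", "TM", "P")],
                   w[c("TX", "TM", "P")])
  g <- inject_missingness(w, 0.1, seed = 42)
  filled <- impute_var_temperature_precip(g$series)
  mask <- attr(filled, "imputed")
  expect_identical(as.matrix(mask), as.matrix(g$mask[c("TX", "TM", "P")]))
  for (v in c("TX", "TM", "P")) {
    expect_false(anyNA(filled[[v]]))
    obs <- !g$mask[[v]]
    expect_identical(filled[[v]][obs], w[[v]][obs])
  }
  expect_true(all(filled$TM <= filled$TX))
  short <- g$series[1:30, ]
  expect_error(impute_var_temperature_precip(short), "complete")
})

test_that("VAR fill recovers held-out temperatures", {
  w <- tiny_weather(2000, seed = 51)
  g <- inject_missingness(w, 0.1, seed = 52)
  filled <- impute_var_temperature_precip(g$series)
  for (v in c("TX", "TM")) {
    i <- g$mask[[v]]
    expect_gte(cor(filled[[v]][i], g$truth[[v]][i]), 0.7)
  }
})

test_that("forest fill recovers humidity and respects bounds", {
  w <- tiny_weather(1500, seed = 61)
  g <- inject_missingness(w, c(RH = 0.1), seed = 62)
  expect_identical(impute_forest_rh_sr(w, "RH"), w, ignore_attr = TRUE)
  filled <- impute_forest_rh_sr(g$series, "RH", seed = 63)
  i <- g$mask$RH
  expect_false(anyNA(filled$RH))
  expect_true(all(filled$RH >= 0 & filled$RH <= 100))
  expect_gte(cor(filled$RH[i], g$truth$RH[i]), 0.9)
  ## gap days with missing predictors stay missing and are reported
  g2 <- g$series
  g2$TX[which(i)[1]] <- NA
  filled2 <- impute_forest_rh_sr(g2, "RH", seed = 63)
  expect_true(is.na(filled2$RH[which(i)[1]]))
  expect_equal(attr(filled2, "unfilled"), g2$date[which(i)[1]])
})
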