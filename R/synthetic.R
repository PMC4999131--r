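#' Parameters for the synthetic tropical weather generator
#'
#' The generator is a minimal structural emulator of tropical lowland daily
#' weather: maximum temperature is a seasonal harmonic plus an AR(1) anomaly,
#' minimum temperature follows from a stochastic positive diurnal range,
#' precipitation comes from a seasonally modulated two-state wet/dry Markov
#' chain with gamma-distributed wet-day amounts (optionally bimodal in the
#' annual cycle), relative humidity is inversely coupled to the diurnal range,
#' and solar radiation is a clear-sky value attenuated on wet (cloudy) days.
#' Defaults describe an irrigated tropical rice environment (warm, weakly
#' seasonal, bimodal rainfall).
#'
#' @param latitude_deg station latitude, degrees.
#' @param tx_mean annual mean of daily maximum temperature, degrees C.
#' @param tx_seasonal_amp amplitude of the annual harmonic of TX, degrees C.
#' @param tx_seasonal_phase day of year at which the TX harmonic peaks.
#' @param dr_mean mean diurnal temperature range TX - TM, degrees C.
#' @param dr_min hard floor on the diurnal range, degrees C (keeps TM < TX).
#' @param dr_seasonal_amp amplitude of the annual harmonic of the diurnal
#'   range (largest in the dry season), degrees C.
#' @param dr_ar1 lag-1 autoregressive coefficient of the diurnal-range
#'   anomaly (cloud-cover persistence), in (-1, 1).
#' @param ar1_coef lag-1 autoregressive coefficient of the TX anomaly,
#'   in (-1, 1).
#' @param precip_wet_prob long-run probability of a wet day (before seasonal
#'   modulation); 0 disables precipitation entirely.
#' @param precip_persistence Markov persistence of the wet/dry state, in
#'   `[0, 1)`.
#' @param precip_gamma_shape,precip_gamma_scale gamma parameters of wet-day
#'   amounts (mm).
#' @param bimodal_precip logical; if `TRUE` the wet-day probability is
#'   modulated by a semiannual (two wet seasons) harmonic rather than an
#'   annual one.
#' @param rh_base baseline relative humidity, percent.
#' @param rh_dr_slope decrease in RH per degree of diurnal-range anomaly.
#' @param rh_wet_bump RH increase on wet days, percent.
#' @param sr_clear_sky clear-sky daily solar radiation, cal cm-2 day-1.
#' @param sr_wet_frac fractional SR reduction on wet days.
#' @param noise_sd named list of innovation standard deviations for
#'   `tx` (AR(1) innovations, degrees C), `dr` (degrees C), `rh` (percent)
#'   and `sr` (cal cm-2 day-1).
#' @param seed integer seed making every generated series reproducible.
#'
#' @return An object of class `weather_gen_params` (a validated list).
#' @export
weather_gen_params <- function(latitude_deg = 3.9,
                               tx_mean = 32, tx_seasonal_amp = 2.0,
                               tx_seasonal_phase = 60,
                               dr_mean = 9, dr_min = 0.5,
                               dr_seasonal_amp = 1.5, dr_ar1 = 0.6,
                               ar1_coef = 0.7,
                               precip_wet_prob = 0.35,
                               precip_persistence = 0.3,
                               precip_gamma_shape = 0.8,
                               precip_gamma_scale = 12,
                               bimodal_precip = TRUE,
                               rh_base = 80, rh_dr_slope = 2.5,
                               rh_wet_bump = 3,
                               sr_clear_sky = 550, sr_wet_frac = 0.28,
                               noise_sd = list(tx = 1.0, dr = 1.2,
                                               rh = 1.5, sr = 30),
                               seed = 1L) {
  p <- list(latitude_deg = latitude_deg, tx_mean = tx_mean,
            tx_seasonal_amp = tx_seasonal_amp,
            tx_seasonal_phase = tx_seasonal_phase,
            dr_mean = dr_mean, dr_min = dr_min,
            dr_seasonal_amp = dr_seasonal_amp, dr_ar1 = dr_ar1,
            ar1_coef = ar1_coef,
            precip_wet_prob = precip_wet_prob,
            precip_persistence = precip_persistence,
            precip_gamma_shape = precip_gamma_shape,
            precip_gamma_scale = precip_gamma_scale,
            bimodal_precip = isTRUE(bimodal_precip),
            rh_base = rh_base, rh_dr_slope = rh_dr_slope,
            rh_wet_bump = rh_wet_bump,
            sr_clear_sky = sr_clear_sky, sr_wet_frac = sr_wet_frac,
            noise_sd = noise_sd, seed = as.integer(seed))
  num <- unlist(p[c("latitude_deg", "tx_mean", "tx_seasonal_amp", "dr_mean",
                    "ar1_coef", "precip_wet_prob", "precip_gamma_shape",
                    "precip_gamma_scale", "rh_base", "sr_clear_sky")])
  if (any(!is.finite(num)))
    stopf("non-finite weather generator parameter: %s",
          paste(names(num)[!is.finite(num)], collapse = ", "))
  if (any(!is.finite(unlist(noise_sd))) || any(unlist(noise_sd) < 0))
    stopf("noise_sd entries must be finite and non-negative")
  if (abs(p$ar1_coef) >= 1)
    stopf("ar1_coef must lie strictly inside (-1, 1), got %g", p$ar1_coef)
  if (abs(p$dr_ar1) >= 1)
    stopf("dr_ar1 must lie strictly inside (-1, 1), got %g", p$dr_ar1)
  if (p$precip_wet_prob < 0 || p$precip_wet_prob > 1)
    stopf("precip_wet_prob must be a probability")
  if (p$dr_mean <= 0 || p$dr_min <= 0) stopf("diurnal range must be positive")
  if (p$sr_clear_sky <= 0) stopf("sr_clear_sky must be positive")
  class(p) <- "weather_gen_params"
  p
}

#' Seasonal harmonic of maximum temperature
#'
#' Deterministic seasonal component of TX used by [generate_daily_weather()];
#' exposed so anomalies can be recovered exactly.
#'
#' @param params a [weather_gen_params()] object.
#' @param doy day of year (1-366), vectorized.
#' @return TX harmonic values, degrees C.
#' @export
tx_seasonal_mean <- function(params, doy) {
  params$tx_mean + params$tx_seasonal_amp *
    cos(2 * pi * (doy - params$tx_seasonal_phase) / 365.25)
}

wet_day_prob <- function(params, doy) {
  if (params$precip_wet_prob <= 0) return(rep(0, length(doy)))
  period <- if (params$bimodal_precip) 2 else 1
  mod <- 1 + 0.6 * cos(period * 2 * pi *
                         (doy - params$tx_seasonal_phase - 45) / 365.25)
  pmin(0.99, pmax(0, params$precip_wet_prob * mod))
}

#' Generate a synthetic daily weather series
#'
#' Produces one complete station series of daily maximum temperature (TX),
#' minimum temperature (TM), precipitation (P), relative humidity (RH) and
#' solar radiation (SR).  The series is bit-reproducible given
#' `params$seed`; each climatic variable consumes its own sub-stream of the
#' seed so that the realization of, say, temperature does not change when
#' the precipitation model is altered.
#'
#' Physical constraints hold on every generated day: TM < TX, P >= 0,
#' RH in `[0, 100]`, SR > 0.
#'
#' @param params a [weather_gen_params()] object.
#' @param start_date first day of the series (`Date` or ISO-8601 string).
#' @param n_days number of days to generate (>= 1).
#' @return A `data.frame` with columns `date`, `TX`, `TM`, `P`, `RH`, `SR`,
#'   carrying the generating parameters in attribute `"params"`.
#' @export
generate_daily_weather <- function(params, start_date = "2007-01-01",
                                   n_days = 365L) {
  if (!inherits(params, "weather_gen_params"))
    params <- do.call(weather_gen_params, params)
  n_days <- as.integer(n_days)
  if (is.na(n_days) || n_days < 1) stopf("n_days must be >= 1")
  dates <- as.Date(start_date) + seq_len(n_days) - 1L
  doy <- as.integer(format(dates, "%j"))
  seeds <- split_seed(params$seed, 5L)
  ns <- params$noise_sd

  ## TX: harmonic + AR(1) anomaly
  tx_anom <- with_seed(seeds[[1]], {
    e <- rnorm(n_days, sd = ns$tx)
    a <- numeric(n_days)
    a[1] <- if (abs(params$ar1_coef) < 1 && ns$tx > 0)
      rnorm(1, sd = ns$tx / sqrt(1 - params$ar1_coef^2)) else 0
    for (t in seq_len(n_days)[-1]) a[t] <- params$ar1_coef * a[t - 1] + e[t]
    a
  })
  TX <- tx_seasonal_mean(params, doy) + tx_anom

  ## diurnal range (own seasonal cycle and persistent cloud-cover anomaly)
  DR <- with_seed(seeds[[2]], {
    e <- rnorm(n_days, sd = ns$dr)
    a <- numeric(n_days)
    a[1] <- if (abs(params$dr_ar1) < 1 && ns$dr > 0)
      rnorm(1, sd = ns$dr / sqrt(1 - params$dr_ar1^2)) else 0
    for (t in seq_len(n_days)[-1]) a[t] <- params$dr_ar1 * a[t - 1] + e[t]
    harm <- params$dr_seasonal_amp *
      cos(2 * pi * (doy - params$tx_seasonal_phase) / 365.25)
    pmax(params$dr_min, params$dr_mean + harm + a)
  })
  TM <- TX - DR

  ## precipitation: seasonally modulated two-state Markov chain, gamma amounts
  pw <- wet_day_prob(params, doy)
  prec <- with_seed(seeds[[3]], {
    u <- runif(n_days)
    wet <- logical(n_days)
    prev <- FALSE
    for (t in seq_len(n_days)) {
      pr <- pw[t] + params$precip_persistence * ((prev * 1) - pw[t])
      wet[t] <- u[t] < min(max(pr, 0), 0.999)
      prev <- wet[t]
    }
    amount <- numeric(n_days)
    if (any(wet))
      amount[wet] <- rgamma(sum(wet), shape = params$precip_gamma_shape,
                            scale = params$precip_gamma_scale)
    list(P = amount, wet = wet)
  })

  ## RH inversely coupled to diurnal range, bumped on wet days
  RH <- with_seed(seeds[[4]], {
    base <- params$rh_base - params$rh_dr_slope * (DR - params$dr_mean) +
      params$rh_wet_bump * prec$wet
    pmin(100, pmax(0, base + rnorm(n_days, sd = ns$rh)))
  })

  ## SR: clear-sky value, attenuated on wet days, mild seasonal cycle
  SR <- with_seed(seeds[[5]], {
    frac <- 0.78 + 0.05 * cos(2 * pi * (doy - params$tx_seasonal_phase) /
                                365.25) - params$sr_wet_frac * prec$wet
    pmax(30, params$sr_clear_sky * frac + rnorm(n_days, sd = ns$sr))
  })

  out <- data.frame(date = dates, TX = TX, TM = TM, P = prec$P,
                    RH = RH, SR = SR)
  attr(out, "params") <- params
  out
}

#' Default cultivar growth-stage duration profiles
#'
#' Typical durations (days) of the vegetative, reproductive and ripening
#' stages on a reference cropping cycle.  Real profiles are expert knowledge
#' supplied as configuration; these defaults are synthetic stand-ins on the
#' customary 126-day reference cycle.
#'
#' @param reference_cycle reference cycle length in days.
#' @return data.frame with columns `cultivar`, `veg_days`, `rep_days`,
#'   `rip_days`, `reference_cycle`.
#' @export
cultivar_profiles <- function(reference_cycle = 126L) {
  prof <- data.frame(cultivar = c("F733", "F60", "F50"),
                     veg_days = c(55L, 57L, 53L),
                     rep_days = c(36L, 34L, 38L),
                     rip_days = c(35L, 35L, 35L))
  prof$reference_cycle <- as.integer(reference_cycle)
  stopifnot(all(prof$veg_days + prof$rep_days + prof$rip_days ==
                  prof$reference_cycle))
  prof
}

#' Generate synthetic cropping events over a weather series
#'
#' Draws sowing dates uniformly inside a window, cycle lengths from a
#' rounded normal clipped to `[100, 160]` days, and cultivars from the
#' supplied profile table with given probabilities.  Yields are left unset;
#' see [ground_truth_yield()].
#'
#' @param weather daily weather series (from [generate_daily_weather()]).
#' @param n_events number of events.
#' @param cultivars cultivar profile table ([cultivar_profiles()]).
#' @param cultivar_probs sampling probabilities, recycled/normalized.
#' @param sowing_window length-2 Date vector; defaults to the widest window
#'   such that the longest admissible cycle still fits in `weather`.
#' @param cycle_days_mean,cycle_days_sd cycle length distribution (days).
#' @param locality locality label attached to every event.
#' @param seed integer seed.
#' @return data.frame of class `cropping_events` with columns `event_id`,
#'   `locality`, `cultivar`, `sowing_date`, `harvest_date`, `yield` (NA).
#' @export
generate_cropping_events <- function(weather, n_events,
                                     cultivars = cultivar_profiles(),
                                     cultivar_probs = NULL,
                                     sowing_window = NULL,
                                     cycle_days_mean = 126,
                                     cycle_days_sd = 5,
                                     locality = "Synthetica", seed = 1L) {
  n_events <- as.integer(n_events)
  stopifnot(n_events >= 1)
  cover <- range(weather$date)
  max_cycle <- min(160, ceiling(cycle_days_mean + 4 * cycle_days_sd))
  if (is.null(sowing_window))
    sowing_window <- c(cover[1], cover[2] - max_cycle)
  sowing_window <- as.Date(sowing_window)
  if (sowing_window[2] < sowing_window[1] ||
      sowing_window[1] < cover[1] ||
      sowing_window[2] + max_cycle > cover[2])
    stopf("sowing window plus maximum cycle does not fit inside the weather coverage")
  probs <- cultivar_probs %||% rep(1, nrow(cultivars))
  probs <- probs / sum(probs)
  seeds <- split_seed(seed, 3L)
  span <- as.integer(sowing_window[2] - sowing_window[1])
  sow <- with_seed(seeds[[1]],
                   sowing_window[1] + sample.int(span + 1L, n_events,
                                                 replace = TRUE) - 1L)
  cyc <- with_seed(seeds[[2]], {
    raw <- round(rnorm(n_events, cycle_days_mean, cycle_days_sd))
    as.integer(pmin(160, pmax(100, raw)))
  })
  cult <- with_seed(seeds[[3]],
                    sample(cultivars$cultivar, n_events, replace = TRUE,
                           prob = probs))
  out <- data.frame(event_id = sprintf("ev%05d", seq_len(n_events)),
                    locality = locality, cultivar = cult,
                    sowing_date = sow, harvest_date = sow + cyc,
                    yield = NA_real_)
  class(out) <- c("cropping_events", "data.frame")
  attr(out, "cultivar_profiles") <- cultivars
  out
}

#' Known ground-truth yield response
#'
#' Defines how synthetic yields are produced from growth-stage indicators:
#' a base yield, additive cultivar effects, a sum of driver terms (linear,
#' hinge or saturating in one indicator each) and Gaussian noise, truncated
#' below at a positive floor.  The default drivers encode the canonical
#' scenario used throughout the package's validation: a hinge penalty of
#' -300 kg ha-1 per degree C of reproductive-stage minimum temperature above
#' 22.7 degrees C, and a positive linear response of 0.29 kg ha-1 per
#' cal cm-2 of ripening-stage accumulated solar radiation (about 1,000 kg
#' ha-1 per 100 cal cm-2 day-1 over a 35-day stage, the classic controlled-
#' environment sensitivity for rice).
#'
#' @param base_yield base (intercept) yield, kg ha-1; with the default
#'   drivers and generator the mean generated yield lands near the typical
#'   irrigated-rice average of about 6,100 kg ha-1.
#' @param cultivar_effects named numeric vector of additive effects,
#'   kg ha-1; unnamed cultivars get 0.
#' @param driver_terms list of terms, each
#'   `list(indicator =, form = "linear"|"hinge"|"saturating", coef =,
#'   breakpoint = )` (`breakpoint` used by hinge; half-saturation constant
#'   for saturating).
#' @param noise_sd residual standard deviation, kg ha-1.
#' @param yield_floor truncation floor, kg ha-1.
#' @return object of class `ground_truth_response`.
#' @export
ground_truth_response <- function(base_yield = 2300,
                                  cultivar_effects = c(F733 = 300, F60 = 0,
                                                       F50 = -300),
                                  driver_terms = list(
                                    list(indicator = "TM_Avg_REP",
                                         form = "hinge", coef = -600,
                                         breakpoint = 22.7),
                                    list(indicator = "SR_Accu_RIP",
                                         form = "linear", coef = 0.29)),
                                  noise_sd = 400,
                                  yield_floor = 500) {
  valid <- indicator_names()
  for (term in driver_terms) {
    if (!term$indicator %in% valid)
      stopf("unknown indicator in driver term: %s", term$indicator)
    if (!term$form %in% c("linear", "hinge", "saturating"))
      stopf("unknown driver functional form: %s", term$form)
  }
  structure(list(base_yield = base_yield,
                 cultivar_effects = cultivar_effects,
                 driver_terms = driver_terms,
                 noise_sd = noise_sd, yield_floor = yield_floor),
            class = "ground_truth_response")
}

driver_contribution <- function(term, x) {
  switch(term$form,
         linear = term$coef * x,
         hinge = term$coef * pmax(0, x - term$breakpoint),
         saturating = term$coef * x / (x + term$breakpoint))
}

#' Deterministic part of the ground-truth yield
#'
#' @param indicators data.frame with a `Cultivar` column and the driver
#'   indicator columns.
#' @param response a [ground_truth_response()] object.
#' @return numeric vector of expected yields (before noise and truncation).
#' @export
ground_truth_signal <- function(indicators, response) {
  eff <- response$cultivar_effects[as.character(indicators$Cultivar)]
  eff[is.na(eff)] <- 0
  y <- rep(response$base_yield, nrow(indicators)) + unname(eff)
  for (term in response$driver_terms) {
    if (!term$indicator %in% names(indicators))
      stopf("driver indicator %s absent from the indicator table",
            term$indicator)
    y <- y + driver_contribution(term, indicators[[term$indicator]])
  }
  y
}

#' Draw ground-truth yields for indicator rows
#'
#' yield = base + cultivar effect + sum of driver terms + N(0, noise_sd),
#' truncated below at the response's yield floor.
#'
#' @inheritParams ground_truth_signal
#' @param seed integer seed (ignored when `noise_sd = 0`).
#' @return numeric vector of yields, kg ha-1.
#' @export
ground_truth_yield <- function(indicators, response, seed = 1L) {
  mu <- ground_truth_signal(indicators, response)
  if (response$noise_sd > 0)
    mu <- mu + with_seed(seed, rnorm(length(mu), sd = response$noise_sd))
  pmax(response$yield_floor, mu)
}

#' Calibrate the response noise to a target population R-squared
#'
#' Sets `noise_sd` so that var(signal) / (var(signal) + noise_sd^2) equals
#' `target_r2`, where the signal variance is measured empirically over the
#' supplied indicator rows (cultivar effects included).
#'
#' @inheritParams ground_truth_signal
#' @param target_r2 desired population coefficient of determination.
#' @return the response object with `noise_sd` replaced.
#' @export
calibrate_noise_sd <- function(indicators, response, target_r2 = 0.35) {
  stopifnot(target_r2 > 0, target_r2 < 1)
  vs <- var(ground_truth_signal(indicators, response))
  response$noise_sd <- sqrt(vs * (1 - target_r2) / target_r2)
  response
}

#' Inject missing-completely-at-random gaps into a weather series
#'
#' @param series daily weather data.frame (columns `TX`, `TM`, `P`, `RH`,
#'   `SR` or any subset).
#' @param rate scalar or named per-variable missingness probability in
#'   `[0, 1)`.
#' @param seed integer seed.
#' @return list of class `gapped_weather`: `series` (with NAs), `mask`
#'   (logical data.frame, TRUE where removed) and `truth` (the original
#'   series).
#' @export
inject_missingness <- function(series, rate = 0.1, seed = 1L) {
  vars <- intersect(c("TX", "TM", "P", "RH", "SR"), names(series))
  rates <- setNames(rep(0, length(vars)), vars)
  if (is.null(names(rate))) rates[] <- rate
  else rates[intersect(names(rate), vars)] <-
      rate[intersect(names(rate), vars)]
  if (any(rates < 0 | rates >= 1)) stopf("rates must lie in [0, 1)")
  truth <- series
  mask <- as.data.frame(matrix(FALSE, nrow(series), length(vars),
                               dimnames = list(NULL, vars)))
  seeds <- split_seed(seed, length(vars))
  for (k in seq_along(vars)) {
    v <- vars[k]
    r <- rates[[v]]
    if (r > 0) {
      drop <- with_seed(seeds[[k]], runif(nrow(series)) < r)
      mask[[v]] <- drop
      series[[v]][drop] <- NA_real_
    }
  }
  structure(list(series = series, mask = mask, truth = truth),
            class = "gapped_weather")
}

#' Generate a mixture of weather regimes with known labels
#'
#' Generates `k` weather series from distinct parameter sets, draws
#' `events_per_regime` cropping events inside each, and attaches the daily
#' weather windows, returning the true generating regime of every event for
#' external validation of pattern clustering.
#'
#' @param k number of regimes (>= 1).
#' @param params_list list of `k` [weather_gen_params()] objects (defaults
#'   to regimes separated by +4 degrees C steps in `tx_mean`).
#' @param events_per_regime events per regime (scalar or length k).
#' @param n_days,start_date weather coverage per regime.
#' @param cycle_days_mean,cycle_days_sd event cycle-length distribution.
#' @param seed integer seed.
#' @return list with `events` (data.frame including `regime`), `bundles`
#'   (list of [event_series_bundle] objects) and `weather` (list of series).
#' @export
generate_regime_mixture <- function(k = 2, params_list = NULL,
                                    events_per_regime = 40,
                                    n_days = 400, start_date = "2010-01-01",
                                    cycle_days_mean = 126, cycle_days_sd = 3,
                                    seed = 1L) {
  k <- as.integer(k)
  stopifnot(k >= 1)
  if (is.null(params_list)) {
    seeds0 <- split_seed(seed, k)
    params_list <- lapply(seq_len(k), function(i)
      weather_gen_params(tx_mean = 32 + 4 * (i - 1), seed = seeds0[[i]]))
  }
  if (length(params_list) != k) stopf("params_list must have length k")
  sig <- vapply(params_list, function(p)
    paste(format(unlist(p[setdiff(names(p), "seed")]), digits = 10),
          collapse = "|"), "")
  if (k > 1 && anyDuplicated(sig))
    warnf("some regimes share identical parameters; recovery is not identifiable")
  counts <- rep_len(as.integer(events_per_regime), k)
  seeds <- split_seed(seed + 1L, k)
  ev_list <- list()
  bundles <- list()
  weather <- list()
  for (i in seq_len(k)) {
    w <- generate_daily_weather(params_list[[i]], start_date, n_days)
    ev <- generate_cropping_events(w, counts[i],
                                   cycle_days_mean = cycle_days_mean,
                                   cycle_days_sd = cycle_days_sd,
                                   locality = sprintf("regime%d", i),
                                   seed = seeds[[i]])
    ev$regime <- i
    ev$event_id <- sprintf("r%d_%s", i, ev$event_id)
    ev_list[[i]] <- ev
    weather[[i]] <- w
    bundles <- c(bundles, lapply(seq_len(nrow(ev)), function(j)
      event_series_bundle(attach_weather_window(ev[j, ], w))))
  }
  events <- do.call(rbind, lapply(ev_list, as.data.frame))
  list(events = events, bundles = bundles, weather = weather)
}

#' Simulate a complete indicator dataset with known ground truth
#'
#' End-to-end convenience: weather -> cropping events -> stage indicators ->
#' yields.  When `target_r2` is non-NULL the response noise is calibrated so
#' the population R-squared of the generated yields equals it.
#'
#' @param n_events number of cropping events.
#' @param response a [ground_truth_response()] (default drivers if NULL).
#' @param target_r2 population R-squared to calibrate the noise to, or NULL
#'   to keep `response$noise_sd`.
#' @param params weather generator parameters.
#' @param n_days weather series length (must cover all cycles).
#' @param seed master integer seed.
#' @return list: `indicators` (table with Cultivar, 27 indicators, Yield),
#'   `events`, `weather`, `response` (with the noise actually used),
#'   `signal` (noise-free yields).
#' @export
simulate_indicator_dataset <- function(n_events = 600, response = NULL,
                                       target_r2 = 0.35,
                                       params = NULL, n_days = 1200,
                                       seed = 1L) {
  seeds <- split_seed(seed, 4L)
  params <- params %||% weather_gen_params(seed = seeds[[1]])
  weather <- generate_daily_weather(params, "2007-01-01", n_days)
  events <- generate_cropping_events(weather, n_events, seed = seeds[[2]])
  evs <- lapply(seq_len(nrow(events)), function(j)
    attach_weather_window(events[j, ], weather))
  tab <- build_indicator_table(lapply(evs, compute_stage_indicators))
  response <- response %||% ground_truth_response()
  if (!is.null(target_r2))
    response <- calibrate_noise_sd(tab, response, target_r2)
  tab$Yield <- ground_truth_yield(tab, response, seed = seeds[[3]])
  events$yield <- tab$Yield
  list(indicators = tab, events = events, weather = weather,
       response = response, signal = ground_truth_signal(tab, response))
}
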