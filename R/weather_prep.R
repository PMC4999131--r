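#' Screen weather stations by distance and altitude
#'
#' Keeps stations within `max_dist_km` great-circle kilometres of the crop
#' location and within `alt_tol_m` metres of its altitude, sorted by
#' distance.  These are the customary station-screening rules for relating
#' field records to point weather observations (<10 km, +/-50 m).
#'
#' @param stations data.frame with columns `station_id`, `latitude_deg`,
#'   `longitude_deg`, `altitude_m` (and optionally `provider`).
#' @param crop_lat,crop_lon,crop_alt crop location (degrees, degrees, m).
#' @param max_dist_km maximum distance, km (strict `<`).
#' @param alt_tol_m maximum absolute altitude difference, m (`<=`).
#' @return the eligible stations with a `dist_km` column, nearest first.
#' @export
select_stations <- function(stations, crop_lat, crop_lon, crop_alt,
                            max_dist_km = 10, alt_tol_m = 50) {
  stopifnot(all(c("station_id", "latitude_deg", "longitude_deg",
                  "altitude_m") %in% names(stations)))
  if (any(abs(stations$latitude_deg) > 90) || abs(crop_lat) > 90)
    stopf("latitudes must lie in [-90, 90]")
  d_km <- geosphere::distHaversine(
    cbind(stations$longitude_deg, stations$latitude_deg),
    c(crop_lon, crop_lat)) / 1000
  keep <- d_km < max_dist_km &
    abs(stations$altitude_m - crop_alt) <= alt_tol_m
  if (!any(keep))
    stopf("no eligible station within %g km and %g m altitude", max_dist_km,
          alt_tol_m)
  out <- stations[keep, , drop = FALSE]
  out$dist_km <- d_km[keep]
  out[order(out$dist_km), , drop = FALSE]
}

#' Aggregate hourly station records to daily values
#'
#' A day's value for a variable is computed only when strictly more than
#' `min_completeness` of its 24 hourly values are available; otherwise the
#' day is missing for that variable.  TX is the daily max and TM the daily
#' min of hourly temperature, P and SR are daily sums, RH is the daily mean.
#'
#' @param hourly data.frame with a POSIXct (or parseable) `time` column and
#'   any of `temp`, `P`, `RH`, `SR`.
#' @param min_completeness required fraction of valid hours (strict `>`).
#' @return daily data.frame with `date` and the derivable columns among
#'   `TX`, `TM`, `P`, `RH`, `SR`.
#' @export
aggregate_hourly_to_daily <- function(hourly, min_completeness = 0.8) {
  stopifnot("time" %in% names(hourly))
  tm <- as.POSIXct(hourly$time, tz = "UTC")
  if (anyDuplicated(tm)) {
    dup <- format(as.Date(tm[duplicated(tm)][1]))
    stopf("duplicate hourly timestamps (first offending day: %s)", dup)
  }
  day <- as.Date(tm)
  need <- min_completeness * 24
  agg <- function(v, fun) {
    if (!v %in% names(hourly)) return(NULL)
    x <- hourly[[v]]
    vapply(split(x, day), function(h) {
      if (sum(!is.na(h)) > need) fun(h, na.rm = TRUE) else NA_real_
    }, 0.0)
  }
  out <- data.frame(date = as.Date(names(split(seq_along(day), day))))
  tx <- agg("temp", max); tmn <- agg("temp", min)
  if (!is.null(tx)) { out$TX <- unname(tx); out$TM <- unname(tmn) }
  for (spec in list(c("P", "sum"), c("RH", "mean"), c("SR", "sum"))) {
    v <- agg(spec[1], match.fun(spec[2]))
    if (!is.null(v)) out[[spec[1]]] <- unname(v)
  }
  out
}

#' Default daily quality-control limits
#'
#' Plausibility ranges for tropical lowland stations, configurable per
#' deployment.  `flatline_days` is the minimum run of identical consecutive
#' values flagged for temperature and humidity sensors.
#'
#' @param TX,TM,P,RH,SR length-2 numeric ranges (inclusive; SR lower bound
#'   exclusive).
#' @param flatline_days run length that triggers a flatline flag.
#' @return list of limits used by [qc_daily()].
#' @export
qc_limits <- function(TX = c(10, 45), TM = c(5, 35), P = c(0, 300),
                      RH = c(0, 100), SR = c(0, 900), flatline_days = 5L) {
  list(TX = TX, TM = TM, P = P, RH = RH, SR = SR,
       flatline_days = as.integer(flatline_days))
}

flatline_runs <- function(x, min_run) {
  n <- length(x)
  flag <- logical(n)
  r <- rle(ifelse(is.na(x), "NA", format(x, digits = 12)))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in which(r$lengths >= min_run & r$values != "NA"))
    flag[starts[k]:ends[k]] <- TRUE
  flag
}

#' Quality-control a daily weather series
#'
#' WMO-style plausibility screening: values outside the configured ranges,
#' days with TM > TX (both values flagged) and flatline runs of identical
#' temperature/humidity values are flagged and set to missing.  QC never
#' aborts; it reports.
#'
#' @param series daily data.frame with `date` and any of `TX`, `TM`, `P`,
#'   `RH`, `SR`.
#' @param limits a [qc_limits()] list.
#' @return list: `series` (flagged cells set to `NA`), `flags` (logical
#'   data.frame) and `report` (per-variable counts of range violations,
#'   consistency violations, flatline days, total cells set missing).
#' @export
qc_daily <- function(series, limits = qc_limits()) {
  vars <- intersect(c("TX", "TM", "P", "RH", "SR"), names(series))
  flags <- as.data.frame(matrix(FALSE, nrow(series), length(vars),
                                dimnames = list(NULL, vars)))
  report <- data.frame(variable = vars, range = 0L, consistency = 0L,
                       flatline = 0L, set_missing = 0L)
  rownames(report) <- vars
  for (v in vars) {
    x <- series[[v]]
    lim <- limits[[v]]
    bad <- !is.na(x) & (x < lim[1] | x > lim[2])
    if (v == "SR") bad <- bad | (!is.na(x) & x <= lim[1])
    report[v, "range"] <- sum(bad)
    flags[[v]] <- flags[[v]] | bad
  }
  if (all(c("TX", "TM") %in% vars)) {
    inc <- !is.na(series$TX) & !is.na(series$TM) & series$TM > series$TX
    report["TX", "consistency"] <- report["TM", "consistency"] <- sum(inc)
    flags$TX <- flags$TX | inc
    flags$TM <- flags$TM | inc
  }
  for (v in intersect(c("TX", "TM", "RH"), vars)) {
    fl <- flatline_runs(series[[v]], limits$flatline_days)
    report[v, "flatline"] <- sum(fl)
    flags[[v]] <- flags[[v]] | fl
  }
  for (v in vars) {
    series[[v]][flags[[v]]] <- NA_real_
    report[v, "set_missing"] <- sum(flags[[v]])
  }
  list(series = series, flags = flags, report = report)
}

#' Extraterrestrial solar radiation (FAO-56)
#'
#' Daily extraterrestrial radiation from the inverse relative Earth-Sun
#' distance, solar declination and sunset hour angle, computed in
#' MJ m-2 day-1 and optionally converted to cal cm-2 day-1
#' (1 MJ m-2 = 23.884 cal cm-2).
#'
#' @param latitude_deg latitude, degrees; `|lat| <= 66.5` (polar day/night
#'   not handled).
#' @param day_of_year 1-366, vectorized.
#' @param unit `"cal"` (cal cm-2 day-1, default) or `"MJ"`.
#' @return extraterrestrial radiation.
#' @export
extraterrestrial_radiation <- function(latitude_deg, day_of_year,
                                       unit = c("cal", "MJ")) {
  unit <- match.arg(unit)
  if (any(abs(latitude_deg) > 66.5))
    stopf("polar latitudes (|lat| > 66.5) are not supported")
  if (any(day_of_year < 1 | day_of_year > 366))
    stopf("day_of_year must lie in [1, 366]")
  phi <- latitude_deg * pi / 180
  dr <- 1 + 0.033 * cos(2 * pi * day_of_year / 365)
  delta <- 0.409 * sin(2 * pi * day_of_year / 365 - 1.39)
  ws <- acos(pmin(1, pmax(-1, -tan(phi) * tan(delta))))
  ra_mj <- 24 * 60 / pi * 0.0820 * dr *
    (ws * sin(phi) * sin(delta) + cos(phi) * cos(delta) * sin(ws))
  if (unit == "MJ") ra_mj else ra_mj * MJ_TO_CAL
}

#' Astronomical day length (hours)
#'
#' @inheritParams extraterrestrial_radiation
#' @return maximum possible sunshine duration N, hours.
#' @export
daylength <- function(latitude_deg, day_of_year) {
  phi <- latitude_deg * pi / 180
  delta <- 0.409 * sin(2 * pi * day_of_year / 365 - 1.39)
  ws <- acos(pmin(1, pmax(-1, -tan(phi) * tan(delta))))
  24 / pi * ws
}

#' Solar radiation from sunshine duration (Angstrom-Prescott)
#'
#' SR = (a + b * n/N) * Ra, with N the astronomical day length and Ra the
#' extraterrestrial radiation.  Default coefficients a = 0.25, b = 0.50 are
#' the FAO-56 recommendation for use when no local calibration exists.
#'
#' @param sunshine_hours measured bright sunshine n, hours (values above N
#'   are clipped with a warning).
#' @param latitude_deg latitude, degrees.
#' @param day_of_year 1-366.
#' @param a,b Angstrom coefficients.
#' @return SR in cal cm-2 day-1.
#' @export
solar_from_sunshine <- function(sunshine_hours, latitude_deg, day_of_year,
                                a = 0.25, b = 0.50) {
  if (any(sunshine_hours < 0, na.rm = TRUE))
    stopf("sunshine duration cannot be negative")
  N <- daylength(latitude_deg, day_of_year)
  over <- !is.na(sunshine_hours) & sunshine_hours > N
  if (any(over)) {
    warnf("%d sunshine values exceed the day length; clipped", sum(over))
    sunshine_hours[over] <- N[over]
  }
  ra <- extraterrestrial_radiation(latitude_deg, day_of_year, unit = "cal")
  (a + b * sunshine_hours / N) * ra
}

#' Merge two station series with complementary coverage
#'
#' Per day and variable the primary station's value is kept when present,
#' else the secondary's.  Days where both stations report and disagree by
#' more than the tolerance (2 degrees C for temperatures, 20 percent
#' relative difference for precipitation) are logged; the primary value is
#' kept.
#'
#' @param primary,secondary daily data.frames with `date` and a common
#'   variable set.
#' @param temp_tol,p_tol conflict tolerances.
#' @return merged data.frame with attributes `"provenance"` (character
#'   matrix: "primary"/"secondary"/NA per cell) and `"conflicts"`
#'   (data.frame of logged disagreements).
#' @export
merge_station_series <- function(primary, secondary, temp_tol = 2,
                                 p_tol = 0.2) {
  vars <- intersect(c("TX", "TM", "P", "RH", "SR"), names(primary))
  if (!setequal(vars, intersect(c("TX", "TM", "P", "RH", "SR"),
                                names(secondary))))
    stopf("primary and secondary series must share the same variable set")
  dates <- sort(unique(c(primary$date, secondary$date)))
  out <- data.frame(date = dates)
  prov <- matrix(NA_character_, length(dates), length(vars),
                 dimnames = list(NULL, vars))
  conflicts <- list()
  ip <- match(dates, primary$date)
  is_ <- match(dates, secondary$date)
  for (v in vars) {
    pv <- primary[[v]][ip]
    sv <- secondary[[v]][is_]
    val <- ifelse(!is.na(pv), pv, sv)
    prov[, v] <- ifelse(!is.na(pv), "primary",
                        ifelse(!is.na(sv), "secondary", NA))
    both <- !is.na(pv) & !is.na(sv)
    bad <- if (v %in% c("TX", "TM")) both & abs(pv - sv) > temp_tol
           else if (v == "P") both & abs(pv - sv) > p_tol * pmax(pv, sv, 1)
           else rep(FALSE, length(pv))
    if (any(bad))
      conflicts[[v]] <- data.frame(date = dates[bad], variable = v,
                                   primary = pv[bad], secondary = sv[bad])
    out[[v]] <- val
  }
  attr(out, "provenance") <- prov
  attr(out, "conflicts") <- if (length(conflicts))
    do.call(rbind, conflicts) else
    data.frame(date = as.Date(character()), variable = character(),
               primary = numeric(), secondary = numeric())
  out
}

## circularly smoothed day-of-year climatology of one column
doy_climatology <- function(x, doy, window = 15L) {
  cl <- vapply(1:366, function(d) {
    v <- x[doy == d]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, 0.0)
  cl[is.na(cl)] <- mean(x, na.rm = TRUE)
  half <- window %/% 2
  ext <- c(tail(cl, half), cl, head(cl, half))
  sm <- stats::filter(ext, rep(1 / window, window), sides = 2)
  as.numeric(sm[(half + 1):(half + 366)])
}

#' Fill temperature and precipitation gaps with a vector-autoregressive model
#'
#' A deliberately simple anomaly-VAR gap filler: each variable is
#' deseasonalized against a smoothed day-of-year climatology (precipitation
#' on a log1p scale), a VAR(1) is fitted by least squares to the complete
#' day pairs, and gaps are filled by the Gaussian conditional expectation
#' given the same-day observed variables and the neighbouring days (a
#' forward and a backward pass, averaged).  Optional stochastic fill adds
#' conditional noise.  Precipitation is back-transformed and small filled
#' amounts (< 0.1 mm) snapped to zero, preserving dry days.  Observed cells
#' are never altered; a filled series with inverted TM/TX has the pair
#' swapped and flagged.
#'
#' @param series daily data.frame with `date`, `TX`, `TM`, `P` (other
#'   columns pass through).
#' @param neighbors optional list of additional station series (same
#'   columns) used as extra predictors in the VAR.
#' @param min_complete minimum number of complete consecutive-day pairs
#'   needed to fit (default 60).
#' @param stochastic add seeded conditional noise to the fill.
#' @param seed integer seed (used only when `stochastic = TRUE`).
#' @return the series with TX/TM/P gaps filled; attribute
#'   `"imputed"` is a logical data.frame marking exactly the originally
#'   missing cells, attribute `"swapped"` flags TM/TX inversions repaired
#'   after filling.
#' @export
impute_var_temperature_precip <- function(series, neighbors = NULL,
                                          min_complete = 60,
                                          stochastic = FALSE, seed = NULL) {
  vars <- c("TX", "TM", "P")
  stopifnot(all(vars %in% names(series)))
  miss <- as.data.frame(lapply(series[vars], is.na))
  if (!any(unlist(miss))) {
    attr(series, "imputed") <- miss
    attr(series, "swapped") <- rep(FALSE, nrow(series))
    return(series)
  }
  doy <- as.integer(format(series$date, "%j"))
  build_block <- function(s, tag) {
    m <- cbind(TX = s$TX, TM = s$TM, P = log1p(s$P))
    colnames(m) <- paste0(tag, c("TX", "TM", "P"))
    m
  }
  V <- build_block(series, "")
  if (!is.null(neighbors))
    for (i in seq_along(neighbors))
      V <- cbind(V, build_block(neighbors[[i]], sprintf("n%d_", i)))
  clim <- vapply(seq_len(ncol(V)), function(j)
    doy_climatology(V[, j], doy), numeric(366))
  A <- V - clim[doy, , drop = FALSE]
  n <- nrow(A); k <- ncol(A)

  ok <- complete.cases(A)
  pair <- which(ok[-n] & ok[-1])
  if (length(pair) < min_complete)
    stopf("only %d complete consecutive-day pairs available; %d required",
          length(pair), min_complete)
  Z <- A[pair, , drop = FALSE]
  Y <- A[pair + 1, , drop = FALSE]
  B <- qr.solve(crossprod(Z) + diag(1e-8, k), crossprod(Z, Y))
  E <- Y - Z %*% B
  Sig <- crossprod(E) / (nrow(E) - 1)

  cond_fill <- function(A, forward = TRUE, noise_seed = NULL) {
    idx <- if (forward) seq_len(n) else rev(seq_len(n))
    Ah <- A
    Ah[is.na(Ah)] <- 0
    fill <- A
    if (!is.null(noise_seed)) set.seed(noise_seed)
    for (t in idx) {
      mrow <- is.na(A[t, ])
      if (!any(mrow)) { Ah[t, ] <- A[t, ]; next }
      prev <- if (forward) t - 1 else t + 1
      mu <- if (prev >= 1 && prev <= n) as.numeric(Ah[prev, ] %*% B)
            else rep(0, k)
      obs <- !mrow
      if (any(obs)) {
        Soo <- Sig[obs, obs, drop = FALSE] + diag(1e-8, sum(obs))
        Smo <- Sig[mrow, obs, drop = FALSE]
        gain <- Smo %*% solve(Soo)
        cm <- mu[mrow] + as.numeric(gain %*% (A[t, obs] - mu[obs]))
        if (!is.null(noise_seed)) {
          Scc <- Sig[mrow, mrow, drop = FALSE] - gain %*% t(Smo)
          cm <- cm + as.numeric(chol(Scc + diag(1e-8, sum(mrow))) %*%
                                  rnorm(sum(mrow)))
        }
      } else {
        cm <- mu[mrow]
        if (!is.null(noise_seed))
          cm <- cm + as.numeric(chol(Sig[mrow, mrow, drop = FALSE] +
                                       diag(1e-8, sum(mrow))) %*%
                                  rnorm(sum(mrow)))
      }
      fill[t, mrow] <- cm
      Ah[t, obs] <- A[t, obs]
      Ah[t, mrow] <- cm
    }
    fill
  }
  sds <- if (stochastic) split_seed(seed %||% 1L, 2L) else list(NULL, NULL)
  Ff <- cond_fill(A, TRUE, sds[[1]])
  Fb <- cond_fill(A, FALSE, sds[[2]])
  filled <- (Ff + Fb) / 2
  filled[!is.na(A)] <- A[!is.na(A)]
  W <- filled + clim[doy, , drop = FALSE]

  out <- series
  out$TX[miss$TX] <- W[miss$TX, "TX"]
  out$TM[miss$TM] <- W[miss$TM, "TM"]
  pfill <- expm1(W[miss$P, "P"])
  pfill[pfill < 0.1] <- 0
  out$P[miss$P] <- pfill
  swapped <- !is.na(out$TX) & !is.na(out$TM) & out$TM > out$TX
  if (any(swapped)) {
    tmp <- out$TX[swapped]
    out$TX[swapped] <- out$TM[swapped]
    out$TM[swapped] <- tmp
  }
  attr(out, "imputed") <- miss
  attr(out, "swapped") <- swapped
  out
}

#' Fill RH or SR gaps with a regression random forest
#'
#' Trains a random forest (800 trees, two candidate predictors per node by
#' default, matching common practice for this task) on the days where the
#' target is observed, using TX, TM and P as predictors, and predicts the
#' gaps.  Filled RH is clipped to `[0, 100]`; filled SR is floored at a
#' small positive value.  Days whose predictors are themselves missing are
#' left missing and reported.
#'
#' @param series daily data.frame with `date`, `TX`, `TM`, `P` and the
#'   target column.
#' @param target `"RH"` or `"SR"`.
#' @param ntree,mtry forest size and candidate predictors per node.
#' @param min_train minimum number of complete training days.
#' @param sr_floor positive floor applied to filled SR.
#' @param seed integer seed.
#' @return the series with the target filled; attribute `"imputed"` marks
#'   filled cells, attribute `"unfilled"` lists days left missing for lack
#'   of predictors.
#' @export
impute_forest_rh_sr <- function(series, target = c("RH", "SR"),
                                ntree = 800, mtry = 2, min_train = 100,
                                sr_floor = 10, seed = NULL) {
  target <- match.arg(target)
  preds <- c("TX", "TM", "P")
  stopifnot(all(c(preds, target) %in% names(series)))
  gap <- is.na(series[[target]])
  if (!any(gap)) {
    attr(series, "imputed") <- gap
    attr(series, "unfilled") <- as.Date(character())
    return(series)
  }
  train <- !gap & complete.cases(series[preds])
  if (sum(train) < min_train)
    stopf("only %d complete training days; %d required", sum(train),
          min_train)
  can_fill <- gap & complete.cases(series[preds])
  with_seed(seed, {
    rf <- randomForest::randomForest(x = series[train, preds],
                                     y = series[[target]][train],
                                     ntree = ntree, mtry = mtry)
    if (any(can_fill)) {
      pred <- predict(rf, series[can_fill, preds])
      pred <- if (target == "RH") pmin(100, pmax(0, pred))
              else pmax(sr_floor, pred)
      series[[target]][can_fill] <- pred
    }
  })
  attr(series, "imputed") <- can_fill
  attr(series, "unfilled") <- series$date[gap & !can_fill]
  series
}

#' Derive mean temperature and diurnal range
#'
#' TA = (TX + TM) / 2 and DR = TX - TM.  The `"paper_literal"` switch
#' reproduces the alternative printed convention TA = (TX - TM) / 2 for
#' cross-checking legacy outputs; the default keeps TM <= TA <= TX.
#'
#' @param series daily data.frame with `TX` and `TM`.
#' @param ta_formula `"mean"` (default) or `"paper_literal"`.
#' @return the series with `TA` and `DR` columns added.
#' @export
derive_ta_dr <- function(series, ta_formula = c("mean", "paper_literal")) {
  ta_formula <- match.arg(ta_formula)
  stopifnot(all(c("TX", "TM") %in% names(series)))
  series$TA <- if (ta_formula == "mean") (series$TX + series$TM) / 2
               else (series$TX - series$TM) / 2
  series$DR <- series$TX - series$TM
  series
}

#' Full weather preparation chain
#'
#' Quality control, VAR-based filling of TX/TM/P, forest-based filling of
#' RH/SR, and TA/DR derivation, producing one complete locality series.
#'
#' @param series raw daily data.frame with `date`, `TX`, `TM`, `P`, `RH`,
#'   `SR`.
#' @param limits QC limits ([qc_limits()]).
#' @param seed integer seed for the forest imputer.
#' @param ... passed to [impute_var_temperature_precip()].
#' @return complete series with `TA`/`DR`; attributes `"qc_report"` and the
#'   imputation masks of the component steps.
#' @export
prepare_weather <- function(series, limits = qc_limits(), seed = NULL, ...) {
  qc <- qc_daily(series, limits)
  s <- impute_var_temperature_precip(qc$series, ...)
  var_mask <- attr(s, "imputed")
  s <- impute_forest_rh_sr(s, "RH", seed = seed)
  rh_mask <- attr(s, "imputed")
  s <- impute_forest_rh_sr(s, "SR", seed = seed)
  sr_mask <- attr(s, "imputed")
  s <- derive_ta_dr(s)
  attr(s, "qc_report") <- qc$report
  attr(s, "imputed") <- cbind(var_mask, RH = rh_mask, SR = sr_mask)
  s
}
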