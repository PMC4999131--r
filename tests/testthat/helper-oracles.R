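## Independent brute-force oracles used across the suite.

## exhaustive DTW: enumerate every boundary-anchored monotone warping path
## (steps down/right/diagonal) and take the minimal cumulative |a_i - b_j|
dtw_enumerate <- function(a, b) {
  n <- length(a); m <- length(b)
  best <- Inf
  rec <- function(i, j, acc) {
    acc <- acc + abs(a[i] - b[j])
    if (acc >= best) return(invisible())
    if (i == n && j == m) {
      best <<- acc
      return(invisible())
    }
    if (i < n) rec(i + 1, j, acc)
    if (j < m) rec(i, j + 1, acc)
    if (i < n && j < m) rec(i + 1, j + 1, acc)
    invisible()
  }
  rec(1, 1, 0)
  best
}

## daily-loop recomputation of the 27 stage indicators for one event
indicators_by_loop <- function(event) {
  w <- event$window
  thr <- c(VEG = 35, REP = 37, RIP = 31)
  starts <- c(VEG = event$sowing_date,
              REP = event$stages$panicle_initiation,
              RIP = event$stages$heading)
  ends <- c(event$stages$panicle_initiation, event$stages$heading,
            event$harvest_date)
  out <- list()
  for (k in 1:3) {
    s <- names(starts)[k]
    acc <- list(TX = c(), TM = c(), TA = c(), DR = c(), P = c(),
                RH = c(), SR = c())
    for (r in seq_len(nrow(w))) {
      d <- w$date[r]
      if (d >= starts[[k]] && d < ends[[k]])
        for (v in names(acc)) acc[[v]] <- c(acc[[v]], w[[v]][r])
    }
    nd <- length(acc$TX)
    out[[paste0("TX_Avg_", s)]] <- mean(acc$TX)
    out[[paste0("TM_Avg_", s)]] <- mean(acc$TM)
    out[[paste0("TA_Avg_", s)]] <- mean(acc$TA)
    out[[paste0("DR_Avg_", s)]] <- mean(acc$DR)
    out[[sprintf("TX_%d_Freq_%s", thr[[s]], s)]] <-
      sum(acc$TX > thr[[s]]) / nd
    out[[paste0("P_Accu_", s)]] <- sum(acc$P)
    out[[paste0("P_10_Freq_", s)]] <- sum(acc$P > 10) / nd
    out[[paste0("RH_Avg_", s)]] <- mean(acc$RH)
    out[[paste0("SR_Accu_", s)]] <- sum(acc$SR)
  }
  unlist(out)[indicator_names()]
}

## per-day loop over an hourly fixture, mirroring the stated aggregation
## rules one day at a time
hourly_daily_by_loop <- function(hourly, min_completeness = 0.8) {
  days <- sort(unique(as.Date(hourly$time)))
  res <- data.frame(date = days, TX = NA_real_, TM = NA_real_,
                    P = NA_real_, RH = NA_real_, SR = NA_real_)
  for (i in seq_along(days)) {
    sel <- as.Date(hourly$time) == days[i]
    for (spec in list(list("temp", "TX", function(x) max(x)),
                      list("temp", "TM", function(x) min(x)),
                      list("P", "P", function(x) sum(x)),
                      list("RH", "RH", function(x) mean(x)),
                      list("SR", "SR", function(x) sum(x)))) {
      v <- hourly[[spec[[1]]]][sel]
      ok <- !is.na(v)
      if (sum(ok) > min_completeness * 24)
        res[i, spec[[2]]] <- spec[[3]](v[ok])
    }
  }
  res
}

## plain haversine with a fixed Earth radius
haversine_km <- function(lat1, lon1, lat2, lon2, r = 6378.137) {
  p <- pi / 180
  a <- sin((lat2 - lat1) * p / 2)^2 +
    cos(lat1 * p) * cos(lat2 * p) * sin((lon2 - lon1) * p / 2)^2
  2 * r * asin(sqrt(a))
}

## small complete synthetic weather fixture
tiny_weather <- function(n_days = 400, seed = 11, ...) {
  generate_daily_weather(weather_gen_params(seed = seed, ...),
                         "2010-01-01", n_days)
}
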