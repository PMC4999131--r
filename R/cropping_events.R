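#' Names of the 27 growth-stage indicators
#'
#' The standard indicator set: per growth stage (VEG, REP, RIP) the stage
#' means of TX, TM, TA, DR and RH, the stage-specific heat-exceedance
#' frequencies (TX > 35 in VEG, > 37 in REP, > 31 in RIP), accumulated
#' precipitation, the frequency of days with more than 10 mm precipitation,
#' and accumulated solar energy.
#'
#' @return character vector of the 27 indicator column names.
#' @export
indicator_names <- function() {
  stages <- c("VEG", "REP", "RIP")
  c(paste0("TX_Avg_", stages), paste0("TM_Avg_", stages),
    paste0("TA_Avg_", stages), paste0("DR_Avg_", stages),
    "TX_35_Freq_VEG", "TX_37_Freq_REP", "TX_31_Freq_RIP",
    paste0("P_Accu_", stages), paste0("P_10_Freq_", stages),
    paste0("RH_Avg_", stages), paste0("SR_Accu_", stages))
}

TX_THRESHOLDS <- c(VEG = 35, REP = 37, RIP = 31)

#' Standardize raw harvest records
#'
#' Canonicalizes cultivar and locality spellings through alias maps,
#' collapses exact duplicates of (locality, cultivar, harvest_date, yield),
#' and removes incoherent rows (non-positive yield, harvest on or before
#' sowing) with a reason log.
#'
#' @param raw data.frame with columns mappable to `locality`, `cultivar`,
#'   `sowing_date` (optional), `harvest_date`, `yield`.
#' @param column_map named character vector mapping canonical names to the
#'   raw column names, e.g. `c(yield = "rend_kg_ha")`; identity by default.
#' @param cultivar_aliases,locality_aliases named character vectors mapping
#'   raw spellings to canonical names (applied after upper-casing and
#'   removal of non-alphanumeric characters).
#' @return list: `records` (clean data.frame with an `event_id`) and
#'   `removed` (log with reasons).
#' @export
standardize_records <- function(raw, column_map = NULL,
                                cultivar_aliases = NULL,
                                locality_aliases = NULL) {
  canon <- c("locality", "cultivar", "sowing_date", "harvest_date", "yield")
  for (nm in names(column_map %||% character())) {
    if (!column_map[[nm]] %in% names(raw))
      stopf("mapped column '%s' (for %s) not found", column_map[[nm]], nm)
    names(raw)[names(raw) == column_map[[nm]]] <- nm
  }
  mandatory <- setdiff(canon, "sowing_date")
  if (!all(mandatory %in% names(raw)))
    stopf("missing mandatory columns: %s",
          paste(setdiff(mandatory, names(raw)), collapse = ", "))
  if (!"sowing_date" %in% names(raw)) raw$sowing_date <- as.Date(NA)
  norm_name <- function(x, aliases) {
    key <- toupper(gsub("[^[:alnum:]]", "", as.character(x)))
    if (!is.null(aliases)) {
      akey <- toupper(gsub("[^[:alnum:]]", "", names(aliases)))
      hit <- match(key, akey)
      key[!is.na(hit)] <- aliases[hit[!is.na(hit)]]
    }
    key
  }
  raw$cultivar <- norm_name(raw$cultivar, cultivar_aliases)
  raw$locality <- norm_name(raw$locality, locality_aliases)
  raw$sowing_date <- as.Date(raw$sowing_date)
  raw$harvest_date <- as.Date(raw$harvest_date)
  raw$yield <- as.numeric(raw$yield)

  removed <- data.frame(row = integer(), reason = character())
  bad_yield <- is.na(raw$yield) | raw$yield <= 0
  bad_order <- !is.na(raw$sowing_date) & raw$sowing_date >= raw$harvest_date
  bad_harv <- is.na(raw$harvest_date)
  drop <- bad_yield | bad_order | bad_harv
  if (any(drop))
    removed <- data.frame(
      row = which(drop),
      reason = ifelse(bad_harv[drop], "missing harvest date",
                      ifelse(bad_yield[drop], "non-positive or missing yield",
                             "sowing on or after harvest")))
  rec <- raw[!drop, , drop = FALSE]
  dup <- duplicated(rec[c("locality", "cultivar", "harvest_date", "yield")])
  if (any(dup))
    removed <- rbind(removed,
                     data.frame(row = which(!drop)[dup],
                                reason = "duplicate record"))
  rec <- rec[!dup, , drop = FALSE]
  rec$event_id <- sprintf("ev%05d", seq_len(nrow(rec)))
  rownames(rec) <- NULL
  list(records = rec[c("event_id", canon)], removed = removed)
}

#' Estimate missing sowing dates from the harvest date
#'
#' Where the sowing date is absent it is estimated by subtracting the
#' locality's typical cycle length from the harvest date (126 days in
#' Saldana, 128 in Villavicencio by default).  Records with a sowing date
#' are left unchanged.
#'
#' @param records harvest-record data.frame with `locality`,
#'   `sowing_date`, `harvest_date`.
#' @param cycle_map named integer vector locality -> cycle days.
#' @param default_cycle fallback cycle length for unmapped localities, or
#'   NULL to reject them.
#' @return the records with `sowing_date` completed and a logical column
#'   `sowing_estimated`.
#' @export
estimate_sowing_date <- function(records,
                                 cycle_map = c(SALDANA = 126L,
                                               VILLAVICENCIO = 128L),
                                 default_cycle = NULL) {
  names(cycle_map) <- toupper(gsub("[^[:alnum:]]", "", names(cycle_map)))
  key <- toupper(gsub("[^[:alnum:]]", "", records$locality))
  cyc <- cycle_map[key]
  need <- is.na(records$sowing_date)
  if (any(need & is.na(cyc))) {
    if (is.null(default_cycle))
      stopf("no cycle length configured for locality: %s",
            paste(unique(records$locality[need & is.na(cyc)]),
                  collapse = ", "))
    cyc[is.na(cyc)] <- default_cycle
  }
  records$sowing_estimated <- need
  records$sowing_date[need] <- records$harvest_date[need] -
    as.integer(cyc[need])
  records
}

#' Split a cropping cycle into growth stages
#'
#' Scales a cultivar's reference stage durations proportionally to the
#' actual cycle length (harvest minus sowing, days), with largest-remainder
#' rounding so the three stage lengths sum exactly to the actual cycle.
#'
#' @param sowing,harvest Dates.
#' @param profile one-row cultivar profile with `veg_days`, `rep_days`,
#'   `rip_days`, `reference_cycle`.
#' @param plausible_cycle admissible actual cycle range (days); events
#'   outside are rejected as implausible.
#' @return list: `lengths` (named integer VEG/REP/RIP),
#'   `panicle_initiation` and `heading` (Dates).
#' @export
split_growth_stages <- function(sowing, harvest, profile,
                                plausible_cycle = c(60L, 200L)) {
  sowing <- as.Date(sowing); harvest <- as.Date(harvest)
  actual <- as.integer(harvest - sowing)
  if (actual < plausible_cycle[1] || actual > plausible_cycle[2])
    stopf("implausible cycle length of %d days (admissible %d-%d)",
          actual, plausible_cycle[1], plausible_cycle[2])
  ref <- c(profile$veg_days, profile$rep_days, profile$rip_days)
  if (any(ref <= 0) || sum(ref) != profile$reference_cycle)
    stopf("stage profile must be positive and sum to the reference cycle")
  raw <- ref * actual / sum(ref)
  lengths <- floor(raw)
  rem <- actual - sum(lengths)
  if (rem > 0) {
    order_rem <- order(raw - floor(raw), decreasing = TRUE)
    lengths[order_rem[seq_len(rem)]] <- lengths[order_rem[seq_len(rem)]] + 1L
  }
  lengths <- as.integer(lengths)
  names(lengths) <- c("VEG", "REP", "RIP")
  if (any(lengths == 0)) stopf("stage of zero length after scaling")
  list(lengths = lengths,
       panicle_initiation = sowing + lengths[["VEG"]],
       heading = sowing + lengths[["VEG"]] + lengths[["REP"]])
}

#' Attach the daily weather window to a harvest record
#'
#' Slices the locality series over `[sowing, harvest]` (both endpoints
#' included) and computes the growth-stage boundaries from the cultivar's
#' profile.  Records whose window is not completely covered are rejected
#' with an explicit reason.
#'
#' @param record one-row data.frame with `event_id`, `cultivar`,
#'   `sowing_date`, `harvest_date`, `yield` (may be NA).
#' @param locality_series prepared daily weather series covering the window.
#' @param profiles cultivar profile table ([cultivar_profiles()]).
#' @return an object of class `cropping_event`: list with the record
#'   fields, `stages` (from [split_growth_stages()]) and `window` (daily
#'   data.frame with TA/DR derived).
#' @export
attach_weather_window <- function(record, locality_series,
                                  profiles = NULL) {
  profiles <- profiles %||% attr(record, "cultivar_profiles") %||%
    cultivar_profiles()
  sow <- as.Date(record$sowing_date)
  harv <- as.Date(record$harvest_date)
  idx <- locality_series$date >= sow & locality_series$date <= harv
  window <- locality_series[idx, , drop = FALSE]
  expected <- as.integer(harv - sow) + 1L
  if (nrow(window) != expected ||
      anyNA(window[intersect(c("TX", "TM", "P", "RH", "SR"),
                             names(window))]))
    stopf("event %s: weather window %s..%s not completely covered",
          record$event_id, format(sow), format(harv))
  prow <- profiles[profiles$cultivar == as.character(record$cultivar), ]
  if (nrow(prow) != 1)
    stopf("no stage profile for cultivar %s", record$cultivar)
  stages <- split_growth_stages(sow, harv, prow)
  if (!all(c("TA", "DR") %in% names(window)))
    window <- derive_ta_dr(window)
  structure(list(event_id = record$event_id,
                 locality = record$locality %||% NA_character_,
                 cultivar = as.character(record$cultivar),
                 sowing_date = sow, harvest_date = harv,
                 yield = record$yield %||% NA_real_,
                 stages = stages, window = window),
            class = "cropping_event")
}

#' @export
print.cropping_event <- function(x, ...) {
  cat(sprintf("<cropping_event %s: %s, %s -> %s (%d d), stages %s>\n",
              x$event_id, x$cultivar, format(x$sowing_date),
              format(x$harvest_date),
              as.integer(x$harvest_date - x$sowing_date),
              paste(x$stages$lengths, collapse = "/")))
  invisible(x)
}

stage_day_index <- function(event) {
  d <- event$window$date
  pi_ <- event$stages$panicle_initiation
  hd <- event$stages$heading
  ## half-open stage intervals [start, next_start); the harvest day itself
  ## closes the cycle and belongs to no stage
  list(VEG = d >= event$sowing_date & d < pi_,
       REP = d >= pi_ & d < hd,
       RIP = d >= hd & d < event$harvest_date)
}

#' Compute the 27 growth-stage indicators for one cropping event
#'
#' Per stage: arithmetic means of TX, TM, TA, DR and RH; exceedance
#' frequencies of TX strictly above the stage threshold (35 degrees C in
#' VEG, 37 in REP, 31 in RIP); accumulated P and SR; and the proportion of
#' days with strictly more than 10 mm precipitation.
#'
#' @param event a [attach_weather_window()] `cropping_event`.
#' @return one-row data.frame: `event_id`, `Cultivar`, the 27 indicators,
#'   `Yield`.
#' @export
compute_stage_indicators <- function(event) {
  stopifnot(inherits(event, "cropping_event"))
  idx <- stage_day_index(event)
  w <- event$window
  out <- list(event_id = event$event_id,
              Cultivar = event$cultivar)
  for (s in c("VEG", "REP", "RIP")) {
    sel <- idx[[s]]
    nd <- sum(sel)
    if (nd == 0) stopf("event %s: empty %s stage", event$event_id, s)
    out[[paste0("TX_Avg_", s)]] <- mean(w$TX[sel])
    out[[paste0("TM_Avg_", s)]] <- mean(w$TM[sel])
    out[[paste0("TA_Avg_", s)]] <- mean(w$TA[sel])
    out[[paste0("DR_Avg_", s)]] <- mean(w$DR[sel])
    out[[sprintf("TX_%d_Freq_%s", TX_THRESHOLDS[[s]], s)]] <-
      sum(w$TX[sel] > TX_THRESHOLDS[[s]]) / nd
    out[[paste0("P_Accu_", s)]] <- sum(w$P[sel])
    out[[paste0("P_10_Freq_", s)]] <- sum(w$P[sel] > 10) / nd
    out[[paste0("RH_Avg_", s)]] <- mean(w$RH[sel])
    out[[paste0("SR_Accu_", s)]] <- sum(w$SR[sel])
  }
  out$Yield <- event$yield
  as.data.frame(out[c("event_id", "Cultivar", indicator_names(), "Yield")])
}

#' Bind per-event indicator rows into one table
#'
#' @param rows list of one-row data.frames from
#'   [compute_stage_indicators()].
#' @return data.frame with `event_id`, `Cultivar` (factor), the 27
#'   indicators and `Yield`.
#' @export
build_indicator_table <- function(rows) {
  tab <- do.call(rbind, rows)
  tab$Cultivar <- factor(tab$Cultivar)
  rownames(tab) <- NULL
  tab
}

#' Remove degenerate predictors and outlying events
#'
#' Drops indicator columns with (near-)zero variability (absolute standard
#' deviation below `variance_tol`, or coefficient of variation below
#' `cv_tol` when the mean is nonzero) and event rows where the yield or any
#' surviving predictor falls outside `median +/- 3 IQR`, computed per
#' locality when a `locality` column is present.  Every removal is logged
#' with its reason.
#'
#' @param table indicator table from [build_indicator_table()].
#' @param variance_tol absolute standard-deviation threshold.
#' @param cv_tol coefficient-of-variation threshold (`NULL` disables).
#' @param iqr_mult fence width in IQR multiples.
#' @return list: `table` (cleaned), `removed_columns`,
#'   `removed_rows` (logs with reasons).
#' @export
clean_indicator_table <- function(table, variance_tol = 1e-8,
                                  cv_tol = 0.01, iqr_mult = 3) {
  stopifnot(nrow(table) > 0)
  preds <- intersect(indicator_names(), names(table))
  drop_cols <- character(); col_reason <- character()
  for (v in preds) {
    x <- table[[v]]
    s <- sd(x)
    m <- mean(x)
    if (s < variance_tol) {
      drop_cols <- c(drop_cols, v)
      col_reason <- c(col_reason, "near-zero variance")
    } else if (!is.null(cv_tol) && abs(m) > 0 && s / abs(m) < cv_tol) {
      drop_cols <- c(drop_cols, v)
      col_reason <- c(col_reason, sprintf("coefficient of variation < %g",
                                          cv_tol))
    }
  }
  keep_preds <- setdiff(preds, drop_cols)
  fence_bad <- function(x) {
    md <- median(x); iq <- stats::IQR(x)
    ## a degenerate spread (half the values identical) gives no usable
    ## fence; skip rather than flag every non-median value
    if (iq == 0) return(rep(FALSE, length(x)))
    x < md - iqr_mult * iq | x > md + iqr_mult * iq
  }
  grp <- if ("locality" %in% names(table)) table$locality else
    rep("all", nrow(table))
  bad_row <- rep(FALSE, nrow(table))
  row_reason <- rep(NA_character_, nrow(table))
  for (g in unique(grp)) {
    sel <- which(grp == g)
    for (v in c(keep_preds, "Yield")) {
      b <- fence_bad(table[[v]][sel])
      new <- sel[b & !bad_row[sel]]
      row_reason[new] <- sprintf("%s outside median +/- %g IQR", v, iqr_mult)
      bad_row[sel[b]] <- TRUE
    }
  }
  out <- table[!bad_row, setdiff(names(table), drop_cols), drop = FALSE]
  if (nrow(out) == 0) stopf("all rows removed by outlier screening")
  list(table = out,
       removed_columns = data.frame(column = drop_cols,
                                    reason = col_reason),
       removed_rows = data.frame(
         event_id = table$event_id[bad_row],
         reason = row_reason[bad_row]))
}
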