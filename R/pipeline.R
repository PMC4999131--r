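#' Structured configuration for the analysis pipeline
#'
#' One nested list holds every scientific setting of a run (generator
#' parameters, QC limits, forest and ensemble settings, clustering
#' options, seeds) so that a run is auditable and reproducible from its
#' configuration alone.  The configuration round-trips losslessly through
#' JSON ([jsonlite]).
#'
#' @param n_events number of synthetic cropping events.
#' @param n_days length of the synthetic weather series.
#' @param target_r2 population R-squared the yield noise is calibrated to.
#' @param ntree,runs forest and ensemble sizes.
#' @param k_min,k_max cluster-number search range.
#' @param cluster_events number of events entering the pattern clustering
#'   (a subset keeps the distance matrix tractable; `NULL` uses all).
#' @param seed master seed.
#' @param ... further entries stored verbatim.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_events = 600, n_days = 1200,
                            target_r2 = 0.35, ntree = 200, runs = 20,
                            k_min = 2, k_max = 20, cluster_events = 120,
                            seed = 1L, ...) {
  structure(list(n_events = as.integer(n_events),
                 n_days = as.integer(n_days), target_r2 = target_r2,
                 ntree = as.integer(ntree), runs = as.integer(runs),
                 k_min = as.integer(k_min), k_max = as.integer(k_max),
                 cluster_events = if (is.null(cluster_events)) NULL
                 else as.integer(cluster_events),
                 seed = as.integer(seed), ...),
            class = "pipeline_config")
}

write_manifest <- function(path, config, stages) {
  jsonlite::write_json(
    list(package = "agroclim",
         version = as.character(utils::packageVersion("agroclim")),
         timestamp = format(Sys.time(), tz = "UTC"),
         config = unclass(config), stages = stages),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
}

log_line <- function(con, fmt, ...) {
  writeLines(sprintf(fmt, ...), con)
}

#' Simulate a synthetic study and write its files
#'
#' Generates weather, cropping events and ground-truth yields under the
#' configuration and writes `weather.csv`, `events.csv`, `truth.json`, a
#' run `manifest.json` and `run.log` into `out_dir`.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return (invisibly) the list returned by
#'   [simulate_indicator_dataset()], with the file paths in attribute
#'   `"files"`.
#' @export
cmd_simulate <- function(config = pipeline_config(), out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stopf("cannot create output directory %s", out_dir)
  t0 <- Sys.time()
  sim <- simulate_indicator_dataset(n_events = config$n_events,
                                    target_r2 = config$target_r2,
                                    n_days = config$n_days,
                                    seed = config$seed)
  files <- file.path(out_dir, c("weather.csv", "events.csv", "truth.json",
                                "manifest.json", "run.log"))
  names(files) <- c("weather", "events", "truth", "manifest", "log")
  w <- sim$weather
  w$date <- format(w$date, "%Y-%m-%d")
  write.csv(w, files["weather"], row.names = FALSE)
  ev <- sim$events
  ev$sowing_date <- format(ev$sowing_date, "%Y-%m-%d")
  ev$harvest_date <- format(ev$harvest_date, "%Y-%m-%d")
  write.csv(as.data.frame(ev), files["events"], row.names = FALSE)
  jsonlite::write_json(
    list(response = list(base_yield = sim$response$base_yield,
                         cultivar_effects = as.list(sim$response$cultivar_effects),
                         driver_terms = sim$response$driver_terms,
                         noise_sd = sim$response$noise_sd,
                         yield_floor = sim$response$yield_floor),
         seed = config$seed),
    files["truth"], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  stages <- list(simulate = list(
    n_weather_days = nrow(sim$weather),
    n_events = nrow(sim$events),
    seconds = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2)))
  write_manifest(files["manifest"], config, stages)
  con <- file(files["log"], "w")
  log_line(con, "simulate: %d weather days, %d events, seed %d",
           nrow(sim$weather), nrow(sim$events), config$seed)
  close(con)
  attr(sim, "files") <- files
  invisible(sim)
}

#' Run the full synthetic analysis pipeline and write its reports
#'
#' Simulation, indicator construction, variable-importance ensemble,
#' partial dependence of the top predictor, and DTW pattern clustering
#' with yield and cultivar analysis; writes the indicator table, per-run
#' and final importance tables with letters, partial-dependence profile,
#' cluster labels and summaries, a manifest and a log into `out_dir`.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @return (invisibly) list with the main in-memory results (`vi`, `pd`,
#'   `clusters`, `yield_summary`, `cultivar_tests`, `indicators`).
#' @export
cmd_run_all <- function(config = pipeline_config(), out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stopf("cannot create output directory %s", out_dir)
  con <- file(file.path(out_dir, "run.log"), "w")
  on.exit(close(con))
  stages <- list()
  tick <- function(label, t0, ...) {
    stages[[label]] <<- c(list(...),
      seconds = round(as.numeric(difftime(Sys.time(), t0,
                                          units = "secs")), 2))
    log_line(con, "%s done (%.1fs)", label, stages[[label]]$seconds)
  }

  t0 <- Sys.time()
  sim <- simulate_indicator_dataset(n_events = config$n_events,
                                    target_r2 = config$target_r2,
                                    n_days = config$n_days,
                                    seed = config$seed)
  tick("simulate", t0, n_events = nrow(sim$events))

  t0 <- Sys.time()
  cleaned <- clean_indicator_table(sim$indicators)
  tab <- cleaned$table
  write.csv(tab, file.path(out_dir, "indicators.csv"), row.names = FALSE)
  write.csv(cleaned$removed_rows, file.path(out_dir, "removals.csv"),
            row.names = FALSE)
  tick("indicators", t0, rows_in = nrow(sim$indicators),
       rows_out = nrow(tab), columns_dropped = nrow(cleaned$removed_columns))

  t0 <- Sys.time()
  vi <- vi_ensemble(tab, control = cif_control(ntree = config$ntree),
                    runs = config$runs, seed = config$seed)
  write.csv(data.frame(run = seq_len(nrow(vi$scaled)), r2 = vi$r2,
                       vi$scaled, check.names = FALSE),
            file.path(out_dir, "vi_runs.csv"), row.names = FALSE)
  write.csv(summary(vi), file.path(out_dir, "vi_final.csv"),
            row.names = FALSE)
  tick("vi_ensemble", t0, runs = nrow(vi$scaled),
       mean_r2 = round(mean(vi$r2), 4))

  t0 <- Sys.time()
  top <- names(vi$final_vi)[vi$final_vi > 0 &
                              names(vi$final_vi) != "Cultivar"][1]
  fit <- cif_forest(tab[setdiff(names(tab), c("event_id", "Yield"))],
                    tab$Yield, control = cif_control(ntree = config$ntree),
                    seed = config$seed)
  pd <- partial_dependence(fit, top)
  write.csv(data.frame(predictor = top, pd),
            file.path(out_dir, "pd_profile.csv"), row.names = FALSE)
  tick("partial_dependence", t0, predictor = top)

  t0 <- Sys.time()
  ev_ids <- sim$indicators$event_id
  if (!is.null(config$cluster_events) &&
      length(ev_ids) > config$cluster_events)
    ev_ids <- with_seed(config$seed,
                        sample(ev_ids, config$cluster_events))
  sel <- sim$events$event_id %in% ev_ids
  bundles <- lapply(which(sel), function(j)
    event_series_bundle(attach_weather_window(sim$events[j, ],
                                              sim$weather)))
  cl <- weather_pattern_clusters(bundles, k_min = config$k_min,
                                 k_max = config$k_max)
  ys <- cluster_yield_analysis(cl$labels, cl$yields)
  cw <- cultivar_within_cluster(cl$labels, cl$yields, cl$cultivars)
  write.csv(data.frame(event_id = names(cl$labels), cluster = cl$labels,
                       yield = cl$yields, cultivar = cl$cultivars),
            file.path(out_dir, "cluster_labels.csv"), row.names = FALSE)
  summ <- ys$summary
  if (!is.null(ys$letters))
    summ$letters <- ys$letters$letters[as.character(summ$cluster)]
  write.csv(summ, file.path(out_dir, "cluster_summary.csv"),
            row.names = FALSE)
  tick("clustering", t0, n_events = length(bundles), k = cl$k)

  write_manifest(file.path(out_dir, "manifest.json"), config, stages)
  invisible(list(vi = vi, pd = pd, clusters = cl, yield_summary = ys,
                 cultivar_tests = cw, indicators = tab))
}
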