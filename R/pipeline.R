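#' End-to-end behavioral pipeline
#'
#' Simulate (or ingest) a cohort, segment every session into laps,
#' compute session- and day-level behavioral metrics, per-animal
#' day-level chance bands from trial shuffling, and group statistics
#' (mixed two-way ANOVA on the day curves when two or more groups are
#' present).  All analysis parameters default to the protocol registry
#' in [analysis_defaults()]; everything random flows from `seed`, so a
#' rerun with the same configuration is bit-identical.
#'
#' @param config list with elements:
#'   \describe{
#'     \item{cohort}{simulation spec passed to [simulate_experiment()]:
#'       `groups`, `days`, `sessions_per_day`, `task`.  Alternatively
#'       `log_paths`: character vector of session-log files to ingest.}
#'     \item{seed}{integer seed.}
#'     \item{n_shuffles}{shuffles for the chance bands (default from the
#'       registry; bands are skipped when 0).}
#'     \item{chance_metric}{`"correct"` or `"rule"` (default both).}
#'   }
#' @param out_dir optional directory; when given, tidy tables
#'   (`session_metrics.csv`, `day_metrics.csv`, `chance_bands.csv`,
#'   `anova.csv`) plus `summary.json` and `manifest.json` are written.
#' @param maze a [maze_config()].
#' @return list with `session_metrics`, `day_metrics`, `chance_bands`,
#'   `anova` (NULL for a single group), `manifest`.
#' @export
run_behavior_pipeline <- function(config, out_dir = NULL,
                                  maze = maze_config()) {
  seed <- config$seed %||% 1L
  n_shuffles <- config$n_shuffles %||% analysis_defaults()$n_shuffles
  metrics_wanted <- config$chance_metric %||% c("correct", "rule")
  set.seed(seed)
  if (!is.null(config$cohort)) {
    co <- config$cohort
    sim <- simulate_experiment(co$groups, days = co$days %||% 5,
                               sessions_per_day = co$sessions_per_day %||% 4,
                               task = co$task %||% "FRL", maze = maze)
    logs <- sim$logs
    meta <- sim$sessions
  } else if (!is.null(config$log_paths)) {
    logs <- lapply(config$log_paths, read_session_log, maze = maze)
    meta <- do.call(rbind, lapply(seq_along(logs), function(i)
      data.frame(animal_id = logs[[i]]$animal_id, group = "all",
                 day = logs[[i]]$day,
                 session_index = logs[[i]]$session_index,
                 rewarded_feeder = logs[[i]]$rewarded_feeder, log = i)))
  } else stop("config must provide either 'cohort' or 'log_paths'")

  laps_list <- lapply(logs, segment_laps, maze = maze)
  sess <- do.call(rbind, lapply(seq_along(laps_list), function(i)
    cbind(meta[i, c("animal_id", "group", "day", "session_index")],
          session_metrics(laps_list[[i]]))))
  rownames(sess) <- NULL

  day <- do.call(rbind, lapply(
    split(seq_len(nrow(sess)), list(sess$animal_id, sess$day), drop = TRUE),
    function(idx) cbind(group = sess$group[idx[1]],
                        aggregate_day(sess[idx, ]))))
  day <- day[order(day$animal_id, day$day), ]
  rownames(day) <- NULL

  chance <- NULL
  if (n_shuffles > 0) {
    rows <- list()
    for (an in unique(meta$animal_id)) {
      for (d in unique(meta$day[meta$animal_id == an])) {
        idx <- which(meta$animal_id == an & meta$day == d)
        usable <- Filter(function(i) length(complete_laps(laps_list[[i]])) > 0,
                         idx)
        if (!length(usable)) next
        for (metric in metrics_wanted) {
          band <- day_chance_band(laps_list[usable], metric = metric,
                                  n_shuffles = n_shuffles)
          rows[[length(rows) + 1L]] <- data.frame(
            animal_id = an, day = d, metric = metric,
            observed = band$observed, band_lo = band$band[1],
            band_hi = band$band[2], p_value = band$p_value,
            learned = band$exceeds_all)
        }
      }
    }
    chance <- do.call(rbind, rows)
  }

  anova <- NULL
  if (length(unique(day$group)) >= 2 && length(unique(day$day)) >= 2) {
    anova <- do.call(rbind, lapply(
      c("correct_response_rate", "rule_learning_rate", "n_laps",
        "mean_speed_cm_s"),
      function(v) {
        d <- day[!is.na(day[[v]]), ]
        res <- try(mixed_anova_gg(d, value = v, subject = "animal_id",
                                  within = "day", between = "group"),
                   silent = TRUE)
        if (inherits(res, "try-error")) return(NULL)
        cbind(outcome = v, res)
      }))
  }

  manifest <- list(pipeline = "behavior", seed = seed,
                   n_sessions = length(logs), n_shuffles = n_shuffles,
                   parameters = analysis_defaults())
  out <- list(session_metrics = sess, day_metrics = day,
              chance_bands = chance, anova = anova, manifest = manifest)
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

#' End-to-end photometry pipeline
#'
#' For each (sensor kind, stimulation duration) condition: simulate (or
#' read) a trace, build the peri-event matrix, Z-score it, and report
#' phase means and suprathreshold trial counts.
#'
#' @param config list with `conditions` (data.frame or list of lists
#'   with `sensor_kind`, `duration`), optional `protocol` args, `seed`,
#'   and optional `models` (named `sensor_kind.duration` ->
#'   [photo_model()], overriding the presets).
#' @param out_dir optional output directory (writes `photometry.csv`,
#'   `summary.json`, `manifest.json`).
#' @return list with `summary` (one row per condition: phase means,
#'   exceedance count, trials) and `manifest`.
#' @export
run_photometry_pipeline <- function(config = list(), out_dir = NULL) {
  seed <- config$seed %||% 1L
  conditions <- config$conditions %||%
    expand.grid(sensor_kind = c("GCaMP6f", "GRAB_DA2h"),
                duration = c("short_10ms", "long_40ms"),
                stringsAsFactors = FALSE)
  protocol <- do.call(stim_protocol, config$protocol %||% list())
  rows <- list()
  for (i in seq_len(nrow(conditions))) {
    sk <- conditions$sensor_kind[i]
    du <- conditions$duration[i]
    key <- paste(sk, du, sep = ".")
    model <- (config$models %||% list())[[key]] %||%
      photo_model(sensor_kind = sk, duration = du)
    tr <- simulate_photometry(model, protocol, seed = seed + i)
    peth <- compute_peth(tr)
    z <- zscore_peth(peth)
    ph <- phase_means(peth)
    ex <- count_exceedances(z)
    rows[[i]] <- data.frame(sensor_kind = sk, duration = du,
                            n_trials = nrow(peth),
                            stim_mean_pct = ph$mean[["stim"]],
                            early_mean_pct = ph$mean[["early"]],
                            late_mean_pct = ph$mean[["late"]],
                            exceedance_count = ex$count)
  }
  summary <- do.call(rbind, rows)
  manifest <- list(pipeline = "photometry", seed = seed,
                   protocol = protocol[c("total_min", "cycle_s", "stim_s",
                                         "freq_hz", "fs", "n_sessions")],
                   parameters = analysis_defaults())
  out <- list(summary = summary, manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(summary, file.path(out_dir, "photometry.csv"),
                     row.names = FALSE)
    jsonlite::write_json(out, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

write_pipeline_outputs <- function(out, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(out$session_metrics,
                   file.path(out_dir, "session_metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(out$day_metrics, file.path(out_dir, "day_metrics.csv"),
                   row.names = FALSE)
  if (!is.null(out$chance_bands))
    utils::write.csv(out$chance_bands,
                     file.path(out_dir, "chance_bands.csv"),
                     row.names = FALSE)
  if (!is.null(out$anova))
    utils::write.csv(out$anova, file.path(out_dir, "anova.csv"),
                     row.names = FALSE)
  jsonlite::write_json(
    list(day_metrics = out$day_metrics, chance_bands = out$chance_bands,
         anova = out$anova, manifest = out$manifest),
    file.path(out_dir, "summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(out$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
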