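# Configuration-driven orchestration: simulate datasets to disk and run the
# full analysis (classification, metrics, aggregation, statistics) from a
# YAML or list configuration. These are the entry points the analysis
# scripts drive; every computation lives in the module functions.

DEFAULT_ANALYZE_CONFIG <- list(
  tracks = NULL, contexts = NULL, manifest = NULL, out_dir = NULL,
  thresholds = list(static_speed_nm_s = 25, static_total_nm = 1000,
                    bidirectional_nm = 1500, min_dwell_s = 1.2,
                    min_disp_nm = 525),
  stats = list(level = "mt", gate_alpha = 0.05, posthoc = "conover",
               adjust = "holm",
               metrics = c("landing_rate_um_min", "event_freq_um_s",
                           "mean_run_length_nm", "mean_dwell_time_s",
                           "mean_speed_nm_s")),
  seed = 1L
)

merge_config <- function(defaults, config, where = "config") {
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0)
    stop("unknown ", where, " key(s): ", paste(unknown, collapse = ", "))
  for (nm in names(config)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]])) &&
        is.list(config[[nm]]))
      defaults[[nm]] <- merge_config(defaults[[nm]], config[[nm]],
                                     paste0(where, "$", nm))
    else defaults[[nm]] <- config[[nm]]
  }
  defaults
}

load_config <- function(config, defaults) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  merge_config(defaults, config)
}

#' Run the analysis pipeline from a configuration
#'
#' Reads tracks, contexts and manifest; orients tracks to the plus-end
#' positive convention; classifies directionality; computes per-track and
#' per-microtubule metrics; aggregates superplot summaries; and, when the
#' manifest contains more than one condition, runs the group-comparison
#' battery on the configured per-microtubule metrics. All outputs are
#' written as CSV/JSON under `out_dir` together with a run log. The run is
#' deterministic: identical inputs and configuration give identical
#' numeric outputs.
#'
#' @param config List or YAML path with keys `tracks`, `contexts`,
#'   `manifest` (CSV paths), `out_dir`, and optional `thresholds` and
#'   `stats` blocks (see the vignette). Unknown keys are rejected.
#' @return Invisible list of the computed tables (classifications,
#'   track-level metrics, microtubule-level metrics, superplot summaries,
#'   stats report).
#' @export
run_analyze <- function(config) {
  cfg <- load_config(config, DEFAULT_ANALYZE_CONFIG)
  for (key in c("tracks", "contexts", "manifest", "out_dir"))
    if (is.null(cfg[[key]])) stop("config key '", key, "' is required")
  thr <- cfg$thresholds
  contexts <- read_contexts(cfg$contexts)
  vertices <- read_tracks(cfg$tracks, contexts)
  manifest <- read_manifest(cfg$manifest, contexts)
  vertices <- orient_tracks(vertices, contexts)
  message(sprintf("read %d tracks on %d microtubules",
                  length(unique(vertices$track_id)), nrow(contexts)))

  cls <- classify_tracks(vertices,
                         list(static_speed_nm_s = thr$static_speed_nm_s,
                              static_total_nm = thr$static_total_nm,
                              bidirectional_nm = thr$bidirectional_nm))
  message("classified: ",
          paste(sprintf("%s=%d", names(table(cls$label)), table(cls$label)),
                collapse = ", "))
  tm <- tracks_metrics(vertices, thr$static_speed_nm_s)
  mt <- per_mt_metrics(vertices, contexts, thr$min_dwell_s, thr$min_disp_nm,
                       thr$static_speed_nm_s)
  dirprop <- directionality_proportions(cls, manifest)

  superplots <- list()
  for (metric in intersect(cfg$stats$metrics, names(mt))) {
    vals <- mt[!is.na(mt[[metric]]), c("context_id", metric)]
    if (nrow(vals) > 0)
      superplots[[metric]] <- aggregate_values(vals, manifest, metric,
                                               level = cfg$stats$level)
  }

  stats_report <- NULL
  conds <- unique(manifest$condition)
  if (length(conds) > 1) {
    stats_report <- list()
    cond_of <- manifest$condition[match(mt$context_id, manifest$context_id)]
    for (metric in intersect(cfg$stats$metrics, names(mt))) {
      ok <- !is.na(mt[[metric]])
      groups <- split(mt[[metric]][ok], cond_of[ok])
      groups <- groups[vapply(groups, length, 1L) > 0]
      if (length(groups) < 2) next
      stats_report[[metric]] <- compare_groups(
        groups, gate_alpha = cfg$stats$gate_alpha,
        posthoc = cfg$stats$posthoc, adjust = cfg$stats$adjust)
    }
  }

  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(df, name)
    utils::write.csv(df, file.path(cfg$out_dir, name), row.names = FALSE)
  wcsv(cls, "per_track_classifications.csv")
  wcsv(tm, "per_track_metrics.csv")
  wcsv(mt, "per_mt_metrics.csv")
  if (length(superplots) > 0)
    wcsv(do.call(rbind, lapply(superplots, superplot_table)),
         "superplot_summaries.csv")
  wcsv(dirprop$pooled, "directionality_pooled.csv")
  wcsv(dirprop$experiment_summary, "directionality_per_experiment.csv")
  if (!is.null(stats_report)) {
    rep_json <- lapply(stats_report, function(r) list(
      path = r$path,
      normality = r$normality,
      omnibus = if (is.null(r$omnibus)) NULL else
        list(method = r$omnibus$method, statistic = r$omnibus$statistic,
             df = r$omnibus$df, p_value = r$omnibus$p_value),
      pairwise = r$pairwise))
    jsonlite::write_json(rep_json, file.path(cfg$out_dir, "stats_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  log <- list(timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
              package_version = as.character(utils::packageVersion("kymotility")),
              r_version = R.version.string,
              config = cfg[setdiff(names(cfg), "out_dir")],
              n_tracks = length(unique(vertices$track_id)),
              n_contexts = nrow(contexts),
              class_counts = as.list(table(cls$label)))
  jsonlite::write_json(log, file.path(cfg$out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(classifications = cls, track_metrics = tm, mt_metrics = mt,
                 directionality = dirprop, superplots = superplots,
                 stats = stats_report))
}

DEFAULT_SIMULATE_CONFIG <- list(preset = NULL, params = NULL, out_dir = NULL,
                                seed = 1L)

#' Simulate a dataset to disk
#'
#' Thin wrapper over [simulate_trackset()]: builds parameters from a preset
#' name (or takes a [sim_params()] object), runs the simulation, and writes
#' the track/context/manifest CSVs, the ground truth (JSON) and the
#' parameters (YAML) under `out_dir`.
#'
#' @param config List or YAML path: `preset` (one of the [sim_preset()]
#'   names) or `params` (a `sim_params` object), `out_dir`, `seed`.
#' @return Invisible simulation result list (see [simulate_trackset()]).
#' @export
run_simulate <- function(config) {
  cfg <- load_config(config, DEFAULT_SIMULATE_CONFIG)
  if (is.null(cfg$out_dir)) stop("config key 'out_dir' is required")
  params <- if (!is.null(cfg$params)) cfg$params
            else if (!is.null(cfg$preset)) sim_preset(cfg$preset, seed = cfg$seed)
            else stop("config needs either 'preset' or 'params'")
  if (!inherits(params, "sim_params")) stop("'params' must be a sim_params object")
  sim <- simulate_trackset(params)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_tracks(sim$tracks, file.path(cfg$out_dir, "tracks.csv"))
  write_tracks(sim$frames, file.path(cfg$out_dir, "frames.csv"))
  write_contexts(sim$contexts, file.path(cfg$out_dir, "contexts.csv"))
  utils::write.csv(sim$manifest, file.path(cfg$out_dir, "manifest.csv"),
                   row.names = FALSE)
  jsonlite::write_json(sim$truth, file.path(cfg$out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  par_out <- params[c("landing_rate_um_s", "mt_length_nm", "duration_s",
                      "frame_interval_s", "pixel_size_nm", "noise_sd_nm",
                      "n_experiments", "movies_per_experiment",
                      "mts_per_movie", "condition", "seed")]
  par_out$populations <- lapply(params$populations, function(p)
    list(name = p$name, weight = p$weight))
  yaml::write_yaml(par_out, file.path(cfg$out_dir, "params.yaml"))
  message(sprintf("simulated %d tracks on %d microtubules (seed %d)",
                  length(unique(sim$tracks$track_id)), nrow(sim$contexts),
                  params$seed))
  invisible(sim)
}
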