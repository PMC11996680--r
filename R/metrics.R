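# Per-track and per-microtubule motility metrics: run length, dwell time,
# average speed, landing rate, and processive-event detection.

#' Motility metrics for one segmented track
#'
#' Dwell time is the total time the complex stays on the microtubule,
#' including pauses (last vertex time minus first). Total run length is the
#' sum of the absolute lengths of all runs; average speed is total run
#' length divided by dwell time (so a purely paused track has speed 0).
#'
#' @param t_s Vertex times of the track.
#' @param runs,pauses Outputs of [segment_runs()].
#' @return One-row data frame: `total_run_length_nm`, `plus_run_length_nm`,
#'   `minus_run_length_nm`, `dwell_time_s`, `average_speed_nm_s`,
#'   `time_plus_s`, `time_minus_s`, `time_paused_s`.
#' @export
track_metrics <- function(t_s, runs, pauses) {
  dwell <- t_s[length(t_s)] - t_s[1]
  plus_len <- sum(runs$length_nm[runs$direction == "plus"])
  minus_len <- sum(runs$length_nm[runs$direction == "minus"])
  total <- plus_len + minus_len
  data.frame(
    total_run_length_nm = total,
    plus_run_length_nm = plus_len,
    minus_run_length_nm = minus_len,
    dwell_time_s = dwell,
    average_speed_nm_s = if (dwell > 0) total / dwell else 0,
    time_plus_s = sum(runs$duration_s[runs$direction == "plus"]),
    time_minus_s = sum(runs$duration_s[runs$direction == "minus"]),
    time_paused_s = sum(pauses$duration_s)
  )
}

#' Metrics for every track in a vertex table
#'
#' @param vertices Oriented, validated vertex table.
#' @param static_speed_nm_s Static-speed threshold for [segment_runs()].
#' @return Data frame with one row per track (`track_id`, `context_id`,
#'   then the [track_metrics()] columns).
#' @export
tracks_metrics <- function(vertices, static_speed_nm_s = 25) {
  tracks <- split_tracks(vertices)
  rows <- lapply(tracks, function(tr) {
    seg <- compute_segments(tr$t_s, tr$x_nm)
    rp <- segment_runs(seg, static_speed_nm_s)
    cbind(data.frame(track_id = tr$track_id[1], context_id = tr$context_id[1]),
          track_metrics(tr$t_s, rp$runs, rp$pauses))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Landing rate of complexes on a microtubule
#'
#' The landing rate is the number of tracks per kymograph width (nm) and
#' length (s), converted to events per micrometer per minute by multiplying
#' by 60,000 (1000 nm/um times 60 s/min).
#'
#' @param n_tracks Number of tracks observed on the kymograph.
#' @param mt_length_nm Microtubule (kymograph width) in nm.
#' @param duration_s Movie length in s.
#' @return List: `n_tracks`, `rate_um_min`.
#' @export
landing_rate <- function(n_tracks, mt_length_nm, duration_s) {
  if (!is.finite(mt_length_nm) || mt_length_nm <= 0)
    stop("mt_length_nm must be > 0")
  if (!is.finite(duration_s) || duration_s <= 0)
    stop("duration_s must be > 0")
  if (n_tracks < 0) stop("n_tracks must be >= 0")
  list(n_tracks = n_tracks,
       rate_um_min = n_tracks / (mt_length_nm * duration_s) * 60000)
}

#' Detect a processive event in one track
#'
#' A complex qualifies as a processive event iff it stays associated with
#' the microtubule for at least `min_dwell_s` and moves at least
#' `min_disp_nm` (both thresholds inclusive). The defaults (1.2 s, 525 nm)
#' correspond to five 105-nm pixels of displacement on the kymograph.
#' Displacement is measured as total run length by default (consistent with
#' the pixel-count rationale of a traced line spanning five pixels); set
#' `displacement = "net"` to use |net displacement| instead. Event velocity
#' is run length over event duration.
#'
#' @param t_s,x_nm Oriented track vertices.
#' @param min_dwell_s Minimum association time in s (default 1.2).
#' @param min_disp_nm Minimum displacement in nm (default 525).
#' @param static_speed_nm_s Static threshold used to segment runs.
#' @param displacement `"run_length"` (default) or `"net"`.
#' @return Data frame with 0 or 1 rows: `duration_s`, `run_length_nm`,
#'   `velocity_nm_s`.
#' @export
detect_processive_events <- function(t_s, x_nm, min_dwell_s = 1.2,
                                     min_disp_nm = 525,
                                     static_speed_nm_s = 25,
                                     displacement = c("run_length", "net")) {
  displacement <- match.arg(displacement)
  dwell <- t_s[length(t_s)] - t_s[1]
  seg <- compute_segments(t_s, x_nm)
  rp <- segment_runs(seg, static_speed_nm_s)
  run_len <- sum(rp$runs$length_nm)
  disp <- if (displacement == "net") abs(x_nm[length(x_nm)] - x_nm[1]) else run_len
  empty <- data.frame(duration_s = numeric(), run_length_nm = numeric(),
                      velocity_nm_s = numeric())
  if (dwell >= min_dwell_s && disp >= min_disp_nm)
    data.frame(duration_s = dwell, run_length_nm = run_len,
               velocity_nm_s = run_len / dwell)
  else empty
}

#' Processive-event frequency on a microtubule
#'
#' @param n_events Number of processive events.
#' @param mt_length_nm Microtubule length in nm.
#' @param duration_s Movie length in s.
#' @return List: `n_events`, `freq_um_s` (events per micrometer per second).
#' @export
event_frequency <- function(n_events, mt_length_nm, duration_s) {
  if (!is.finite(mt_length_nm) || mt_length_nm <= 0)
    stop("mt_length_nm must be > 0")
  if (!is.finite(duration_s) || duration_s <= 0)
    stop("duration_s must be > 0")
  if (n_events < 0) stop("n_events must be >= 0")
  list(n_events = n_events,
       freq_um_s = n_events / ((mt_length_nm / 1000) * duration_s))
}

#' Per-microtubule metric summary
#'
#' For each context: track count, landing rate (per um per min), processive
#' event count and event frequency (per um per s), and the per-microtubule
#' means of the per-track metrics. Contexts with no tracks get zero rates.
#'
#' @param vertices Oriented vertex table.
#' @param contexts Context table.
#' @param min_dwell_s,min_disp_nm Processive-event thresholds.
#' @param static_speed_nm_s Static-speed threshold.
#' @return Data frame with one row per context.
#' @export
per_mt_metrics <- function(vertices, contexts, min_dwell_s = 1.2,
                           min_disp_nm = 525, static_speed_nm_s = 25) {
  contexts <- as.data.frame(contexts)
  tm <- if (nrow(vertices) > 0) tracks_metrics(vertices, static_speed_nm_s) else NULL
  rows <- lapply(seq_len(nrow(contexts)), function(i) {
    ctx <- contexts[i, ]
    sub <- vertices[vertices$context_id == ctx$context_id, , drop = FALSE]
    ids <- unique(sub$track_id)
    n_tracks <- length(ids)
    n_events <- 0
    mean_speed <- NA_real_; mean_run <- NA_real_; mean_dwell <- NA_real_
    if (n_tracks > 0) {
      for (id in ids) {
        tr <- sub[sub$track_id == id, ]
        ev <- detect_processive_events(tr$t_s, tr$x_nm, min_dwell_s,
                                       min_disp_nm, static_speed_nm_s)
        n_events <- n_events + nrow(ev)
      }
      sel <- tm[tm$context_id == ctx$context_id, ]
      mean_speed <- mean(sel$average_speed_nm_s)
      mean_run <- mean(sel$total_run_length_nm)
      mean_dwell <- mean(sel$dwell_time_s)
    }
    data.frame(
      context_id = ctx$context_id,
      n_tracks = n_tracks,
      landing_rate_um_min = landing_rate(n_tracks, ctx$mt_length_nm,
                                         ctx$duration_s)$rate_um_min,
      n_processive_events = n_events,
      event_freq_um_s = event_frequency(n_events, ctx$mt_length_nm,
                                        ctx$duration_s)$freq_um_s,
      mean_run_length_nm = mean_run,
      mean_dwell_time_s = mean_dwell,
      mean_speed_nm_s = mean_speed
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
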