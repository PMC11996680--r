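# Stochastic simulator of bidirectional motor tracks on microtubules.
#
# Complexes land as a Poisson process along the microtubule, then evolve by
# a continuous-time Markov process over three states (plus-directed run,
# minus-directed run, pause) with exponential state dwells, per-state
# detachment rates, and truncated-normal speeds. The exact piecewise-linear
# path is kept as ground truth; the "traced" track handed to the analysis
# carries localization noise on its vertices, emulating manual tracing of
# the kymograph line. Per-frame sampled positions are also produced, for
# kymograph rendering and for the optional per-frame analysis mode.

SIM_STATES <- c("plus_run", "minus_run", "pause")

#' Define a motor population for simulation
#'
#' @param name Population label carried into the ground truth.
#' @param weight Mixture fraction (weights are normalized across
#'   populations).
#' @param speed_plus_nm_s,speed_minus_nm_s Mean speed magnitudes of the two
#'   run states, nm/s (> 0).
#' @param speed_cv Coefficient of variation of the per-interval speed draw
#'   (truncated normal, no sign flips within a state; default 0.25).
#' @param dwell_mean_s Named numeric: mean exponential dwell in each state
#'   before switching (`Inf` = never switches out).
#' @param detach_rate_s Named numeric: detachment rate per state, 1/s.
#' @param switch Named 3x3 row-stochastic matrix of switch destinations
#'   (zero diagonal); only rows of states with finite dwell are used.
#' @param initial_prob Named initial-state probabilities.
#' @return Object of class `population_spec`.
#' @export
population_spec <- function(name, weight,
                            speed_plus_nm_s = 500, speed_minus_nm_s = 600,
                            speed_cv = 0.25,
                            dwell_mean_s = c(plus_run = Inf, minus_run = Inf,
                                             pause = Inf),
                            detach_rate_s = c(plus_run = 0.1, minus_run = 0.1,
                                              pause = 0.1),
                            switch = NULL,
                            initial_prob = c(plus_run = 0, minus_run = 1,
                                             pause = 0)) {
  if (weight < 0) stop("population weight must be >= 0")
  if (speed_plus_nm_s <= 0 || speed_minus_nm_s <= 0)
    stop("speed magnitudes must be > 0")
  if (speed_cv < 0) stop("speed_cv must be >= 0")
  dwell_mean_s <- dwell_mean_s[SIM_STATES]
  detach_rate_s <- detach_rate_s[SIM_STATES]
  initial_prob <- initial_prob[SIM_STATES]
  if (anyNA(dwell_mean_s) || anyNA(detach_rate_s) || anyNA(initial_prob))
    stop("dwell_mean_s, detach_rate_s and initial_prob must name states ",
         paste(SIM_STATES, collapse = ", "))
  if (any(detach_rate_s < 0) || any(dwell_mean_s <= 0))
    stop("rates must be >= 0 and dwell means > 0")
  if (sum(initial_prob) <= 0) stop("initial_prob must have positive mass")
  if (is.null(switch)) {
    switch <- matrix(0, 3, 3, dimnames = list(SIM_STATES, SIM_STATES))
    switch["plus_run", "pause"] <- 1
    switch["minus_run", "pause"] <- 1
    switch["pause", c("plus_run", "minus_run")] <- 0.5
  }
  switch <- switch[SIM_STATES, SIM_STATES]
  if (any(diag(switch) != 0)) stop("switch matrix must have a zero diagonal")
  for (s in SIM_STATES) {
    if (is.finite(dwell_mean_s[s])) {
      if (abs(sum(switch[s, ]) - 1) > 1e-9)
        stop("switch row for '", s, "' must sum to 1")
    }
  }
  structure(list(name = name, weight = weight,
                 speed_mean = c(plus_run = speed_plus_nm_s,
                                minus_run = -speed_minus_nm_s, pause = 0),
                 speed_cv = speed_cv,
                 dwell_mean_s = dwell_mean_s, detach_rate_s = detach_rate_s,
                 switch = switch,
                 initial_prob = initial_prob / sum(initial_prob)),
            class = "population_spec")
}

#' Simulation parameters
#'
#' @param landing_rate_um_s Poisson landing intensity, events per micrometer
#'   of microtubule per second.
#' @param populations List of [population_spec()] objects; weights are
#'   normalized.
#' @param mt_length_nm,duration_s Microtubule length and movie duration.
#' @param frame_interval_s,pixel_size_nm Acquisition geometry (defaults
#'   0.136 s, 105 nm).
#' @param noise_sd_nm Localization noise s.d. applied to traced vertices and
#'   frame samples (nm).
#' @param n_experiments,movies_per_experiment,mts_per_movie Replicate
#'   hierarchy; one kymograph context per microtubule.
#' @param condition Condition label written to the manifest.
#' @param seed Integer RNG seed; identical parameters and seed give
#'   bit-identical datasets.
#' @return Object of class `sim_params`.
#' @export
sim_params <- function(landing_rate_um_s, populations,
                       mt_length_nm = 20000, duration_s = 120,
                       frame_interval_s = 0.136, pixel_size_nm = 105,
                       noise_sd_nm = 20,
                       n_experiments = 1, movies_per_experiment = 1,
                       mts_per_movie = 1, condition = "sim", seed = 1) {
  if (landing_rate_um_s < 0) stop("landing rate must be >= 0")
  if (length(populations) == 0) stop("at least one population is required")
  if (!all(vapply(populations, inherits, TRUE, "population_spec")))
    stop("populations must be population_spec objects")
  w <- vapply(populations, function(p) p$weight, 1)
  if (sum(w) <= 0) stop("population weights must have positive mass")
  if (mt_length_nm <= 0 || duration_s <= 0 || frame_interval_s <= 0 ||
      pixel_size_nm <= 0)
    stop("geometry parameters must be > 0")
  if (noise_sd_nm < 0) stop("noise_sd_nm must be >= 0")
  structure(list(landing_rate_um_s = landing_rate_um_s,
                 populations = populations, pop_weights = w / sum(w),
                 mt_length_nm = mt_length_nm, duration_s = duration_s,
                 frame_interval_s = frame_interval_s,
                 pixel_size_nm = pixel_size_nm, noise_sd_nm = noise_sd_nm,
                 n_experiments = n_experiments,
                 movies_per_experiment = movies_per_experiment,
                 mts_per_movie = mts_per_movie,
                 condition = condition, seed = as.integer(seed)),
            class = "sim_params")
}

draw_speed <- function(mean_speed, cv) {
  if (mean_speed == 0) return(0)
  if (cv == 0) return(mean_speed)
  repeat {
    v <- stats::rnorm(1, mean_speed, abs(mean_speed) * cv)
    if (sign(v) == sign(mean_speed) && abs(v) > 0) return(v)
  }
}

# Evolve one complex from landing to detachment / boundary / movie end.
# Returns exact path vertices and the state log.
sim_path <- function(pop, t0, x0, mt_length_nm, duration_s,
                     max_events = 10000L) {
  t <- t0; x <- x0
  vt <- t0; vx <- x0
  st_state <- character(); st_t0 <- numeric(); st_t1 <- numeric()
  st_speed <- numeric()
  state <- sample(SIM_STATES, 1, prob = pop$initial_prob)
  reason <- "movie_end"
  for (ev in seq_len(max_events)) {
    rate_sw <- if (is.finite(pop$dwell_mean_s[state]))
      1 / pop$dwell_mean_s[state] else 0
    rate_det <- pop$detach_rate_s[state]
    t_sw <- if (rate_sw > 0) stats::rexp(1, rate_sw) else Inf
    t_det <- if (rate_det > 0) stats::rexp(1, rate_det) else Inf
    speed <- draw_speed(pop$speed_mean[state], pop$speed_cv)
    dt <- min(t_sw, t_det, duration_s - t)
    hit_boundary <- FALSE
    if (speed > 0 && x + speed * dt > mt_length_nm) {
      dt <- (mt_length_nm - x) / speed; hit_boundary <- TRUE
    } else if (speed < 0 && x + speed * dt < 0) {
      dt <- -x / speed; hit_boundary <- TRUE
    }
    if (dt <= 0) { reason <- if (hit_boundary) "boundary" else "movie_end"; break }
    t_next <- t + dt; x_next <- x + speed * dt
    vt <- c(vt, t_next); vx <- c(vx, x_next)
    st_state <- c(st_state, state); st_t0 <- c(st_t0, t); st_t1 <- c(st_t1, t_next)
    st_speed <- c(st_speed, speed)
    t <- t_next; x <- x_next
    if (hit_boundary) { reason <- "boundary"; break }
    if (t >= duration_s) { reason <- "movie_end"; break }
    if (t_det < t_sw) { reason <- "detached"; break }
    state <- sample(SIM_STATES, 1, prob = pop$switch[state, ])
  }
  list(t = vt, x = vx, end_reason = reason,
       states = data.frame(state = st_state, t_start = st_t0, t_end = st_t1,
                           speed_nm_s = st_speed))
}

#' Classify the exact (noise-free) path of a simulated track
#'
#' Applies the same segmentation and classification rules used by the
#' pipeline to the exact piecewise-linear path, yielding the ground-truth
#' label that a noisy traced track should recover.
#'
#' @param t_s,x_nm Exact path vertices.
#' @param thresholds Classification thresholds ([default_thresholds()]).
#' @return Class label string.
#' @export
true_class <- function(t_s, x_nm, thresholds = default_thresholds()) {
  seg <- compute_segments(t_s, x_nm)
  rp <- segment_runs(seg, thresholds$static_speed_nm_s)
  classify_track(rp$runs, thresholds$static_total_nm,
                 thresholds$bidirectional_nm)$label
}

#' Simulate a full traced-track dataset with ground truth
#'
#' Landing events follow a Poisson process with intensity
#' `landing_rate_um_s` x microtubule length (um) x movie duration (s), with
#' uniform landing times and positions. Each complex evolves by its
#' population's state process; paths are truncated at the microtubule ends
#' (treated as detachment) and at the movie end. The returned `tracks`
#' table contains the traced polyline (state-change vertices with
#' localization noise) the analysis consumes; `frames` contains per-frame
#' sampled noisy positions for kymograph rendering.
#'
#' @param params A [sim_params()] object.
#' @return List: `tracks`, `frames`, `contexts`, `manifest`, `truth`
#'   (per-track ground-truth table with `population`, `end_reason`,
#'   `true_label`), `state_log`, `params`.
#' @export
simulate_trackset <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  n_ctx <- params$n_experiments * params$movies_per_experiment *
    params$mts_per_movie
  ctx_ids <- sprintf("mt%04d", seq_len(n_ctx))
  grid <- expand.grid(mt = seq_len(params$mts_per_movie),
                      movie = seq_len(params$movies_per_experiment),
                      exp = seq_len(params$n_experiments))
  contexts <- data.frame(
    context_id = ctx_ids,
    mt_length_nm = params$mt_length_nm,
    duration_s = params$duration_s,
    pixel_size_nm = params$pixel_size_nm,
    frame_interval_s = params$frame_interval_s,
    polarity = "plus_right", stringsAsFactors = FALSE)
  manifest <- data.frame(
    condition = params$condition,
    experiment_id = sprintf("%s_e%02d", params$condition, grid$exp),
    movie_id = sprintf("%s_e%02d_m%02d", params$condition, grid$exp, grid$movie),
    context_id = ctx_ids, stringsAsFactors = FALSE)

  mu <- params$landing_rate_um_s * (params$mt_length_nm / 1000) *
    params$duration_s
  # accumulate plain vectors; data frames are assembled once at the end
  trk <- list(id = list(), ctx = list(), t = list(), x = list())
  frm <- list(id = list(), ctx = list(), t = list(), x = list())
  tru <- list(id = character(), ctx = character(), pop = character(),
              t0 = numeric(), t1 = numeric(), reason = character(),
              nstates = integer(), label = character())
  slg <- list(id = list(), states = list())
  tix <- 0L
  for (ci in seq_len(n_ctx)) {
    n_land <- stats::rpois(1, mu)
    if (n_land == 0) next
    t_land <- sort(stats::runif(n_land, 0, params$duration_s))
    x_land <- stats::runif(n_land, 0, params$mt_length_nm)
    for (j in seq_len(n_land)) {
      pop_i <- sample.int(length(params$populations), 1,
                          prob = params$pop_weights)
      pop <- params$populations[[pop_i]]
      path <- sim_path(pop, t_land[j], x_land[j], params$mt_length_nm,
                       params$duration_s)
      if (length(path$t) < 2) next  # zero-duration landing at movie end
      tix <- tix + 1L
      id <- sprintf("trk%06d", tix)
      nv <- length(path$t)
      trk$id[[tix]] <- rep(id, nv); trk$ctx[[tix]] <- rep(ctx_ids[ci], nv)
      trk$t[[tix]] <- path$t
      trk$x[[tix]] <- path$x + stats::rnorm(nv, 0, params$noise_sd_nm)
      dt <- params$frame_interval_s
      f0 <- ceiling(path$t[1] / dt) * dt
      if (f0 <= path$t[nv]) {
        tf <- seq(f0, path$t[nv], by = dt)
        xf <- stats::approx(path$t, path$x, xout = tf)$y +
          stats::rnorm(length(tf), 0, params$noise_sd_nm)
        k <- length(frm$id) + 1L
        frm$id[[k]] <- rep(id, length(tf)); frm$ctx[[k]] <- rep(ctx_ids[ci], length(tf))
        frm$t[[k]] <- tf; frm$x[[k]] <- xf
      }
      tru$id[tix] <- id; tru$ctx[tix] <- ctx_ids[ci]; tru$pop[tix] <- pop$name
      tru$t0[tix] <- path$t[1]; tru$t1[tix] <- path$t[nv]
      tru$reason[tix] <- path$end_reason
      tru$nstates[tix] <- nrow(path$states)
      tru$label[tix] <- true_class(path$t, path$x)
      if (nrow(path$states) > 0) {
        k <- length(slg$id) + 1L
        slg$id[[k]] <- rep(id, nrow(path$states)); slg$states[[k]] <- path$states
      }
    }
  }
  vtab <- function(v) data.frame(
    track_id = as.character(unlist(v$id)),
    context_id = as.character(unlist(v$ctx)),
    t_s = as.numeric(unlist(v$t)), x_nm = as.numeric(unlist(v$x)),
    stringsAsFactors = FALSE)
  states_all <- if (length(slg$states)) do.call(rbind, slg$states) else
    data.frame(state = character(), t_start = numeric(), t_end = numeric(),
               speed_nm_s = numeric())
  list(
    tracks = vtab(trk),
    frames = vtab(frm),
    contexts = contexts,
    manifest = manifest,
    truth = data.frame(track_id = tru$id, context_id = tru$ctx,
                       population = tru$pop, t_land_s = tru$t0,
                       t_end_s = tru$t1, end_reason = tru$reason,
                       n_states = tru$nstates, true_label = tru$label,
                       stringsAsFactors = FALSE),
    state_log = cbind(data.frame(track_id = as.character(unlist(slg$id)),
                                 stringsAsFactors = FALSE), states_all),
    params = params
  )
}

#' Preset simulation scenarios
#'
#' Named parameter sets emulating the assay conditions the package is
#' designed for. Population mixtures for `"ddhk"` follow the measured
#' directionality split of dynein-dynactin-HOOK3-KIF1C complexes
#' (about 83% minus, 13% plus, ~2% static, ~2% switching); `"ddh"` and
#' `"hk"` are the corresponding single-motor-class controls, and `"fhf"`
#' mimics a sparse, weakly activated dynein condition (low landing rate,
#' exponential run length with ~6,300 nm mean). Speeds and kinetic rates
#' are round free-choice values (per-condition speeds are not tabulated in
#' the source data); see the package vignette.
#'
#' @param name One of `"ddh"`, `"hk"`, `"ddhk"`, `"fhf"`.
#' @param seed RNG seed passed through to [sim_params()].
#' @param ... Overrides forwarded to [sim_params()].
#' @return A [sim_params()] object.
#' @export
sim_preset <- function(name = c("ddh", "hk", "ddhk", "fhf"), seed = 1, ...) {
  name <- match.arg(name)
  minus_walker <- function(w) population_spec(
    "minus_walker", w,
    dwell_mean_s = c(plus_run = Inf, minus_run = Inf, pause = Inf),
    detach_rate_s = c(plus_run = 0, minus_run = 0.1, pause = 0),
    initial_prob = c(plus_run = 0, minus_run = 1, pause = 0))
  plus_walker <- function(w) population_spec(
    "plus_walker", w,
    dwell_mean_s = c(plus_run = Inf, minus_run = Inf, pause = Inf),
    detach_rate_s = c(plus_run = 0.12, minus_run = 0, pause = 0),
    initial_prob = c(plus_run = 1, minus_run = 0, pause = 0))
  static_pop <- function(w) population_spec(
    "static", w,
    dwell_mean_s = c(plus_run = Inf, minus_run = Inf, pause = Inf),
    detach_rate_s = c(plus_run = 0, minus_run = 0, pause = 0.08),
    initial_prob = c(plus_run = 0, minus_run = 0, pause = 1))
  switcher <- function(w) {
    sw <- matrix(0, 3, 3, dimnames = list(SIM_STATES, SIM_STATES))
    sw["plus_run", "minus_run"] <- 1
    sw["minus_run", "plus_run"] <- 1
    sw["pause", c("plus_run", "minus_run")] <- 0.5
    population_spec(
      "switcher", w,
      dwell_mean_s = c(plus_run = 6, minus_run = 6, pause = Inf),
      detach_rate_s = c(plus_run = 0.05, minus_run = 0.05, pause = 0),
      switch = sw,
      initial_prob = c(plus_run = 0.5, minus_run = 0.5, pause = 0))
  }
  pops <- switch(name,
    ddh = list(minus_walker(0.96), static_pop(0.04)),
    hk = list(plus_walker(0.96), static_pop(0.04)),
    ddhk = list(minus_walker(0.834), plus_walker(0.134),
                static_pop(0.016), switcher(0.016)),
    fhf = list(population_spec(
      "fhf_minus", 1,
      dwell_mean_s = c(plus_run = Inf, minus_run = Inf, pause = Inf),
      detach_rate_s = c(plus_run = 0, minus_run = 600 / 6300, pause = 0),
      initial_prob = c(plus_run = 0, minus_run = 1, pause = 0)))
  )
  lambda <- switch(name, ddh = 0.02, hk = 0.02, ddhk = 0.03, fhf = 0.065)
  sim_params(landing_rate_um_s = lambda, populations = pops,
             condition = name, seed = seed, ...)
}

#' Render a synthetic kymograph image
#'
#' Builds a (frames x pixels) intensity image from per-frame track
#' positions: each track contributes a 1-D Gaussian profile (the point
#' spread function) centered at its position in each frame; Poisson photon
#' noise is applied on top of a constant background. Uses the current RNG
#' state; set a seed beforehand for reproducibility.
#'
#' @param frames Per-frame sample table (`t_s`, `x_nm`) for one context, as
#'   produced by [simulate_trackset()].
#' @param context One-row context data frame.
#' @param psf_sigma_px PSF sigma in pixels (default 1.3).
#' @param background Mean background photons per pixel (default 5).
#' @param photon_scale Peak photons per molecule per frame (default 150).
#' @param poisson_noise Apply Poisson noise (default TRUE).
#' @return Numeric matrix, rows = frames, columns = pixels.
#' @export
render_kymograph <- function(frames, context, psf_sigma_px = 1.3,
                             background = 5, photon_scale = 150,
                             poisson_noise = TRUE) {
  n_px <- ceiling(context$mt_length_nm / context$pixel_size_nm)
  n_fr <- floor(context$duration_s / context$frame_interval_s) + 1
  img <- matrix(background, n_fr, n_px)
  if (nrow(frames) > 0) {
    px_centers <- (seq_len(n_px) - 0.5) * context$pixel_size_nm
    sig_nm <- psf_sigma_px * context$pixel_size_nm
    fi <- round(frames$t_s / context$frame_interval_s) + 1
    keep <- fi >= 1 & fi <= n_fr
    for (r in which(keep)) {
      prof <- photon_scale *
        exp(-(px_centers - frames$x_nm[r])^2 / (2 * sig_nm^2))
      img[fi[r], ] <- img[fi[r], ] + prof
    }
  }
  if (poisson_noise)
    img <- matrix(stats::rpois(length(img), img), nrow(img), ncol(img))
  img
}

#' Write a kymograph image as 16-bit TIFF
#'
#' @param img Matrix from [render_kymograph()].
#' @param path Output TIFF path.
#' @export
write_kymograph_tiff <- function(img, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required to write TIFF images")
  tiff::writeTIFF(img / max(img, 1), path, bits.per.sample = 16)
  invisible(path)
}
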