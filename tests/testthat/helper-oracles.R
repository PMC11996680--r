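# Independent oracles and random-data generators shared across tests.

# Brute-force run/pause partition: a literal linear scan that labels each
# segment and closes a block whenever the label changes. Written
# independently of segment_runs() on purpose.
oracle_partition <- function(segments, thr) {
  lab <- character(nrow(segments))
  for (i in seq_len(nrow(segments))) {
    sp <- segments$speed_nm_s[i]
    lab[i] <- if (abs(sp) < thr) "pause" else if (sp > 0) "run+" else "run-"
  }
  blocks <- list()
  cur <- NULL
  for (i in seq_len(nrow(segments))) {
    if (is.null(cur) || cur$lab != lab[i]) {
      if (!is.null(cur)) blocks[[length(blocks) + 1]] <- cur
      cur <- list(lab = lab[i], len = 0, dur = 0, net = 0)
    }
    cur$len <- cur$len + abs(segments$dx_nm[i])
    cur$dur <- cur$dur + segments$dt_s[i]
    cur$net <- cur$net + segments$dx_nm[i]
  }
  blocks[[length(blocks) + 1]] <- cur
  list(labels = lab, blocks = blocks)
}

# Random segment list with speeds spanning +-[0, 2000] nm/s, deliberately
# including exact-threshold and zero speeds.
random_segments <- function(n, thr = 25) {
  pick <- sample(1:4, n, replace = TRUE, prob = c(0.55, 0.2, 0.15, 0.1))
  speed <- numeric(n)
  speed[pick == 1] <- runif(sum(pick == 1), -2000, 2000)
  speed[pick == 2] <- runif(sum(pick == 2), -thr, thr)      # mostly static
  speed[pick == 3] <- sample(c(-thr, thr), sum(pick == 3), replace = TRUE)
  speed[pick == 4] <- 0
  dt <- runif(n, 0.05, 3)
  data.frame(dt_s = dt, dx_nm = speed * dt, speed_nm_s = speed)
}

# Random valid track (vertex table rows for one track).
random_track <- function(id, ctx = "mt1", n = NULL) {
  if (is.null(n)) n <- sample(2:12, 1)
  t <- cumsum(c(runif(1, 0, 5), runif(n - 1, 0.05, 4)))
  x <- cumsum(c(runif(1, -5000, 5000), runif(n - 1, -2000, 2000)))
  data.frame(track_id = id, context_id = ctx, t_s = t, x_nm = x,
             stringsAsFactors = FALSE)
}

make_context <- function(id = "mt1", polarity = "plus_right",
                         mt_length_nm = 20000, duration_s = 120) {
  data.frame(context_id = id, mt_length_nm = mt_length_nm,
             duration_s = duration_s, pixel_size_nm = 105,
             frame_interval_s = 0.136, polarity = polarity,
             stringsAsFactors = FALSE)
}

# Run table constructed directly, for classification-rule tests.
make_runs <- function(plus = numeric(), minus = numeric()) {
  data.frame(
    direction = c(rep("plus", length(plus)), rep("minus", length(minus))),
    length_nm = c(plus, minus),
    signed_length_nm = c(plus, -minus),
    duration_s = rep(1, length(plus) + length(minus)),
    n_segments = rep(1L, length(plus) + length(minus)))
}

# Fixed samples (with cross-group ties) for the rank-test reference checks.
fixed_groups <- list(
  a = c(2.1, 3.5, 1.2, 4.8, 3.5, 2.2, 5.1, 0.7),
  b = c(4.0, 5.5, 6.1, 3.5, 7.2, 5.0, 4.4),
  c = c(1.0, 2.0, 2.0, 1.5, 0.5, 3.0, 2.5, 1.0, 1.8))

# Four-population mixture used for classification-recovery checks.
recovery_populations <- function() {
  states <- c("plus_run", "minus_run", "pause")
  sw <- matrix(0, 3, 3, dimnames = list(states, states))
  sw["plus_run", "minus_run"] <- 1
  sw["minus_run", "plus_run"] <- 1
  sw["pause", c("plus_run", "minus_run")] <- 0.5
  list(
    population_spec("minus", 0.25,
                    detach_rate_s = c(plus_run = 0, minus_run = 0.1, pause = 0),
                    initial_prob = c(plus_run = 0, minus_run = 1, pause = 0)),
    population_spec("plus", 0.25,
                    detach_rate_s = c(plus_run = 0.12, minus_run = 0, pause = 0),
                    initial_prob = c(plus_run = 1, minus_run = 0, pause = 0)),
    population_spec("static", 0.25,
                    detach_rate_s = c(plus_run = 0, minus_run = 0, pause = 0.08),
                    initial_prob = c(plus_run = 0, minus_run = 0, pause = 1)),
    population_spec("switcher", 0.25,
                    dwell_mean_s = c(plus_run = 6, minus_run = 6, pause = Inf),
                    detach_rate_s = c(plus_run = 0.05, minus_run = 0.05,
                                      pause = 0),
                    switch = sw,
                    initial_prob = c(plus_run = 0.5, minus_run = 0.5, pause = 0))
  )
}
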