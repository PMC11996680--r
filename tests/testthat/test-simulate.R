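minus_walker_params <- function(lambda = 0.02, noise = 0, seed = 1, ...) {
  pop <- population_spec(
    "minus", 1,
    detach_rate_s = c(plus_run = 0, minus_run = 0.1, pause = 0),
    initial_prob = c(plus_run = 0, minus_run = 1, pause = 0))
  sim_params(lambda, list(pop), noise_sd_nm = noise, seed = seed, ...)
}

test_that("zero landing intensity produces zero tracks", {
  s <- simulate_trackset(minus_walker_params(lambda = 0))
  expect_equal(nrow(s$tracks), 0)
  expect_equal(nrow(s$truth), 0)
  expect_equal(nrow(s$contexts), 1)
})

test_that("parameter validation rejects impossible settings", {
  pop <- population_spec("p", 1)
  expect_error(sim_params(-1, list(pop)), "landing rate")
  expect_error(sim_params(1, list()), "at least one population")
  expect_error(population_spec("p", 1, speed_cv = -1), "speed_cv")
  expect_error(population_spec("p", -1), "weight")
  states <- c("plus_run", "minus_run", "pause")
  sw <- diag(3); dimnames(sw) <- list(states, states)
  expect_error(population_spec("p", 1, switch = sw), "diagonal")
})

test_that("a pure minus population with zero noise classifies minus", {
  s <- simulate_trackset(minus_walker_params(
    lambda = 0.05, mt_length_nm = 30000, duration_s = 200, seed = 5))
  expect_gt(nrow(s$truth), 50)
  cls <- classify_tracks(orient_tracks(s$tracks, s$contexts))
  # every track whose exact path is a qualifying minus run is recovered;
  # short-lived landings are legitimately static under the 1,000 nm rule
  m <- merge(cls[, c("track_id", "label")],
             s$truth[, c("track_id", "true_label")])
  expect_true(all(m$label == m$true_label))
  expect_true(all(m$label %in% c("minus", "static")))
  expect_gt(mean(m$label == "minus"), 0.5)
})

test_that("identical seeds give bit-identical datasets", {
  p1 <- minus_walker_params(lambda = 0.03, noise = 15, seed = 77)
  p2 <- minus_walker_params(lambda = 0.03, noise = 15, seed = 77)
  s1 <- simulate_trackset(p1); s2 <- simulate_trackset(p2)
  expect_identical(s1$tracks, s2$tracks)
  expect_identical(s1$frames, s2$frames)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_trackset(minus_walker_params(lambda = 0.03, noise = 15,
                                              seed = 78))
  expect_false(identical(s1$tracks, s3$tracks))
})

test_that("landing counts follow the Poisson intensity", {
  # lambda * L * T = 0.1 * 10 * 100 = 100 expected tracks per kymograph
  pop <- population_spec(
    "m", 1, detach_rate_s = c(plus_run = 0, minus_run = 2, pause = 0),
    initial_prob = c(plus_run = 0, minus_run = 1, pause = 0))
  n_mt <- 500
  p <- sim_params(0.1, list(pop), mt_length_nm = 10000, duration_s = 100,
                  noise_sd_nm = 0, mts_per_movie = n_mt, seed = 31)
  s <- simulate_trackset(p)
  counts <- table(factor(s$truth$context_id, levels = s$contexts$context_id))
  se <- sqrt(100 / n_mt)
  expect_lt(abs(mean(counts) - 100), 3 * se)
  # landing positions are uniform: mean near the microtubule midpoint
  expect_lt(abs(mean(s$tracks$x_nm[!duplicated(s$tracks$track_id)]) - 5000),
            3 * 10000 / sqrt(12 * nrow(s$truth)))
})

test_that("ground-truth state log spans each track's attachment interval", {
  s <- simulate_trackset(minus_walker_params(lambda = 0.02, seed = 9))
  for (id in unique(s$truth$track_id)) {
    st <- s$state_log[s$state_log$track_id == id, ]
    tr <- s$truth[s$truth$track_id == id, ]
    expect_equal(min(st$t_start), tr$t_land_s)
    expect_equal(max(st$t_end), tr$t_end_s)
    # contiguous intervals
    if (nrow(st) > 1)
      expect_equal(st$t_start[-1], st$t_end[-nrow(st)])
  }
})

test_that("true_class applies the pipeline rules to the exact path", {
  expect_equal(true_class(c(0, 10), c(5000, 0)), "minus")
  # switcher with > 1,500 nm both ways
  expect_equal(true_class(c(0, 5, 10), c(0, 2000, 0)), "bidirectional")
  expect_equal(true_class(c(0, 10), c(100, 100)), "static")
})

test_that("kymograph rendering is additive and respects geometry", {
  ctx <- make_context("mt1", mt_length_nm = 2100, duration_s = 1.36)
  empty <- data.frame(track_id = character(), context_id = character(),
                      t_s = numeric(), x_nm = numeric())
  img0 <- render_kymograph(empty, ctx, background = 5, poisson_noise = FALSE)
  expect_equal(dim(img0), c(11, 20))
  expect_true(all(img0 == 5))

  # one static molecule -> a bright constant column
  frames <- data.frame(track_id = "t1", context_id = "mt1",
                       t_s = seq(0, 1.36, by = 0.136), x_nm = 1000)
  img1 <- render_kymograph(frames, ctx, background = 5, photon_scale = 100,
                           poisson_noise = FALSE)
  peak_px <- which.max(colSums(img1))
  expect_equal(peak_px, round(1000 / 105 + 0.5))
  expect_true(all(img1[, peak_px] > 50))

  # integrated signal grows linearly with molecule count
  frames2 <- rbind(frames, transform(frames, track_id = "t2"))
  img2 <- render_kymograph(frames2, ctx, background = 5, photon_scale = 100,
                           poisson_noise = FALSE)
  expect_equal(sum(img2 - 5), 2 * sum(img1 - 5), tolerance = 1e-8)

  # Poisson noise is reproducible under an explicit seed
  set.seed(1); a <- render_kymograph(frames, ctx)
  set.seed(1); b <- render_kymograph(frames, ctx)
  expect_identical(a, b)
})

test_that("presets build valid parameter sets", {
  for (nm in c("ddh", "hk", "ddhk", "fhf")) {
    p <- sim_preset(nm, seed = 2)
    expect_s3_class(p, "sim_params")
    expect_equal(sum(p$pop_weights), 1)
  }
  expect_equal(sim_preset("ddhk")$pop_weights[1], 0.834)
})
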