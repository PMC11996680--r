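test_that("per-segment arithmetic and conservation hold", {
  seg <- compute_segments(c(0, 10), c(0, -500))
  expect_equal(seg$speed_nm_s, -50)
  expect_equal(compute_segments(c(0, 1), c(0, 0))$speed_nm_s, 0)

  set.seed(201)
  for (i in 1:25) {
    tr <- random_track("t", n = 10)
    seg <- compute_segments(tr$t_s, tr$x_nm)
    expect_equal(sum(seg$dt_s), tr$t_s[10] - tr$t_s[1])
    expect_equal(sum(seg$dx_nm), tr$x_nm[10] - tr$x_nm[1])
  }
  expect_error(compute_segments(c(0, 0), c(0, 1)), "strictly increasing")
  expect_error(compute_segments(0, 0), "at least 2")
})

test_that("runs merge same-sign moving segments and pauses split them", {
  seg <- data.frame(dt_s = c(1, 1), dx_nm = c(-100, -80),
                    speed_nm_s = c(-100, -80))
  rp <- segment_runs(seg)
  expect_equal(nrow(rp$runs), 1)
  expect_equal(rp$runs$direction, "minus")
  expect_equal(rp$runs$length_nm, 180)
  expect_equal(nrow(rp$pauses), 0)

  seg2 <- data.frame(dt_s = c(1, 1, 1), dx_nm = c(-100, 10, -100),
                     speed_nm_s = c(-100, 10, -100))
  rp2 <- segment_runs(seg2, 25)
  expect_equal(nrow(rp2$runs), 2)
  expect_true(all(rp2$runs$direction == "minus"))
  expect_equal(nrow(rp2$pauses), 1)
  expect_equal(rp2$pauses$drift_nm, 10)
})

test_that("partition matches the brute-force linear-scan oracle", {
  set.seed(202)
  for (i in 1:300) {
    seg <- random_segments(sample(1:30, 1))
    rp <- segment_runs(seg, 25)
    orc <- oracle_partition(seg, 25)
    expect_identical(rp$phase, orc$labels)
    types <- vapply(orc$blocks, function(b) b$lab, "")
    expect_equal(nrow(rp$runs), sum(types != "pause"))
    expect_equal(nrow(rp$pauses), sum(types == "pause"))
    run_blocks <- orc$blocks[types != "pause"]
    expect_equal(rp$runs$length_nm,
                 vapply(run_blocks, function(b) b$len, 1))
    expect_equal(rp$runs$duration_s,
                 vapply(run_blocks, function(b) b$dur, 1))
    pause_blocks <- orc$blocks[types == "pause"]
    expect_equal(rp$pauses$drift_nm,
                 vapply(pause_blocks, function(b) b$net, 1))
  }
})

test_that("a segment exactly at the static threshold counts as moving", {
  seg <- data.frame(dt_s = 1, dx_nm = 25, speed_nm_s = 25)
  rp <- segment_runs(seg, 25)
  expect_equal(nrow(rp$runs), 1)
  seg2 <- data.frame(dt_s = 1, dx_nm = 24.999, speed_nm_s = 24.999)
  expect_equal(nrow(segment_runs(seg2, 25)$runs), 0)
})

test_that("raising the static threshold shrinks the moving set monotonically", {
  # The run COUNT is not monotone in the threshold (a slow middle segment
  # can split one run into two), but the set of moving segments and the
  # total run length are.
  set.seed(203)
  for (i in 1:50) {
    seg <- random_segments(20)
    prev_moving <- rep(TRUE, nrow(seg))
    prev_total <- Inf
    for (thr in c(5, 25, 100, 500)) {
      rp <- segment_runs(seg, thr)
      moving <- rp$phase != "pause"
      expect_true(all(prev_moving | !moving))  # moving set only shrinks
      total <- sum(rp$runs$length_nm)
      expect_lte(total, prev_total)
      prev_moving <- moving
      prev_total <- total
    }
  }
})

test_that("partition conserves durations and respects net displacement", {
  set.seed(204)
  for (i in 1:30) {
    tr <- random_track("t", n = 8)
    seg <- compute_segments(tr$t_s, tr$x_nm)
    rp <- segment_runs(seg, 25)
    expect_equal(sum(rp$runs$duration_s) + sum(rp$pauses$duration_s),
                 tr$t_s[8] - tr$t_s[1])
    net <- abs(tr$x_nm[8] - tr$x_nm[1])
    expect_gte(sum(rp$runs$length_nm) + sum(abs(rp$pauses$drift_nm)) + 1e-9,
               net)
  }
})

test_that("segmentation is invariant to time and position offsets", {
  set.seed(205)
  tr <- random_track("t", n = 10)
  rp <- segment_runs(compute_segments(tr$t_s, tr$x_nm), 25)
  rp2 <- segment_runs(compute_segments(tr$t_s + 137.5, tr$x_nm - 4200), 25)
  expect_equal(rp$runs, rp2$runs)
  expect_equal(rp$pauses, rp2$pauses)
})

test_that("classification follows the rule order with strict inequalities", {
  # heavily lopsided bidirectional travel stays directional
  cl <- classify_track(make_runs(plus = 200, minus = 20000))
  expect_equal(cl$label, "minus")
  expect_equal(cl$total_run_length_nm, 20200)

  expect_equal(classify_track(make_runs(plus = 999))$label, "static")
  expect_equal(classify_track(make_runs(plus = 1000))$label, "plus")
  expect_equal(classify_track(make_runs(minus = 1000))$label, "minus")
  # exactly 1,500 nm both ways is not bidirectional (strict >): it is a
  # majority tie
  expect_warning(
    cl2 <- classify_track(make_runs(plus = 1500, minus = 1500)), "tie")
  expect_equal(cl2$label, "bidirectional")
  expect_equal(classify_track(make_runs(plus = 1500, minus = 5000))$label,
               "minus")
  expect_equal(classify_track(make_runs(plus = 1501, minus = 5000))$label,
               "bidirectional")
  expect_equal(classify_track(make_runs(plus = 1600, minus = 1600))$label,
               "bidirectional")
  # no runs at all -> static
  expect_equal(classify_track(make_runs())$label, "static")
})

test_that("negating positions swaps directional labels only", {
  set.seed(206)
  for (i in 1:50) {
    tr <- random_track("t", n = sample(3:9, 1))
    seg <- compute_segments(tr$t_s, tr$x_nm)
    a <- suppressWarnings(classify_track(segment_runs(seg, 25)$runs))
    segm <- compute_segments(tr$t_s, -tr$x_nm)
    b <- suppressWarnings(classify_track(segment_runs(segm, 25)$runs))
    swap <- c(plus = "minus", minus = "plus", static = "static",
              bidirectional = "bidirectional")
    expect_identical(b$label, unname(swap[a$label]))
    expect_equal(b$total_run_length_nm, a$total_run_length_nm)
    expect_equal(b$plus_total_nm, a$minus_total_nm)
  }
})

test_that("classify_tracks produces one labeled row per track", {
  v <- rbind(
    data.frame(track_id = "a", context_id = "mt1", t_s = c(0, 10),
               x_nm = c(0, -5000)),
    data.frame(track_id = "b", context_id = "mt1", t_s = c(0, 10),
               x_nm = c(0, 0)))
  cls <- classify_tracks(v)
  expect_equal(cls$label[cls$track_id == "a"], "minus")
  expect_equal(cls$label[cls$track_id == "b"], "static")
  expect_equal(cls$n_runs, c(1, 0))
})
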