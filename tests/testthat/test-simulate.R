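test_that("simulation is deterministic under a fixed seed", {
  cfg <- simulation_config(duration_s = 5, rng_seed = 42)
  a <- simulate_track(cfg)
  b <- simulate_track(cfg)
  expect_identical(a$points, b$points)
  c <- simulate_track(simulation_config(duration_s = 5, rng_seed = 43))
  expect_false(isTRUE(all.equal(a$points$x, c$points$x)))
})

test_that("long tracks realize the configured mean speed and stay in the arena", {
  cfg <- simulation_config(duration_s = 200, rng_seed = 7)  # 10^4 frames
  tr <- simulate_track(cfg)
  p <- tr$points
  speeds <- sqrt(diff(p$x)^2 + diff(p$y)^2 + diff(p$z)^2) * cfg$frame_rate_hz
  expect_lt(abs(mean(speeds) - 24) / 24, 0.05)
  b <- cfg$arena
  expect_true(all(p$x >= b$x[1] & p$x <= b$x[2]))
  expect_true(all(p$y >= b$y[1] & p$y <= b$y[2]))
  expect_true(all(p$z >= b$z[1] & p$z <= b$z[2]))
})

test_that("full persistence yields near-straight flight", {
  # short enough that the straight path cannot reach a reflecting wall
  cfg <- simulation_config(duration_s = 2, rng_seed = 2, persistence = 1)
  p <- simulate_track(cfg)$points
  path <- sum(sqrt(diff(p$x)^2 + diff(p$y)^2 + diff(p$z)^2))
  chord <- sqrt((p$x[nrow(p)] - p$x[1])^2 + (p$y[nrow(p)] - p$y[1])^2 +
                  (p$z[nrow(p)] - p$z[1])^2)
  expect_equal(path / chord, 1, tolerance = 1e-6)
})

test_that("zero corruption rates leave tracks untouched", {
  cfg <- simulation_config(duration_s = 5, rng_seed = 3, gap_rate = 0,
                           spike_rate = 0)
  tr <- simulate_track(cfg)
  out <- corrupt_track(tr, cfg)
  expect_identical(out$track$points, tr$points)
  expect_length(out$gap_frames, 0L)
  expect_length(out$spike_frames, 0L)
})

test_that("injected six-frame gaps split tracks under the five-frame rule", {
  cfg <- simulation_config(duration_s = 20, rng_seed = 9, gap_rate = 0.004,
                           gap_length_range = c(6, 6), spike_rate = 0)
  tr <- simulate_track(cfg)
  out <- corrupt_track(tr, cfg)
  n_gaps <- length(out$gap_frames) / 6
  expect_gt(n_gaps, 0)
  pieces <- interpolate_gaps(out$track, cleaning_config())
  expect_equal(length(pieces), n_gaps + 1)
  expect_false(any(unlist(lapply(pieces, function(t) t$points$status)) ==
                     "interpolated"))
})

test_that("the outlier filter removes exactly the injected spike frames", {
  cfg <- simulation_config(duration_s = 40, rng_seed = 21, gap_rate = 0,
                           spike_rate = 0.01)
  tr <- simulate_track(cfg)
  out <- corrupt_track(tr, cfg)
  expect_gt(length(out$spike_frames), 0)
  filtered <- filter_outliers(out$track, cleaning_config())
  removed <- setdiff(out$track$points$frame, filtered$points$frame)
  expect_setequal(removed, out$spike_frames)
  # interpolation then restores the spiked frames close to the clean truth
  restored <- interpolate_gaps(filtered, cleaning_config())[[1]]
  expect_equal(nrow(restored$points), nrow(tr$points))
  err <- max(abs(restored$points$x - tr$points$x))
  expect_lt(err, 2)  # linear fill across a single frame of smooth flight
})

test_that("visit scenarios realize their plan with exact per-label counts", {
  cbA <- build_cuboid(c(45, 75), c(120, 160), "horizontal", label = "A")
  cbB <- build_cuboid(c(15, 35), c(60, 90), "vertical", label = "B")
  cfg <- simulation_config(duration_s = 90, rng_seed = 1)
  sc <- make_visit_scenario(list(cbA, cbB),
                            data.frame(label = c("A", "B"),
                                       n_visits = c(3, 1),
                                       dwell_s = c(1, 2)), cfg)
  expect_length(sc$tracks, 2L)
  truth <- sc$truth
  expect_equal(truth$n_visits[truth$track_id == "plan_1_A" &
                                truth$label == "A"], 3L)
  expect_equal(truth$n_visits[truth$track_id == "plan_2_B" &
                                truth$label == "B"], 1L)
  expect_equal(truth$n_visits[truth$track_id == "plan_1_A" &
                                truth$label == "B"], 0L)

  # planned dwell is realized within one frame by the segmented visits
  visA <- segment_visits(sc$tracks[["plan_1_A"]], cbA)
  expect_length(visA, 3L)
  durations <- vapply(visA, function(v) v$metrics$duration_s, numeric(1))
  expect_true(all(abs(durations - 1) <= 0.02))

  # an empty plan yields a track that avoids every cuboid
  sc0 <- make_visit_scenario(list(cbA),
                             data.frame(label = "A", n_visits = 0,
                                        dwell_s = 1), cfg)
  expect_equal(sc0$truth$n_visits, 0L)

  expect_error(
    make_visit_scenario(list(cbA),
                        data.frame(label = "A", n_visits = 40, dwell_s = 5),
                        simulation_config(duration_s = 10)),
    "infeasible")
})
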