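test_that("cuboids grow by the buffer and take orientation-specific heights", {
  cb <- build_cuboid(c(45, 75), c(80, 120), "horizontal")
  expect_equal(diff(cb$x), 50)   # 30 + 2 x 10
  expect_equal(diff(cb$y), 60)   # 40 + 2 x 10
  expect_equal(cb$z, c(0, 30))

  cbv <- build_cuboid(c(45, 75), c(80, 120), "vertical")
  expect_equal(cbv$z, c(0, 60))

  cb0 <- build_cuboid(c(45, 75), c(80, 120), "horizontal", buffer_cm = 0)
  expect_equal(cb0$x, c(45, 75))
  expect_equal(cb0$y, c(80, 120))

  expect_warning(build_cuboid(c(0, 30), c(80, 120), "horizontal"), "clipped")
})

test_that("the no-target control copies dimensions and sits downwind", {
  ref <- build_cuboid(c(45, 75), c(120, 160), "horizontal")
  ctl <- no_target_cuboid(ref)
  expect_equal(diff(ctl$x), diff(ref$x))
  expect_equal(diff(ctl$y), diff(ref$y))
  expect_equal(ctl$z, ref$z)
  expect_equal(ctl$label, "no-target")
  expect_lt(ctl$y[2], 120)  # downwind of the target
})

test_that("visits are maximal in-cuboid runs of at least two points", {
  cb <- build_cuboid(c(40, 80), c(90, 130), "horizontal", buffer_cm = 0)
  # straight pass through the cuboid along y, twice
  seg <- function(y0, frames) data.frame(frame = frames, x = 60,
                                         y = y0 + seq_along(frames) - 1, z = 15)
  pts <- rbind(seg(60, 1:100), seg(60, 121:220))
  tr <- flight_track("two-pass", pts, frame_rate_hz = 50)
  visits <- segment_visits(tr, cb)
  expect_length(visits, 2L)
  expect_true(all(vapply(visits, function(v) nrow(v$points), integer(1)) == 40L))

  outside <- flight_track("away", data.frame(frame = 1:50, x = 10, y = 10,
                                             z = 15))
  expect_length(segment_visits(outside, cb), 0L)

  graze <- flight_track("graze", data.frame(
    frame = 1:3, x = c(10, 60, 10), y = c(10, 100, 10), z = 15))
  expect_length(segment_visits(graze, cb), 0L)
})

test_that("vertical-target visits are labeled by side of the target plane", {
  cb <- build_cuboid(c(40, 80), c(90, 110), "vertical")  # plane at y = 100
  up <- flight_track("up", data.frame(frame = 1:20, x = 60, y = 105, z = 20))
  down <- flight_track("down", data.frame(frame = 1:20, x = 60, y = 92, z = 20))
  expect_equal(segment_visits(up, cb)[[1]]$side, "upwind")
  expect_equal(segment_visits(down, cb)[[1]]$side, "downwind")
})

test_that("visit metrics match closed forms", {
  # straight 24 cm/s segment: 51 points at 50 fps
  tr <- line_track(51)
  m <- visit_metrics(list(points = tr$points), 50)
  expect_equal(m$duration_s, 1)
  expect_equal(m$path_length_cm, 24, tolerance = 1e-12)
  expect_equal(m$tortuosity, 1, tolerance = 1e-12)
  expect_equal(m$mean_speed_cms, 24, tolerance = 1e-12)

  # right-angle path, two 30 cm legs
  leg1 <- data.frame(frame = 1:31, x = seq(0, 30, by = 1), y = 0, z = 10)
  leg2 <- data.frame(frame = 32:61, x = 30, y = seq(1, 30, by = 1), z = 10)
  m2 <- visit_metrics(list(points = rbind(leg1, leg2)), 50)
  expect_equal(m2$path_length_cm, 60)
  expect_equal(m2$tortuosity, sqrt(2), tolerance = 1e-6)

  # out-and-back: degenerate chord, tortuosity undefined
  out_back <- data.frame(frame = 1:21, x = c(0:10, 9:0), y = 5, z = 5)
  m3 <- visit_metrics(list(points = out_back), 50)
  expect_true(is.na(m3$tortuosity))
  expect_gte(m3$path_length_cm, 20)

  expect_error(visit_metrics(list(points = leg1[1, ]), 50), "2 points")
})

test_that("target summaries aggregate visits and compute landing density", {
  cb <- build_cuboid(c(40, 80), c(90, 130), "horizontal", buffer_cm = 0)
  y_path <- c(seq(50, 149.5, by = 0.5), seq(149, 50, by = -0.5))
  tr <- flight_track("t", data.frame(
    frame = seq_along(y_path), x = 60, y = y_path, z = 15))
  visits <- segment_visits(tr, cb)
  s <- summarize_target(visits, landings = 4, target_area_cm2 = 1200)
  expect_equal(s$n_visits, length(visits))
  expect_equal(s$total_time_s,
               sum(vapply(visits, function(v) v$metrics$duration_s, 1)))
  expect_equal(s$total_distance_cm,
               sum(vapply(visits, function(v) v$metrics$path_length_cm, 1)))
  expect_equal(s$landing_density_per_100cm2, 1 / 3, tolerance = 1e-12)

  s2 <- summarize_target(list(), landings = 2, target_area_cm2 = 300)
  expect_equal(s2$landing_density_per_100cm2, 2 / 3, tolerance = 1e-12)
  expect_equal(s2$n_visits, 0L)
  expect_equal(s2$total_time_s, 0)

  s3 <- summarize_target(list(), landings = 0, target_area_cm2 = 500)
  expect_equal(s3$landing_density_per_100cm2, 0)

  expect_error(summarize_target(list(), 1, 0), "positive")

  # visits from different cuboids refuse to aggregate
  cb2 <- build_cuboid(c(10, 30), c(10, 30), "horizontal", buffer_cm = 0,
                      label = "other")
  tr2 <- flight_track("t2", data.frame(frame = 1:20, x = 20, y = 20, z = 10))
  mixed <- c(visits, segment_visits(tr2, cb2))
  expect_error(summarize_target(mixed, 1, 100), "multiple")
})

test_that("heatmaps conserve the number of binned points", {
  tr <- simulate_track(simulation_config(duration_s = 4, rng_seed = 5))
  g <- heatmap_density(tr, "XY", bin_cm = 2)
  expect_equal(sum(g), nrow(tr$points))
  g2 <- heatmap_density(tr, "YZ", bin_cm = 10)
  expect_equal(sum(g2), nrow(tr$points))

  one_spot <- flight_track("s", data.frame(frame = 1:7, x = 33, y = 51, z = 9))
  g3 <- heatmap_density(one_spot, "XY", bin_cm = 5)
  expect_equal(sum(g3 > 0), 1L)
  expect_equal(max(g3), 7)

  empty <- flight_track("e", data.frame(frame = integer(0), x = numeric(0),
                                        y = numeric(0), z = numeric(0)))
  expect_equal(sum(heatmap_density(empty, "XY", 2)), 0)
})
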