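test_that("containment and disjoint stimulation limits are exact", {
  p <- eye_parameters()
  # huge image covering the whole eye patch: every receptive field full
  img <- project_target(target_spec(30, "vertical", distance_cm = 5), p)
  expect_equal(ommatidium_stimulation(img, list(x_deg = 0, y_deg = 0), p), 100)
  expect_equal(ommatidium_stimulation(img, list(x_deg = 24, y_deg = 0), p),
               100)
  # tiny image far from a peripheral axis
  tiny <- project_target(target_spec(1, "vertical", distance_cm = 400), p)
  expect_equal(ommatidium_stimulation(tiny, list(x_deg = 24, y_deg = 0), p), 0)
})

test_that("polygon clipping matches the equal-circle lens value of ~39.1%", {
  p <- eye_parameters()
  img <- project_target(target_with_angular_radius(20), p)
  got <- ommatidium_stimulation(img, list(x_deg = 20, y_deg = 0), p)
  expect_equal(got, lens_stim_pct(20, 20, 20), tolerance = 0.005)
  expect_equal(got, 39.1, tolerance = 0.01)
})

test_that("clipped overlap agrees with analytic lens and Monte-Carlo oracles", {
  p <- eye_parameters()
  rf_r <- p$receptive_field_deg / 2
  cases <- expand.grid(rho = c(5, 12, 20, 28), offset = c(0, 8, 16, 24, 30))
  for (i in seq_len(nrow(cases))) {
    rho <- cases$rho[i]
    off <- cases$offset[i]
    img <- project_target(target_with_angular_radius(rho), p)
    got <- ommatidium_stimulation(img, list(x_deg = off, y_deg = 0), p)
    expect_lt(abs(got - lens_stim_pct(rho, rf_r, off)), 0.5)
  }
  # spot-check the sampling oracle on a partial overlap
  img <- project_target(target_with_angular_radius(12), p)
  got <- ommatidium_stimulation(img, list(x_deg = 16, y_deg = 0), p)
  expect_lt(abs(got - mc_stim_pct(img, 16, 0, rf_r)), 0.5)
})

test_that("stimulation stays in [0, 100] and totals follow the summation rule", {
  p <- eye_parameters()
  eye <- ommatidial_array(p)
  for (d in c(20, 60, 150)) {
    m <- eye_stimulation(
      project_target(target_spec(25, "vertical", distance_cm = d), p), eye, p)
    expect_true(all(m$per_ommatidium_pct >= 0 & m$per_ommatidium_pct <= 100))
    expect_lte(m$total_pct, sum(m$per_ommatidium_pct))
    above <- m$per_ommatidium_pct >= p$individual_threshold_pct - 1e-9
    expect_equal(m$total_pct,
                 sum(m$per_ommatidium_pct[above] - p$individual_threshold_pct))
  }
})

test_that("the threshold-sum rule reproduces the forced bookkeeping example", {
  # per-ommatidium {25, 25, 25, 25, 10}, thresholds 20/100: the 10 is
  # excluded and the total is exactly 100 under the plain sum rule
  p_sum <- eye_parameters(summation_rule = "sum")
  m <- mozsight:::new_stimulation_map(c(25, 25, 25, 25, 10), p_sum)
  expect_equal(m$total_pct, 100)
  expect_true(m$detected)

  p_exc <- eye_parameters()
  m2 <- mozsight:::new_stimulation_map(c(25, 25, 25, 25, 10), p_exc)
  expect_equal(m2$total_pct, 20)
  expect_false(m2$detected)

  m3 <- mozsight:::new_stimulation_map(rep(0, 37), p_sum)
  expect_equal(m3$total_pct, 0)
  expect_false(m3$detected)
})

test_that("a 30 cm vertical target 50 cm away is detected with defaults", {
  p <- eye_parameters()
  m <- eye_stimulation(
    project_target(target_spec(30, "vertical", distance_cm = 50), p), NULL, p)
  expect_true(m$detected)
})

test_that("centered vertical targets stimulate symmetry-equivalent ommatidia equally", {
  # hexagonal rings contain two geometric classes beyond ring 1 (corner and
  # edge axes at different angular distances); equality holds within groups
  # of equal distance from the gaze center
  p <- eye_parameters()
  eye <- ommatidial_array(p)
  m <- eye_stimulation(
    project_target(target_spec(30, "vertical", distance_cm = 45), p), eye, p)
  groups <- split(m$per_ommatidium_pct,
                  round(sqrt(eye$x_deg^2 + eye$y_deg^2), 6))
  for (g in groups) {
    expect_lt(diff(range(g)), 0.05)
  }
})

test_that("per-ommatidium stimulation decreases with distance for vertical targets", {
  p <- eye_parameters()
  eye <- ommatidial_array(p)
  stim <- sapply(c(30, 50, 80, 130, 210), function(d) {
    eye_stimulation(project_target(target_spec(30, "vertical",
                                               distance_cm = d), p),
                    eye, p)$per_ommatidium_pct
  })
  # allow a whisker of clipping discretization noise
  expect_true(all(diff(t(stim)) <= 1e-6))
})
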