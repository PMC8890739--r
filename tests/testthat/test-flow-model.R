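test_that("walls are exactly no-slip at all times", {
  model <- default_model()
  wc <- wall_contour(default_geometry(), 250)
  for (t in c(0, 0.2, 0.55, 0.83)) {
    v <- sample_velocity(model, wc, t)
    expect_lt(max(abs(v)), 1e-12)
  }
})

test_that("velocity field is periodic in time", {
  model <- default_model()
  pts <- rbind(c(0, 0), c(2, 3), c(-3, 12), c(1.4, 3.4), c(0, 19))
  for (t in c(0.13, 0.47)) {
    v1 <- sample_velocity(model, pts, t)
    v2 <- sample_velocity(model, pts, t + model$waveform$cycle_duration)
    expect_equal(v1, v2, tolerance = 1e-12)
  }
})

test_that("parent-vessel centerline reaches the configured peak velocity", {
  model <- default_model()
  v <- sample_velocity(model, cbind(0, 0), peak_time())
  expect_equal(v[1, 1], model$waveform$peak_velocity, tolerance = 1e-9)
  expect_equal(v[1, 2:3], c(0, 0), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("the sac center is a stagnation zone relative to the jet", {
  model <- default_model()
  geom <- default_geometry()
  vc <- sample_velocity(model, rbind(geom$sac_center), peak_time())
  vp1 <- sample_velocity(model, geom$probes["P1", , drop = FALSE],
                         peak_time())
  expect_lt(sqrt(sum(vc^2)), 0.05 * sqrt(sum(vp1^2)))
})

test_that("the in-plane sac field is divergence-free on the grid", {
  model <- default_model()
  geom <- default_geometry()
  h <- 0.05
  xs <- seq(-6, 6, by = 0.5)
  ys <- seq(5, 18, by = 0.5)
  pts <- cbind(rep(xs, each = length(ys)), rep(ys, length(xs)))
  keep <- in_lumen(geom, pts[, 1], pts[, 2]) & pts[, 2] > 3 &
    sqrt((pts[, 1] - geom$sac_center[1])^2 +
           (pts[, 2] - geom$sac_center[2])^2) < geom$sac_radius - 2 * h
  pts <- pts[keep, ]
  t0 <- peak_time()
  dudx <- (sample_velocity(model, cbind(pts[, 1] + h, pts[, 2]), t0)[, 1] -
             sample_velocity(model, cbind(pts[, 1] - h, pts[, 2]), t0)[, 1]) /
    (2 * h)
  dvdy <- (sample_velocity(model, cbind(pts[, 1], pts[, 2] + h), t0)[, 2] -
             sample_velocity(model, cbind(pts[, 1], pts[, 2] - h), t0)[, 2]) /
    (2 * h)
  div <- dudx + dvdy    # 1/mm units with velocity in m/s
  u_scale <- model$jet_strength * model$waveform$peak_velocity
  # stated tolerance: |div| * jet_width / U_jet below 2 %
  expect_lt(max(abs(div)) * model$jet_width / u_scale, 0.02)
})

test_that("points outside lumen or slab return zero velocity with a flag", {
  model <- default_model()
  pts <- rbind(c(0, -3, 0),      # below the vessel
               c(9, 5, 0),       # outside sac, above vessel
               c(0, 12, 1.0))    # in the sac but outside the slab
  v <- sample_velocity(model, pts, 0.2)
  expect_true(all(v == 0))
  expect_true(all(attr(v, "outside")))
  expect_error(sample_velocity(model, cbind(NA_real_, 1), 0.1), "finite")
})

test_that("sampling is deterministic and cycle-seeded", {
  model <- model_with("FDC3")
  pts <- cbind(runif(20, -5, 5), runif(20, 6, 16))
  v1 <- sample_velocity(model, pts, 0.31, cycle = 2)
  v2 <- sample_velocity(model, pts, 0.31, cycle = 2)
  expect_identical(v1, v2)
  v3 <- sample_velocity(model, pts, 0.31, cycle = 3)
  expect_false(isTRUE(all.equal(v1[, 3], v3[, 3])))
  # in-plane components are cycle-independent
  expect_equal(v1[, 1:2], v3[, 1:2], tolerance = 1e-15)
})

test_that("ROI cyclic-mean speed decreases strictly with attenuation", {
  geom <- default_geometry()
  pts <- cbind(rep(seq(-8, 8, by = 1), each = 17), rep(seq(4, 20, 1), 17))
  pts <- pts[in_lumen(geom, pts[, 1], pts[, 2]) & pts[, 2] > 2, ]
  base <- default_model()
  means <- vapply(c(0, 0.2, 0.5, 0.78, 0.95), function(a) {
    m <- apply_scenario(base, scenario_config(alpha = a,
                                              oop_fluctuation = 0))
    mean(local_mean_speed(m, pts))
  }, 0)
  expect_true(all(diff(means) < 0))
})

test_that("scenarios cannot be applied twice and identity leaves the field", {
  model <- default_model()
  m2 <- apply_scenario(model, scenario_preset("FDC1"))
  expect_error(apply_scenario(m2, scenario_preset("FDC2")), "already")
  ident <- apply_scenario(model,
                          scenario_config(alpha = 0, jet_entry_shift = 0,
                                          oop_fluctuation = 0))
  pts <- cbind(runif(50, -9, 9), runif(50, -1.9, 20))
  for (t in c(0.1, 0.6)) {
    expect_equal(sample_velocity(ident, pts, t),
                 sample_velocity(model, pts, t), tolerance = 1e-15)
  }
})
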