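# build a recording list [(cycle)][(phase)] from a function
# field_fn(cycle, phase) -> list(u, v, w)
make_recordings <- function(n_cyc, n_phase, x, y, field_fn) {
  lapply(seq_len(n_cyc), function(ic) {
    lapply(seq_len(n_phase), function(ip) {
      f <- field_fn(ic, ip)
      c(list(x = x, y = y), f)
    })
  })
}

grid_xy <- list(x = seq(0, 4, by = 1), y = seq(0, 3, by = 1))

test_that("identical cycles average to themselves with zero deviation", {
  fn <- function(ic, ip) {
    base <- matrix(ip / 10, 4, 5)
    list(u = base, v = -base, w = base * 0.1)
  }
  rec <- make_recordings(6, 4, grid_xy$x, grid_xy$y, fn)
  pac <- phase_average(rec, cycle_duration = 0.8)
  expect_equal(pac$n_cycles, 6)
  expect_equal(pac$phase_duration, 0.2)
  for (p in 1:4) {
    expect_equal(pac$mean[, , 1, p], matrix(p / 10, 4, 5))
    expect_true(all(pac$sd[, , , p] == 0))
  }
})

test_that("a single cycle yields the mean but no deviations", {
  rec <- make_recordings(1, 3, grid_xy$x, grid_xy$y, function(ic, ip)
    list(u = matrix(1, 4, 5), v = matrix(0, 4, 5), w = matrix(0, 4, 5)))
  pac <- phase_average(rec)
  expect_null(pac$sd)
  expect_error(oop_fluctuation_ratio(pac, matrix(TRUE, 4, 5)),
               "two cycles")
})

test_that("pooled deviation and mean error follow the statistical oracle", {
  # truth + iid N(0, sigma) noise over N = 36 cycles: the pooled per-phase
  # sd estimates sigma within 15 %, and the RMS error of the mean is about
  # sigma / 6 within 20 % (Monte-Carlo statistical oracle)
  sigma <- 0.08
  truth <- 0.3
  withr::with_seed(99, {
    rec <- make_recordings(36, 5, grid_xy$x, grid_xy$y, function(ic, ip) {
      list(u = matrix(truth + rnorm(20, sd = sigma), 4, 5),
           v = matrix(rnorm(20, sd = sigma), 4, 5),
           w = matrix(0, 4, 5))
    })
  })
  pac <- phase_average(rec)
  pooled <- sqrt(mean(pac$sd[, , 1:2, ]^2))
  expect_equal(pooled, sigma, tolerance = 0.15)
  rms_mean <- sqrt(mean((pac$mean[, , 1, ] - truth)^2))
  expect_equal(rms_mean, sigma / 6, tolerance = 0.2)
})

test_that("phase averaging is linear and permutation-invariant", {
  withr::with_seed(5, {
    rec <- make_recordings(5, 3, grid_xy$x, grid_xy$y, function(ic, ip)
      list(u = matrix(rnorm(20), 4, 5), v = matrix(rnorm(20), 4, 5),
           w = matrix(rnorm(20), 4, 5)))
  })
  pac <- phase_average(rec)
  scaled <- rapply(rec, function(m) if (is.matrix(m)) 3 * m else m,
                   how = "replace")
  pac3 <- phase_average(scaled)
  expect_equal(pac3$mean, 3 * pac$mean, tolerance = 1e-12)
  expect_equal(pac3$sd, 3 * pac$sd, tolerance = 1e-12)
  perm <- phase_average(rec[c(4, 2, 5, 1, 3)])
  expect_identical(perm$mean, pac$mean)
  expect_identical(perm$sd, pac$sd)
})

test_that("cycle averages: magnitude-then-time vs vector identities", {
  # alternating +u / -u over equal half-cycles: the vector average
  # cancels, the speed average does not
  fn <- function(ic, ip) {
    sgn <- if (ip <= 2) 1 else -1
    list(u = matrix(0.2 * sgn, 4, 5), v = matrix(0, 4, 5),
         w = matrix(0, 4, 5))
  }
  pac <- phase_average(make_recordings(2, 4, grid_xy$x, grid_xy$y, fn))
  ca <- cycle_average(pac)
  expect_equal(ca$speed, matrix(0.2, 4, 5))
  expect_lt(max(abs(ca$vector)), 1e-15)
  # two-phase cycle with speeds 1 and 3: the time average is 2
  fn2 <- function(ic, ip) list(u = matrix(c(1, 3)[ip], 4, 5),
                               v = matrix(0, 4, 5), w = matrix(0, 4, 5))
  ca2 <- cycle_average(phase_average(make_recordings(1, 2, grid_xy$x,
                                                     grid_xy$y, fn2)))
  expect_equal(ca2$speed, matrix(2, 4, 5))
  # triangle inequality: speed map >= |vector map| pointwise
  withr::with_seed(6, {
    rec <- make_recordings(3, 6, grid_xy$x, grid_xy$y, function(ic, ip)
      list(u = matrix(rnorm(20), 4, 5), v = matrix(rnorm(20), 4, 5),
           w = matrix(rnorm(20), 4, 5)))
  })
  ca3 <- cycle_average(phase_average(rec))
  vec_norm <- sqrt(apply(ca3$vector^2, c(1, 2), sum))
  expect_true(all(ca3$speed >= vec_norm - 1e-12))
})

test_that("peak systole is located with lowest-index tie breaking", {
  M <- 64
  amp <- rep(1, M); amp[17] <- 3
  fn <- function(ic, ip) list(u = matrix(amp[ip], 4, 5),
                              v = matrix(0, 4, 5), w = matrix(0, 4, 5))
  pac <- phase_average(make_recordings(2, M, grid_xy$x, grid_xy$y, fn))
  roi <- matrix(TRUE, 4, 5)
  expect_equal(find_peak_phase(pac, roi), 17L)
  flat <- phase_average(make_recordings(1, 8, grid_xy$x, grid_xy$y,
                                        function(ic, ip)
                                          list(u = matrix(1, 4, 5),
                                               v = matrix(0, 4, 5),
                                               w = matrix(0, 4, 5))))
  expect_equal(find_peak_phase(flat, roi), 1L)
  expect_error(find_peak_phase(flat, matrix(FALSE, 4, 5)), "empty ROI")
})

test_that("the phantom peak phase matches the configured waveform maximum", {
  pac <- truth_pac("base", n_cycles = 1, n_phases = 32, pitch = 1)
  roi <- truth_roi(pac)
  p <- find_peak_phase(pac, roi)
  wf <- default_model()$waveform
  # direct maximization of the configured waveform on the phase grid
  w <- waveform_eval(wf, (seq_len(32) - 1) / 32 * wf$cycle_duration)
  expect_equal(p, which.max(w))
})

test_that("inconsistent grids and ragged cycles are rejected", {
  rec <- make_recordings(2, 3, grid_xy$x, grid_xy$y, function(ic, ip)
    list(u = matrix(1, 4, 5), v = matrix(0, 4, 5), w = matrix(0, 4, 5)))
  rec[[2]][[2]]$x <- rec[[2]][[2]]$x + 1
  expect_error(phase_average(rec), "grids")
  rec2 <- make_recordings(2, 3, grid_xy$x, grid_xy$y, function(ic, ip)
    list(u = matrix(1, 4, 5), v = matrix(0, 4, 5), w = matrix(0, 4, 5)))
  rec2[[2]][[3]] <- NULL
  expect_error(phase_average(rec2), "same phases")
})
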