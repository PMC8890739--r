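test_that("EnSight Gold cases round-trip losslessly", {
  dir <- withr::local_tempdir()
  x <- seq(-2, 2, by = 0.5); y <- seq(0, 3, by = 0.5)
  withr::with_seed(21, {
    fields <- lapply(1:3, function(i)
      array(rnorm(length(y) * length(x) * 3), c(length(y), length(x), 3)))
  })
  times <- c(0, 0.01, 0.02)
  case <- file.path(dir, "trip.case")
  write_ensight(case, x, y, fields, times)
  back <- read_ensight(case)
  expect_equal(back$x, x, tolerance = 1e-6)
  expect_equal(back$y, y, tolerance = 1e-6)
  expect_equal(back$times, times, tolerance = 1e-6)
  for (i in 1:3) {
    expect_equal(back$velocity[, , , i], fields[[i]], tolerance = 1e-6)
  }
})

test_that("a hand-written 2x2 ASCII case parses to its literal contents", {
  dir <- withr::local_tempdir()
  writeLines(c("EnSight geometry file", "tiny grid", "node id off",
               "element id off", "part", "1", "plane", "block",
               "2 2 1",
               "0.0", "1.0", "0.0", "1.0",      # x coords
               "0.0", "0.0", "2.0", "2.0",      # y coords
               "0.0", "0.0", "0.0", "0.0"),     # z coords
             file.path(dir, "tiny.geo"))
  writeLines(c("velocity", "part", "1", "block",
               "0.1", "0.2", "0.3", "0.4",      # vx
               "1.1", "1.2", "1.3", "1.4",      # vy
               "-1.0", "-2.0", "-3.0", "-4.0"), # vz
             file.path(dir, "tiny_velocity_0000.vec"))
  writeLines(c("FORMAT", "type: ensight gold", "GEOMETRY",
               "model: tiny.geo", "VARIABLE",
               "vector per node: 1 velocity tiny_velocity_****.vec",
               "TIME", "time set: 1", "number of steps: 1",
               "filename start number: 0", "filename increment: 1",
               "time values:", "0.0"),
             file.path(dir, "tiny.case"))
  ens <- read_ensight(file.path(dir, "tiny.case"))
  expect_equal(ens$x, c(0, 1))
  expect_equal(ens$y, c(0, 2))
  # node ordering: x fastest -> rows are y
  expect_equal(ens$velocity[, , 1, 1], rbind(c(0.1, 0.2), c(0.3, 0.4)))
  expect_equal(ens$velocity[, , 2, 1], rbind(c(1.1, 1.2), c(1.3, 1.4)))
  expect_equal(ens$velocity[, , 3, 1], rbind(c(-1, -2), c(-3, -4)))
})

test_that("missing referenced files are reported by name", {
  dir <- withr::local_tempdir()
  x <- seq(0, 1, by = 0.5); y <- seq(0, 1, by = 0.5)
  fields <- list(array(0, c(3, 3, 3)))
  case <- file.path(dir, "broken.case")
  write_ensight(case, x, y, fields, 0)
  unlink(file.path(dir, "broken_velocity_0000.vec"))
  expect_error(read_ensight(case), "broken_velocity_0000.vec")
  unlink(file.path(dir, "broken.geo"))
  expect_error(read_ensight(case), "broken.geo")
  expect_error(read_ensight(file.path(dir, "absent.case")), "not found")
})

test_that("binary-looking geometry files are rejected", {
  dir <- withr::local_tempdir()
  x <- c(0, 1); y <- c(0, 1)
  case <- file.path(dir, "bin.case")
  write_ensight(case, x, y, list(array(0, c(2, 2, 3))), 0)
  writeBin(as.raw(c(0x43, 0x20, 0x42, 0x69, 0x6e, 0x61, 0x72, 0x79, 0x00,
                    0x00, 0x01)), file.path(dir, "bin.geo"))
  expect_error(read_ensight(case), "binary|Binary")
})

test_that("deposited-style datasets flow into the metrics unchanged", {
  # a synthetic stand-in for a deposited phase-averaged dataset: known
  # uniform sac speed, written to EnSight and read back through the
  # metrics path
  geom <- default_geometry()
  x <- seq(-11, 11, by = 0.5); y <- seq(-1, 21, by = 0.5)
  roi <- roi_mask_for(geom, x, y)
  M <- 8
  fields <- lapply(seq_len(M), function(p) {
    f <- array(0, c(length(y), length(x), 3))
    speed <- 0.119 * (1 + 0.3 * sin(2 * pi * (p - 1) / M))
    f[, , 1][roi] <- speed
    f
  })
  dir <- withr::local_tempdir()
  case <- file.path(dir, "synthetic_deposited.case")
  write_ensight(case, x, y, fields, times = (seq_len(M) - 1) / M)
  pac <- ensight_to_phase_cycle(read_ensight(case))
  expect_equal(pac$n_phases, M)
  expect_equal(pac$cycle_duration, 1, tolerance = 1e-9)
  # the sinusoidal modulation averages out: cyclic mean = the known value
  expect_equal(roi_mean_speed(pac, roi, "cyclic_mean"), 0.119,
               tolerance = 0.001)
})

test_that("phase cycles export to EnSight and read back identically", {
  pac <- truth_pac("noFD", n_cycles = 2, n_phases = 8)
  dir <- withr::local_tempdir()
  case <- file.path(dir, "pac.case")
  phase_cycle_to_ensight(pac, case)
  back <- ensight_to_phase_cycle(read_ensight(case))
  m1 <- pac$mean; m1[is.na(m1)] <- 0
  expect_equal(back$mean, m1, tolerance = 1e-6)
  expect_equal(back$phase_duration, pac$phase_duration, tolerance = 1e-9)
})
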