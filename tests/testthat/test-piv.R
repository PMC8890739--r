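test_that("integer shifts of random texture are recovered exactly", {
  roll <- function(m, dr, dc) {
    m <- m[((seq_len(nrow(m)) - 1 - dr) %% nrow(m)) + 1, ]
    m[, ((seq_len(ncol(m)) - 1 - dc) %% ncol(m)) + 1]
  }
  a <- withr::with_seed(1, matrix(runif(64 * 64), 64))
  r <- cross_correlate(a, roll(a, 2, 3))
  expect_equal(r$dx, 3, tolerance = 0.02)
  expect_equal(r$dy, 2, tolerance = 0.02)
  expect_gt(r$peak_ratio, 3)
})

test_that("sub-pixel shifts match a dense direct-correlation oracle", {
  centers <- random_centers(64, 50, seed = 7)
  shift <- c(0.25, -0.25)
  a <- particle_tile(64, centers)
  b <- particle_tile(64, cbind(centers[, 1] + shift[1],
                               centers[, 2] + shift[2]))
  r <- cross_correlate(a, b)
  expect_lt(abs(r$dx - shift[1]), 0.05)
  expect_lt(abs(r$dy - shift[2]), 0.05)

  # independent oracle: direct spatial-domain correlation over a small
  # search range with the same 3-point Gaussian refinement
  a0 <- a - mean(a); b0 <- b - mean(b)
  score <- function(di, dj) {
    ia <- seq(9, 56); ja <- seq(9, 56)
    sum(a0[ia, ja] * b0[ia + di, ja + dj])
  }
  S <- outer(-2:2, -2:2, Vectorize(score))
  pk <- which(S == max(S), arr.ind = TRUE)[1, ]
  g3 <- function(cm, c0, cp) (log(cm) - log(cp)) /
    (2 * log(cm) - 4 * log(c0) + 2 * log(cp))
  dy_or <- (-2:2)[pk[1]] + g3(S[pk[1] - 1, pk[2]], S[pk[1], pk[2]],
                              S[pk[1] + 1, pk[2]])
  dx_or <- (-2:2)[pk[2]] + g3(S[pk[1], pk[2] - 1], S[pk[1], pk[2]],
                              S[pk[1], pk[2] + 1])
  expect_lt(abs(r$dx - dx_or), 0.05)
  expect_lt(abs(r$dy - dy_or), 0.05)
})

test_that("uncorrelated tiles give a low peak ratio; flat tiles error", {
  a <- withr::with_seed(2, matrix(runif(32 * 32), 32))
  b <- withr::with_seed(3, matrix(runif(32 * 32), 32))
  r <- cross_correlate(a, b)
  expect_lt(r$peak_ratio, 1.5)
  expect_error(cross_correlate(matrix(1, 32, 32), matrix(1, 32, 32)),
               "constant tile")
  expect_error(cross_correlate(a, matrix(0, 16, 16)), "equal square")
})

make_pair <- function(frame_a, frame_b, dt_us = 200) {
  structure(list(frame_a = frame_a, frame_b = frame_b, dt_us = dt_us,
                 camera_id = "cam1", phase = 1L, cycle = 1L),
            class = "aneupiv_image_pair")
}

test_that("a uniform shift is recovered across the whole vector grid", {
  centers <- random_centers(280, 1600, seed = 11)
  a <- particle_tile(280, centers)
  b <- particle_tile(280, cbind(centers[, 1] + 4.6, centers[, 2]))
  fld <- multipass_piv(make_pair(a, b), piv_config())
  ok <- fld$flags == "valid"
  expect_gt(mean(ok), 0.9)
  # the 3-point Gaussian estimator carries a small locking bias at this
  # 0.6 px fraction; the field mean and RMS stay within 0.05 px
  expect_lt(abs(mean(fld$dx[ok]) - 4.6), 0.05)
  expect_lt(sqrt(mean((fld$dx[ok] - 4.6)^2)), 0.05)
  expect_lt(max(abs(fld$dx[ok] - 4.6)), 0.15)
  expect_lt(sqrt(mean(fld$dy[ok]^2)), 0.05)
})

test_that("vector grid pitch is the final window times (1 - overlap)", {
  centers <- random_centers(512, 6000, seed = 12)
  a <- particle_tile(512, centers)
  fld <- multipass_piv(make_pair(a, a), piv_config())
  expect_equal(fld$pitch, 16L)
  expect_equal(unique(diff(fld$cx)), 16L)
  expect_equal(unique(diff(fld$cy)), 16L)
  # 16 px at the reference magnification of 8.8125 um/px is 141 um
  expect_equal(16 * 8.8125, 141)
})

test_that("linear shear is recovered as truth filtered by the window", {
  n <- 320
  centers <- random_centers(n, 2600, seed = 13)
  shear <- 0.02   # px displacement per px of y
  disp <- shear * (centers[, 2] - n / 2)
  a <- particle_tile(n, centers)
  b <- particle_tile(n, cbind(centers[, 1] + disp, centers[, 2]))
  fld <- multipass_piv(make_pair(a, b), piv_config())
  # oracle: the window top-hat averages the linear profile, which leaves
  # it unchanged at the window center -> truth itself, within 0.1 px
  truth <- outer(shear * (fld$cy - n / 2), rep(1, length(fld$cx)))
  ok <- fld$flags == "valid"
  expect_gt(mean(ok), 0.9)
  expect_lt(sqrt(mean((fld$dx - truth)[ok]^2)), 0.1)
})

test_that("translating both frames together leaves displacements unchanged", {
  centers <- random_centers(280, 1800, seed = 14)
  shift <- c(1.7, -2.4)
  a <- particle_tile(280, centers)
  b <- particle_tile(280, cbind(centers[, 1] + shift[1],
                                centers[, 2] + shift[2]))
  f1 <- multipass_piv(make_pair(a, b), piv_config())
  trans <- c(16, 32)  # whole-image translation, integer multiple of pitch
  a2 <- particle_tile(280, cbind(centers[, 1] + trans[1],
                                 centers[, 2] + trans[2]))
  b2 <- particle_tile(280, cbind(centers[, 1] + shift[1] + trans[1],
                                 centers[, 2] + shift[2] + trans[2]))
  f2 <- multipass_piv(make_pair(a2, b2), piv_config())
  # compare on the overlapping part of the grids
  i1 <- which(f1$cy %in% (f2$cy - trans[2])); j1 <- which(f1$cx %in% (f2$cx - trans[1]))
  i2 <- which((f2$cy - trans[2]) %in% f1$cy); j2 <- which((f2$cx - trans[1]) %in% f1$cx)
  ok <- f1$flags[i1, j1] == "valid" & f2$flags[i2, j2] == "valid"
  expect_gt(mean(ok), 0.8)
  expect_equal(f1$dx[i1, j1][ok], f2$dx[i2, j2][ok], tolerance = 0.02)
  expect_equal(f1$dy[i1, j1][ok], f2$dy[i2, j2][ok], tolerance = 0.02)
})

test_that("masked windows produce masked vectors and nothing outside", {
  centers <- random_centers(280, 1800, seed = 15)
  a <- particle_tile(280, centers)
  b <- particle_tile(280, cbind(centers[, 1] + 2, centers[, 2]))
  mask <- matrix(FALSE, 280, 280)
  mask[1:140, ] <- TRUE
  fld <- multipass_piv(make_pair(a, b), piv_config(), mask = mask)
  inside <- fld$cy <= 140
  expect_true(all(fld$flags[!inside, ] == "masked"))
  expect_true(all(is.na(fld$dx[fld$flags == "masked"])))
  expect_true(any(fld$flags[inside, ] == "valid"))
})

test_that("images smaller than the largest window are rejected", {
  a <- matrix(runif(48 * 48), 48)
  expect_error(multipass_piv(make_pair(a, a), piv_config(c(64L, 32L))),
               "smaller than")
  expect_error(piv_config(windows = c(32L, 64L)), "decreasing")
  expect_error(piv_config(windows = c(48L, 24L)), "powers of two")
  expect_error(piv_config(overlap = 1), "overlap")
})

test_that("the locking histogram is a proper distribution over fractions", {
  centers <- random_centers(280, 1600, seed = 21)
  a <- particle_tile(280, centers)
  b <- particle_tile(280, cbind(centers[, 1] + 2.37, centers[, 2] - 1.12))
  fld <- multipass_piv(make_pair(a, b), piv_config())
  h <- locking_histogram(fld)
  expect_equal(sum(h), 1, tolerance = 1e-12)
  expect_length(h, 10)
  # displacements cluster at the constructed fractions .37 and -.12
  expect_gt(h[["0.35"]] + h[["-0.15"]], 0.8)
})
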