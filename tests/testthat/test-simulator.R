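# Image-domain forward model: range kernel, PSF, scaling, Poisson noise.

test_that("range kernel is normalized, radially symmetric and has the right mean", {
  k <- small_kernel()
  expect_equal(sum(k$taps), 1, tolerance = 1e-9)
  # radial symmetry: taps at mirrored offsets are identical
  d <- dim(k$taps)[1]
  expect_equal(k$taps, k$taps[d:1, , ])
  expect_equal(k$taps, aperm(k$taps, c(2, 1, 3)))
  # Monte Carlo mean displacement magnitude (continuous law)
  s <- sample_range_displacements(k, 1e5, seed = 42)
  m <- mean(sqrt(rowSums(s^2)))
  se <- sd(sqrt(rowSums(s^2))) / sqrt(nrow(s))
  expect_lt(abs(m - 3.5), 3 * se)
})

test_that("a sub-voxel mean range degenerates to a delta kernel", {
  k <- build_range_kernel(1e-3, 0.4)
  expect_equal(dim(k$taps), c(1L, 1L, 1L))
  expect_equal(sum(k$taps), 1)
})

test_that("biexponential law reproduces its mixture mean", {
  k <- build_range_kernel(1, 0.8, law = "biexponential",
                          params = list(fraction = 0.7, tau1_mm = 1,
                                        tau2_mm = 5))
  expect_equal(k$parameterization$mean_mm, 0.7 * 1 + 0.3 * 5)
  s <- sample_range_displacements(k, 2e5, seed = 3)
  m <- mean(sqrt(rowSums(s^2)))
  se <- sd(sqrt(rowSums(s^2))) / sqrt(nrow(s))
  expect_lt(abs(m - 2.2), 3 * se)
})

test_that("expectation path is the scaled identity when blur vanishes", {
  act <- array(0, c(16, 16, 8))
  act[8, 9, 4] <- 2e6; act[4, 4, 6] <- 1e6
  ph <- prcnet:::new_voxel_phantom(act, array(1L, dim(act)),
                                   phantom_grid(16L, 8L, 0.8), "rod5", "pt")
  acq <- acq_config(psf_fwhm_mm = 1e-9, sensitivity = 1e-3, seed = 1)
  img <- simulate_image(ph, acq, "gamma", noise = FALSE)
  expect_equal(img$data, act * (0.08^3) * 1200 * 1e-3, tolerance = 1e-12)
})

test_that("expectation path is linear in the activity", {
  pr <- small_rod5_pair()
  acq <- fast_acq()
  ph <- pr$phantom
  ph2 <- ph
  ph2$activity <- 3 * ph$activity
  i1 <- simulate_image(ph, acq, "ga68", noise = FALSE, kernel = small_kernel())
  i2 <- simulate_image(ph2, acq, "ga68", noise = FALSE, kernel = small_kernel())
  expect_equal(i2$data, 3 * i1$data, tolerance = 1e-10)
})

test_that("range blur conserves counts and broadens a point source", {
  act <- array(0, c(80, 80, 80))
  act[40, 40, 40] <- 1e8
  ph <- prcnet:::new_voxel_phantom(act, array(0L, dim(act)),
                                   phantom_grid(80L, 80L, 0.8), "rod5", "pt")
  acq <- acq_config(seed = 1)
  g <- simulate_image(ph, acq, "gamma", noise = FALSE)
  b <- simulate_image(ph, acq, "ga68", noise = FALSE, kernel = small_kernel())
  # mass preservation (margin exceeds the kernel support)
  expect_equal(sum(b$data), sum(g$data), tolerance = 5e-3)
  # blur lowers the peak and broadens the profile
  expect_lt(max(b$data), max(g$data))
  fwhm_x <- function(img) {
    prof <- img$data[, 40, 40]
    sum(prof >= max(prof) / 2) * img$voxel_size_mm
  }
  expect_gt(fwhm_x(b), fwhm_x(g))
})

test_that("Poisson noise has variance close to the mean across seeds", {
  act <- array(1e6, c(6, 6, 4))
  ph <- prcnet:::new_voxel_phantom(act, array(1L, dim(act)),
                                   phantom_grid(6L, 4L, 0.8), "rod5", "u")
  sims <- sapply(1:200, function(s) {
    as.vector(simulate_image(ph, acq_config(psf_fwhm_mm = 1e-9, seed = s,
                                            sensitivity = 1e-7),
                             "gamma")$data)
  })
  ratio <- apply(sims, 1, var) / apply(sims, 1, mean)
  expect_equal(mean(ratio), 1, tolerance = 0.05)
})

test_that("paired simulation is seeded, reproducible and blur-sensitive", {
  ph <- make_rod5_phantom(0, grid = small_grid())
  p1 <- simulate_pair(ph, fast_acq(seed = 5), kernel = small_kernel())
  p2 <- simulate_pair(ph, fast_acq(seed = 5), kernel = small_kernel())
  expect_identical(p1$gamma$data, p2$gamma$data)
  expect_identical(p1$ga68$data, p2$ga68$data)
  expect_gt(sqrt(mean((p1$ga68$data - p1$gamma$data)^2)), 0)
  p3 <- simulate_pair(ph, fast_acq(seed = 6), kernel = small_kernel())
  expect_false(identical(p1$gamma$data, p3$gamma$data))
})

test_that("doubling the scan duration shrinks relative noise like 1/sqrt(2)", {
  act <- array(2e5, c(8, 8, 4))
  ph <- prcnet:::new_voxel_phantom(act, array(1L, dim(act)),
                                   phantom_grid(8L, 4L, 0.8), "rod5", "u")
  cv_of <- function(dur) {
    vals <- sapply(1:120, function(s) {
      img <- simulate_image(ph, acq_config(scan_duration_s = dur,
                                           psf_fwhm_mm = 1e-9, seed = s,
                                           sensitivity = 1e-3), "gamma")
      img$data[4, 4, 2]
    })
    sd(vals) / mean(vals)
  }
  r <- cv_of(2400) / cv_of(1200)
  expect_equal(r, 1 / sqrt(2), tolerance = 0.2)
})

test_that("a zero-activity phantom yields an all-zero image with a warning", {
  act <- array(0, c(6, 6, 2))
  ph <- prcnet:::new_voxel_phantom(act, array(0L, dim(act)),
                                   phantom_grid(6L, 2L, 0.8), "rod5", "z")
  expect_warning(img <- simulate_image(ph, fast_acq(), "gamma"),
                 "zero total activity")
  expect_equal(sum(img$data), 0)
})
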