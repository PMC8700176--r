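# NEMA-style metrics against naive double-loop oracles and closed forms.

naive_rmse <- function(a, b) {
  s <- 0; v <- 0
  for (k in seq_len(dim(a)[3])) for (j in seq_len(dim(a)[2]))
    for (i in seq_len(dim(a)[1])) {
      s <- s + (a[i, j, k] - b[i, j, k])^2
      v <- v + 1
    }
  sqrt(s / v)
}

test_that("RMSE and PSNR match the naive recomputation and closed forms", {
  set.seed(21)
  a <- array(runif(10 * 12 * 8, 0, 10), c(10, 12, 8))
  b <- a + array(rnorm(10 * 12 * 8), c(10, 12, 8))
  b[b < 0] <- 0
  st <- compute_pair_stats(as_image(a), as_image(b))
  expect_equal(st$rmse, naive_rmse(a, b), tolerance = 1e-10)
  expect_equal(st$psnr, 20 * log10(max(a) / st$rmse), tolerance = 1e-10)
  expect_equal(st$v, length(a))
  # identity: rmse 0, psnr infinite
  id <- compute_pair_stats(as_image(a), as_image(a))
  expect_equal(id$rmse, 0)
  expect_equal(id$psnr, Inf)
  # constant offset d -> rmse |d|
  st2 <- compute_pair_stats(as_image(a), as_image(a + 0.5))
  expect_equal(st2$rmse, 0.5, tolerance = 1e-12)
  # i_max 10, rmse 1 -> 20 dB
  r <- array(0, c(4, 4, 1)); r[1, 1, 1] <- 10
  t2 <- r; t2[] <- r + 1
  stat <- compute_pair_stats(as_image(r), as_image(t2))
  expect_equal(stat$rmse, 1, tolerance = 1e-12)
  expect_equal(stat$psnr, 20, tolerance = 1e-10)
  # scale invariance of PSNR, linearity of RMSE
  st3 <- compute_pair_stats(as_image(7 * a), as_image(7 * b))
  expect_equal(st3$rmse, 7 * st$rmse, tolerance = 1e-10)
  expect_equal(st3$psnr, st$psnr, tolerance = 1e-10)
})

test_that("RC is 1 with zero CV on a noiseless blur-free uniform pair", {
  g <- small_grid()
  rod5 <- make_rod5_phantom(1, grid = g)   # TBR 1: rods = background
  sph <- make_sphere1_phantom(grid = g)
  img_r <- as_image(rod5$activity)
  img_s <- as_image(sph$activity)
  rc <- compute_rc(img_r, rod5, img_s)
  expect_equal(rc$per_rod$rc, rep(1, 5), tolerance = 1e-12)
  expect_equal(rc$per_rod$cv_rc, rep(0, 5), tolerance = 1e-12)
})

test_that("RC matches a naive reimplementation of the profile procedure", {
  g <- small_grid()
  rod5 <- make_rod5_phantom(0, grid = g)
  sph <- make_sphere1_phantom(grid = g)
  pr <- simulate_pair(rod5, fast_acq(), kernel = small_kernel())
  im_s <- simulate_image(sph, fast_acq(), "ga68", kernel = small_kernel())
  rc <- compute_rc(pr$ga68, rod5, im_s)
  # naive: average central slices, per-rod max search in dilated footprint,
  # axial profile stats, 10 mm uniform ROI on the sphere phantom cylinder
  vx <- 0.8
  z <- (seq_len(dim(pr$ga68$data)[3]) - (dim(pr$ga68$data)[3] + 1) / 2) * vx
  idx <- which(abs(z) <= min(50, dim(pr$ga68$data)[3] * vx) / 2 + 1e-9)
  avg <- apply(pr$ga68$data[, , idx], c(1, 2), mean)
  avgs <- apply(im_s$data[, , idx], c(1, 2), mean)
  n <- dim(avg)[1]
  co <- (seq_len(n) - (n + 1) / 2) * vx
  roi <- outer(co - 12.5, co, function(a, b) a^2 + b^2) <= 25
  avg_u <- mean(avgs[roi]); sd_u <- sd(avgs[roi])
  expect_equal(rc$avg_uniform, avg_u, tolerance = 1e-12)
  expect_equal(rc$sd_uniform, sd_u, tolerance = 1e-12)
  for (i in 1:5) {
    foot <- apply(rod5$labels == i, c(1, 2), any)
    # dilate by one voxel (8-neighbour)
    dil <- foot
    for (dr in -1:1) for (dc in -1:1) {
      sh <- matrix(FALSE, n, n)
      rs <- pmin(pmax(seq_len(n) + dr, 1), n)
      cs <- pmin(pmax(seq_len(n) + dc, 1), n)
      sh <- foot[rs, cs]
      dil <- dil | sh
    }
    best <- c(-Inf, 0, 0)
    for (r in seq_len(n)) for (cc in seq_len(n))
      if (dil[r, cc] && avg[r, cc] > best[1]) best <- c(avg[r, cc], r, cc)
    # lexicographic tie-break replicated by strict > scan in row-major order
    prof <- pr$ga68$data[best[2], best[3], idx]
    expect_equal(rc$per_rod$avg_target[i], mean(prof), tolerance = 1e-12)
    expect_equal(rc$per_rod$rc[i], mean(prof) / avg_u, tolerance = 1e-12)
    expect_equal(rc$per_rod$cv_rc[i],
                 sqrt((sd(prof) / mean(prof))^2 + (sd_u / avg_u)^2),
                 tolerance = 1e-12)
  }
})

test_that("SOR matches closed forms, the Pythagorean CV and degenerate guards", {
  g <- small_grid()
  sph <- make_sphere1_phantom(grid = g)
  # noiseless blur-free image: cold sphere stays zero -> SOR 0, CV flagged
  img <- as_image(sph$activity)
  s0 <- compute_sor(img, sph)
  expect_equal(s0$sor, 0)
  expect_false(s0$cv_sor_defined)
  expect_true(is.na(s0$cv_sor))
  # blurred: spill-in makes 0 < SOR, and CV obeys the quadrature identity
  im <- simulate_image(sph, fast_acq(), "ga68", kernel = small_kernel())
  s1 <- compute_sor(im, sph)
  expect_gt(s1$sor, 0)
  expect_equal(s1$cv_sor,
               sqrt((s1$sd_cold / s1$avg_cold)^2 +
                      (s1$sd_hot / s1$avg_hot)^2), tolerance = 1e-12)
  # 3-4-5 identity on the quadrature formula
  expect_equal(sqrt(0.3^2 + 0.4^2), 0.5)
  # naive double-loop recomputation of the ROI means on the center slice
  k <- s1$slice
  n <- dim(im$data)[1]
  co <- (seq_len(n) - (n + 1) / 2) * 0.8
  s_cold <- c(); s_hot <- c()
  for (r in seq_len(n)) for (cc in seq_len(n)) {
    d2c <- co[r]^2 + co[cc]^2
    d2h <- (co[r] - 12.5)^2 + co[cc]^2
    if (d2c <= 25) s_cold <- c(s_cold, im$data[r, cc, k])
    if (d2h <= 25) s_hot <- c(s_hot, im$data[r, cc, k])
  }
  expect_equal(s1$avg_cold, mean(s_cold), tolerance = 1e-10)
  expect_equal(s1$avg_hot, mean(s_hot), tolerance = 1e-10)
  expect_equal(s1$sor, mean(s_cold) / mean(s_hot), tolerance = 1e-10)
  # ratio example: avg_cold 1, avg_hot 50 -> 0.02
  expect_equal(1 / 50, 0.02)
  # scale invariance
  im2 <- im; im2$data <- im$data * 13
  s2 <- compute_sor(im2, sph)
  expect_equal(s2$sor, s1$sor, tolerance = 1e-12)
  expect_equal(s2$cv_sor, s1$cv_sor, tolerance = 1e-12)
})

test_that("positron-range blur spills activity into the cold sphere", {
  g <- small_grid()
  sph <- make_sphere1_phantom(grid = g)
  gamma <- simulate_image(sph, fast_acq(), "gamma")
  ga68 <- simulate_image(sph, fast_acq(), "ga68", kernel = small_kernel())
  expect_gt(compute_sor(ga68, sph)$sor, compute_sor(gamma, sph)$sor)
})

test_that("metrics_table collects objects into one tidy table", {
  g <- small_grid()
  sph <- make_sphere1_phantom(grid = g)
  rod5 <- make_rod5_phantom(1, grid = g)
  img <- as_image(sph$activity)
  tbl <- metrics_table(compute_pair_stats(img, img),
                       compute_rc(as_image(rod5$activity), rod5, img),
                       compute_sor(img, sph))
  expect_setequal(unique(tbl$metric),
                  c("rmse", "psnr", "rc", "cv_rc", "sor", "cv_sor"))
  expect_equal(sum(tbl$metric == "rc"), 5L)
})
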