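# Voxelized phantom construction: geometry, activities, labels, transforms.

test_that("five-rod phantom has the nominal rods, activities and TBR scaling", {
  g <- phantom_grid(160L, 8L, 0.4)
  ph <- make_rod5_phantom(10, grid = g)
  rods <- ph$regions[ph$regions$region == "rod", ]
  expect_equal(sort(rods$diameter_mm), c(2, 4, 6, 8, 10))
  expect_setequal(unique(ph$labels[ph$labels > 0 & ph$labels <= 5]), 1:5)
  # rod concentration and background = rod / TBR
  expect_equal(unique(ph$activity[ph$labels == 1]), 1.69e6)
  expect_equal(unique(ph$activity[ph$labels == 6]), 1.69e5)
  # TBR 0 means a cold background
  ph0 <- make_rod5_phantom(0, grid = g)
  expect_equal(max(ph0$activity[ph0$labels == 6]), 0)
  # rod cross-sections match the analytic disc area within one voxel-width
  # annulus of the rim
  va <- 0.4^2
  for (i in seq_len(nrow(rods))) {
    n_vox <- sum(ph$labels[, , 1] == rods$label[i])
    r <- rods$diameter_mm[i] / 2
    expect_lt(abs(n_vox * va - pi * r^2), 2 * pi * r * 0.4 + va)
  }
})

test_that("cold-sphere phantom is cold inside and hot in the cylinder", {
  ph <- make_sphere1_phantom(grid = small_grid())
  expect_equal(max(ph$activity[ph$labels == 2]), 0)
  expect_equal(unique(ph$activity[ph$labels == 1]), 1.69e6)
  # sphere volume converges on the closed form as the voxel size shrinks
  for (vx in c(0.8, 0.4)) {
    g <- phantom_grid(round(51.2 / vx), round(19.2 / vx), vx)
    p <- make_sphere1_phantom(grid = g)
    vol <- sum(p$labels == 2) * vx^3
    expect_lt(abs(vol - 4 / 3 * pi * 5^3), 4 * pi * 5^2 * vx)
  }
})

test_that("twenty-rod phantom has 20 rods at two activity levels inside the bore", {
  ph <- make_rod20_phantom(grid = small_grid())
  rods <- ph$regions[ph$regions$region == "rod", ]
  expect_equal(nrow(rods), 20L)
  expect_setequal(unique(rods$diameter_mm), c(2, 3, 4, 5))
  # gray/white concentration ratio ~ 0.5
  expect_equal(8.44e5 / 1.69e6, 0.4994, tolerance = 1e-3)
  expect_setequal(unique(rods$activity_bq_ml), c(1.69e6, 8.44e5))
  ctr <- ph$meta$rod_centers_mm
  expect_true(all((ctr$x / 27.5)^2 + (ctr$y / 25)^2 < 1))
})

test_that("brain surrogate normalizes total activity and is reproducible", {
  ph <- make_brain_phantom(seed = 1, grid = small_brain_grid())
  expect_equal(phantom_total_activity(ph), 3.7e6, tolerance = 1e-3)
  ph2 <- make_brain_phantom(seed = 1, grid = small_brain_grid())
  expect_identical(ph$activity, ph2$activity)
  ph3 <- make_brain_phantom(seed = 2, grid = small_brain_grid())
  expect_false(identical(ph$activity, ph3$activity))
})

test_that("brain translation shifts label centroids by exactly the voxel offset", {
  g <- small_brain_grid()  # 0.8 mm voxels; 1.6 mm = 2 voxels
  p0 <- make_brain_phantom(seed = 1, translation = c(0, 0), grid = g)
  p1 <- make_brain_phantom(seed = 1, translation = c(1.6, 0), grid = g)
  for (lab in c(1L, 2L)) {
    c0 <- which(p0$labels == lab, arr.ind = TRUE)
    c1 <- which(p1$labels == lab, arr.ind = TRUE)
    shift <- colMeans(c1) - colMeans(c0)
    expect_equal(unname(shift), c(2, 0, 0), tolerance = 1e-8)
  }
})

test_that("transforms that would clip the brain raise a margin-naming error", {
  expect_error(
    make_brain_phantom(seed = 1, translation = c(30, 0),
                       grid = small_brain_grid()),
    "margin")
})

test_that("the default configuration plan enumerates 30 phantoms", {
  plan <- default_configuration_plan()
  expect_equal(nrow(plan), 30L)
  expect_equal(sum(plan$family == "brain"), 20L)
  expect_equal(sum(plan$family == "rod5"), 8L)
  expect_equal(sum(plan$family == "sphere1"), 1L)
  expect_equal(sum(plan$family == "rod20"), 1L)
  expect_setequal(plan$tbr[plan$family == "rod5"], c(0, 2, 4, 5, 8, 10, 16, 20))
  # duplicated ids are rejected
  bad <- plan
  bad$config_id[2] <- bad$config_id[1]
  expect_error(enumerate_configurations(bad, grid = small_grid()),
               "duplicate")
})
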