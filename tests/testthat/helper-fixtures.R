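# Shared small fixtures, built once per test run and cached.

.fx <- new.env(parent = emptyenv())

# Small grids: 0.8 mm voxels keep the 50 mm phantoms inside a 64-voxel FOV.
small_grid <- function() phantom_grid(64L, 24L, 0.8)
small_brain_grid <- function() phantom_grid(64L, 80L, 0.8)

fast_acq <- function(seed = 11L, ...) acq_config(seed = seed, ...)

cached <- function(name, expr) {
  if (is.null(.fx[[name]])) .fx[[name]] <- force(expr)
  .fx[[name]]
}

# One simulated rod5 pair on the small grid, reused by dataset/model tests.
small_rod5_pair <- function() {
  cached("rod5_pair", {
    ph <- make_rod5_phantom(0, grid = small_grid())
    kern <- build_range_kernel(3.5, 0.8)
    pr <- simulate_pair(ph, fast_acq(), kernel = kern)
    list(phantom = ph, gamma = pr$gamma, ga68 = pr$ga68)
  })
}

small_kernel <- function() cached("kernel08", build_range_kernel(3.5, 0.8))

# A tiny patch set with uniform random values, for training-mechanics tests.
random_patch_set <- function(arch, n = 64L, seed = 1L) {
  spec <- build_model(arch)
  K <- output_size(spec, 32L)
  prcnet:::with_seed(seed, {
    inputs <- array(runif(32 * 32 * n), c(32, 32, n))
    labels <- array(runif(K * K * n), c(K, K, n))
    prcnet:::new_patch_pair_set(inputs, labels, 14L, "train", NULL, NULL)
  })
}

# Wrap a bare array as an image volume.
as_image <- function(data, voxel_size_mm = 0.8, provenance = "gamma",
                     config_id = "synthetic") {
  prcnet:::new_image_volume(data, voxel_size_mm, provenance, config_id)
}

withr_like_tempdir <- function() {
  d <- tempfile("prcnet-test-")
  dir.create(d, recursive = TRUE)
  d
}
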