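# Internal helpers: seeded RNG scoping, deterministic sub-seed derivation,
# separable and FFT-based convolution on 3-d arrays.

# Evaluate `code` under a local RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic sub-seed from a parent seed and a stream label.  Keeps every
# derived seed inside the 32-bit integer range R requires.
derive_seed <- function(seed, label) {
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 131 + ch) %% 2147483563L
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483563L + 1)
}

fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# Discrete normalized Gaussian tap vector for a given sigma in voxels.
gaussian_taps <- function(sigma_vox, radius = NULL) {
  if (sigma_vox <= 0) return(1)
  if (is.null(radius)) radius <- max(1L, ceiling(4 * sigma_vox))
  x <- seq(-radius, radius)
  k <- exp(-x^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# Zero-padded 1-d convolution of every fibre of a 3-d array along `axis`
# with a centered odd-length kernel, implemented with mvfft on a matrix
# reshaping of the array.
convolve_axis <- function(vol, taps, axis) {
  if (length(taps) == 1) return(vol * taps)
  d <- dim(vol)
  perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  v <- aperm(vol, perm)
  dp <- dim(v)
  n <- dp[1]
  m <- length(taps)
  r <- (m - 1) / 2
  np <- nextn(n + m - 1, c(2, 3, 5))
  mat <- matrix(0, np, dp[2] * dp[3])
  mat[seq_len(n), ] <- v
  kv <- numeric(np)
  kv[seq_len(m)] <- taps
  out <- Re(mvfft(mvfft(mat) * as.vector(fft(kv)), inverse = TRUE)) / np
  res <- array(out[r + seq_len(n), ], dp)
  aperm(res, order(perm))
}

# Separable Gaussian smoothing of a 3-d volume; fwhm in mm.
gaussian_blur3d <- function(vol, fwhm_mm, voxel_size_mm) {
  if (fwhm_mm <= 0) return(vol)
  taps <- gaussian_taps(fwhm_to_sigma(fwhm_mm) / voxel_size_mm)
  for (ax in 1:3) vol <- convolve_axis(vol, taps, ax)
  vol
}

# Zero-padded linear convolution of a 3-d volume with a centered 3-d kernel
# of odd dimensions, returning the "same"-sized central part.
convolve3d_fft <- function(vol, kern) {
  dv <- dim(vol)
  dk <- dim(kern)
  if (all(dk == 1)) return(vol * kern[1])
  stopifnot(all(dk %% 2 == 1))
  dp <- vapply(dv + dk - 1, function(n) nextn(n, c(2, 3, 5)), numeric(1))
  pv <- array(0, dp)
  pv[seq_len(dv[1]), seq_len(dv[2]), seq_len(dv[3])] <- vol
  pk <- array(0, dp)
  pk[seq_len(dk[1]), seq_len(dk[2]), seq_len(dk[3])] <- kern
  full <- Re(fft(fft(pv) * fft(pk), inverse = TRUE)) / prod(dp)
  r <- (dk - 1) / 2
  full[r[1] + seq_len(dv[1]), r[2] + seq_len(dv[2]), r[3] + seq_len(dv[3])]
}

# Voxel-center world coordinates (mm) along one axis of length n, centered
# on the grid so that the FOV midpoint is 0.
axis_coords <- function(n, voxel_size_mm) {
  (seq_len(n) - (n + 1) / 2) * voxel_size_mm
}

`%||%` <- function(a, b) if (is.null(a)) b else a
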