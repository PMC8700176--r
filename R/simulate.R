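# Image-domain acquisition model: the positron-range blur is a radially
# symmetric convolution kernel, the scanner response an isotropic Gaussian
# PSF, and counting statistics are Poisson on the expected-counts image.

#' Build a positron-range blurring kernel
#'
#' Constructs the voxelized, radially symmetric 3-d kernel of annihilation
#' displacements.  The displacement magnitude follows an exponential
#' density `p(r) = (1/tau) exp(-r/tau)` with `tau = range_mean_mm` (the
#' mean 3-d positron range; 3.5 mm for Ga-68), emitted isotropically; a
#' two-exponential mixture is available via `law = "biexponential"`.
#' Voxels are grouped into radial shells one voxel thick and each shell
#' receives its analytic probability mass, so the discrete kernel is
#' radially symmetric by construction.  The support is truncated where the
#' residual mass falls below `truncation` and the taps are renormalized to
#' sum to one.
#'
#' @param range_mean_mm Mean displacement magnitude in mm.
#' @param voxel_size_mm Isotropic voxel size in mm.
#' @param law `"exponential"` (default) or `"biexponential"`.
#' @param params For `"biexponential"`, a list with `fraction`, `tau1_mm`,
#'   `tau2_mm`; `range_mean_mm` is ignored for the mean in that case.
#' @param truncation Maximum probability mass allowed outside the support.
#' @return A `range_kernel` with fields `taps` (3-d array summing to 1),
#'   `voxel_size_mm`, `support_radius_mm` and `parameterization`.
#' @export
build_range_kernel <- function(range_mean_mm = 3.5, voxel_size_mm = 0.4,
                               law = c("exponential", "biexponential"),
                               params = NULL, truncation = 1e-3) {
  law <- match.arg(law)
  stopifnot(range_mean_mm > 0, voxel_size_mm > 0, truncation > 0)
  if (law == "exponential") {
    cdf <- function(r) pexp(r, rate = 1 / range_mean_mm)
    r_max <- qexp(1 - truncation, rate = 1 / range_mean_mm)
    parameterization <- list(law = law, mean_mm = range_mean_mm)
  } else {
    stopifnot(!is.null(params$fraction), !is.null(params$tau1_mm),
              !is.null(params$tau2_mm))
    f <- params$fraction
    cdf <- function(r) f * pexp(r, 1 / params$tau1_mm) +
      (1 - f) * pexp(r, 1 / params$tau2_mm)
    r_max <- stats::uniroot(function(r) cdf(r) - (1 - truncation),
                            c(0, 100 * max(params$tau1_mm, params$tau2_mm)))$root
    parameterization <- list(law = law,
                             mean_mm = f * params$tau1_mm + (1 - f) * params$tau2_mm,
                             params = params)
  }
  R <- ceiling(r_max / voxel_size_mm)
  if (r_max < voxel_size_mm / 2) {  # sub-voxel range: a delta kernel
    taps <- array(1, c(1, 1, 1))
    return(structure(list(taps = taps, voxel_size_mm = voxel_size_mm,
                          support_radius_mm = 0,
                          parameterization = parameterization),
                     class = "range_kernel"))
  }
  n <- 2L * R + 1L
  ax <- seq(-R, R) * voxel_size_mm
  r <- sqrt(outer(outer(ax^2, ax^2, `+`), ax^2, `+`))
  keep <- r <= r_max
  shell <- pmin(floor(r / voxel_size_mm), R)  # one-voxel-thick radial bins
  taps <- array(0, c(n, n, n))
  counts <- tabulate(shell[keep] + 1L, nbins = R + 1L)
  edges <- seq(0, (R + 1)) * voxel_size_mm
  mass <- cdf(pmin(edges[-1], r_max)) - cdf(edges[-length(edges)])
  captured <- sum(mass[counts > 0])
  if (1 - captured > 1.5 * truncation)
    stop("kernel truncation loses too much mass; enlarge the support")
  tap_val <- ifelse(counts > 0, mass / counts, 0)
  taps[keep] <- tap_val[shell[keep] + 1L]
  taps <- taps / sum(taps)
  structure(list(taps = taps, voxel_size_mm = voxel_size_mm,
                 support_radius_mm = R * voxel_size_mm,
                 parameterization = parameterization),
            class = "range_kernel")
}

#' @export
print.range_kernel <- function(x, ...) {
  cat(sprintf("<range_kernel> %s law, mean %.2f mm, support %.1f mm, %s taps\n",
              x$parameterization$law, x$parameterization$mean_mm,
              x$support_radius_mm, paste(dim(x$taps), collapse = "x")))
  invisible(x)
}

#' Sample annihilation displacement vectors
#'
#' Draws 3-d displacement vectors from the continuous law the kernel
#' discretizes: isotropic direction, magnitude from the (two-)exponential
#' density.
#'
#' @param kernel A `range_kernel`.
#' @param n Number of draws.
#' @param seed Optional seed for a self-contained draw.
#' @return An `n` x 3 matrix of displacements in mm.
#' @export
sample_range_displacements <- function(kernel, n, seed = NULL) {
  draw <- function() {
    p <- kernel$parameterization
    r <- if (p$law == "exponential") {
      rexp(n, rate = 1 / p$mean_mm)
    } else {
      pick <- runif(n) < p$params$fraction
      ifelse(pick, rexp(n, 1 / p$params$tau1_mm), rexp(n, 1 / p$params$tau2_mm))
    }
    u <- matrix(rnorm(3 * n), n, 3)
    u <- u / sqrt(rowSums(u^2))
    u * r
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Acquisition settings for the image-domain simulator
#'
#' @param scan_duration_s Emission scan duration in seconds (default
#'   1200 s, a 20 min scan).
#' @param sensitivity Expected detected counts per decay (calibration
#'   scalar; the default gives a five-rod phantom at 20 min roughly 1e7
#'   expected counts).
#' @param psf_fwhm_mm System resolution FWHM of the Gaussian PSF in mm.
#' @param range_mean_mm Mean Ga-68 positron range in mm.
#' @param seed Integer seed for the Poisson noise streams.
#' @param post_filter_fwhm_mm Optional Gaussian post-reconstruction filter
#'   FWHM in mm (0 disables it).
#' @param range_law Displacement-magnitude law, see [build_range_kernel()].
#' @param range_params Optional parameters for the biexponential law.
#' @return An `acq_config` list.
#' @export
acq_config <- function(scan_duration_s = 1200, sensitivity = 3.6e-4,
                       psf_fwhm_mm = 1.5, range_mean_mm = 3.5, seed = 1L,
                       post_filter_fwhm_mm = 0,
                       range_law = "exponential", range_params = NULL) {
  stopifnot(scan_duration_s > 0, sensitivity > 0, psf_fwhm_mm > 0,
            range_mean_mm > 0, post_filter_fwhm_mm >= 0)
  structure(list(scan_duration_s = scan_duration_s, sensitivity = sensitivity,
                 psf_fwhm_mm = psf_fwhm_mm, range_mean_mm = range_mean_mm,
                 seed = as.integer(seed),
                 post_filter_fwhm_mm = post_filter_fwhm_mm,
                 range_law = range_law, range_params = range_params),
            class = "acq_config")
}

new_image_volume <- function(data, voxel_size_mm, provenance, source_config_id,
                             model_id = NULL, meta = list()) {
  stopifnot(provenance %in% c("gamma", "ga68", "prc"))
  structure(list(data = data, voxel_size_mm = voxel_size_mm,
                 provenance = provenance, source_config_id = source_config_id,
                 model_id = model_id, meta = meta),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_volume> %s from %s%s: %d x %d x %d @ %.2f mm, total %.4g\n",
              x$provenance, x$source_config_id,
              if (is.null(x$model_id)) "" else paste0(" (", x$model_id, ")"),
              d[1], d[2], d[3], x$voxel_size_mm, sum(x$data)))
  invisible(x)
}

#' Simulate a PET image from a phantom
#'
#' Image-domain forward model: the expected image is the activity map
#' convolved with the positron-range kernel (Ga-68 mode only) and the
#' Gaussian system PSF, scaled to expected counts by
#' `scan_duration x sensitivity x voxel volume`; the observed image is a
#' voxelwise Poisson draw, optionally post-filtered.  Back-to-back gamma
#' mode skips the range blur and is the range-free reference.
#'
#' @param phantom A `voxel_phantom`.
#' @param acq An [acq_config()].
#' @param mode `"gamma"` or `"ga68"`.
#' @param noise Apply Poisson counting noise (`TRUE`) or return the
#'   expectation image (`FALSE`).
#' @param kernel Optional prebuilt `range_kernel` (rebuilt from `acq`
#'   otherwise); ignored in gamma mode.
#' @return An `image_volume` in counts per voxel.
#' @export
simulate_image <- function(phantom, acq, mode = c("gamma", "ga68"),
                           noise = TRUE, kernel = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(phantom, "voxel_phantom"), inherits(acq, "acq_config"))
  vx <- phantom$voxel_size_mm
  lam <- phantom$activity
  warn <- NULL
  if (sum(lam) == 0) {
    warn <- "phantom has zero total activity; returning an all-zero image"
    warning(warn)
    img <- array(0, dim(lam))
    return(new_image_volume(img, vx, mode, phantom$config_id,
                            meta = list(acq = unclass(acq), warning = warn,
                                        total_counts = 0)))
  }
  if (mode == "ga68") {
    if (is.null(kernel))
      kernel <- build_range_kernel(acq$range_mean_mm, vx, law = acq$range_law,
                                   params = acq$range_params)
    lam <- convolve3d_fft(lam, kernel$taps)
    lam[lam < 0] <- 0  # clip FFT round-off
  }
  lam <- gaussian_blur3d(lam, acq$psf_fwhm_mm, vx)
  lam[lam < 0] <- 0
  lam <- lam * voxel_volume_ml(vx) * acq$scan_duration_s * acq$sensitivity
  img <- if (noise) {
    seed <- derive_seed(acq$seed, paste0(phantom$config_id, ":", mode))
    with_seed(seed, array(rpois(length(lam), lam), dim(lam)))
  } else lam
  if (acq$post_filter_fwhm_mm > 0) {
    img <- gaussian_blur3d(img, acq$post_filter_fwhm_mm, vx)
    img[img < 0] <- 0
  }
  new_image_volume(img, vx, mode, phantom$config_id,
                   meta = list(acq = unclass(acq), noise = noise,
                               total_counts = sum(img)))
}

#' Simulate the paired gamma / Ga-68 acquisition of one phantom
#'
#' Each phantom is "scanned" twice with independent Poisson noise streams
#' (sub-seeds derived from `acq$seed`): once as back-to-back 511-keV
#' gammas (no positron-range blur; the training label) and once as Ga-68
#' (range-blurred; the training input).
#'
#' @inheritParams simulate_image
#' @return A list with elements `gamma` and `ga68`, both `image_volume`s.
#' @export
simulate_pair <- function(phantom, acq, noise = TRUE, kernel = NULL) {
  list(gamma = simulate_image(phantom, acq, "gamma", noise = noise),
       ga68 = simulate_image(phantom, acq, "ga68", noise = noise,
                             kernel = kernel))
}
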