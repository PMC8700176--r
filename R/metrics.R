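# NEMA NU-4 style image-quality metrics: whole-image RMSE and PSNR,
# per-rod recovery coefficients from axial line profiles, and cold-sphere
# spill-over ratios, each with its quadrature coefficient of variation.

#' Whole-image RMSE and PSNR between a reference and a test volume
#'
#' `rmse = sqrt(sum((ref - test)^2) / V)` over all `V` voxels and
#' `psnr = 20 log10(i_max / rmse)` in dB, with `i_max` the maximum of the
#' reference (gamma) volume by default.  Identical images give `rmse = 0`
#' and `psnr = Inf`.
#'
#' @param reference Reference `image_volume` (the range-free gamma image).
#' @param test Test `image_volume` (Ga-68 or corrected) on the same grid.
#' @param i_max_source `"reference"` or `"test"`: which image supplies the
#'   PSNR numerator.
#' @return An `image_pair_stats` list with `rmse`, `psnr`, `v`, `i_max`.
#' @export
compute_pair_stats <- function(reference, test,
                               i_max_source = c("reference", "test")) {
  i_max_source <- match.arg(i_max_source)
  stopifnot(inherits(reference, "image_volume"), inherits(test, "image_volume"),
            identical(dim(reference$data), dim(test$data)))
  v <- length(reference$data)
  rmse <- sqrt(sum((reference$data - test$data)^2) / v)
  i_max <- if (i_max_source == "reference") max(reference$data)
  else max(test$data)
  psnr <- if (rmse > 0) 20 * log10(i_max / rmse) else Inf
  structure(list(rmse = rmse, psnr = psnr, v = v, i_max = i_max,
                 test_provenance = test$provenance,
                 model_id = test$model_id),
            class = "image_pair_stats")
}

#' @export
print.image_pair_stats <- function(x, ...) {
  cat(sprintf("<image_pair_stats> RMSE %.4g, PSNR %.3f dB (V = %d)\n",
              x$rmse, x$psnr, x$v))
  invisible(x)
}

# Mean 2-d slice over the central `length_mm` of the axial extent; clamps
# to the available extent on short (desk-scale) grids.
central_average_image <- function(img, length_mm = 50) {
  d <- dim(img$data)
  z <- axis_coords(d[3], img$voxel_size_mm)
  use <- min(length_mm, d[3] * img$voxel_size_mm)
  idx <- which(abs(z) <= use / 2 + 1e-9)
  list(avg = apply(img$data[, , idx, drop = FALSE], c(1, 2), mean), idx = idx)
}

# 8-neighbour dilation of a logical matrix by `by` voxels.
dilate_mask <- function(mask, by = 1L) {
  if (by < 1) return(mask)
  d <- dim(mask)
  out <- mask
  for (i in seq_len(by)) {
    g <- out
    sh <- function(m, dr, dc) {
      r <- matrix(FALSE, d[1], d[2])
      rs <- seq_len(d[1]) + dr; cs <- seq_len(d[2]) + dc
      ok_r <- rs >= 1 & rs <= d[1]; ok_c <- cs >= 1 & cs <= d[2]
      r[which(ok_r), which(ok_c)] <- m[rs[ok_r], cs[ok_c]]
      r
    }
    for (dr in -1:1) for (dc in -1:1)
      if (dr || dc) out <- out | sh(g, dr, dc)
  }
  out
}

# Max-intensity pixel of `avg` restricted to `mask`; ties broken on the
# smallest (row, col) lexicographically.
max_pixel_in_mask <- function(avg, mask) {
  vals <- avg[mask]
  mx <- max(vals)
  hits <- which(mask & avg >= mx, arr.ind = TRUE)
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  hits[1, ]
}

# Logical disc mask: pixel centers within radius_mm of center_mm (x, y).
disc_mask <- function(n_xy, voxel_size_mm, center_mm, radius_mm) {
  x <- axis_coords(n_xy, voxel_size_mm)
  X <- matrix(x, n_xy, n_xy)
  Y <- matrix(x, n_xy, n_xy, byrow = TRUE)
  (X - center_mm[1])^2 + (Y - center_mm[2])^2 <= radius_mm^2
}

# The fixed hot/uniform ROI site: on the cylinder at half its radius,
# diametrically opposite the sphere (along +x for the centered sphere).
uniform_roi_center_mm <- function() c(CYLINDER_DIAMETER_MM / 4, 0)

#' Rod recovery coefficients from a five-rod and a cold-sphere image
#'
#' Implements the modified NU-4 hot-rod procedure: the five-rod volume is
#' averaged over the central 50 mm; for each rod the maximum-intensity
#' pixel of the average image (searched within that rod's footprint
#' dilated by one voxel) anchors an axial line profile over the same
#' central extent, giving `AVG_target`/`SD_target`.  A 10 mm diameter
#' circular ROI on the cylinder of the averaged cold-sphere image gives
#' `AVG_uniform`/`SD_uniform`.  Then `RC = AVG_target / AVG_uniform` and
#' `CV_RC` combines the two relative standard deviations in quadrature.
#'
#' @param img_rod5 Five-rod `image_volume`.
#' @param rod5_phantom The matching `voxel_phantom` (for rod footprints).
#' @param img_sphere1 Cold-sphere `image_volume` on a matching grid.
#' @param profile_length_mm Axial averaging/profile length (50 mm;
#'   clamped to the grid).
#' @param roi_diameter_mm Uniform-ROI diameter (10 mm).
#' @return A `rod_recovery_stats` object; `$per_rod` is a tibble keyed by
#'   rod diameter.
#' @export
compute_rc <- function(img_rod5, rod5_phantom, img_sphere1,
                       profile_length_mm = 50, roi_diameter_mm = 10) {
  stopifnot(inherits(img_rod5, "image_volume"),
            inherits(rod5_phantom, "voxel_phantom"),
            inherits(img_sphere1, "image_volume"),
            identical(dim(img_rod5$data), dim(rod5_phantom$activity)))
  ca <- central_average_image(img_rod5, profile_length_mm)
  rods <- rod5_phantom$regions[rod5_phantom$regions$region == "rod", ]
  # uniform region from the averaged cold-sphere image
  cs <- central_average_image(img_sphere1, profile_length_mm)
  umask <- disc_mask(dim(img_sphere1$data)[1], img_sphere1$voxel_size_mm,
                     uniform_roi_center_mm(), roi_diameter_mm / 2)
  avg_u <- mean(cs$avg[umask])
  sd_u <- sd(cs$avg[umask])
  per_rod <- lapply(seq_len(nrow(rods)), function(i) {
    lab <- rods$label[i]
    foot <- apply(rod5_phantom$labels == lab, c(1, 2), any)
    if (!any(foot))
      stop(sprintf("rod %g mm (label %d) has no voxels on this grid",
                   rods$diameter_mm[i], lab))
    px <- max_pixel_in_mask(ca$avg, dilate_mask(foot, 1L))
    profile <- img_rod5$data[px[1], px[2], ca$idx]
    avg_t <- mean(profile)
    sd_t <- sd(profile)
    tibble::tibble(diameter_mm = rods$diameter_mm[i], label = lab,
                   row = px[1], col = px[2],
                   avg_target = avg_t, sd_target = sd_t,
                   rc = avg_t / avg_u,
                   cv_rc = sqrt((sd_t / avg_t)^2 + (sd_u / avg_u)^2))
  })
  structure(list(per_rod = do.call(rbind, per_rod),
                 avg_uniform = avg_u, sd_uniform = sd_u,
                 profile_length_mm = min(profile_length_mm,
                                         dim(img_rod5$data)[3] *
                                           img_rod5$voxel_size_mm),
                 provenance = img_rod5$provenance,
                 model_id = img_rod5$model_id),
            class = "rod_recovery_stats")
}

#' @export
print.rod_recovery_stats <- function(x, ...) {
  cat(sprintf("<rod_recovery_stats> (%s) AVG_uniform %.4g\n",
              x$provenance, x$avg_uniform))
  print(x$per_rod[, c("diameter_mm", "rc", "cv_rc")])
  invisible(x)
}

#' Spill-over ratio of the cold-sphere phantom
#'
#' In the axial slice through the sphere center, a 10 mm diameter ROI on
#' the cold sphere gives `AVG_cold`/`SD_cold` and a second 10 mm ROI on
#' the hot cylinder (at half the cylinder radius, opposite side) gives
#' `AVG_hot`/`SD_hot`; `SOR = AVG_cold / AVG_hot` and `CV_SOR` combines
#' the relative standard deviations in quadrature.  When `AVG_cold` is
#' exactly zero, `SOR` is 0 and `CV_SOR` is flagged undefined (`NA` with
#' `cv_sor_defined = FALSE`).
#'
#' @param img_sphere1 Cold-sphere `image_volume`.
#' @param sphere1_phantom The matching `voxel_phantom`.
#' @param roi_diameter_mm ROI diameter (10 mm).
#' @return A `spillover_stats` list.
#' @export
compute_sor <- function(img_sphere1, sphere1_phantom, roi_diameter_mm = 10) {
  stopifnot(inherits(img_sphere1, "image_volume"),
            inherits(sphere1_phantom, "voxel_phantom"),
            identical(dim(img_sphere1$data), dim(sphere1_phantom$activity)))
  d <- dim(img_sphere1$data)
  vx <- img_sphere1$voxel_size_mm
  z <- axis_coords(d[3], vx)
  k <- which.min(abs(z))  # sphere-center slice (sphere centered on grid)
  cold <- disc_mask(d[1], vx, c(0, 0), roi_diameter_mm / 2)
  hot <- disc_mask(d[1], vx, uniform_roi_center_mm(), roi_diameter_mm / 2)
  lab <- sphere1_phantom$labels[, , k]
  if (any(lab[hot] == 0))
    stop("hot ROI extends outside the cylinder on this grid")
  sl <- img_sphere1$data[, , k]
  avg_cold <- mean(sl[cold]); sd_cold <- sd(sl[cold])
  avg_hot <- mean(sl[hot]); sd_hot <- sd(sl[hot])
  sor <- if (avg_hot > 0) avg_cold / avg_hot else NA_real_
  defined <- avg_cold != 0 && avg_hot != 0
  cv <- if (defined) sqrt((sd_cold / avg_cold)^2 + (sd_hot / avg_hot)^2)
  else NA_real_
  structure(list(sor = sor, cv_sor = cv, cv_sor_defined = defined,
                 avg_cold = avg_cold, sd_cold = sd_cold,
                 avg_hot = avg_hot, sd_hot = sd_hot, slice = k,
                 provenance = img_sphere1$provenance,
                 model_id = img_sphere1$model_id),
            class = "spillover_stats")
}

#' @export
print.spillover_stats <- function(x, ...) {
  cat(sprintf("<spillover_stats> (%s) SOR %.4g, CV_SOR %s\n",
              x$provenance, x$sor,
              if (x$cv_sor_defined) sprintf("%.4g", x$cv_sor) else "undefined"))
  invisible(x)
}

#' Collect metrics objects into a tidy table
#'
#' @param ... `image_pair_stats`, `rod_recovery_stats` or
#'   `spillover_stats` objects (optionally named).
#' @return A tibble with one row per scalar metric (rods keyed by
#'   diameter).
#' @export
metrics_table <- function(...) {
  objs <- list(...)
  rows <- lapply(objs, function(o) {
    variant <- if (!is.null(o$model_id)) paste0("prc_", o$model_id)
    else (o$provenance %||% o$test_provenance) %||% NA_character_
    if (inherits(o, "image_pair_stats")) {
      tibble::tibble(variant = variant, metric = c("rmse", "psnr"),
                     diameter_mm = NA_real_, value = c(o$rmse, o$psnr))
    } else if (inherits(o, "rod_recovery_stats")) {
      tibble::tibble(variant = variant,
                     metric = rep(c("rc", "cv_rc"),
                                  each = nrow(o$per_rod)),
                     diameter_mm = rep(o$per_rod$diameter_mm, 2),
                     value = c(o$per_rod$rc, o$per_rod$cv_rc))
    } else if (inherits(o, "spillover_stats")) {
      tibble::tibble(variant = variant, metric = c("sor", "cv_sor"),
                     diameter_mm = NA_real_, value = c(o$sor, o$cv_sor))
    } else stop("unsupported metrics object of class ", class(o)[1])
  })
  do.call(rbind, rows)
}
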