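#' Voxel grid description for digital phantoms
#'
#' Phantoms are built on an isotropic voxel grid centered on the scanner
#' field of view, `n_xy` voxels in-plane and `n_z` voxels axially.  The
#' default 250 x 250 x 200 grid at 0.4 mm matches a 10 cm transaxial FOV
#' and the 80 mm length of the cylindrical image-quality phantoms; the
#' brain surrogate uses a longer 290-slice grid (11.6 cm axial FOV).
#'
#' @param n_xy In-plane grid size (voxels).
#' @param n_z Number of axial slices.
#' @param voxel_size_mm Isotropic voxel edge length in mm.
#' @return A `phantom_grid` list with fields `n_xy`, `n_z`, `voxel_size_mm`.
#' @export
phantom_grid <- function(n_xy = 250L, n_z = 200L, voxel_size_mm = 0.4) {
  stopifnot(n_xy >= 1, n_z >= 1, voxel_size_mm > 0)
  structure(list(n_xy = as.integer(n_xy), n_z = as.integer(n_z),
                 voxel_size_mm = voxel_size_mm),
            class = "phantom_grid")
}

# In-plane voxel-center coordinate matrices (mm), grid-centered.
plane_coords <- function(grid) {
  x <- axis_coords(grid$n_xy, grid$voxel_size_mm)
  list(X = matrix(x, grid$n_xy, grid$n_xy),
       Y = matrix(x, grid$n_xy, grid$n_xy, byrow = TRUE))
}

# Axial slice selector for a phantom of physical length `length_mm`; grids
# shorter than the phantom simply truncate it.
z_indices <- function(grid, length_mm) {
  z <- axis_coords(grid$n_z, grid$voxel_size_mm)
  which(abs(z) <= length_mm / 2 + 1e-9)
}

voxel_volume_ml <- function(voxel_size_mm) (voxel_size_mm / 10)^3

new_voxel_phantom <- function(activity, labels, grid, family, config_id,
                              tbr = NULL, regions = NULL, meta = list()) {
  stopifnot(identical(dim(activity), dim(labels)), all(activity >= 0))
  storage.mode(labels) <- "integer"
  structure(list(activity = activity, labels = labels,
                 voxel_size_mm = grid$voxel_size_mm, family = family,
                 config_id = config_id, tbr = tbr, regions = regions,
                 meta = meta),
            class = "voxel_phantom")
}

#' @export
print.voxel_phantom <- function(x, ...) {
  d <- dim(x$activity)
  cat(sprintf("<voxel_phantom> %s (%s)\n", x$config_id, x$family))
  cat(sprintf("  grid %d x %d x %d @ %.2f mm, total activity %.4g Bq\n",
              d[1], d[2], d[3], x$voxel_size_mm, phantom_total_activity(x)))
  if (!is.null(x$tbr)) cat(sprintf("  TBR = %g\n", x$tbr))
  invisible(x)
}

#' Total activity of a phantom in Bq
#'
#' Sums activity concentration (Bq/mL) times voxel volume over the grid.
#' @param phantom A `voxel_phantom`.
#' @return Total activity in Bq.
#' @export
phantom_total_activity <- function(phantom) {
  sum(phantom$activity) * voxel_volume_ml(phantom$voxel_size_mm)
}

# Stack a 2-d in-plane field into slices `zidx` of an empty volume.
stack_slices <- function(field2d, grid, zidx) {
  vol <- array(0, c(grid$n_xy, grid$n_xy, grid$n_z))
  vol[, , zidx] <- field2d
  vol
}

# ---------------------------------------------------------------------------
# Five-rod cylinder phantom

ROD5_DIAMETERS_MM <- c(2, 4, 6, 8, 10)
ROD5_ANGLES_DEG   <- c(90, 162, 234, 306, 18)
ROD5_RING_RADIUS_MM <- 14
ROD_ACTIVITY_BQ_ML <- 1.69e6
CYLINDER_DIAMETER_MM <- 50
CYLINDER_LENGTH_MM <- 80

#' Five-rod image-quality phantom
#'
#' A 50 mm diameter, 80 mm long cylinder holding five rods of 2, 4, 6, 8
#' and 10 mm diameter filled at 1.69e6 Bq/mL.  The cylinder background is
#' filled at `rod / tbr` for a target-to-background ratio `tbr > 0`, and is
#' cold (zero activity) for `tbr = 0`.  Rod angular positions are fixed
#' package constants (72 degrees apart on a 14 mm ring).
#'
#' @param tbr Target-to-background ratio, >= 0.
#' @param grid A [phantom_grid()].
#' @param config_id Configuration identifier.
#' @return A `voxel_phantom` with rod labels 1..5 (ascending diameter) and
#'   cylinder background label 6.
#' @export
make_rod5_phantom <- function(tbr, grid = phantom_grid(),
                              config_id = sprintf("rod5_tbr%g", tbr)) {
  stopifnot(is.numeric(tbr), length(tbr) == 1, tbr >= 0)
  pc <- plane_coords(grid)
  r_cyl <- CYLINDER_DIAMETER_MM / 2
  cyl <- pc$X^2 + pc$Y^2 <= r_cyl^2
  lab2d <- matrix(0L, grid$n_xy, grid$n_xy)
  lab2d[cyl] <- 6L
  bg_act <- if (tbr > 0) ROD_ACTIVITY_BQ_ML / tbr else 0
  act2d <- matrix(0, grid$n_xy, grid$n_xy)
  act2d[cyl] <- bg_act
  theta <- ROD5_ANGLES_DEG * pi / 180
  cx <- ROD5_RING_RADIUS_MM * cos(theta)
  cy <- ROD5_RING_RADIUS_MM * sin(theta)
  for (i in seq_along(ROD5_DIAMETERS_MM)) {
    m <- (pc$X - cx[i])^2 + (pc$Y - cy[i])^2 <= (ROD5_DIAMETERS_MM[i] / 2)^2
    lab2d[m] <- i
    act2d[m] <- ROD_ACTIVITY_BQ_ML
  }
  zidx <- z_indices(grid, CYLINDER_LENGTH_MM)
  regions <- tibble::tibble(
    label = c(1:5, 6L),
    region = c(rep("rod", 5), "cylinder"),
    diameter_mm = c(ROD5_DIAMETERS_MM, CYLINDER_DIAMETER_MM),
    activity_bq_ml = c(rep(ROD_ACTIVITY_BQ_ML, 5), bg_act))
  new_voxel_phantom(stack_slices(act2d, grid, zidx),
                    stack_slices(lab2d, grid, zidx),
                    grid, "rod5", config_id, tbr = tbr, regions = regions,
                    meta = list(rod_centers_mm = cbind(x = cx, y = cy)))
}

# ---------------------------------------------------------------------------
# Cold-sphere cylinder phantom

#' Cold-sphere spill-over phantom
#'
#' A 50 mm diameter, 80 mm long cylinder at 1.69e6 Bq/mL with a 10 mm
#' diameter water-filled (cold) sphere at its center.
#'
#' @param grid A [phantom_grid()].
#' @param config_id Configuration identifier.
#' @return A `voxel_phantom` with cylinder label 1 and sphere label 2.
#' @export
make_sphere1_phantom <- function(grid = phantom_grid(), config_id = "sphere1") {
  pc <- plane_coords(grid)
  r_cyl <- CYLINDER_DIAMETER_MM / 2
  cyl2d <- pc$X^2 + pc$Y^2 <= r_cyl^2
  zidx <- z_indices(grid, CYLINDER_LENGTH_MM)
  act <- stack_slices(ifelse(cyl2d, ROD_ACTIVITY_BQ_ML, 0), grid, zidx)
  lab <- stack_slices(ifelse(cyl2d, 1L, 0L), grid, zidx)
  z <- axis_coords(grid$n_z, grid$voxel_size_mm)
  r2d <- pc$X^2 + pc$Y^2
  for (k in zidx) {
    sph <- r2d + z[k]^2 <= 5^2
    if (any(sph)) {
      sl_a <- act[, , k]; sl_a[sph] <- 0; act[, , k] <- sl_a
      sl_l <- lab[, , k]; sl_l[sph] <- 2L; lab[, , k] <- sl_l
    }
  }
  regions <- tibble::tibble(
    label = c(1L, 2L), region = c("cylinder", "sphere"),
    diameter_mm = c(CYLINDER_DIAMETER_MM, 10),
    activity_bq_ml = c(ROD_ACTIVITY_BQ_ML, 0))
  new_voxel_phantom(act, lab, grid, "sphere1", config_id, regions = regions,
                    meta = list(sphere_center_mm = c(0, 0, 0),
                                sphere_diameter_mm = 10))
}

# ---------------------------------------------------------------------------
# Twenty-rod (hot-rod) elliptical phantom

ROD20_SECTORS <- data.frame(
  angle_deg = c(45, 135, 225, 315),
  diameter_mm = c(2, 4, 3, 5),
  shade = c("white", "white", "gray", "gray"))
ROD20_GRAY_ACTIVITY_BQ_ML <- 8.44e5
ROD20_BASE_RADIUS_MM <- 15

# Rod-center offsets (radial u, tangential v) of one 5-rod sector cluster,
# center-to-center spacing 2 d: a tangential row of three plus an inner row
# of two.
rod20_sector_offsets <- function(d) {
  a <- 2 * d
  cbind(u = c(0, 0, 0, -a * sqrt(3) / 2, -a * sqrt(3) / 2),
        v = c(-a, 0, a, -a / 2, a / 2))
}

#' Twenty-rod hot-rod phantom
#'
#' An elliptical cylinder (major axis 55 mm, minor axis 50 mm, length
#' 80 mm) holding 20 rods in four diameter-grouped sectors (2, 3, 4, 5 mm;
#' five rods each).  "White" rods (2 and 4 mm sectors) are filled at
#' 1.69e6 Bq/mL and "gray" rods (3 and 5 mm sectors) at 8.44e5 Bq/mL; the
#' ellipse background is cold.  Rod positions are fixed package constants.
#'
#' @param grid A [phantom_grid()].
#' @param config_id Configuration identifier.
#' @return A `voxel_phantom` with rod labels 1..20 and ellipse label 21.
#' @export
make_rod20_phantom <- function(grid = phantom_grid(), config_id = "rod20") {
  pc <- plane_coords(grid)
  ell <- (pc$X / 27.5)^2 + (pc$Y / 25)^2 <= 1
  lab2d <- matrix(0L, grid$n_xy, grid$n_xy)
  lab2d[ell] <- 21L
  act2d <- matrix(0, grid$n_xy, grid$n_xy)
  centers <- NULL
  for (s in seq_len(nrow(ROD20_SECTORS))) {
    th <- ROD20_SECTORS$angle_deg[s] * pi / 180
    d <- ROD20_SECTORS$diameter_mm[s]
    er <- c(cos(th), sin(th)); et <- c(-sin(th), cos(th))
    off <- rod20_sector_offsets(d)
    for (i in seq_len(nrow(off))) {
      ctr <- ROD20_BASE_RADIUS_MM * er + off[i, "u"] * er + off[i, "v"] * et
      centers <- rbind(centers, data.frame(
        x = ctr[1], y = ctr[2], diameter_mm = d,
        shade = ROD20_SECTORS$shade[s]))
    }
  }
  # Geometric sanity: rods must not overlap and centers must lie inside the
  # ellipse bore.
  n <- nrow(centers)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dist <- sqrt((centers$x[i] - centers$x[j])^2 + (centers$y[i] - centers$y[j])^2)
    if (dist < (centers$diameter_mm[i] + centers$diameter_mm[j]) / 2)
      stop(sprintf("rods %d and %d overlap (center distance %.2f mm)", i, j, dist))
  }
  if (any((centers$x / 27.5)^2 + (centers$y / 25)^2 >= 1))
    stop("a rod center lies outside the elliptical bore")
  for (i in seq_len(n)) {
    m <- (pc$X - centers$x[i])^2 + (pc$Y - centers$y[i])^2 <=
      (centers$diameter_mm[i] / 2)^2
    lab2d[m] <- as.integer(i)
    act2d[m] <- if (centers$shade[i] == "white") ROD_ACTIVITY_BQ_ML
                else ROD20_GRAY_ACTIVITY_BQ_ML
  }
  zidx <- z_indices(grid, CYLINDER_LENGTH_MM)
  regions <- tibble::tibble(
    label = c(seq_len(n), 21L),
    region = c(rep("rod", n), "ellipse"),
    diameter_mm = c(centers$diameter_mm, NA_real_),
    shade = c(centers$shade, NA_character_),
    activity_bq_ml = c(ifelse(centers$shade == "white", ROD_ACTIVITY_BQ_ML,
                              ROD20_GRAY_ACTIVITY_BQ_ML), 0))
  new_voxel_phantom(stack_slices(act2d, grid, zidx),
                    stack_slices(lab2d, grid, zidx),
                    grid, "rod20", config_id, regions = regions,
                    meta = list(rod_centers_mm = centers))
}

# ---------------------------------------------------------------------------
# Procedural brain surrogate

BRAIN_TOTAL_ACTIVITY_BQ <- 3.7e6
# Mild affine deformations indexed 0..4 (identity, anisotropic scalings and
# a shear); exactly invertible so transformed phantoms stay analytic.
brain_deformation_matrix <- function(index) {
  switch(index + 1L,
         diag(3),
         diag(c(1.04, 0.96, 1.00)),
         diag(c(0.96, 1.04, 1.01)),
         matrix(c(1, 0.05, 0, 0, 1, 0, 0, 0, 1), 3, 3),
         diag(c(1.02, 1.02, 0.95)))
}

#' Procedural brain-surrogate phantom
#'
#' A multi-compartment activity map standing in for a voxelized brain
#' phantom: a cortical gray-matter shell (relative activity 4) around a
#' white-matter core (relative activity 1), two cold ventricles and four
#' hot deep-nuclei blobs (relative activity 4), the classic 4:1
#' gray-to-white uptake ratio.  The phantom can be translated in-plane,
#' rotated about the axial axis and deformed by one of five mild affine
#' deformations; structure positions are jittered by up to 1 mm using
#' `seed`, and the activity map is rescaled after transformation so the
#' total activity is exactly `total_activity_bq`.
#'
#' @param seed Integer seed controlling structure jitter.
#' @param translation In-plane translation (x, y) in mm.
#' @param rotation_deg Rotation about the axial axis in degrees.
#' @param deformation_index Integer 0..4 selecting the deformation.
#' @param grid A [phantom_grid()]; the default brain grid has 290 slices.
#' @param total_activity_bq Total activity after transformation (Bq).
#' @param config_id Configuration identifier.
#' @return A `voxel_phantom` with labels: 1 cortex, 2 white matter,
#'   3-4 ventricles, 5-8 deep nuclei.
#' @export
make_brain_phantom <- function(seed, translation = c(0, 0), rotation_deg = 0,
                               deformation_index = 0L,
                               grid = phantom_grid(250L, 290L),
                               total_activity_bq = BRAIN_TOTAL_ACTIVITY_BQ,
                               config_id = NULL) {
  stopifnot(length(translation) == 2,
            deformation_index %in% 0:4)
  if (is.null(config_id))
    config_id <- sprintf("brain_t%g.%g_r%g_d%d", translation[1], translation[2],
                         rotation_deg, deformation_index)
  fov_xy <- grid$n_xy * grid$voxel_size_mm
  fov_z <- grid$n_z * grid$voxel_size_mm
  # Head ellipsoid semi-axes scale with the grid so reduced desk grids hold
  # a proportionally smaller head; full-size default is 38 x 46 x 34 mm.
  sc <- min(fov_xy / 100, fov_z / 116, 1)
  ax <- c(38, 46, 34) * sc
  jit <- with_seed(seed, runif(18, -1, 1)) * sc
  ventricles <- list(
    list(c = c(-7, 8, 6) * sc + jit[1:3],   s = c(4.5, 13, 7) * sc),
    list(c = c(7, 8, 6) * sc + jit[4:6],    s = c(4.5, 13, 7) * sc))
  nuclei <- list(
    list(c = c(-7, -4, -2) * sc + jit[7:9],   s = c(5, 6.5, 5.5) * sc),
    list(c = c(7, -4, -2) * sc + jit[10:12],  s = c(5, 6.5, 5.5) * sc),
    list(c = c(-11, 12, 0) * sc + jit[13:15], s = c(4.5, 7, 5) * sc),
    list(c = c(11, 12, 0) * sc + jit[16:18],  s = c(4.5, 7, 5) * sc))

  th <- rotation_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  M <- brain_deformation_matrix(as.integer(deformation_index))
  # World -> local: undo deformation and rotation after removing the
  # translation; shapes are evaluated analytically in local coordinates.
  A <- solve(M %*% R)

  pc <- plane_coords(grid)
  z <- axis_coords(grid$n_z, grid$voxel_size_mm)
  Xs <- pc$X - translation[1]
  Ys <- pc$Y - translation[2]
  act <- array(0, c(grid$n_xy, grid$n_xy, grid$n_z))
  lab <- array(0L, c(grid$n_xy, grid$n_xy, grid$n_z))
  inside_ell <- function(x, y, zc, ctr, s)
    ((x - ctr[1]) / s[1])^2 + ((y - ctr[2]) / s[2])^2 + ((zc - ctr[3]) / s[3])^2 <= 1
  for (k in seq_len(grid$n_z)) {
    xl <- A[1, 1] * Xs + A[1, 2] * Ys + A[1, 3] * z[k]
    yl <- A[2, 1] * Xs + A[2, 2] * Ys + A[2, 3] * z[k]
    zl <- A[3, 1] * Xs + A[3, 2] * Ys + A[3, 3] * z[k]
    outer_m <- (xl / ax[1])^2 + (yl / ax[2])^2 + (zl / ax[3])^2 <= 1
    if (!any(outer_m)) next
    inner_m <- (xl / (0.8 * ax[1]))^2 + (yl / (0.8 * ax[2]))^2 +
      (zl / (0.8 * ax[3]))^2 <= 1
    a2d <- matrix(0, grid$n_xy, grid$n_xy)
    l2d <- matrix(0L, grid$n_xy, grid$n_xy)
    a2d[outer_m] <- 4; l2d[outer_m] <- 1L          # cortex shell
    a2d[inner_m] <- 1; l2d[inner_m] <- 2L          # white matter
    for (i in seq_along(nuclei)) {
      m <- inner_m & inside_ell(xl, yl, zl, nuclei[[i]]$c, nuclei[[i]]$s)
      a2d[m] <- 4; l2d[m] <- 4L + i
    }
    for (i in seq_along(ventricles)) {
      m <- inner_m & inside_ell(xl, yl, zl, ventricles[[i]]$c, ventricles[[i]]$s)
      a2d[m] <- 0; l2d[m] <- 2L + i
    }
    act[, , k] <- a2d
    lab[, , k] <- l2d
  }
  check_not_clipped(act, grid)
  tot <- sum(act) * voxel_volume_ml(grid$voxel_size_mm)
  if (tot <= 0) stop("brain surrogate has no activity on this grid")
  act <- act * (total_activity_bq / tot)
  regions <- tibble::tibble(
    label = 1:8,
    region = c("cortex", "white_matter", "ventricle", "ventricle",
               rep("nucleus", 4)),
    diameter_mm = NA_real_,
    activity_bq_ml = NA_real_)
  new_voxel_phantom(act, lab, grid, "brain", config_id, regions = regions,
                    meta = list(seed = seed, translation_mm = translation,
                                rotation_deg = rotation_deg,
                                deformation_index = as.integer(deformation_index),
                                geometry_scale = sc))
}

# Error (naming the offending margin) if nonzero activity reaches the grid
# boundary, i.e. the transform clipped the phantom.
check_not_clipped <- function(act, grid) {
  d <- dim(act)
  faces <- list(`x-min` = act[1, , ], `x-max` = act[d[1], , ],
                `y-min` = act[, 1, ], `y-max` = act[, d[2], ],
                `z-min` = act[, , 1], `z-max` = act[, , d[3]])
  bad <- names(faces)[vapply(faces, function(f) any(f > 0), logical(1))]
  if (length(bad))
    stop("phantom activity clipped at grid margin(s): ",
         paste(bad, collapse = ", "))
  invisible(TRUE)
}

# ---------------------------------------------------------------------------
# Configuration plan

#' Default 30-configuration phantom plan
#'
#' Twenty brain-surrogate configurations (2 translations x 2 rotations x
#' 5 deformations), eight five-rod phantoms (TBR 0, 2, 4, 5, 8, 10, 16,
#' 20), one cold-sphere phantom and one twenty-rod phantom.
#'
#' @return A `configuration_plan` tibble with one row per configuration.
#' @export
default_configuration_plan <- function() {
  brain <- expand.grid(deformation = 0:4, rotation_deg = c(0, 10),
                       tx = c(0, 2), KEEP.OUT.ATTRS = FALSE)
  entries <- tibble::tibble(
    family = c(rep("brain", nrow(brain)), rep("rod5", 8), "sphere1", "rod20"),
    config_id = c(sprintf("brain_t%g.0_r%g_d%d", brain$tx, brain$rotation_deg,
                          brain$deformation),
                  sprintf("rod5_tbr%g", c(0, 2, 4, 5, 8, 10, 16, 20)),
                  "sphere1", "rod20"),
    tbr = c(rep(NA_real_, nrow(brain)), c(0, 2, 4, 5, 8, 10, 16, 20),
            NA_real_, NA_real_),
    translation_x = c(brain$tx, rep(NA_real_, 10)),
    translation_y = c(rep(0, nrow(brain)), rep(NA_real_, 10)),
    rotation_deg = c(brain$rotation_deg, rep(NA_real_, 10)),
    deformation = c(brain$deformation, rep(NA_integer_, 10)))
  structure(entries, class = c("configuration_plan", class(entries)))
}

#' Materialize a configuration plan into phantoms
#'
#' @param plan A plan tibble as returned by [default_configuration_plan()]
#'   (the default when `NULL`).
#' @param grid Grid for the cylindrical phantoms.
#' @param brain_grid Grid for the brain surrogates (defaults to `grid`
#'   dimensions with 290 slices at the full 0.4 mm scale, or `grid` itself
#'   when a custom grid is given).
#' @param seed Base seed; each brain configuration derives its own
#'   structure-jitter seed from it.
#' @return A named list of `voxel_phantom` objects, one per plan row.
#' @export
enumerate_configurations <- function(plan = NULL, grid = phantom_grid(),
                                     brain_grid = NULL, seed = 1L) {
  if (is.null(plan)) plan <- default_configuration_plan()
  if (anyDuplicated(plan$config_id))
    stop("duplicate config_id in plan: ",
         plan$config_id[duplicated(plan$config_id)][1])
  if (is.null(brain_grid))
    brain_grid <- phantom_grid(grid$n_xy,
                               max(grid$n_z, round(grid$n_z * 290 / 200)),
                               grid$voxel_size_mm)
  phantoms <- vector("list", nrow(plan))
  names(phantoms) <- plan$config_id
  for (i in seq_len(nrow(plan))) {
    phantoms[[i]] <- switch(
      plan$family[i],
      brain = make_brain_phantom(
        seed = derive_seed(seed, plan$config_id[i]),
        translation = c(plan$translation_x[i], plan$translation_y[i]),
        rotation_deg = plan$rotation_deg[i],
        deformation_index = plan$deformation[i],
        grid = brain_grid, config_id = plan$config_id[i]),
      rod5 = make_rod5_phantom(plan$tbr[i], grid = grid,
                               config_id = plan$config_id[i]),
      sphere1 = make_sphere1_phantom(grid = grid,
                                     config_id = plan$config_id[i]),
      rod20 = make_rod20_phantom(grid = grid, config_id = plan$config_id[i]),
      stop("unknown phantom family: ", plan$family[i]))
  }
  phantoms
}
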