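# ggplot2 visualization helpers.

#' Plot an axial slice of an image volume or phantom
#'
#' @param x An `image_volume` or `voxel_phantom`.
#' @param slice Axial slice index (defaults to the central slice).
#' @return A ggplot object.
#' @export
plot_slice <- function(x, slice = NULL) {
  dat <- if (inherits(x, "voxel_phantom")) x$activity else x$data
  vx <- x$voxel_size_mm
  d <- dim(dat)
  slice <- slice %||% ceiling(d[3] / 2)
  df <- expand.grid(x = axis_coords(d[1], vx), y = axis_coords(d[2], vx))
  df$value <- as.vector(dat[, , slice])
  ggplot2::ggplot(df, ggplot2::aes(x = x, y = y,
                                   fill = value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(option = "inferno") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)", fill = "intensity",
                  title = sprintf("%s, slice %d",
                                  if (inherits(x, "voxel_phantom"))
                                    x$config_id
                                  else paste(x$source_config_id,
                                             x$provenance), slice))
}

#' Compare intensity profiles across image variants
#'
#' Draws the intensity along a horizontal line (fixed y) through an axial
#' slice for several volumes on a shared axis — the standard way to show
#' boundary sharpening after correction.
#'
#' @param images Named list of `image_volume`s on the same grid.
#' @param y_mm In-plane y position of the line (mm).
#' @param slice Axial slice index (defaults to central).
#' @return A ggplot object.
#' @export
plot_line_profiles <- function(images, y_mm = 0, slice = NULL) {
  stopifnot(length(images) >= 1)
  d <- dim(images[[1]]$data)
  vx <- images[[1]]$voxel_size_mm
  slice <- slice %||% ceiling(d[3] / 2)
  row <- which.min(abs(axis_coords(d[2], vx) - y_mm))
  dfs <- lapply(names(images), function(nm) {
    data.frame(x = axis_coords(d[1], vx),
               intensity = images[[nm]]$data[, row, slice], image = nm)
  })
  df <- do.call(rbind, dfs)
  ggplot2::ggplot(df, ggplot2::aes(x = x, y = intensity,
                                   colour = image)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "x (mm)", y = "intensity (counts)",
                  title = sprintf("Line profile at y = %g mm, slice %d",
                                  y_mm, slice))
}

#' Plot the training loss history of a model
#'
#' @param model A trained `trained_model`.
#' @param window Smoothing window (iterations) for the running mean.
#' @return A ggplot object.
#' @export
plot_training <- function(model, window = 100L) {
  stopifnot(length(model$history) > 0)
  h <- model$history
  sm <- stats::filter(h, rep(1 / window, window), sides = 1)
  df <- data.frame(iteration = seq_along(h), loss = h,
                   smoothed = as.numeric(sm))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = iteration)) +
    ggplot2::geom_line(ggplot2::aes(y = loss), alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = smoothed), colour = "red",
                       na.rm = TRUE) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(y = "training loss", title = model$spec$arch_id)
  if (!is.null(model$test_history))
    p <- p + ggplot2::geom_point(
      data = model$test_history,
      ggplot2::aes(x = iteration, y = test_loss),
      colour = "blue")
  p
}

utils::globalVariables(c("x", "y", "value", "intensity", "image",
                         "iteration", "loss", "smoothed", "test_loss"))
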