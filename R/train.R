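# Momentum-SGD training of the deblurring networks and whole-volume
# inference.

#' Training configuration
#'
#' Defaults: mini-batches of 128 patches,
#' learning rate 0.01, momentum 0.9, and the root-mean-square error as
#' the loss (`loss_reduction = "rmse"`), whose self-normalizing gradient
#' keeps the default learning rate stable and effective regardless of the
#' label patch area.  `"pixel_mean"` (per-pixel MSE) and `"patch_sum"`
#' (per-patch squared-error sums averaged over the batch) are available
#' alternatives; the latter diverges at the default learning rate.
#'
#' @param iterations Number of SGD iterations (mini-batches).
#' @param batch_size Mini-batch size.
#' @param learning_rate SGD step size.
#' @param momentum Classical momentum coefficient.
#' @param seed Seed for shuffling (and any stochastic bookkeeping).
#' @param head_weights Deep-supervision head loss weights (recycled to the
#'   number of heads).
#' @param loss_reduction `"rmse"` (default), `"pixel_mean"` or
#'   `"patch_sum"`.
#' @param log_every Record test loss every this many iterations when a
#'   test set is supplied to [train()].
#' @return A `train_config` list.
#' @export
train_config <- function(iterations = 2000L, batch_size = 128L,
                         learning_rate = 0.01, momentum = 0.9, seed = 1L,
                         head_weights = 0.3,
                         loss_reduction = c("rmse", "pixel_mean",
                                            "patch_sum"),
                         log_every = 200L) {
  stopifnot(iterations >= 0, batch_size >= 1, learning_rate >= 0,
            momentum >= 0, momentum < 1)
  structure(list(iterations = as.integer(iterations),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, momentum = momentum,
                 seed = as.integer(seed), head_weights = head_weights,
                 loss_reduction = match.arg(loss_reduction),
                 log_every = as.integer(log_every)),
            class = "train_config")
}

# Reshape (H, W, N) patch stacks to the (H, W, 1, N) batch layout.
as_batch <- function(patches, idx) {
  d <- dim(patches)
  array(patches[, , idx], c(d[1], d[2], 1L, length(idx)))
}

batch_loss <- function(model, x, y, cfg) {
  fwd <- nn_forward(model, x, want_heads = TRUE, want_cache = FALSE)
  main <- loss_and_grad(fwd$out, y, cfg$loss_reduction)$loss
  if (!is.null(fwd$heads)) {
    hw <- rep_len(cfg$head_weights, length(fwd$heads))
    for (h in seq_along(fwd$heads))
      main <- main + hw[h] * loss_and_grad(fwd$heads[[h]], y,
                                           cfg$loss_reduction)$loss
  }
  main
}

#' Train a deblurring network
#'
#' Classical momentum SGD (`v <- momentum * v - lr * g; w <- w + v`) on
#' seeded, reshuffled epochs of the training patches.  For the deeply
#' supervised network the objective is the main loss plus the weighted sum
#' of the head losses, each head compared against the (already
#' center-aligned) label patch.  Training aborts with a diagnostic if the
#' loss becomes non-finite.
#'
#' @param model A `trained_model` from [init_weights()].
#' @param data A training `patch_pair_set` whose label size matches the
#'   architecture.
#' @param cfg A [train_config()].
#' @param test_data Optional held-out `patch_pair_set` for periodic test
#'   loss logging.
#' @return The model with updated weights, per-iteration `history`, and
#'   (if `test_data` given) a `test_history` data frame.
#' @export
train <- function(model, data, cfg = train_config(), test_data = NULL) {
  stopifnot(inherits(model, "trained_model"), inherits(data, "patch_pair_set"))
  K <- output_size(model$spec, dim(data$inputs)[1])
  if (dim(data$labels)[1] != K)
    stop(sprintf("label size %d does not match architecture output %d",
                 dim(data$labels)[1], K))
  if (cfg$iterations == 0L) return(model)
  n <- dim(data$inputs)[3]
  spec <- model$spec
  hw <- rep_len(cfg$head_weights, length(model$weights$heads))
  # Deterministic reshuffled-epoch batch schedule for the whole run.
  order_all <- integer(0)
  rng_seed <- cfg$seed
  need <- cfg$iterations * cfg$batch_size
  while (length(order_all) < need) {
    rng_seed <- rng_seed + 1L
    order_all <- c(order_all, with_seed(rng_seed, sample.int(n)))
  }
  batch_idx <- matrix(order_all[seq_len(need)], nrow = cfg$batch_size)
  test_x <- test_y <- NULL
  if (!is.null(test_data)) {
    m <- min(dim(test_data$inputs)[3], 256L)
    test_x <- as_batch(test_data$inputs, seq_len(m))
    test_y <- array(test_data$labels[, , seq_len(m)], c(K, K, 1L, m))
  }
  head_stages <- vapply(spec$supervision_heads, function(h) h$stage,
                        integer(1))
  history <- numeric(0)
  test_log <- NULL
  vel <- NULL
  seg_len <- if (is.null(test_data)) cfg$iterations else cfg$log_every
  done <- 0L
  while (done < cfg$iterations) {
    take <- min(seg_len, cfg$iterations - done)
    res <- .train_sgd(model$weights$layers, model$weights$heads,
                      spec$kernels, spec$channels, spec$in_channels,
                      spec$activation == "relu", spec$dense,
                      as.integer(head_stages), as.numeric(hw),
                      data$inputs, data$labels,
                      batch_idx[, done + seq_len(take), drop = FALSE],
                      cfg$learning_rate, cfg$momentum,
                      match(cfg$loss_reduction,
                            c("rmse", "pixel_mean", "patch_sum")) - 1L, vel)
    if (res$diverged_at > 0)
      stop(sprintf("training diverged at iteration %d",
                   done + res$diverged_at))
    model$weights$layers <- res$layers
    model$weights$heads <- res$heads
    vel <- res$vel
    history <- c(history, res$history)
    done <- done + take
    if (!is.null(test_x))
      test_log <- rbind(test_log,
                        data.frame(iteration = done,
                                   test_loss = batch_loss(model, test_x,
                                                          test_y, cfg)))
  }
  model$history <- c(model$history, history)
  model$test_history <- test_log
  model$train_config <- unclass(cfg)
  model
}

# Symmetric (edge-reflecting) padding of an (H, W, 1, N) array by m pixels.
pad_reflect <- function(x, m) {
  d <- dim(x)
  ri <- c(rev(seq_len(m)), seq_len(d[1]), d[1] + 1 - seq_len(m))
  ci <- c(rev(seq_len(m)), seq_len(d[2]), d[2] + 1 - seq_len(m))
  x[ri, ci, , , drop = FALSE]
}

#' Apply a trained network to a Ga-68 volume
#'
#' Slice-wise fully convolutional inference: each axial slice is
#' normalized by the volume maximum, symmetrically padded by the network's
#' half-shrink margin so the output matches the input shape, forwarded,
#' rescaled back to counts, and clamped at zero.
#'
#' @param model A trained `trained_model`.
#' @param img An `image_volume` with provenance `"ga68"`.
#' @param chunk_slices Number of slices forwarded per batch (memory knob).
#' @return An `image_volume` with provenance `"prc"` and `model_id` set to
#'   the architecture id.
#' @export
apply_correction <- function(model, img, chunk_slices = 8L) {
  stopifnot(inherits(model, "trained_model"), inherits(img, "image_volume"))
  if (img$provenance != "ga68")
    stop("apply_correction expects a ga68 volume, got ", img$provenance)
  shrink <- model$spec$total_shrink
  m <- shrink / 2
  stopifnot(m == floor(m))
  nv <- normalize_volume(img)
  d <- dim(img$data)
  out <- array(0, d)
  ks <- seq_len(d[3])
  for (grp in split(ks, ceiling(ks / chunk_slices))) {
    x <- array(nv$image$data[, , grp], c(d[1], d[2], 1L, length(grp)))
    xp <- pad_reflect(x, m)
    y <- nn_forward(model, xp)$out
    out[, , grp] <- y[, , 1, ]
  }
  out <- pmax(out, 0) * nv$scale
  new_image_volume(out, img$voxel_size_mm, "prc", img$source_config_id,
                   model_id = model$spec$arch_id,
                   meta = c(img$meta, list(normalization_scale = nv$scale)))
}
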