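# The three valid-convolution deblurring networks.
#
# CNN1: 3 layers, kernels 9/1/5, channels 64/32/1 (the classic shallow
#       super-resolution network); total shrink 12, so 32 -> 20.
# CNN2: 4 layers, kernels 7/5/3/3, channels 64/64/32/1; shrink 14, 32 -> 18.
# CNN3: the CNN2 backbone with layer-wise dense connections (earlier
#       feature maps are center-cropped and concatenated into every later
#       layer's input) and deeply supervised 1x1 prediction heads on each
#       hidden stage.
#
# All hidden activations are ReLU; the final layer (and every head) is
# linear with one output channel.

#' Build a network architecture specification
#'
#' @param arch_id One of `"CNN1"`, `"CNN2"`, `"CNN3"`.
#' @param head_weight Loss weight of each deep-supervision head (CNN3).
#' @return A `model_spec` describing layers, activations, dense
#'   connections and supervision heads.
#' @export
build_model <- function(arch_id = c("CNN1", "CNN2", "CNN3"),
                        head_weight = 0.3) {
  arch_id <- match.arg(arch_id)
  cfg <- switch(arch_id,
    CNN1 = list(kernels = c(9L, 1L, 5L), channels = c(64L, 32L, 1L),
                dense = FALSE, heads = integer(0)),
    CNN2 = list(kernels = c(7L, 5L, 3L, 3L), channels = c(64L, 64L, 32L, 1L),
                dense = FALSE, heads = integer(0)),
    CNN3 = list(kernels = c(7L, 5L, 3L, 3L), channels = c(64L, 64L, 32L, 1L),
                dense = TRUE, heads = 1:3))
  L <- length(cfg$kernels)
  activation <- c(rep("relu", L - 1), "linear")
  # Input channels per layer: previous layer's output, or, with dense
  # connections, the raw input plus every earlier feature map.
  in_channels <- integer(L)
  for (l in seq_len(L)) {
    in_channels[l] <- if (l == 1) 1L
    else if (cfg$dense) 1L + sum(cfg$channels[seq_len(l - 1)])
    else cfg$channels[l - 1]
  }
  structure(list(arch_id = arch_id, kernels = cfg$kernels,
                 channels = cfg$channels, in_channels = in_channels,
                 activation = activation, dense = cfg$dense,
                 supervision_heads = if (length(cfg$heads))
                   lapply(cfg$heads, function(s) list(stage = s,
                                                      weight = head_weight))
                 else list(),
                 total_shrink = sum(cfg$kernels - 1L)),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s: kernels %s, channels %s%s%s\n", x$arch_id,
              paste(x$kernels, collapse = "/"),
              paste(x$channels, collapse = "/"),
              if (x$dense) ", dense" else "",
              if (length(x$supervision_heads))
                sprintf(", %d supervision heads", length(x$supervision_heads))
              else ""))
  cat(sprintf("  32 x 32 input -> %d x %d output\n",
              32L - x$total_shrink, 32L - x$total_shrink))
  invisible(x)
}

#' Output spatial size of a network for a given input size
#' @param spec A `model_spec`.
#' @param input_size Input spatial width in pixels.
#' @return Output spatial width (input minus the total valid-convolution
#'   shrink).
#' @export
output_size <- function(spec, input_size = 32L) {
  as.integer(input_size - spec$total_shrink)
}

xavier_sd <- function(kh, kw, cin, cout) sqrt(2 / (kh * kw * cin + kh * kw * cout))

#' Initialize network weights
#'
#' Filter weights are drawn from a zero-mean normal with the Glorot/Xavier
#' variance `2 / (fan_in + fan_out)` (fans counted as kernel area times
#' channels); all biases start at zero.  Deep-supervision heads are
#' initialized the same way.
#'
#' @param spec A `model_spec`.
#' @param seed Integer seed; the same seed reproduces the weights bit for
#'   bit.
#' @return A `trained_model` with untrained weights and empty history.
#' @export
init_weights <- function(spec, seed = 1L) {
  weights <- with_seed(seed, {
    layers <- lapply(seq_along(spec$kernels), function(l) {
      k <- spec$kernels[l]
      cin <- spec$in_channels[l]
      cout <- spec$channels[l]
      list(W = array(rnorm(k * k * cin * cout, sd = xavier_sd(k, k, cin, cout)),
                     c(k, k, cin, cout)),
           b = numeric(cout))
    })
    heads <- lapply(spec$supervision_heads, function(h) {
      cin <- spec$channels[h$stage]
      list(W = array(rnorm(cin, sd = xavier_sd(1, 1, cin, 1)),
                     c(1L, 1L, cin, 1L)),
           b = numeric(1))
    })
    list(layers = layers, heads = heads)
  })
  structure(list(spec = spec, weights = weights, history = numeric(0),
                 test_history = NULL, seed = as.integer(seed)),
            class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  print(x$spec)
  if (length(x$history))
    cat(sprintf("  trained %d iterations; final loss %.4g\n",
                length(x$history), tail(x$history, 1)))
  else cat("  untrained\n")
  invisible(x)
}

# --- array helpers ---------------------------------------------------------

# Center-crop the spatial dimensions of an (H, W, C, N) array to size s.
crop_spatial <- function(x, s) {
  d <- dim(x)
  if (d[1] == s) return(x)
  m <- (d[1] - s) / 2
  stopifnot(m == floor(m))
  x[m + seq_len(s), m + seq_len(s), , , drop = FALSE]
}

# Zero-pad the spatial dimensions back to size s (adjoint of crop_spatial).
uncrop_spatial <- function(g, s) {
  d <- dim(g)
  if (d[1] == s) return(g)
  m <- (s - d[1]) / 2
  out <- array(0, c(s, s, d[3], d[4]))
  out[m + seq_len(d[1]), m + seq_len(d[2]), , ] <- g
  out
}

bind_channels <- function(parts) {
  d1 <- dim(parts[[1]])
  ch <- vapply(parts, function(p) dim(p)[3], integer(1))
  out <- array(0, c(d1[1], d1[2], sum(ch), d1[4]))
  at <- 0L
  for (p in parts) {
    out[, , at + seq_len(dim(p)[3]), ] <- p
    at <- at + dim(p)[3]
  }
  out
}

# --- forward / backward ----------------------------------------------------

# Forward pass over a batch x of shape (H, W, 1, N).  Returns the network
# output, head outputs, and (optionally) the cache needed for backprop.
nn_forward <- function(model, x, want_heads = FALSE, want_cache = FALSE) {
  spec <- model$spec
  L <- length(spec$kernels)
  feats <- vector("list", L)
  inputs <- if (want_cache) vector("list", L) else NULL
  cur <- x
  for (l in seq_len(L)) {
    inp <- if (l == 1) {
      x
    } else if (spec$dense) {
      s <- dim(feats[[l - 1]])[1]
      bind_channels(c(list(crop_spatial(x, s)),
                      lapply(feats[seq_len(l - 1)], crop_spatial, s = s)))
    } else {
      feats[[l - 1]]
    }
    if (want_cache) inputs[[l]] <- inp
    pre <- .conv2d_forward(inp, model$weights$layers[[l]]$W,
                           model$weights$layers[[l]]$b)
    feats[[l]] <- if (spec$activation[l] == "relu") pmax(pre, 0) else pre
  }
  out <- feats[[L]]
  heads <- NULL
  if (want_heads && length(spec$supervision_heads)) {
    s_out <- dim(out)[1]
    heads <- lapply(seq_along(spec$supervision_heads), function(h) {
      stage <- spec$supervision_heads[[h]]$stage
      .conv2d_forward(crop_spatial(feats[[stage]], s_out),
                      model$weights$heads[[h]]$W, model$weights$heads[[h]]$b)
    })
  }
  list(out = out,
       heads = heads,
       cache = if (want_cache) list(x = x, inputs = inputs, feats = feats)
       else NULL)
}

# Backward pass: gradients of a scalar loss with respect to all weights,
# given the gradient g_out at the network output and optionally g_heads at
# each supervision head output.  Dense concatenations backpropagate by
# splitting the input gradient into channel blocks and zero-padding each
# back to its source's spatial size.
nn_backward <- function(model, cache, g_out, g_heads = NULL) {
  spec <- model$spec
  L <- length(spec$kernels)
  feats <- cache$feats
  g_feat <- vector("list", L)   # grad wrt post-activation feature maps
  g_feat[[L]] <- g_out
  grads <- list(layers = vector("list", L),
                heads = vector("list", length(spec$supervision_heads)))
  # Head contributions attach to their stage's feature map.
  if (length(spec$supervision_heads) && !is.null(g_heads)) {
    s_out <- dim(feats[[L]])[1]
    for (h in seq_along(spec$supervision_heads)) {
      stage <- spec$supervision_heads[[h]]$stage
      cropped <- crop_spatial(feats[[stage]], s_out)
      bw <- .conv2d_backward(cropped, model$weights$heads[[h]]$W,
                             g_heads[[h]], TRUE)
      grads$heads[[h]] <- list(W = bw$gw, b = bw$gb)
      contrib <- uncrop_spatial(bw$gx, dim(feats[[stage]])[1])
      g_feat[[stage]] <- if (is.null(g_feat[[stage]])) contrib
      else g_feat[[stage]] + contrib
    }
  }
  for (l in rev(seq_len(L))) {
    g <- g_feat[[l]]
    if (is.null(g)) {  # stage feeds nothing that received gradient
      k <- spec$kernels[l]
      grads$layers[[l]] <- list(
        W = array(0, dim(model$weights$layers[[l]]$W)),
        b = numeric(spec$channels[l]))
      next
    }
    if (spec$activation[l] == "relu") g <- g * (feats[[l]] > 0)
    need_gx <- l > 1
    bw <- .conv2d_backward(cache$inputs[[l]], model$weights$layers[[l]]$W,
                           g, need_gx)
    grads$layers[[l]] <- list(W = bw$gw, b = bw$gb)
    if (!need_gx) next
    gx <- bw$gx
    if (spec$dense) {
      # channel blocks: [input image, feats 1 .. l-1]
      at <- 1L
      blocks <- c(list(NULL), feats[seq_len(l - 1)])
      sizes <- c(1L, spec$channels[seq_len(l - 1)])
      for (b in seq_along(blocks)) {
        gb <- gx[, , at - 1L + seq_len(sizes[b]), , drop = FALSE]
        at <- at + sizes[b]
        if (b == 1L) next  # gradient wrt the input image is not needed
        tgt <- b - 1L
        contrib <- uncrop_spatial(gb, dim(feats[[tgt]])[1])
        g_feat[[tgt]] <- if (is.null(g_feat[[tgt]])) contrib
        else g_feat[[tgt]] + contrib
      }
    } else {
      g_feat[[l - 1]] <- if (is.null(g_feat[[l - 1]])) gx
      else g_feat[[l - 1]] + gx
    }
  }
  grads
}

#' Euclidean training loss
#'
#' Mean over the batch of the per-patch summed squared error
#' `sum((pred - label)^2)`, the Euclidean-distance loss (a monotone
#' transform of the per-patch RMSE).
#'
#' @param pred,label Arrays of matching shape; the trailing dimension (if
#'   any) indexes the batch.
#' @return A scalar loss.
#' @export
euclidean_loss <- function(pred, label) {
  if (!identical(dim(pred) %||% length(pred), dim(label) %||% length(label)))
    stop("prediction and label shapes differ")
  nd <- length(dim(pred))
  n <- if (nd >= 3) dim(pred)[nd] else 1L
  sum((pred - label)^2) / n
}

# Loss value and output gradient under the configured reduction.
#  - "rmse":       square root of the per-pixel mean squared error; its
#                  gradient is self-normalizing (diff / (m * rmse)), so the
#                  effective step adapts as the error shrinks
#  - "patch_sum":  mean over batch of per-patch squared-error sums
#  - "pixel_mean": mean squared error per pixel
loss_and_grad <- function(pred, label, reduction = "rmse") {
  n <- dim(pred)[4]
  diff <- pred - label
  if (reduction == "patch_sum") {
    list(loss = sum(diff^2) / n, grad = 2 * diff / n)
  } else if (reduction == "pixel_mean") {
    m <- length(diff)
    list(loss = sum(diff^2) / m, grad = 2 * diff / m)
  } else {
    m <- length(diff)
    l <- sqrt(sum(diff^2) / m)
    list(loss = l, grad = diff / (m * max(l, 1e-12)))
  }
}
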