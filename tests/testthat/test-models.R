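# Network architectures, initialization, loss, training mechanics and
# whole-volume inference.

test_that("valid-convolution arithmetic gives the stated output sizes", {
  expect_equal(sum(build_model("CNN1")$kernels - 1L), 12L)
  expect_equal(sum(build_model("CNN2")$kernels - 1L), 14L)
  expect_equal(output_size(build_model("CNN1")), 20L)
  expect_equal(output_size(build_model("CNN2")), 18L)
  expect_equal(output_size(build_model("CNN3")), 18L)
  # and by actually forwarding a 32x32 patch
  x <- array(runif(32 * 32), c(32, 32, 1, 1))
  for (arch in c("CNN1", "CNN2", "CNN3")) {
    m <- init_weights(build_model(arch), seed = 1)
    out <- prcnet:::nn_forward(m, x)$out
    expect_equal(dim(out)[1:2],
                 rep(if (arch == "CNN1") 20L else 18L, 2))
  }
  expect_length(build_model("CNN3")$supervision_heads, 3L)
  expect_length(build_model("CNN1")$supervision_heads, 0L)
  expect_length(build_model("CNN2")$supervision_heads, 0L)
})

test_that("deep-supervision head maps share the final output size", {
  m <- init_weights(build_model("CNN3"), seed = 2)
  x <- array(runif(32 * 32 * 4), c(32, 32, 1, 4))
  fwd <- prcnet:::nn_forward(m, x, want_heads = TRUE)
  for (h in fwd$heads) expect_equal(dim(h)[1:2], dim(fwd$out)[1:2])
})

test_that("Xavier initialization has the prescribed variance and zero biases", {
  m <- init_weights(build_model("CNN1"), seed = 7)
  for (l in m$weights$layers) expect_true(all(l$b == 0))
  W1 <- m$weights$layers[[1]]$W  # 9x9x1x64: fan_in 81, fan_out 81*64
  expect_gte(length(W1), 5000)
  target <- 2 / (81 + 81 * 64)
  expect_equal(var(as.vector(W1)), target, tolerance = 0.1)
  expect_equal(mean(as.vector(W1)), 0, tolerance = 3 * sqrt(target / length(W1)))
  expect_identical(init_weights(build_model("CNN1"), seed = 7)$weights,
                   m$weights)
})

test_that("euclidean loss matches hand-computed cases", {
  p <- array(0, c(2, 2, 1, 1)); p[1, 1, 1, 1] <- 1; p[2, 2, 1, 1] <- 1
  l <- array(0, c(2, 2, 1, 1))
  expect_equal(euclidean_loss(p, l), 2)      # four terms: 1+0+0+1
  expect_equal(euclidean_loss(l, l), 0)
  K <- 5; n <- 3; c <- 0.2
  lab <- array(runif(K * K * n), c(K, K, 1, n))
  expect_equal(euclidean_loss(lab + c, lab), K^2 * c^2, tolerance = 1e-12)
  expect_error(euclidean_loss(array(0, c(2, 2)), array(0, c(3, 3))), "shape")
})

test_that("analytic gradients agree with finite differences", {
  # one-layer model, double-precision reference path
  spec <- structure(list(arch_id = "CNN1", kernels = 3L, channels = 2L,
                         in_channels = 1L, activation = "linear",
                         dense = FALSE, supervision_heads = list(),
                         total_shrink = 2L), class = "model_spec")
  m <- init_weights(spec, seed = 4)
  # collapse the two channels so the output is scalar-valued per pixel:
  # use channel 1 only as the "output" via a loss on the full tensor
  x <- array(runif(6 * 6 * 1 * 2), c(6, 6, 1, 2))
  y <- array(runif(4 * 4 * 2 * 2), c(4, 4, 2, 2))
  loss_of <- function(W) {
    mm <- m; mm$weights$layers[[1]]$W <- W
    out <- prcnet:::nn_forward(mm, x)$out
    prcnet:::loss_and_grad(out, y, "pixel_mean")$loss
  }
  fwd <- prcnet:::nn_forward(m, x, want_cache = TRUE)
  g <- prcnet:::loss_and_grad(fwd$out, y, "pixel_mean")$grad
  grads <- prcnet:::nn_backward(m, fwd$cache, g)
  W <- m$weights$layers[[1]]$W
  eps <- 1e-5
  for (i in c(1, 7, 13, 18)) {
    Wp <- W; Wp[i] <- Wp[i] + eps
    Wm <- W; Wm[i] <- Wm[i] - eps
    fd <- (loss_of(Wp) - loss_of(Wm)) / (2 * eps)
    expect_equal(grads$layers[[1]]$W[i], fd, tolerance = 1e-4)
  }
})

test_that("multi-layer backward matches finite differences through ReLU and heads", {
  for (arch in c("CNN2", "CNN3")) {
    m <- init_weights(build_model(arch), seed = 6)
    x <- array(runif(32 * 32 * 1 * 2), c(32, 32, 1, 2))
    y <- array(runif(18 * 18 * 1 * 2), c(18, 18, 1, 2))
    hw <- rep(0.3, length(m$spec$supervision_heads))
    total_loss <- function(mm) {
      fwd <- prcnet:::nn_forward(mm, x, want_heads = TRUE)
      tot <- prcnet:::loss_and_grad(fwd$out, y, "pixel_mean")$loss
      if (length(hw)) for (h in seq_along(fwd$heads))
        tot <- tot + hw[h] *
          prcnet:::loss_and_grad(fwd$heads[[h]], y, "pixel_mean")$loss
      tot
    }
    fwd <- prcnet:::nn_forward(m, x, want_heads = TRUE, want_cache = TRUE)
    g <- prcnet:::loss_and_grad(fwd$out, y, "pixel_mean")$grad
    gh <- if (length(hw))
      lapply(fwd$heads, function(h)
        0.3 * prcnet:::loss_and_grad(h, y, "pixel_mean")$grad)
    grads <- prcnet:::nn_backward(m, fwd$cache, g, gh)
    eps <- 1e-5
    for (l in c(1L, length(m$spec$kernels))) {
      W <- m$weights$layers[[l]]$W
      i <- min(11, length(W))
      mp <- m; mp$weights$layers[[l]]$W[i] <- W[i] + eps
      mm2 <- m; mm2$weights$layers[[l]]$W[i] <- W[i] - eps
      fd <- (total_loss(mp) - total_loss(mm2)) / (2 * eps)
      expect_equal(grads$layers[[l]]$W[i], fd, tolerance = 1e-3)
    }
  }
})

test_that("patch-wise forward equals the crop of whole-slice forward", {
  m <- init_weights(build_model("CNN1"), seed = 5)
  slice <- array(runif(48 * 48), c(48, 48, 1, 1))
  whole <- prcnet:::nn_forward(m, slice)$out  # 36x36
  patch <- slice[9 + 1:32, 9 + 1:32, , , drop = FALSE]
  sub <- prcnet:::nn_forward(m, patch)$out    # 20x20
  expect_equal(sub[, , 1, 1], whole[9 + 1:20, 9 + 1:20, 1, 1],
               tolerance = 1e-10)
})

test_that("training is deterministic, inert at zero learning rate, and learns", {
  ps <- random_patch_set("CNN1", n = 160)
  m0 <- init_weights(build_model("CNN1"), seed = 3)
  r0 <- train(m0, ps, train_config(iterations = 3, learning_rate = 0,
                                   seed = 5))
  expect_equal(r0$weights, m0$weights, tolerance = 0)
  ra <- train(m0, ps, train_config(iterations = 5, seed = 9))
  rb <- train(m0, ps, train_config(iterations = 5, seed = 9))
  expect_identical(ra$weights, rb$weights)
  expect_length(ra$history, 5L)
  # on a real deblurring task the loss decreases
  pr <- small_rod5_pair()
  real <- extract_patch_grid(normalize_volume(pr$ga68)$image,
                             normalize_volume(pr$gamma)$image,
                             stride = 14, label_size = 20)
  real$split <- "train"
  rt <- train(m0, real, train_config(iterations = 60, seed = 5))
  expect_lt(mean(tail(rt$history, 10)), mean(head(rt$history, 10)))
})

test_that("label size must match the architecture", {
  ps <- random_patch_set("CNN1")  # 20x20 labels
  m <- init_weights(build_model("CNN2"), seed = 1)  # expects 18x18
  expect_error(train(m, ps, train_config(iterations = 1)), "label size")
})

test_that("whole-volume correction preserves shape, clamps and rescales", {
  pr <- small_rod5_pair()
  ps <- extract_patch_grid(normalize_volume(pr$ga68)$image,
                           normalize_volume(pr$gamma)$image,
                           stride = 14, label_size = 20)
  ps$split <- "train"
  m <- init_weights(build_model("CNN1"), seed = 3)
  m <- train(m, ps, train_config(iterations = 40, seed = 5))
  out <- apply_correction(m, pr$ga68)
  expect_equal(dim(out$data), dim(pr$ga68$data))
  expect_true(all(out$data >= 0))
  expect_equal(out$provenance, "prc")
  expect_equal(out$model_id, "CNN1")
  expect_error(apply_correction(m, pr$gamma), "ga68")
})
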