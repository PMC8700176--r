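# Patch-pair dataset construction and the phantom-level split.

test_that("volume normalization records the scale and round-trips", {
  arr <- array(runif(16 * 16 * 4), c(16, 16, 4)) * 500
  arr[3, 3, 1] <- 500
  img <- as_image(arr)
  nv <- normalize_volume(img)
  expect_equal(nv$scale, 500)
  expect_equal(max(nv$image$data), 1)
  expect_equal(nv$image$data * nv$scale, arr, tolerance = 1e-12)
  z <- normalize_volume(as_image(array(0, c(4, 4, 2))))
  expect_equal(z$scale, 1)
  expect_equal(z$image$data, array(0, c(4, 4, 2)))
})

test_that("patch-grid counts match the closed form and brute-force enumeration", {
  brute <- function(n, patch, stride) {
    pos <- 0L; count <- 0L
    while (pos + patch <= n) { count <- count + 1L; pos <- pos + stride }
    count
  }
  for (case in list(c(250, 32, 14, 16), c(250, 32, 21, 11),
                    c(128, 32, 14, 7), c(64, 32, 21, 2))) {
    off <- patch_offsets(case[1], case[2], case[3])
    expect_equal(length(off), case[4])
    expect_equal(length(off), brute(case[1], case[2], case[3]))
  }
})

test_that("extraction pairs each input with its exact center crop", {
  arr_in <- array(runif(64 * 64 * 2) + 0.1, c(64, 64, 2))
  arr_lab <- array(runif(64 * 64 * 2), c(64, 64, 2))
  for (ls in c(20L, 18L)) {
    ps <- extract_patch_grid(as_image(arr_in, provenance = "ga68"),
                             as_image(arr_lab), stride = 14,
                             label_size = ls, keep_empty = TRUE)
    off <- (32 - ls) / 2
    expect_equal(off, if (ls == 20) 6 else 7)
    n_side <- length(patch_offsets(64, 32, 14))
    expect_equal(dim(ps$inputs)[3], n_side^2 * 2)
    # check a specific patch against direct indexing
    p <- 5
    r <- ps$provenance$row[p]; c <- ps$provenance$col[p]
    k <- ps$provenance$slice[p]
    expect_equal(ps$inputs[, , p], arr_in[r + 1:32, c + 1:32, k])
    expect_equal(ps$labels[, , p],
                 arr_lab[r + off + 1:ls, c + off + 1:ls, k])
  }
})

test_that("empty-air patches are dropped by default", {
  arr <- array(0, c(64, 64, 1))
  arr[40:60, 40:60, 1] <- 1
  ps <- extract_patch_grid(as_image(arr, provenance = "ga68"), as_image(arr),
                           stride = 14, label_size = 20)
  full <- extract_patch_grid(as_image(arr, provenance = "ga68"), as_image(arr),
                             stride = 14, label_size = 20, keep_empty = TRUE)
  expect_lt(dim(ps$inputs)[3], dim(full$inputs)[3])
  expect_true(all(apply(ps$inputs, 3, max) > 0))
})

test_that("label-sized crops at stride = label size tile the interior exactly", {
  arr <- array(runif(60 * 60 * 1) + 0.1, c(60, 60, 1))
  ps <- extract_patch_grid(as_image(arr, provenance = "ga68"), as_image(arr),
                           stride = 20, label_size = 20, keep_empty = TRUE)
  recon <- matrix(NA_real_, 60, 60)
  off <- 6
  for (p in seq_len(dim(ps$labels)[3])) {
    r <- ps$provenance$row[p] + off
    c <- ps$provenance$col[p] + off
    expect_true(all(is.na(recon[r + 1:20, c + 1:20])))  # no overlap
    recon[r + 1:20, c + 1:20] <- ps$labels[, , p]
  }
  inner <- recon[off + 1:40, off + 1:40]
  expect_false(anyNA(inner))  # no gaps in the covered region
  expect_equal(inner, arr[off + 1:40, off + 1:40, 1])
})

test_that("too-small images are rejected", {
  expect_error(extract_patch_grid(as_image(array(1, c(20, 20, 1))),
                                  as_image(array(1, c(20, 20, 1)))),
               "smaller")
})

make_fake_pairs <- function() {
  mk <- function(id, family, tbr = NULL) {
    arr <- array(runif(36 * 36 * 2) + 0.1, c(36, 36, 2))
    list(gamma = as_image(arr, config_id = id),
         ga68 = as_image(arr * 0.9, provenance = "ga68", config_id = id),
         family = family, tbr = tbr)
  }
  ids <- c(sprintf("brain_%02d", 1:20), sprintf("rod5_tbr%g",
                                                c(0, 2, 4, 5, 8, 10, 16, 20)),
           "sphere1", "rod20")
  fams <- c(rep("brain", 20), rep("rod5", 8), "sphere1", "rod20")
  tbrs <- c(rep(list(NULL), 20), as.list(c(0, 2, 4, 5, 8, 10, 16, 20)),
            list(NULL), list(NULL))
  pairs <- Map(mk, ids, fams, tbrs)
  names(pairs) <- ids
  pairs
}

test_that("the phantom-level split follows the study protocol", {
  pairs <- make_fake_pairs()
  sp <- make_splits(pairs, label_size = 20)
  tr <- unique(sp$train$provenance$config_id)
  te <- unique(sp$test$provenance$config_id)
  expect_length(intersect(tr, te), 0)
  expect_equal(sum(grepl("brain", tr)), 16L)
  expect_equal(sum(grepl("brain", te)), 4L)
  expect_setequal(tr[grepl("rod5", tr)],
                  sprintf("rod5_tbr%g", c(0, 4, 5, 8)))
  expect_setequal(te[grepl("rod5", te)],
                  sprintf("rod5_tbr%g", c(2, 10, 16, 20)))
  # evaluation-only phantoms are never patched
  expect_false(any(c("sphere1", "rod20") %in% c(tr, te)))
  expect_equal(sp$train$stride, 14L)
  expect_equal(sp$test$stride, 21L)
  # patch values normalized into [0, 1]
  expect_gte(min(sp$train$inputs), 0)
  expect_lte(max(sp$train$inputs), 1)
  expect_lte(max(sp$train$labels), 1)
})

test_that("patch extraction is deterministic given the volume order", {
  pairs <- make_fake_pairs()
  s1 <- make_splits(pairs, label_size = 18)
  s2 <- make_splits(pairs, label_size = 18)
  expect_identical(s1$train$inputs, s2$train$inputs)
  expect_identical(s1$test$labels, s2$test$labels)
})
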