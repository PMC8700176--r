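# Patch-pair dataset construction: volumes are max-normalized, axial slices
# are tiled with 32 x 32 input patches on a regular stride grid, and labels
# are the center crops of the matching reference-image footprints.

#' Normalize an image volume to unit maximum
#'
#' Divides the volume by its global maximum and records the scale so
#' corrected volumes can be mapped back to counts.  An all-zero volume is
#' returned unchanged with scale 1.
#'
#' @param img An `image_volume`.
#' @return A list with `image` (normalized `image_volume`) and `scale`.
#' @export
normalize_volume <- function(img) {
  stopifnot(inherits(img, "image_volume"))
  scale <- max(img$data)
  if (scale <= 0) scale <- 1
  out <- img
  out$data <- img$data / scale
  out$meta$normalization_scale <- scale
  list(image = out, scale = scale)
}

#' Patch-grid positions along one dimension
#'
#' Start offsets (0-based) of `patch`-wide windows placed with a fixed
#' `stride` from the image edge; the number of positions is
#' `floor((n - patch) / stride) + 1`.
#'
#' @param n Extent of the image dimension.
#' @param patch Patch width.
#' @param stride Stride between consecutive windows.
#' @return Integer vector of 0-based start offsets.
#' @export
patch_offsets <- function(n, patch = 32L, stride = 14L) {
  stopifnot(stride >= 1, n >= patch)
  seq.int(0L, by = as.integer(stride),
          length.out = (n - patch) %/% stride + 1L)
}

new_patch_pair_set <- function(inputs, labels, stride, split, normalization,
                               provenance) {
  structure(list(inputs = inputs, labels = labels, stride = as.integer(stride),
                 split = split, normalization = normalization,
                 provenance = provenance),
            class = "patch_pair_set")
}

#' @export
print.patch_pair_set <- function(x, ...) {
  cat(sprintf("<patch_pair_set> %d patches (%s, stride %d), input %dx%d -> label %dx%d\n",
              dim(x$inputs)[3], x$split %||% "unsplit", x$stride,
              dim(x$inputs)[1], dim(x$inputs)[2],
              dim(x$labels)[1], dim(x$labels)[2]))
  invisible(x)
}

#' Extract an aligned patch grid from an image pair
#'
#' Tiles every axial slice of the (already normalized) input volume with
#' `patch` x `patch` windows at the given stride and pairs each with the
#' `label_size` x `label_size` center crop of the same footprint in the
#' label volume — the region a valid-convolution network predicts from the
#' input patch.  Patches whose input window is identically zero carry no
#' signal and are dropped unless `keep_empty = TRUE`.
#'
#' @param input_img Ga-68 (input) `image_volume`, normalized to `[0, 1]`.
#' @param label_img Gamma (label) `image_volume` on the same grid,
#'   normalized to `[0, 1]`.
#' @param patch Input patch size (32).
#' @param stride Stride of the raster grid (14 for training, 21 for
#'   testing).
#' @param label_size Label crop size, 20 or 18 depending on architecture.
#' @param keep_empty Keep all-zero input patches.
#' @return A `patch_pair_set`; `inputs` is a `patch x patch x N` array,
#'   `labels` a `label_size x label_size x N` array, and `provenance`
#'   records (config_id, slice, row, col) per patch (0-based offsets).
#' @export
extract_patch_grid <- function(input_img, label_img, patch = 32L, stride = 14L,
                               label_size = 20L, keep_empty = FALSE) {
  stopifnot(inherits(input_img, "image_volume"),
            inherits(label_img, "image_volume"),
            identical(dim(input_img$data), dim(label_img$data)),
            label_size %in% c(20L, 18L), (patch - label_size) %% 2 == 0)
  d <- dim(input_img$data)
  if (d[1] < patch || d[2] < patch)
    stop(sprintf("in-plane image size %dx%d is smaller than the %d patch",
                 d[1], d[2], patch))
  off <- (patch - label_size) %/% 2
  rows <- patch_offsets(d[1], patch, stride)
  cols <- patch_offsets(d[2], patch, stride)
  pos <- expand.grid(row = rows, col = cols, KEEP.OUT.ATTRS = FALSE)
  n_per_slice <- nrow(pos)
  inputs <- vector("list", d[3])
  labels <- vector("list", d[3])
  prov <- vector("list", d[3])
  for (k in seq_len(d[3])) {
    sl_in <- input_img$data[, , k]
    sl_lab <- label_img$data[, , k]
    xi <- array(0, c(patch, patch, n_per_slice))
    xl <- array(0, c(label_size, label_size, n_per_slice))
    nz <- logical(n_per_slice)
    for (p in seq_len(n_per_slice)) {
      r <- pos$row[p]; c <- pos$col[p]
      w <- sl_in[r + seq_len(patch), c + seq_len(patch)]
      nz[p] <- any(w > 0)
      if (nz[p] || keep_empty) {
        xi[, , p] <- w
        xl[, , p] <- sl_lab[r + off + seq_len(label_size),
                            c + off + seq_len(label_size)]
      }
    }
    sel <- if (keep_empty) rep(TRUE, n_per_slice) else nz
    if (!any(sel)) next
    inputs[[k]] <- xi[, , sel, drop = FALSE]
    labels[[k]] <- xl[, , sel, drop = FALSE]
    prov[[k]] <- data.frame(config_id = input_img$source_config_id,
                            slice = k, row = pos$row[sel], col = pos$col[sel])
  }
  keep <- !vapply(inputs, is.null, logical(1))
  if (!any(keep))
    stop("no non-empty patches extracted from ", input_img$source_config_id)
  inputs <- array(unlist(inputs[keep], use.names = FALSE),
                  c(patch, patch, sum(vapply(inputs[keep], function(a) dim(a)[3],
                                             numeric(1)))))
  nlab <- dim(inputs)[3]
  labels <- array(unlist(labels[keep], use.names = FALSE),
                  c(label_size, label_size, nlab))
  prov <- do.call(rbind, prov[keep])
  scale <- input_img$meta$normalization_scale %||% 1
  norm <- tibble::tibble(config_id = input_img$source_config_id, scale = scale)
  new_patch_pair_set(inputs, labels, stride, NULL, norm,
                     tibble::as_tibble(prov))
}

concat_patch_sets <- function(sets, split, stride) {
  inputs <- do.call(c, lapply(sets, function(s) as.vector(s$inputs)))
  labels <- do.call(c, lapply(sets, function(s) as.vector(s$labels)))
  di <- dim(sets[[1]]$inputs)[1:2]
  dl <- dim(sets[[1]]$labels)[1:2]
  n <- sum(vapply(sets, function(s) dim(s$inputs)[3], numeric(1)))
  new_patch_pair_set(array(inputs, c(di, n)), array(labels, c(dl, n)),
                     stride, split,
                     do.call(rbind, lapply(sets, function(s) s$normalization)),
                     do.call(rbind, lapply(sets, function(s) s$provenance)))
}

# Fixed rod5 TBR membership of the phantom-level split.
TRAIN_ROD5_TBRS <- c(0, 4, 5, 8)
TEST_ROD5_TBRS <- c(2, 10, 16, 20)

#' Phantom-level train/test split and patch extraction
#'
#' Applies the phantom-level protocol: brain surrogates go 80/20 into
#' train/test
#' (the last fifth of the configuration order is held out; 16/4 for the
#' full 20-configuration plan), five-rod phantoms with TBR 0, 4, 5 or 8
#' train while TBR 2, 10, 16 or 20 test, and the cold-sphere and
#' twenty-rod phantoms are reserved for evaluation only and are never
#' patched.  Training patches use stride 14, testing patches stride 21.
#' Each volume is max-normalized before extraction.
#'
#' @param pairs A named list (by config_id) of lists with elements
#'   `gamma`, `ga68` (`image_volume`s) and `family`.
#' @param label_size Label crop size (20 or 18).
#' @param train_stride,test_stride Patch strides.
#' @return A list with `train` and `test` `patch_pair_set`s.
#' @export
make_splits <- function(pairs, label_size = 20L, train_stride = 14L,
                        test_stride = 21L) {
  fam <- vapply(pairs, function(p) p$family, character(1))
  tbr <- vapply(pairs, function(p) p$tbr %||% NA_real_, numeric(1))
  ids <- names(pairs)
  brain_ids <- ids[fam == "brain"]
  n_test_brain <- if (length(brain_ids)) max(1L, floor(length(brain_ids) / 5)) else 0L
  train_ids <- c(head(brain_ids, length(brain_ids) - n_test_brain),
                 ids[fam == "rod5" & tbr %in% TRAIN_ROD5_TBRS])
  test_ids <- c(tail(brain_ids, n_test_brain),
                ids[fam == "rod5" & tbr %in% TEST_ROD5_TBRS])
  if (length(intersect(train_ids, test_ids)))
    stop("train and test configurations overlap: ",
         paste(intersect(train_ids, test_ids), collapse = ", "))
  if (!length(train_ids) || !length(test_ids))
    stop("split produced an empty train or test set")
  extract_for <- function(id, stride) {
    p <- pairs[[id]]
    extract_patch_grid(normalize_volume(p$ga68)$image,
                       normalize_volume(p$gamma)$image,
                       stride = stride, label_size = label_size)
  }
  train <- concat_patch_sets(lapply(train_ids, extract_for,
                                    stride = train_stride),
                             "train", train_stride)
  test <- concat_patch_sets(lapply(test_ids, extract_for,
                                   stride = test_stride),
                            "test", test_stride)
  list(train = train, test = test)
}
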