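#' Training configuration
#'
#' Mini-batch stochastic gradient descent with momentum on a voxel-wise
#' categorical cross-entropy loss. Reference settings: 50 epochs, learning
#' rate 0.001, momentum 0.9, batch size 50 for the 2D SegNet and 8 for the
#' 3D U-Net.
#'
#' @param epochs number of passes over the data.
#' @param learning_rate SGD step size.
#' @param momentum gradient momentum coefficient.
#' @param batch_size mini-batch size.
#' @param seed integer seed controlling shuffling.
#' @param class_weights optional per-class loss weights: `NULL` (default,
#'   unweighted), a numeric vector (length = number of classes), or
#'   `"inverse"` to use inverse class frequencies computed from the
#'   training labels (counters the extreme background/vessel imbalance).
#' @return an object of class `train_config`.
#' @export
train_config <- function(epochs = 50L, learning_rate = 0.001,
                         momentum = 0.9, batch_size = 50L, seed = 1L,
                         class_weights = NULL) {
  stopifnot(epochs >= 1L, learning_rate >= 0, momentum >= 0, momentum < 1,
            batch_size >= 1L)
  structure(list(epochs = as.integer(epochs),
                 learning_rate = learning_rate, momentum = momentum,
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 class_weights = class_weights),
            class = "train_config")
}

#' Build a 2D SegNet
#'
#' Encoder-decoder for per-pixel classification of 2D slices: 8
#' convolutional layers (3x3, stride 1, `filters` channels each), each
#' followed by batch normalization and ReLU; 2 max-pooling stages in the
#' encoder mirrored by 2 up-sampling stages in the decoder (max-unpooling
#' with the stored pooling indices by default, nearest-neighbor
#' optionally); a final 1x1 convolution maps features to class scores for
#' the soft-max head. Input sizes must be divisible by 4. Reference
#' configuration: 256x256 inputs, 80 filters.
#'
#' @param in_size square input side (divisible by 4).
#' @param n_classes number of output classes.
#' @param filters channels per convolutional layer.
#' @param upsample `"indices"` (max-unpooling) or `"nearest"`.
#' @param seed seed for weight initialization.
#' @return an object of class `nn_model`.
#' @export
build_segnet2d <- function(in_size = 256L, n_classes = 3L, filters = 80L,
                           upsample = c("indices", "nearest"), seed = 1L) {
  upsample <- match.arg(upsample)
  if (in_size %% 4L != 0L) stop("build_segnet2d: in_size must be divisible by 4")
  f <- as.integer(filters)
  with_seed(seed, {
    layers <- list(
      layer_conv2d(1L, f), layer_bn(f), layer_relu(),
      layer_conv2d(f, f), layer_bn(f), layer_relu(),
      layer_pool2(),                                   # 7
      layer_conv2d(f, f), layer_bn(f), layer_relu(),
      layer_conv2d(f, f), layer_bn(f), layer_relu(),
      layer_pool2(),                                   # 14
      layer_unpool2(pair = 14L, mode = upsample),
      layer_conv2d(f, f), layer_bn(f), layer_relu(),
      layer_conv2d(f, f), layer_bn(f), layer_relu(),
      layer_unpool2(pair = 7L, mode = upsample),
      layer_conv2d(f, f), layer_bn(f), layer_relu(),
      layer_conv2d(f, f), layer_bn(f), layer_relu(),
      layer_conv2d(f, n_classes, k = 1L)               # class scores
    )
    structure(list(layers = layers, arch = "segnet2d", dim = 2L,
                   in_size = as.integer(in_size),
                   n_classes = as.integer(n_classes), filters = f),
              class = "nn_model")
  })
}

#' Build a 3D U-Net
#'
#' Patch-based volumetric encoder-decoder: an encoder of 6 convolutional
#' layers (each with batch normalization and ReLU) interleaved with 2
#' max-pooling stages, doubling channels at each stage; a decoder of 2
#' up-convolutional (kernel-2, stride-2 transposed convolution) layers and
#' 2 convolutional layers, with the up-sampled feature concatenated to the
#' resolution-matched encoder feature before each decoder batch
#' normalization; a final 1x1x1 convolution produces class scores for the
#' soft-max head. Reference configuration: 64^3 patches.
#'
#' @param in_size cubic patch side (divisible by 4).
#' @param n_classes number of output classes.
#' @param filters base channel count (doubled at each encoder stage).
#' @param seed seed for weight initialization.
#' @return an object of class `nn_model`.
#' @export
build_unet3d <- function(in_size = 64L, n_classes = 3L, filters = 16L,
                         seed = 1L) {
  if (in_size %% 4L != 0L) stop("build_unet3d: in_size must be divisible by 4")
  f <- as.integer(filters)
  with_seed(seed, {
    layers <- list(
      layer_conv3d(1L, f), layer_bn(f), layer_relu(),
      layer_conv3d(f, f), layer_bn(f), layer_relu(),      # 6: skip A
      layer_pool3(),
      layer_conv3d(f, 2L * f), layer_bn(2L * f), layer_relu(),
      layer_conv3d(2L * f, 2L * f), layer_bn(2L * f), layer_relu(),  # 13: skip B
      layer_pool3(),
      layer_conv3d(2L * f, 4L * f), layer_bn(4L * f), layer_relu(),
      layer_conv3d(4L * f, 4L * f), layer_bn(4L * f), layer_relu(),
      layer_upconv3(4L * f, 2L * f),
      layer_concat3(from = 13L),
      layer_bn(4L * f), layer_relu(),
      layer_conv3d(4L * f, 2L * f), layer_bn(2L * f), layer_relu(),
      layer_upconv3(2L * f, f),
      layer_concat3(from = 6L),
      layer_bn(2L * f), layer_relu(),
      layer_conv3d(2L * f, f), layer_bn(f), layer_relu(),
      layer_conv3d(f, n_classes, k = 1L)
    )
    structure(list(layers = layers, arch = "unet3d", dim = 3L,
                   in_size = as.integer(in_size),
                   n_classes = as.integer(n_classes), filters = f),
              class = "nn_model")
  })
}

#' @export
print.nn_model <- function(x, ...) {
  np <- sum(vapply(x$layers, function(l)
    length(l$W) + length(l$b) + length(l$gamma) + length(l$beta), 0))
  cat(sprintf("nn_model '%s': %d layers, %d classes, in_size %d, %d parameters\n",
              x$arch, length(x$layers), x$n_classes, x$in_size, np))
  invisible(x)
}

# intensity normalization applied consistently at train and predict time
normalize_volume <- function(x) {
  mx <- max(x)
  if (mx <= 0) stop("normalize_volume: volume has no positive intensity")
  x / mx
}

case_volume <- function(case) {
  if (inherits(case, "phantom_case")) case$intensity
  else if (!is.null(case$volume)) case$volume
  else stop("expected a phantom_case or a list(volume=, labels=)")
}

case_labels <- function(case) {
  if (inherits(case, "phantom_case")) case$truth
  else if (!is.null(case$labels)) case$labels
  else stop("expected a phantom_case or a list(volume=, labels=)")
}

slice_3d <- function(arr, axis, i) {
  switch(axis, `1` = arr[i, , ], `2` = arr[, i, ], `3` = arr[, , i])
}

# integer nearest-neighbor / bilinear resize of a 2D matrix via EBImage
resize2d <- function(m, size, label = FALSE) {
  if (all(dim(m) == size)) return(m)
  out <- EBImage::resize(m, w = size, h = size,
                         filter = if (label) "none" else "bilinear")
  if (label) storage.mode(out) <- "integer"
  out
}

#' Slice a dataset along one anatomical axis
#'
#' Extracts every 2D slice of each case along the axis, normalizes
#' intensities to `[0, 1]` per volume, and resizes images (bilinear) and
#' labels (nearest-neighbor) to `out_size` x `out_size`. The original
#' slice geometry is recorded for inverse mapping at prediction time.
#'
#' @param cases list of `phantom_case` objects or `list(volume =, labels =)`
#'   pairs (volume an [intensity_volume()], labels a [label_volume()]).
#' @param axis `"axial"`, `"coronal"` or `"sagittal"`.
#' @param out_size network input side (default 256).
#' @return list of records `list(x, y, case, index, axis, orig_dim)` with
#'   `x` a numeric matrix and `y` an integer label matrix, both
#'   `out_size` x `out_size`.
#' @export
slice_dataset <- function(cases, axis, out_size = 256L) {
  ax <- mip_axis(axis)
  out <- list()
  for (ci in seq_along(cases)) {
    vol <- normalize_volume(case_volume(cases[[ci]])$data)
    lab <- case_labels(cases[[ci]])$data
    dims <- dim(vol)
    for (i in seq_len(dims[ax])) {
      img <- resize2d(slice_3d(vol, ax, i), out_size, label = FALSE)
      lbl <- resize2d(slice_3d(lab, ax, i), out_size, label = TRUE)
      out[[length(out) + 1L]] <- list(x = img, y = lbl, case = ci,
                                      index = i, axis = axis,
                                      orig_dim = dim(slice_3d(vol, ax, i)))
    }
  }
  out
}

#' Cut a dataset into 3D patches
#'
#' Regular grid of cubic patches with the given stride; the final start
#' along each axis is shifted to the volume edge so every voxel is covered
#' by at least one patch. Volumes smaller than the patch are zero-padded.
#' Intensities are normalized to `[0, 1]` per volume.
#'
#' @inheritParams slice_dataset
#' @param patch cubic patch side.
#' @param stride patch grid stride (defaults to `patch`, i.e. no overlap).
#' @return list of records `list(x, y, case, origin)`; `x` and `y` are
#'   `patch`^3 arrays.
#' @export
patch_dataset <- function(cases, patch = 64L, stride = patch) {
  out <- list()
  for (ci in seq_along(cases)) {
    vol <- normalize_volume(case_volume(cases[[ci]])$data)
    lab <- case_labels(cases[[ci]])$data
    pv <- pad_to(vol, patch, 0)
    pl <- pad_to(lab, patch, 0L)
    dims <- dim(pv)
    starts <- lapply(dims, function(d) patch_starts(d, patch, stride))
    for (sx in starts[[1]]) for (sy in starts[[2]]) for (sz in starts[[3]]) {
      out[[length(out) + 1L]] <- list(
        x = pv[sx:(sx + patch - 1L), sy:(sy + patch - 1L),
               sz:(sz + patch - 1L)],
        y = pl[sx:(sx + patch - 1L), sy:(sy + patch - 1L),
               sz:(sz + patch - 1L)],
        case = ci, origin = c(sx, sy, sz))
    }
  }
  out
}

patch_starts <- function(d, patch, stride) {
  s <- seq(1L, max(d - patch + 1L, 1L), by = stride)
  if (s[length(s)] != d - patch + 1L) s <- c(s, d - patch + 1L)
  s
}

pad_to <- function(arr, minsize, fill) {
  dims <- dim(arr)
  nd <- pmax(dims, minsize)
  if (all(nd == dims)) return(arr)
  out <- array(fill, nd)
  out[seq_len(dims[1]), seq_len(dims[2]), seq_len(dims[3])] <- arr
  out
}

# stack a list of samples into a channel-first batch tensor
stack_batch <- function(samples, nd) {
  xs <- lapply(samples, `[[`, "x")
  sp <- dim(as.array(xs[[1]]))
  if (is.null(sp)) sp <- length(xs[[1]])
  x <- array(unlist(xs), c(sp, length(xs)))
  y <- array(unlist(lapply(samples, `[[`, "y")), c(sp, length(xs)))
  dim(x) <- c(1L, sp, length(xs))  # one input channel
  list(x = x, y = y)
}

#' Train an encoder-decoder model on labeled samples
#'
#' Mini-batch SGD with momentum minimizing voxel-wise categorical
#' cross-entropy after the soft-max head. Samples are shuffled each epoch
#' (seeded). Training aborts with a diagnostic if the loss becomes
#' non-finite.
#'
#' @param model an `nn_model` from [build_segnet2d()] or [build_unet3d()].
#' @param data list of samples `list(x =, y =)` as produced by
#'   [slice_dataset()] or [patch_dataset()]; labels in `0..n_classes-1`.
#' @param config a [train_config()].
#' @param verbose print per-epoch mean loss.
#' @return list with `model` (trained) and `loss` (per-epoch mean loss).
#' @export
train_model <- function(model, data, config, verbose = FALSE) {
  stopifnot(inherits(model, "nn_model"), length(data) >= 1L)
  nd <- model$dim
  if (identical(config$class_weights, "inverse")) {
    freq <- tabulate(unlist(lapply(data, `[[`, "y")) + 1L,
                     nbins = model$n_classes)
    freq <- pmax(freq, 1L)
    config$class_weights <- sum(freq) / (model$n_classes * freq)
  }
  with_seed(config$seed, {
    loss_trace <- numeric(config$epochs)
    for (ep in seq_len(config$epochs)) {
      ord <- sample(length(data))
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      tot <- 0
      for (bi in batches) {
        bt <- stack_batch(data[bi], nd)
        fwd <- nn_forward(model, bt$x, train = TRUE)
        model <- fwd$model  # batch-norm running statistics
        sl <- softmax_ce(fwd$out, bt$y, config$class_weights)
        if (!is.finite(sl$loss))
          stop("train_model: non-finite loss at epoch ", ep,
               " (diverged; reduce the learning rate)")
        if (config$learning_rate > 0) {
          grads <- nn_backward(model, fwd, sl$grad)
          model <- sgd_update(model, grads, config$learning_rate,
                              config$momentum)
        }
        tot <- tot + sl$loss * length(bi)
      }
      loss_trace[ep] <- tot / length(data)
      if (verbose)
        message(sprintf("epoch %d/%d  loss %.5f", ep, config$epochs,
                        loss_trace[ep]))
    }
    list(model = model, loss = loss_trace)
  })
}

#' Predict class probabilities for a batch of samples
#'
#' Inference-mode forward pass (batch normalization uses running
#' statistics) followed by the soft-max head.
#'
#' @param model a trained `nn_model`.
#' @param x input batch: channel-first array `(1, spatial..., N)`, or a
#'   single 2D/3D sample which is promoted automatically.
#' @return probability array `(n_classes, spatial..., N)`; each site sums
#'   to 1.
#' @export
predict_probs <- function(model, x) {
  x <- as.array(x)
  want <- model$dim + 2L
  if (length(dim(x)) == model$dim) dim(x) <- c(1L, dim(x), 1L)
  if (length(dim(x)) != want) stop("predict_probs: bad input rank")
  fwd <- nn_forward(model, x, train = FALSE)
  nn_softmax(fwd$out)
}

#' Predict a volume with the three-axis SegNet ensemble
#'
#' Each axis model predicts every slice along its axis; the per-slice
#' class probabilities are resized back to the original slice geometry
#' (bilinear, then renormalized to the simplex), stacked into a per-class
#' probability volume, and the three volumes are averaged arithmetically.
#'
#' @param models named list with elements `axial`, `coronal`, `sagittal`,
#'   each a trained `nn_model` with matching `axis` attribute (as returned
#'   by the pipeline) or a plain `nn_model`.
#' @param volume an [intensity_volume()].
#' @param batch slices per forward pass.
#' @return a `prob_map`: 4D array (grid x classes) with unit site sums.
#' @export
predict_segnet_ensemble <- function(models, volume, batch = 16L) {
  if (!all(mip_axes %in% names(models)))
    stop("predict_segnet_ensemble: models must be named axial/coronal/sagittal")
  acc <- NULL
  for (a in mip_axes) {
    m <- models[[a]]
    tagged <- attr(m, "axis")
    if (!is.null(tagged) && !identical(tagged, a))
      stop("predict_segnet_ensemble: model tagged '", tagged,
           "' supplied for axis '", a, "'")
    pv <- predict_segnet_axis(m, volume, a, batch)
    acc <- if (is.null(acc)) pv else acc + pv
  }
  pm <- acc / 3
  class(pm) <- c("prob_map", class(pm))
  pm
}

predict_segnet_axis <- function(model, volume, axis, batch = 16L) {
  ax <- mip_axis(axis)
  vol <- normalize_volume(volume$data)
  dims <- dim(vol)
  L <- model$n_classes
  S <- model$in_size
  n <- dims[ax]
  sl_dim <- dim(slice_3d(vol, ax, 1L))
  out <- array(0, c(dims, L))
  for (b0 in seq(1L, n, by = batch)) {
    ii <- b0:min(b0 + batch - 1L, n)
    xb <- array(0, c(1L, S, S, length(ii)))
    for (j in seq_along(ii))
      xb[1L, , , j] <- resize2d(slice_3d(vol, ax, ii[j]), S)
    probs <- predict_probs(model, xb)  # (L, S, S, N)
    for (j in seq_along(ii)) {
      pl <- array(0, c(sl_dim, L))
      for (l in seq_len(L))
        pl[, , l] <- resize2d_to(probs[l, , , j], sl_dim)
      # bilinear resize distorts the simplex; renormalize per pixel
      sums <- apply(pl, c(1, 2), sum)
      pl <- pl / array(sums, dim(pl))
      for (l in seq_len(L)) {
        if (ax == 1L) out[ii[j], , , l] <- pl[, , l]
        else if (ax == 2L) out[, ii[j], , l] <- pl[, , l]
        else out[, , ii[j], l] <- pl[, , l]
      }
    }
  }
  out
}

resize2d_to <- function(m, size2) {
  if (all(dim(m) == size2)) return(m)
  EBImage::resize(m, w = size2[1], h = size2[2], filter = "bilinear")
}

#' Predict a volume with the patch-based 3D U-Net
#'
#' Sliding-window inference: cubic patches on a regular grid (edge-shifted
#' so every voxel is covered), probabilities averaged where patches
#' overlap. Averaging simplex-valued predictions preserves the simplex.
#'
#' @param model a trained `nn_model` (`unet3d`).
#' @param volume an [intensity_volume()].
#' @param stride patch grid stride (default half the patch side).
#' @return a `prob_map`: 4D array (grid x classes) with unit site sums.
#' @export
predict_unet3d <- function(model, volume, stride = model$in_size %/% 2L) {
  patch <- model$in_size
  vol <- normalize_volume(volume$data)
  dims0 <- dim(vol)
  pv <- pad_to(vol, patch, 0)
  dims <- dim(pv)
  L <- model$n_classes
  acc <- array(0, c(dims, L))
  cnt <- array(0, dims)
  starts <- lapply(dims, function(d) patch_starts(d, patch, stride))
  for (sx in starts[[1]]) for (sy in starts[[2]]) for (sz in starts[[3]]) {
    ix <- sx:(sx + patch - 1L); iy <- sy:(sy + patch - 1L)
    iz <- sz:(sz + patch - 1L)
    probs <- predict_probs(model, pv[ix, iy, iz])  # (L, p, p, p, 1)
    for (l in seq_len(L))
      acc[ix, iy, iz, l] <- acc[ix, iy, iz, l] + probs[l, , , , 1L]
    cnt[ix, iy, iz] <- cnt[ix, iy, iz] + 1
  }
  pm <- acc / array(cnt, dim(acc))
  pm <- pm[seq_len(dims0[1]), seq_len(dims0[2]), seq_len(dims0[3]), ,
           drop = FALSE]
  class(pm) <- c("prob_map", class(pm))
  pm
}

#' Hard labels from a probability map
#'
#' Per-site argmax over classes; ties break toward the lowest class index.
#'
#' @param probmap 4D array (grid x classes), e.g. from
#'   [predict_segnet_ensemble()] or [predict_unet3d()].
#' @return a [label_volume()].
#' @export
probs_to_labels <- function(probmap) {
  p <- unclass(probmap)
  dims <- dim(p)
  L <- dims[4]
  best <- array(0L, dims[1:3])
  best_v <- p[, , , 1L]
  for (l in seq_len(L)[-1]) {
    v <- p[, , , l]
    upd <- v > best_v
    best[upd] <- l - 1L
    best_v[upd] <- v[upd]
  }
  cn <- if (L == 3L) c("background", "tissue", "vessel")
        else paste0("class", 0:(L - 1L))
  label_volume(best, class_names = cn)
}

#' Save / load a model checkpoint
#'
#' Checkpoints carry a format version tag and the architecture metadata
#' needed to reject incompatible files.
#'
#' @param model an `nn_model`.
#' @param path checkpoint path (.rds).
#' @return `save_model` returns `path` invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  saveRDS(list(format = "vesselseg-nn-1", arch = model$arch,
               model = model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$format, "vesselseg-nn-1"))
    stop("load_model: not a vesselseg checkpoint: ", path)
  ck$model
}
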