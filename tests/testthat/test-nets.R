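make_tiny_cases <- function(n = 1, shape = c(32, 32, 32), seed = 71) {
  generate_dataset(phantom_spec(shape = shape, radius_root_vox = 1.5,
                                seed = 1), n, seed = seed)
}

test_that("slice_dataset extracts, resizes, and round-trips labels", {
  cs <- make_tiny_cases()
  dat <- slice_dataset(cs, "axial", out_size = 64)
  expect_length(dat, 32)
  expect_identical(dim(dat[[1]]$x), c(64L, 64L))
  expect_identical(dim(dat[[1]]$y), c(64L, 64L))
  expect_true(all(unlist(lapply(dat, function(s) s$y)) %in% 0:2))

  # constant-label slice stays constant under nearest-neighbor resize
  flat <- list(list(volume = intensity_volume(array(1, c(32, 32, 32)) +
                                                array(0.5, c(32, 32, 32))),
                    labels = label_volume(array(1L, c(32, 32, 32)))))
  dflat <- slice_dataset(flat, "coronal", out_size = 48)
  expect_true(all(dflat[[1]]$y == 1L))

  # nearest-neighbor up-then-down resize is the identity on labels
  lbl <- dat[[10]]$y  # a 64x64 label slice
  up <- vesselseg:::resize2d(lbl, 256L, label = TRUE)
  down <- vesselseg:::resize2d(up, 64L, label = TRUE)
  expect_identical(matrix(as.integer(down), 64, 64),
                   matrix(as.integer(lbl), 64, 64))

  expect_error(slice_dataset(cs, "diagonal"), "unknown axis")
})

test_that("patch_dataset tiles with full coverage", {
  cs <- make_tiny_cases()
  one <- patch_dataset(cs, patch = 32, stride = 32)
  expect_length(one, 1L)

  big <- list(list(volume = intensity_volume(array(runif(48^3, 1, 2),
                                                   c(48, 48, 48))),
                   labels = label_volume(array(0L, c(48, 48, 48)))))
  p16 <- patch_dataset(big, patch = 24, stride = 24)
  expect_length(p16, 8L)

  # uneven size: edge-shifted starts still cover every voxel
  odd <- list(list(volume = intensity_volume(array(runif(40 * 36 * 44, 1, 2),
                                                   c(40, 36, 44))),
                   labels = label_volume(array(0L, c(40, 36, 44)))))
  pods <- patch_dataset(odd, patch = 24, stride = 20)
  cover <- array(0L, c(40, 36, 44))
  for (s in pods) {
    o <- s$origin
    cover[o[1]:(o[1] + 23), o[2]:(o[2] + 23), o[3]:(o[3] + 23)] <- 1L
  }
  expect_true(all(cover == 1L))
})

test_that("probs_to_labels is an argmax with lowest-index tie-break", {
  p <- array(0, c(1, 1, 1, 3))
  p[1, 1, 1, ] <- c(0.1, 0.2, 0.7)
  expect_identical(probs_to_labels(p)$data[1, 1, 1], 2L)
  p[1, 1, 1, ] <- c(0.5, 0.5, 0.0)
  expect_identical(probs_to_labels(p)$data[1, 1, 1], 0L)

  with_seed(73, q <- array(runif(4 * 4 * 4 * 3), c(4, 4, 4, 3)))
  got <- probs_to_labels(q)$data
  oracle <- array(0L, c(4, 4, 4))
  for (i in 1:4) for (j in 1:4) for (k in 1:4)
    oracle[i, j, k] <- which.max(q[i, j, k, ]) - 1L
  expect_identical(got, oracle)
})

test_that("zero learning rate leaves weights untouched", {
  cs <- make_tiny_cases()
  dat <- slice_dataset(cs, "axial", out_size = 32)[1:6]
  m <- build_segnet2d(in_size = 32, n_classes = 3, filters = 4, seed = 5)
  tr <- train_model(m, dat, train_config(epochs = 1, learning_rate = 0,
                                         batch_size = 3, seed = 7))
  for (i in seq_along(m$layers)) {
    if (!is.null(m$layers[[i]]$W))
      expect_identical(tr$model$layers[[i]]$W, m$layers[[i]]$W)
    if (!is.null(m$layers[[i]]$gamma))
      expect_identical(tr$model$layers[[i]]$gamma, m$layers[[i]]$gamma)
  }
  expect_length(tr$loss, 1L)
})

test_that("a short training run reduces the loss on both architectures", {
  cs <- make_tiny_cases()
  pairs <- list(list(volume = cs[[1]]$intensity, labels = cs[[1]]$truth))
  dat <- slice_dataset(pairs, "axial", out_size = 32)
  m <- build_segnet2d(in_size = 32, n_classes = 3, filters = 4, seed = 5)
  tr <- train_model(m, dat, train_config(epochs = 3, learning_rate = 0.02,
                                         batch_size = 8, seed = 7,
                                         class_weights = "inverse"))
  expect_lt(tr$loss[3], tr$loss[1])

  pats <- patch_dataset(pairs, patch = 16, stride = 16)
  m3 <- build_unet3d(in_size = 16, n_classes = 3, filters = 4, seed = 5)
  tr3 <- train_model(m3, pats, train_config(epochs = 3,
                                            learning_rate = 0.02,
                                            batch_size = 4, seed = 7,
                                            class_weights = "inverse"))
  expect_lt(tr3$loss[3], tr3$loss[1])
})

test_that("probability conservation holds on every prediction path", {
  cs <- make_tiny_cases()[[1]]
  m2 <- build_segnet2d(in_size = 32, n_classes = 3, filters = 4, seed = 9)
  # single-axis path
  pv <- vesselseg:::predict_segnet_axis(m2, cs$intensity, "axial")
  sums <- apply(pv, 1:3, sum)
  expect_true(all(abs(sums - 1) < 1e-5))
  # three-axis ensemble path
  models <- list(axial = m2, coronal = m2, sagittal = m2)
  pe <- predict_segnet_ensemble(models, cs$intensity)
  sums_e <- apply(pe, 1:3, sum)
  expect_true(all(abs(sums_e - 1) < 1e-5))
  # patch-stitched U-Net path with overlapping windows
  m3 <- build_unet3d(in_size = 16, n_classes = 3, filters = 4, seed = 9)
  pu <- predict_unet3d(m3, cs$intensity, stride = 8)
  sums_u <- apply(pu, 1:3, sum)
  expect_true(all(abs(sums_u - 1) < 1e-5))
  expect_identical(dim(pu)[1:3], dim(cs$intensity$data))
})

test_that("ensemble prediction is a probability average with axis checks", {
  cs <- make_tiny_cases()[[1]]
  m <- build_segnet2d(in_size = 32, n_classes = 3, filters = 4, seed = 11)
  tagged <- m; attr(tagged, "axis") <- "axial"
  expect_error(predict_segnet_ensemble(list(axial = m, coronal = tagged,
                                            sagittal = m), cs$intensity),
               "tagged")

  # 2/3 majority: average of per-axis maps equals the mean of components
  pa <- vesselseg:::predict_segnet_axis(m, cs$intensity, "axial")
  pc <- vesselseg:::predict_segnet_axis(m, cs$intensity, "coronal")
  ps <- vesselseg:::predict_segnet_axis(m, cs$intensity, "sagittal")
  pe <- predict_segnet_ensemble(list(axial = m, coronal = m, sagittal = m),
                                cs$intensity)
  expect_equal(unclass(pe), (pa + pc + ps) / 3, tolerance = 1e-12)
})

test_that("overlapping U-Net windows average their probabilities", {
  # two overlapping patches on an elongated volume: the overlap must be
  # the hand-computed mean of the two contributing patch predictions
  vol <- intensity_volume(array(runif(16 * 16 * 24, 0.5, 1), c(16, 16, 24)))
  m3 <- build_unet3d(in_size = 16, n_classes = 3, filters = 2, seed = 13)
  pm <- predict_unet3d(m3, vol, stride = 8)
  p1 <- predict_probs(m3, vol$data[, , 1:16] / max(vol$data))
  p2 <- predict_probs(m3, vol$data[, , 9:24] / max(vol$data))
  # voxel (8, 8, 12) lies in both windows
  want <- (p1[, 8, 8, 12, 1] + p2[, 8, 8, 4, 1]) / 2
  expect_equal(as.numeric(pm[8, 8, 12, ]), as.numeric(want),
               tolerance = 1e-10)
})

test_that("model checkpoints round-trip through save/load", {
  m <- build_segnet2d(in_size = 32, n_classes = 3, filters = 4, seed = 15)
  path <- tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  expect_identical(m2$layers, m$layers)
  bad <- tempfile(fileext = ".rds")
  saveRDS(list(format = "other"), bad)
  expect_error(load_model(bad), "checkpoint")
})
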