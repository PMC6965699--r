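test_that("mip equals a brute-force per-pixel maximum", {
  cst <- array(3.5, c(4, 5, 6))
  expect_true(all(mip(cst, "axial") == 3.5))
  expect_identical(dim(mip(cst, "axial")), c(4L, 5L))
  expect_identical(dim(mip(cst, "coronal")), c(4L, 6L))
  expect_identical(dim(mip(cst, "sagittal")), c(5L, 6L))

  one <- array(0, c(5, 5, 5)); one[2, 3, 4] <- 9
  for (a in c("axial", "coronal", "sagittal"))
    expect_identical(sum(mip(one, a) == 9), 1L)

  with_seed(41, v <- array(runif(512), c(8, 8, 8)))
  for (ax in 1:3) {
    got <- mip(v, ax)
    keep <- setdiff(1:3, ax)
    oracle <- array(0, dim(v)[keep])
    for (i in 1:8) for (j in 1:8) for (k in 1:8) {
      p <- c(i, j, k)
      oracle[p[keep[1]], p[keep[2]]] <-
        max(oracle[p[keep[1]], p[keep[2]]], v[i, j, k])
    }
    expect_equal(got, oracle)
  }
  expect_error(mip(v, "oblique"), "unknown axis")
})

test_that("binary-mask MIP commutes with logical OR projection", {
  with_seed(43, m <- array(runif(8^3) < 0.1, c(8, 8, 8)))
  got <- mip(m + 0, "axial")
  or_proj <- apply(m, c(1, 2), any) + 0
  expect_equal(got, or_proj)
})

test_that("vessel_mask extracts class 2 and is idempotent", {
  lab <- label_volume(array(c(0L, 1L, 2L, 1L), c(2, 2, 1)))
  vm <- vessel_mask(lab)
  expect_identical(sum(vm), 1L)
  all_tissue <- label_volume(array(1L, c(3, 3, 3)))
  expect_true(all(vessel_mask(all_tissue) == 0L))
  again <- vessel_mask(array(vm * 2L, dim(vm)))
  expect_identical(again, vm)
})

test_that("confusion counts match an independent per-pixel tally", {
  ref <- matrix(0L, 10, 10); ref[1:5, 1:6] <- 1L
  expect_identical(unclass(confusion(ref, ref))[c("tp", "tn", "fp", "fn")],
                   list(tp = 30L, tn = 70L, fp = 0L, fn = 0L))
  inv <- 1L - ref
  cc <- confusion(inv, ref)
  expect_identical(cc$tp, 0L); expect_identical(cc$tn, 0L)

  with_seed(47, {
    for (rep in 1:5) {
      p <- matrix(runif(72) < 0.4, 8, 9)
      r <- matrix(runif(72) < 0.3, 8, 9)
      cc <- confusion(p + 0, r + 0)
      tally <- c(tp = 0, fp = 0, tn = 0, fn = 0)
      for (i in seq_along(p)) {
        if (p[i] && r[i]) tally["tp"] <- tally["tp"] + 1
        else if (p[i]) tally["fp"] <- tally["fp"] + 1
        else if (r[i]) tally["fn"] <- tally["fn"] + 1
        else tally["tn"] <- tally["tn"] + 1
      }
      expect_equal(c(tp = cc$tp, fp = cc$fp, tn = cc$tn, fn = cc$fn), tally)
    }
  })
  expect_error(confusion(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
})

test_that("metrics implement the textbook definitions", {
  # |A| = 4, |B| = 6, |A n B| = 3 -> DSC = 0.6
  cc <- structure(list(tp = 3L, fp = 1L, tn = 0L, fn = 3L),
                  class = "confusion_counts")
  expect_equal(suppressWarnings(metrics(cc))$dsc, 0.6)

  cc2 <- structure(list(tp = 30L, fp = 10L, tn = 950L, fn = 10L),
                   class = "confusion_counts")
  m2 <- metrics(cc2)
  expect_equal(m2$sensitivity, 0.75)
  expect_equal(m2$precision, 0.75)
  expect_equal(m2$dsc, 0.75)
  expect_equal(m2$accuracy, 0.98)

  full <- confusion(matrix(c(1, 1, 0, 0), 2), matrix(c(1, 1, 0, 0), 2))
  mf <- metrics(full)
  expect_true(all(unlist(mf) == 1))

  # zero denominators surface as NaN with a warning, never silently 0
  none <- structure(list(tp = 0L, fp = 0L, tn = 5L, fn = 0L),
                    class = "confusion_counts")
  expect_warning(expect_warning(expect_warning(
    mn <- metrics(none), "sensitivity"), "precision"), "DSC")
  expect_true(is.nan(mn$sensitivity))
  empty <- structure(list(tp = 0L, fp = 0L, tn = 0L, fn = 0L),
                     class = "confusion_counts")
  expect_error(metrics(empty), "empty")
})

test_that("DSC is symmetric and bounded on random mask pairs", {
  with_seed(53, {
    for (rep in 1:20) {
      a <- matrix(runif(64) < 0.5, 8, 8) + 0
      b <- matrix(runif(64) < 0.5, 8, 8) + 0
      d_ab <- suppressWarnings(metrics(confusion(a, b))$dsc)
      d_ba <- suppressWarnings(metrics(confusion(b, a))$dsc)
      expect_equal(d_ab, d_ba)
      if (!is.nan(d_ab)) expect_true(d_ab >= 0 && d_ab <= 1)
    }
  })
  a <- matrix(c(1, 1, 0, 0), 2)
  expect_equal(metrics(confusion(a, a))$dsc, 1)
  disj <- matrix(c(0, 0, 1, 1), 2)
  expect_equal(metrics(confusion(a, disj))$dsc, 0)
})

test_that("evaluate_case chains mask, MIP and metrics", {
  cs <- rasterize_phantom(small_phantom_spec(seed = 61))
  perfect <- evaluate_case(cs$truth, cs$truth)
  expect_true(all(abs(as.matrix(perfect[, -1]) - 1) < 1e-12))

  none <- label_volume(array(1L, dim(cs$truth$data)))
  rep0 <- suppressWarnings(evaluate_case(none, cs$truth))
  expect_equal(rep0$sensitivity[rep0$axis == "mean"], 0)
  expect_equal(rep0$dsc[rep0$axis == "mean"], 0)

  # independent recomputation through the component oracles
  pl <- make_pseudo_labels(cs$intensity, hmrf_config(seed = 3))
  rep1 <- evaluate_case(pl, cs$truth)
  pm <- vessel_mask(pl); tm <- vessel_mask(cs$truth)
  for (a in c("axial", "coronal", "sagittal")) {
    cc <- confusion(mip(pm, a), mip(tm, a))
    want <- metrics(cc)
    row <- rep1[rep1$axis == a, ]
    expect_equal(row$dsc, want$dsc)
    expect_equal(row$accuracy, want$accuracy)
  }
})

test_that("largest_components filters small islands", {
  m <- array(0L, c(8, 8, 8))
  m[1:3, 1:3, 1:3] <- 1L   # 27 voxels
  m[7, 7, 7] <- 1L         # singleton
  keep <- largest_components(m, min_size = 5L)
  expect_identical(sum(keep), 27L)
  expect_identical(keep[7, 7, 7], 0L)
  expect_true(all(largest_components(array(0L, c(4, 4, 4))) == 0L))
})

test_that("dataset aggregation reports both averaging orders", {
  cs <- rasterize_phantom(small_phantom_spec(seed = 67))
  r <- evaluate_case(cs$truth, cs$truth)
  agg <- evaluate_dataset(list(r, r))
  expect_equal(unname(agg$per_case["dsc"]), 1)
  expect_equal(agg$pooled$dsc, 1)
  expect_identical(nrow(agg$cases), 2L)
})
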