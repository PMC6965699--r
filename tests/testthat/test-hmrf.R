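test_that("gaussian_pdf matches the closed form", {
  expect_equal(gaussian_pdf(0, class_params(0, 1)), 1 / sqrt(2 * pi))
  expect_equal(gaussian_pdf(5, class_params(5, 2)), 1 / (2 * sqrt(2 * pi)))
  expect_equal(gaussian_pdf(1, class_params(0, 1)),
               exp(-0.5) / sqrt(2 * pi), tolerance = 1e-12)
  expect_error(gaussian_pdf(NaN, class_params(0, 1)), "non-finite")
  expect_true(gaussian_pdf(1e3, class_params(0, 1)) >= 0)
})

test_that("likelihood_energy sums per-voxel terms", {
  v1 <- intensity_volume(array(80, c(1, 1, 1)))
  lab1 <- label_volume(array(0L, c(1, 1, 1)), class_names = "c0")
  p <- params2(80, 200, 1, 1)
  expect_equal(likelihood_energy(v1, lab1, p), 0)
  v2 <- intensity_volume(array(81, c(1, 1, 1)))
  expect_equal(likelihood_energy(v2, lab1, p), 0.5)

  mix <- mixture_volume(c(5, 2, 1), c(80, 200), c(10, 10), seed = 3)
  got <- likelihood_energy(mix$volume, mix$labels, params2())
  oracle <- brute_posterior_energy(mix$volume$data, mix$labels$data,
                                   params2(), beta = 0)$likelihood
  expect_equal(got, oracle, tolerance = 1e-10)

  badlab <- label_volume(array(2L, c(5, 2, 1)), class_names = paste0("c", 0:2))
  expect_error(likelihood_energy(mix$volume, badlab, params2()),
               "class parameters")
})

test_that("prior_energy counts disagreeing pairs once", {
  same <- label_volume(array(1L, c(3, 3, 3)), class_names = c("a", "b"))
  expect_equal(prior_energy(same, hmrf_config(beta = 2.7)), 0)

  two <- label_volume(array(c(0L, 1L), c(2, 1, 1)), class_names = c("a", "b"))
  expect_equal(prior_energy(two, hmrf_config(beta = 1)), 1)

  with_seed(9, lab <- array(sample(0:2, 64, TRUE), c(4, 4, 4)))
  lv <- label_volume(lab, class_names = paste0("c", 0:2))
  for (nb in c(6L, 26L)) {
    oracle <- brute_posterior_energy(array(1, c(4, 4, 4)), lab,
                                     list(class_params(1, 1),
                                          class_params(1, 1),
                                          class_params(1, 1)),
                                     beta = 0.7, order = nb)
    expect_equal(prior_energy(lv, hmrf_config(beta = 0.7, neighborhood = nb)),
                 0.7 * oracle$pairs)
  }
  expect_error(hmrf_config(neighborhood = 18), "6 or 26")
})

test_that("energy breakdown is exactly additive", {
  mix <- mixture_volume(c(4, 4, 4), c(80, 200), c(10, 10), seed = 5)
  eb <- energy_breakdown(mix$volume, mix$labels, params2(),
                         hmrf_config(beta = 1.3))
  expect_identical(eb$posterior, eb$likelihood + eb$prior)
})

test_that("ICM with beta = 0 reduces to per-voxel ML classification", {
  mix <- mixture_volume(c(6, 5, 4), c(80, 200), c(15, 15), seed = 7)
  cfg <- hmrf_config(beta = 0)
  start <- label_volume(array(0L, c(6, 5, 4)), class_names = c("a", "b"))
  out <- icm_map_labels(mix$volume, start, params2(), cfg)
  expect_identical(out$data, brute_ml_classify(mix$volume$data, params2()))
})

test_that("ICM keeps an exact two-blob volume at ground truth", {
  dims <- c(6, 6, 6)
  y <- array(50, dims); y[4:6, , ] <- 150
  truth <- array(0L, dims); truth[4:6, , ] <- 1L
  p <- params2(50, 150, 5, 5)
  for (beta in c(0.3, 1)) {
    out <- icm_map_labels(intensity_volume(y),
                          label_volume(truth, class_names = c("a", "b")),
                          p, hmrf_config(beta = beta))
    expect_identical(out$data, truth)
  }
})

test_that("ICM flips an isolated voxel inside a homogeneous region", {
  dims <- c(3, 3, 3)
  mu <- c(100, 103)
  y <- array(mu[2], dims)
  y[2, 2, 2] <- mu[1]  # ML label of the center is class 0
  lab <- array(1L, dims); lab[2, 2, 2] <- 0L
  p <- params2(mu[1], mu[2], 1, 1)
  # hand-computed local conditional energies at the center:
  #   keep class 0: 0 + beta * 6;  flip to 1: (3)^2/2 = 4.5
  out <- icm_map_labels(intensity_volume(y),
                        label_volume(lab, class_names = c("a", "b")),
                        p, hmrf_config(beta = 10))
  expect_identical(out$data[2, 2, 2], 1L)
  en <- attr(out, "sweep_energy")
  expect_true(all(diff(en) <= 1e-9))
})

test_that("ICM ties break toward the lowest class index", {
  y <- array(100, c(1, 1, 1))
  p <- params2(90, 110, 5, 5)  # exactly equidistant, equal sigma
  out <- icm_map_labels(intensity_volume(y),
                        label_volume(array(1L, c(1, 1, 1)),
                                     class_names = c("a", "b")),
                        p, hmrf_config(beta = 0))
  expect_identical(out$data[1, 1, 1], 0L)
})

test_that("e_step responsibilities are normalized mixture posteriors", {
  mix <- mixture_volume(c(4, 4, 3), c(80, 200), c(30, 30), seed = 11)
  cfg0 <- hmrf_config(beta = 0)

  # identical params, beta = 0 -> (0.5, 0.5) everywhere by symmetry
  peq <- params2(100, 100, 10, 10)
  r <- e_step(mix$volume, mix$labels, peq, cfg0)
  expect_true(all(abs(r$probs - 0.5) < 1e-12))

  # beta = 0 -> plain Gaussian-mixture posterior with equal priors
  r2 <- e_step(mix$volume, mix$labels, params2(), cfg0)
  y <- as.vector(mix$volume$data)
  d1 <- dnorm(y, 80, 10); d2 <- dnorm(y, 200, 10)
  expect_equal(as.vector(r2$probs[, , , 1]), d1 / (d1 + d2),
               tolerance = 1e-9)
  sums <- apply(r2$probs, 1:3, sum)
  expect_true(all(abs(sums - 1) < 1e-6))

  # strong prior: center voxel surrounded by class 1 neighbors
  dims <- c(3, 3, 3)
  y3 <- array(100, dims)
  lab3 <- array(1L, dims)
  r3 <- e_step(intensity_volume(y3),
               label_volume(lab3, class_names = c("a", "b")),
               params2(90, 110, 10, 10), hmrf_config(beta = 50))
  expect_gt(r3$probs[2, 2, 2, 2], 1 - 1e-9)
})

test_that("m_step recovers weighted means and fallback behavior", {
  mix <- mixture_volume(c(10, 10, 5), c(50, 150), c(5, 8), seed = 13)
  dims <- dim(mix$volume$data)
  lab <- mix$labels$data
  onehot <- array(0, c(dims, 2))
  onehot[, , , 1][lab == 0L] <- 1
  onehot[, , , 2][lab == 1L] <- 1
  resp <- structure(list(probs = onehot, mask = array(TRUE, dims)),
                    class = "responsibilities")
  est <- m_step(mix$volume, resp)
  for (l in 1:2) {
    vals <- mix$volume$data[lab == l - 1L]
    expect_equal(est[[l]]$mu, mean(vals), tolerance = 1e-10)
    expect_equal(est[[l]]$sigma, sqrt(mean((vals - mean(vals))^2)),
                 tolerance = 1e-10)
  }

  unif <- structure(list(probs = array(0.5, c(dims, 2)),
                         mask = array(TRUE, dims)),
                    class = "responsibilities")
  est2 <- m_step(mix$volume, unif)
  g <- as.vector(mix$volume$data)
  expect_equal(est2[[1]]$mu, est2[[2]]$mu)
  expect_equal(est2[[1]]$mu, mean(g))
  expect_equal(est2[[1]]$sigma, sqrt(mean((g - mean(g))^2)),
               tolerance = 1e-10)

  empty <- onehot; empty[, , , 2] <- 0
  resp3 <- structure(list(probs = empty, mask = array(TRUE, dims)),
                     class = "responsibilities")
  expect_warning(est3 <- m_step(mix$volume, resp3, prev_params = params2()),
                 "negligible responsibility")
  expect_equal(est3[[2]]$mu, 200)
})

test_that("initialize_params finds bimodal modes and is deterministic", {
  v <- mixture_volume(c(40, 25, 20), c(100, 200), c(10, 10), seed = 17)$volume
  p1 <- initialize_params(v, 2, seed = 4)
  p2 <- initialize_params(v, 2, seed = 4)
  expect_identical(p1, p2)
  expect_lt(abs(p1[[1]]$mu - 100), 10)
  expect_lt(abs(p1[[2]]$mu - 200), 10)
  expect_lt(p1[[1]]$mu, p1[[2]]$mu)

  cst <- intensity_volume(array(7, c(4, 4, 2)) + array(0, c(4, 4, 2)))
  pf <- initialize_params(cst, 2, seed = 1)
  expect_equal(pf[[1]]$sigma, pf[[2]]$sigma)
  expect_true(pf[[1]]$sigma > 0)
})

test_that("segment_hmrf honors tol = Inf and sorts classes by mean", {
  mix <- mixture_volume(c(8, 8, 8), c(80, 200), c(10, 10), seed = 19)
  fit <- segment_hmrf(mix$volume, hmrf_config(tol = Inf, seed = 2))
  expect_identical(nrow(fit$energy), 1L)
  fitc <- segment_hmrf(mix$volume, hmrf_config(seed = 2))
  mus <- vapply(fitc$params, function(p) p$mu, 0)
  expect_true(all(diff(mus) > 0))
  expect_equal(fitc$energy$posterior,
               fitc$energy$likelihood + fitc$energy$prior)
  expect_error(segment_hmrf(mix$volume, hmrf_config(),
                            mask = array(FALSE, c(8, 8, 8))), "empty mask")
})

test_that("relabeling the initial classes leaves the segmentation invariant", {
  mix <- mixture_volume(c(10, 10, 10), c(80, 200), c(10, 10), seed = 23)
  cfg <- hmrf_config(beta = 0.5, seed = 2)
  f1 <- segment_hmrf(mix$volume, cfg, init_params = params2(80, 200))
  f2 <- segment_hmrf(mix$volume, cfg, init_params = rev(params2(80, 200)))
  expect_identical(f1$labels$data, f2$labels$data)
  expect_equal(vapply(f1$params, `[[`, 0, "mu"),
               vapply(f2$params, `[[`, 0, "mu"), tolerance = 1e-10)
})

test_that("make_pseudo_labels fixes background and orders classes", {
  cs <- rasterize_phantom(small_phantom_spec(seed = 31))
  pl <- make_pseudo_labels(cs$intensity, hmrf_config(seed = 3))
  expect_setequal(unique(as.vector(pl$data)), 0:2)
  expect_identical(which(pl$data == 0L), which(cs$intensity$data == 0))
  fit <- attr(pl, "fit")
  expect_gt(fit$params[[2]]$mu, fit$params[[1]]$mu)
  expect_gt(fit$params[[2]]$mu, 150)  # vessel class tracks the bright mode
  expect_lt(fit$params[[1]]$mu, 150)

  nozero <- intensity_volume(array(runif(4^3, 1, 2), c(4, 4, 4)))
  expect_warning(make_pseudo_labels(nozero, hmrf_config(max_em_iters = 2)),
                 "background")
  expect_error(intensity_volume(array(0, c(4, 4, 4))), "identically zero")
})
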