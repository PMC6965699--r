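# Small fixtures shared across test files; everything is generated in code.

# tiny deterministic volume from a Gaussian mixture with known labels
mixture_volume <- function(dims, mus, sigmas, seed = 1) {
  vesselseg::with_seed(seed, {
    lab <- array(sample(seq_along(mus) - 1L, prod(dims), replace = TRUE),
                 dims)
    y <- array(rnorm(prod(dims), mus[lab + 1L], sigmas[lab + 1L]), dims)
    y <- pmax(y, 1e-3)
    list(volume = intensity_volume(array(y, dims)),
         labels = label_volume(lab, class_names = paste0("c", seq_along(mus))))
  })
}

# two-class parameter list
params2 <- function(mu1 = 80, mu2 = 200, s1 = 10, s2 = 10) {
  list(class_params(mu1, s1), class_params(mu2, s2))
}

small_phantom_spec <- function(shape = c(48, 48, 48), seed = 1, ...) {
  phantom_spec(shape = shape, seed = seed, ...)
}

# brute-force posterior energy: per-voxel likelihood loop + pairwise
# neighbor enumeration (the independent oracle for the energy functions)
brute_posterior_energy <- function(y, lab, params, beta, order = 6L) {
  dims <- dim(y)
  lik <- 0
  for (i in seq_along(y)) {
    p <- params[[lab[i] + 1L]]
    lik <- lik + (y[i] - p$mu)^2 / (2 * p$sigma^2) + log(p$sigma)
  }
  offs <- if (order == 6L) {
    rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  } else {
    o <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    o <- o[rowSums(abs(o)) > 0, ]
    o[o[, 3] > 0 | (o[, 3] == 0 & (o[, 2] > 0 | (o[, 2] == 0 & o[, 1] > 0))), ,
      drop = FALSE]
  }
  pairs <- 0
  for (x in seq_len(dims[1])) for (yy in seq_len(dims[2]))
    for (z in seq_len(dims[3])) for (k in seq_len(nrow(offs))) {
      q <- c(x, yy, z) + offs[k, ]
      if (all(q >= 1) && all(q <= dims)) {
        if (lab[x, yy, z] != lab[q[1], q[2], q[3]]) pairs <- pairs + 1
      }
    }
  list(likelihood = lik, prior = beta * pairs, pairs = pairs)
}

# independent per-voxel Gaussian maximum-likelihood classification
brute_ml_classify <- function(y, params) {
  dens <- sapply(params, function(p) dnorm(as.vector(y), p$mu, p$sigma))
  array(max.col(dens, ties.method = "first") - 1L, dim(y))
}

dice3d <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
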