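#' HMRF segmentation configuration
#'
#' Settings for the Gaussian hidden Markov random field segmenter. The label
#' field carries a Potts prior: neighboring voxels pay an energy `beta` when
#' their classes disagree. Labels are optimized by iterated conditional
#' modes (ICM) and the class Gaussians re-estimated by EM.
#'
#' @param num_classes number of Gaussian classes L (>= 2).
#' @param beta Potts coupling (>= 0); 0 removes all spatial smoothing.
#' @param neighborhood 3D neighborhood order, 6 (faces) or 26 (faces, edges,
#'   corners).
#' @param max_em_iters maximum EM outer iterations.
#' @param max_icm_iters maximum full ICM sweeps per EM iteration.
#' @param tol relative posterior-energy change below which EM stops.
#' @param sigma_floor lower bound for class standard deviations; `NULL`
#'   means `1e-3` times the intensity range of the (masked) volume.
#' @param seed integer seed for the k-means initialization.
#' @return an object of class `hmrf_config`.
#' @export
hmrf_config <- function(num_classes = 2L, beta = 1.0, neighborhood = 6L,
                        max_em_iters = 20L, max_icm_iters = 10L,
                        tol = 1e-4, sigma_floor = NULL, seed = 1L) {
  stopifnot(num_classes >= 2L, beta >= 0, tol > 0,
            max_em_iters >= 1L, max_icm_iters >= 1L)
  if (!neighborhood %in% c(6L, 26L))
    stop("hmrf_config: neighborhood must be 6 or 26")
  structure(list(num_classes = as.integer(num_classes), beta = beta,
                 neighborhood = as.integer(neighborhood),
                 max_em_iters = as.integer(max_em_iters),
                 max_icm_iters = as.integer(max_icm_iters),
                 tol = tol, sigma_floor = sigma_floor,
                 seed = as.integer(seed)),
            class = "hmrf_config")
}

param_mu <- function(params) vapply(params, function(p) p$mu, 0)
param_sigma <- function(params) vapply(params, function(p) p$sigma, 0)

# full-grid label array -> 0-based C++ encoding with -1 outside the mask
encode_labels <- function(labels, mask) {
  lab <- labels
  storage.mode(lab) <- "integer"
  lab[!mask] <- -1L
  lab
}

#' Gaussian class density
#'
#' Emission density of one class: the probability density of observing
#' intensity `y` under the class Gaussian `N(mu, sigma^2)`.
#'
#' @param y intensity value(s); must be finite.
#' @param params a [class_params()] object.
#' @return density values (per intensity unit), strictly positive.
#' @export
gaussian_pdf <- function(y, params) {
  if (!all(is.finite(y))) stop("gaussian_pdf: non-finite intensity")
  dnorm(y, mean = params$mu, sd = params$sigma)
}

#' Likelihood energy of a labeling
#'
#' The negative log-likelihood of the intensities given the labels, up to
#' the constant `log(2*pi)/2` per voxel:
#' `sum_i [ (y_i - mu_{x_i})^2 / (2 sigma_{x_i}^2) + log(sigma_{x_i}) ]`.
#'
#' @param volume an [intensity_volume()].
#' @param labels a [label_volume()] on the same grid.
#' @param params list of [class_params()], one per class.
#' @param mask optional logical array restricting the voxel domain (voxels
#'   outside contribute nothing; background is fixed, not modeled).
#' @return scalar energy (dimensionless).
#' @export
likelihood_energy <- function(volume, labels, params, mask = NULL) {
  dims <- dim(volume$data)
  lab <- if (inherits(labels, "label_volume")) labels$data else labels
  if (!identical(dim(lab), dims))
    stop("likelihood_energy: labels and volume grids differ")
  if (max(lab) >= length(params))
    stop("likelihood_energy: label index without class parameters")
  keep <- if (is.null(mask)) rep(TRUE, length(lab)) else as_mask(mask, dims)
  y <- volume$data[keep]
  l <- lab[keep] + 1L
  mu <- param_mu(params)[l]
  sg <- param_sigma(params)[l]
  sum((y - mu)^2 / (2 * sg^2) + log(sg))
}

#' Prior (Potts) energy of a labeling
#'
#' `beta` times the number of unordered neighbor pairs with disagreeing
#' labels; each pair is counted once. Pairs with an endpoint outside the
#' mask are excluded.
#'
#' @inheritParams likelihood_energy
#' @param config an [hmrf_config()] supplying `beta` and the neighborhood.
#' @return scalar energy (dimensionless).
#' @export
prior_energy <- function(labels, config, mask = NULL) {
  lab <- if (inherits(labels, "label_volume")) labels$data else labels
  dims <- dim(lab)
  keep <- if (is.null(mask)) array(TRUE, dims) else as_mask(mask, dims)
  pairs <- count_disagree_pairs_cpp(encode_labels(lab, keep),
                                    as.integer(dims), config$neighborhood)
  config$beta * pairs
}

#' Posterior energy breakdown
#'
#' Likelihood energy, prior energy, and their sum (the posterior energy;
#' the additive constant is fixed at 0).
#'
#' @inheritParams likelihood_energy
#' @param config an [hmrf_config()].
#' @return list with `likelihood`, `prior`, `posterior`.
#' @export
energy_breakdown <- function(volume, labels, params, config, mask = NULL) {
  lik <- likelihood_energy(volume, labels, params, mask)
  pri <- prior_energy(labels, config, mask)
  list(likelihood = lik, prior = pri, posterior = lik + pri)
}

#' MAP labeling by iterated conditional modes
#'
#' Sequential raster-order sweeps: each voxel is reassigned to the class
#' minimizing its local conditional energy (Gaussian likelihood term plus
#' `beta` times the number of disagreeing in-mask neighbors). Each accepted
#' move lowers the total posterior energy, so the energy after each full
#' sweep is non-increasing. Sweeps stop when no voxel changes or
#' `max_icm_iters` is reached. Ties break toward the lowest class index.
#'
#' @inheritParams likelihood_energy
#' @param config an [hmrf_config()].
#' @return a [label_volume()]; voxels outside the mask are returned
#'   unchanged. Attribute `sweep_energy` holds the posterior energy before
#'   and after every sweep.
#' @export
icm_map_labels <- function(volume, labels, params, config, mask = NULL) {
  dims <- dim(volume$data)
  lab <- if (inherits(labels, "label_volume")) labels$data else labels
  keep <- if (is.null(mask)) array(TRUE, dims) else as_mask(mask, dims)
  res <- icm_sweeps_cpp(as.double(volume$data), encode_labels(lab, keep),
                        as.integer(dims), param_mu(params),
                        param_sigma(params), config$beta,
                        config$neighborhood, config$max_icm_iters)
  out <- array(res$labels, dims)
  out[!keep] <- lab[!keep]
  cn <- if (inherits(labels, "label_volume")) labels$class_names
        else paste0("class", seq_len(length(params)) - 1L)
  lv <- label_volume(out, class_names = cn)
  attr(lv, "sweep_energy") <- res$energy
  lv
}

#' E-step: per-voxel class responsibilities
#'
#' Posterior class probabilities combining the Gaussian emission density
#' with the local Potts prior given the current neighbor labels:
#' `P(l | y_i) propto g(y_i; theta_l) * exp(-beta * #\{j in N_i : x_j != l\})`,
#' normalized over classes at each voxel. Computed in log space; voxels
#' where every class underflows receive uniform responsibilities with a
#' warning.
#'
#' @inheritParams icm_map_labels
#' @return an object of class `responsibilities`: list with `probs` (4D
#'   array, grid x L; `NA` outside the mask) and `mask`.
#' @export
e_step <- function(volume, labels, params, config, mask = NULL) {
  dims <- dim(volume$data)
  lab <- if (inherits(labels, "label_volume")) labels$data else labels
  keep <- if (is.null(mask)) array(TRUE, dims) else as_mask(mask, dims)
  L <- length(params)
  enc <- encode_labels(lab, keep)
  # counts[i, l]: in-mask neighbors of voxel i currently labeled l
  counts <- neighbor_label_counts_cpp(enc, as.integer(dims), L,
                                      config$neighborhood)
  y <- as.double(volume$data)
  logw <- matrix(0, length(y), L)
  for (l in seq_len(L)) {
    logw[, l] <- dnorm(y, param_mu(params)[l], param_sigma(params)[l],
                       log = TRUE) + config$beta * counts[, l]
  }
  mx <- logw[, 1]
  for (l in seq_len(L)[-1]) mx <- pmax(mx, logw[, l])
  bad <- !is.finite(mx)
  if (any(bad & keep)) {
    warning("e_step: density underflow at ", sum(bad & keep),
            " voxel(s); assigning uniform responsibilities")
    logw[bad, ] <- 0
    mx[bad] <- 0
  }
  w <- exp(logw - mx)
  w <- w / rowSums(w)
  w[!keep, ] <- NA_real_
  probs <- array(w, c(dims, L))
  structure(list(probs = probs, mask = keep), class = "responsibilities")
}

#' M-step: re-estimate class Gaussians from responsibilities
#'
#' Responsibility-weighted mean and standard deviation per class:
#' `mu_l = sum_i P(l|y_i) y_i / sum_i P(l|y_i)`, and the variance update
#' uses the freshly updated mean. Standard deviations are clamped below by
#' `sigma_floor`. A class whose total responsibility falls below `eps`
#' keeps its previous parameters (with a warning).
#'
#' @param volume an [intensity_volume()].
#' @param resp a `responsibilities` object from [e_step()].
#' @param prev_params previous parameter list (fallback for empty classes).
#' @param sigma_floor lower bound for sigma; `NULL` means `1e-3` times the
#'   masked intensity range.
#' @param eps minimum total responsibility for a class to be re-estimated.
#' @return list of [class_params()].
#' @export
m_step <- function(volume, resp, prev_params = NULL, sigma_floor = NULL,
                   eps = 1e-8) {
  dims <- dim(volume$data)
  keep <- resp$mask
  y <- volume$data[keep]
  L <- dim(resp$probs)[4]
  w <- matrix(resp$probs, ncol = L)[keep, , drop = FALSE]
  if (is.null(sigma_floor)) sigma_floor <- 1e-3 * max(diff(range(y)), 1e-6)
  out <- vector("list", L)
  for (l in seq_len(L)) {
    tot <- sum(w[, l])
    if (tot < eps) {
      if (is.null(prev_params))
        stop("m_step: class ", l - 1L, " has no responsibility mass")
      warning("m_step: class ", l - 1L,
              " has negligible responsibility; keeping previous parameters")
      out[[l]] <- prev_params[[l]]
      next
    }
    mu <- sum(w[, l] * y) / tot
    sg <- sqrt(sum(w[, l] * (y - mu)^2) / tot)
    out[[l]] <- class_params(mu, max(sg, sigma_floor))
  }
  out
}

#' Initial class parameters
#'
#' Deterministic seeded k-means on the (masked) intensities; per-cluster
#' mean and standard deviation, floored and sorted by ascending mean. When
#' there are fewer distinct intensities than classes, a quantile split is
#' used instead. Large volumes are subsampled (seeded) before k-means.
#'
#' @param volume an [intensity_volume()].
#' @param num_classes number of classes L.
#' @param seed integer seed.
#' @param mask optional logical array.
#' @param sigma_floor see [m_step()].
#' @param max_sample intensity subsample size for k-means.
#' @return list of [class_params()], ascending in `mu`.
#' @export
initialize_params <- function(volume, num_classes, seed = 1L, mask = NULL,
                              sigma_floor = NULL, max_sample = 20000L) {
  dims <- dim(volume$data)
  keep <- if (is.null(mask)) array(TRUE, dims) else as_mask(mask, dims)
  y <- volume$data[keep]
  if (length(y) < num_classes)
    stop("initialize_params: fewer masked voxels than classes")
  if (is.null(sigma_floor)) sigma_floor <- 1e-3 * max(diff(range(y)), 1e-6)
  n_distinct <- length(unique(y))
  if (n_distinct < num_classes) {
    # degenerate input: quantile-based fallback
    qs <- quantile(y, probs = (2 * seq_len(num_classes) - 1) /
                     (2 * num_classes), names = FALSE)
    sg <- max(sd(y), sigma_floor)
    if (!is.finite(sg)) sg <- sigma_floor
    return(lapply(qs, class_params, sigma = sg))
  }
  with_seed(seed, {
    ys <- if (length(y) > max_sample) sample(y, max_sample) else y
    km <- suppressWarnings(
      kmeans(ys, centers = num_classes, nstart = 4L, iter.max = 50L))
    ord <- order(km$centers[, 1])
    params <- vector("list", num_classes)
    for (i in seq_along(ord)) {
      pts <- ys[km$cluster == ord[i]]
      sg <- if (length(pts) > 1) sd(pts) else sigma_floor
      params[[i]] <- class_params(mean(pts), max(sg, sigma_floor,
                                                 na.rm = TRUE))
    }
    params
  })
}

# per-voxel Gaussian maximum-likelihood classification (lowest index wins
# ties); used for the initial labeling and as the beta = 0 reference
ml_classify <- function(y, params) {
  L <- length(params)
  best <- rep(1L, length(y))
  best_d <- dnorm(y, params[[1]]$mu, params[[1]]$sigma, log = TRUE)
  for (l in seq_len(L)[-1]) {
    d <- dnorm(y, params[[l]]$mu, params[[l]]$sigma, log = TRUE)
    upd <- d > best_d
    best[upd] <- l
    best_d[upd] <- d[upd]
  }
  best - 1L
}

#' Segment a volume with the Gaussian HMRF-EM model
#'
#' Alternates the E-step (responsibilities), M-step (Gaussian parameter
#' re-estimation), and ICM MAP labeling until the relative change in
#' posterior energy falls below `tol` or `max_em_iters` is reached.
#' Parameters are initialized by seeded k-means (or `init_params`) and the
#' initial labeling is per-voxel maximum likelihood. Returned parameters
#' are sorted by ascending mean with labels remapped accordingly.
#'
#' @param volume an [intensity_volume()].
#' @param config an [hmrf_config()].
#' @param mask optional logical array (or [label_volume()] of 0/1);
#'   segmentation runs only inside it. Voxels outside are reported as class
#'   0 by convention and are excluded from every energy.
#' @param init_params optional list of [class_params()] overriding the
#'   k-means initialization.
#' @return an object of class `hmrf_fit`: list with `labels` (a
#'   [label_volume()]), `params` (ascending mean), `energy` (data.frame
#'   with columns iteration, likelihood, prior, posterior), `icm_energy`
#'   (per-EM-iteration vectors of per-sweep posterior energies), `mask`,
#'   `config`.
#' @export
segment_hmrf <- function(volume, config, mask = NULL, init_params = NULL) {
  dims <- dim(volume$data)
  keep <- if (is.null(mask)) array(TRUE, dims) else as_mask(mask, dims)
  if (!any(keep)) stop("segment_hmrf: empty mask")
  L <- config$num_classes
  y <- volume$data
  sigma_floor <- config$sigma_floor
  if (is.null(sigma_floor))
    sigma_floor <- 1e-3 * max(diff(range(y[keep])), 1e-6)

  params <- if (is.null(init_params)) {
    initialize_params(volume, L, seed = config$seed, mask = keep,
                      sigma_floor = sigma_floor)
  } else {
    if (length(init_params) != L)
      stop("segment_hmrf: init_params length must equal num_classes")
    init_params
  }

  lab <- array(0L, dims)
  lab[keep] <- ml_classify(y[keep], params)

  trace <- data.frame(iteration = integer(), likelihood = double(),
                      prior = double(), posterior = double())
  icm_energy <- list()
  post_prev <- NA_real_
  for (t in seq_len(config$max_em_iters)) {
    resp <- e_step(volume, lab, params, config, mask = keep)
    params <- m_step(volume, resp, prev_params = params,
                     sigma_floor = sigma_floor)
    icm_out <- icm_map_labels(volume, lab, params, config, mask = keep)
    lab <- icm_out$data
    icm_energy[[t]] <- attr(icm_out, "sweep_energy")
    eb <- energy_breakdown(volume, lab, params, config, mask = keep)
    trace <- rbind(trace, data.frame(iteration = t,
                                     likelihood = eb$likelihood,
                                     prior = eb$prior,
                                     posterior = eb$posterior))
    if (is.infinite(config$tol)) break
    if (t > 1) {
      rel <- abs(eb$posterior - post_prev) / max(abs(post_prev), 1e-12)
      if (rel < config$tol) break
    }
    post_prev <- eb$posterior
  }

  # canonical class order: ascending mean
  ord <- order(param_mu(params))
  if (!identical(ord, seq_len(L))) {
    remap <- integer(L)
    remap[ord] <- seq_len(L) - 1L
    lab[keep] <- remap[lab[keep] + 1L]
    params <- params[ord]
  }
  labels <- label_volume(lab, class_names = paste0("class", 0:(L - 1)),
                         spacing = volume$spacing, affine = volume$affine)
  structure(list(labels = labels, params = params, energy = trace,
                 icm_energy = icm_energy, mask = keep, config = config),
            class = "hmrf_fit")
}

#' @export
print.hmrf_fit <- function(x, ...) {
  cat(sprintf("hmrf_fit: %d classes, %d EM iterations, final posterior %.6g\n",
              length(x$params), nrow(x$energy),
              x$energy$posterior[nrow(x$energy)]))
  for (i in seq_along(x$params))
    cat(sprintf("  class %d: mu = %.4g, sigma = %.4g\n", i - 1L,
                x$params[[i]]$mu, x$params[[i]]$sigma))
  invisible(x)
}

#' Three-class pseudo-labels for network training
#'
#' Voxels with intensity exactly zero are fixed as background (class 0;
#' preprocessed TOF-MRA volumes have zero background by contract). A
#' two-class Gaussian HMRF (tissue, vessel) is fitted inside the nonzero
#' mask; the lower-mean class becomes brain tissue (class 1) and the
#' higher-mean class vessel (class 2).
#'
#' @param volume an [intensity_volume()] with zero background.
#' @param config an [hmrf_config()]; `num_classes` is forced to 2.
#' @return a three-class [label_volume()]; attribute `fit` holds the
#'   underlying [segment_hmrf()] result.
#' @export
make_pseudo_labels <- function(volume, config = hmrf_config()) {
  mask <- volume$data > 0
  if (all(mask))
    warning("make_pseudo_labels: volume has no zero-intensity background")
  config$num_classes <- 2L
  fit <- segment_hmrf(volume, config, mask = mask)
  out <- array(0L, dim(volume$data))
  out[mask] <- fit$labels$data[mask] + 1L
  lv <- label_volume(out, spacing = volume$spacing, affine = volume$affine)
  attr(lv, "fit") <- fit
  lv
}

#' Write an EM energy trace to CSV
#'
#' @param fit an `hmrf_fit`.
#' @param path output CSV path (columns iteration, likelihood, prior,
#'   posterior).
#' @export
write_energy_trace <- function(fit, path) {
  write.csv(fit$energy, path, row.names = FALSE)
  invisible(path)
}

#' Write class parameters as YAML
#'
#' @param params list of [class_params()].
#' @param path output YAML path.
#' @export
write_params_yaml <- function(params, path) {
  yaml::write_yaml(lapply(params, function(p) list(mu = p$mu,
                                                   sigma = p$sigma)), path)
  invisible(path)
}
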