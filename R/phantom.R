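#' Synthetic TOF-MRA phantom specification
#'
#' Parameters of the synthetic angiography phantom: a brain-shaped
#' ellipsoid of Gaussian-distributed tissue intensity containing randomly
#' grown binary-branching vessel trees of Gaussian-distributed brighter
#' intensity (emulating bright-blood TOF contrast), over an exactly-zero
#' background (emulating skull-stripped, bias-corrected input). Optional
#' smooth multiplicative bias and additive noise degrade the ideal
#' per-class Gaussian intensity model.
#'
#' @param shape grid dimensions (each >= 32).
#' @param n_trees number of vessel trees.
#' @param branch_depth binary branching depth (0 = unbranched).
#' @param radius_root_vox root vessel radius in voxels (>= 0.5).
#' @param radius_decay child/parent radius ratio in (0, 1].
#' @param tissue_mu,tissue_sigma tissue intensity mean / sd.
#' @param vessel_mu,vessel_sigma vessel intensity mean / sd; `vessel_mu`
#'   must exceed `tissue_mu`.
#' @param noise_sigma additive Gaussian noise sd (0 disables).
#' @param bias_amplitude multiplicative low-order polynomial bias strength
#'   in `[0, 1)` (0 disables).
#' @param brain_radius_frac ellipsoid semi-axis as a fraction of each grid
#'   dimension.
#' @param seed integer seed.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64L, 64L, 64L), n_trees = 3L,
                         branch_depth = 3L, radius_root_vox = 1.8,
                         radius_decay = 0.75, tissue_mu = 90,
                         tissue_sigma = 10, vessel_mu = 220,
                         vessel_sigma = 10, noise_sigma = 0,
                         bias_amplitude = 0, brain_radius_frac = 0.42,
                         seed = 1L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 32L), n_trees >= 1L,
            branch_depth >= 0L, radius_root_vox >= 0.5,
            radius_decay > 0, radius_decay <= 1,
            vessel_mu > tissue_mu, tissue_sigma > 0, vessel_sigma > 0,
            noise_sigma >= 0, bias_amplitude >= 0, bias_amplitude < 1,
            brain_radius_frac > 0, brain_radius_frac <= 0.5)
  structure(list(shape = shape, n_trees = as.integer(n_trees),
                 branch_depth = as.integer(branch_depth),
                 radius_root_vox = radius_root_vox,
                 radius_decay = radius_decay, tissue_mu = tissue_mu,
                 tissue_sigma = tissue_sigma, vessel_mu = vessel_mu,
                 vessel_sigma = vessel_sigma, noise_sigma = noise_sigma,
                 bias_amplitude = bias_amplitude,
                 brain_radius_frac = brain_radius_frac,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# squared normalized ellipsoid coordinate; <= 1 is inside the brain
ellipsoid_r2 <- function(p, center, semi) {
  sum(((p - center) / semi)^2)
}

# grow one segment by a smoothly perturbed random walk, steered back
# inward when it approaches the ellipsoid surface
walk_segment <- function(p, d, n_steps, center, semi, kappa = 0.25) {
  pts <- matrix(0, n_steps + 1L, 3L)
  pts[1L, ] <- p
  for (s in seq_len(n_steps)) {
    d <- d + kappa * rnorm(3)
    d <- d / sqrt(sum(d^2))
    cand <- p + d
    if (ellipsoid_r2(cand, center, semi) > 0.92) {
      inward <- (center - p)
      inward <- inward / sqrt(sum(inward^2))
      d <- 0.4 * d + 0.6 * inward
      d <- d / sqrt(sum(d^2))
      cand <- p + d
    }
    p <- cand
    pts[s + 1L, ] <- p
  }
  list(points = pts, dir = d)
}

#' Grow random binary-branching vessel trees
#'
#' Each tree enters at a random point near the brain-ellipsoid surface and
#' random-walks inward; at the end of each segment it splits into two
#' children with radius scaled by `radius_decay`, down to `branch_depth`
#' levels. All centerline points stay inside the brain ellipsoid.
#'
#' @param spec a [phantom_spec()]. The spec's `seed` drives the geometry;
#'   identical specs give identical trees.
#' @return list of segments, each a list with `points` (n x 3 matrix of
#'   voxel coordinates), `radius` (scalar, voxels), `depth`, `tree`, and
#'   `id`/`parent` indices.
#' @export
grow_vessel_tree <- function(spec) {
  shape <- spec$shape
  center <- (shape + 1) / 2
  semi <- spec$brain_radius_frac * shape
  with_seed(spec$seed, {
    segments <- list()
    seg_id <- 0L
    for (tree in seq_len(spec$n_trees)) {
      u <- rnorm(3)
      u <- u / sqrt(sum(u^2))
      p0 <- center + 0.85 * semi * u
      d0 <- -u
      base_len <- round(runif(1, 0.25, 0.4) * min(shape))
      recurse <- function(p, d, radius, depth, parent, len) {
        seg <- walk_segment(p, d, max(4L, round(len)), center, semi)
        seg_id <<- seg_id + 1L
        this_id <- seg_id
        segments[[this_id]] <<- list(points = seg$points, radius = radius,
                                     depth = depth, tree = tree,
                                     id = this_id, parent = parent)
        if (depth < spec$branch_depth) {
          for (j in 1:2) {
            dj <- seg$dir + 0.8 * rnorm(3)
            dj <- dj / sqrt(sum(dj^2))
            recurse(seg$points[nrow(seg$points), ], dj,
                    radius * spec$radius_decay, depth + 1L, this_id,
                    len * 0.75)
          }
        }
      }
      recurse(p0, d0, spec$radius_root_vox, 0L, NA_integer_, base_len)
    }
    segments
  })
}

# drop one random non-root segment and all its descendants (emulates the
# reduced vessel count of a stroke case); seeded independently of growth
prune_tree <- function(segments, seed) {
  candidates <- which(!is.na(vapply(segments, function(s) s$parent, 0L)))
  if (length(candidates) == 0L) return(segments)
  drop_root <- with_seed(seed, sample(candidates, 1L))
  drop <- drop_root
  repeat {
    kids <- which(vapply(segments, function(s)
      !is.na(s$parent) && s$parent %in% drop, TRUE))
    kids <- setdiff(kids, drop)
    if (length(kids) == 0L) break
    drop <- c(drop, kids)
  }
  segments[-drop]
}

# smooth multiplicative bias field: 1 + amplitude * B, with B a random
# second-order polynomial over [-1,1]^3 normalized to max |B| = 1
bias_field <- function(shape, amplitude) {
  cf <- rnorm(9)
  u <- (seq_len(shape[1]) - (shape[1] + 1) / 2) / (shape[1] / 2)
  v <- (seq_len(shape[2]) - (shape[2] + 1) / 2) / (shape[2] / 2)
  w <- (seq_len(shape[3]) - (shape[3] + 1) / 2) / (shape[3] / 2)
  U <- array(u, shape)
  V <- array(rep(v, each = shape[1]), shape)
  W <- array(rep(w, each = shape[1] * shape[2]), shape)
  B <- cf[1] * U + cf[2] * V + cf[3] * W + cf[4] * U * V + cf[5] * U * W +
    cf[6] * V * W + cf[7] * U^2 + cf[8] * V^2 + cf[9] * W^2
  B <- B / max(abs(B))
  1 + amplitude * B
}

# integer offsets within Euclidean distance r of the origin
ball_offsets <- function(r) {
  ri <- ceiling(r)
  g <- expand.grid(x = -ri:ri, y = -ri:ri, z = -ri:ri)
  g <- g[g$x^2 + g$y^2 + g$z^2 <= r^2, , drop = FALSE]
  as.matrix(g)
}

#' Rasterize a phantom case
#'
#' Builds the ground-truth label volume (0 background outside the brain
#' ellipsoid, 1 tissue, 2 vessel within `radius` of a centerline), then
#' draws intensities: tissue voxels from `N(tissue_mu, tissue_sigma^2)`,
#' vessel voxels from `N(vessel_mu, vessel_sigma^2)`, multiplied by the
#' optional bias field and degraded by optional additive noise. Intensities
#' are clipped below at a small positive floor inside the brain so that
#' intensity is exactly zero if and only if truth is background.
#'
#' @param spec a [phantom_spec()].
#' @param stroke if `TRUE`, prune one random subtree before rasterizing
#'   (same grown geometry as the `FALSE` twin with the same seed).
#' @return an object of class `phantom_case`: list with `intensity`
#'   ([intensity_volume()]), `truth` (three-class [label_volume()]),
#'   `centerlines` (list of polylines + radii), `stroke`, `seed`.
#' @export
rasterize_phantom <- function(spec, stroke = FALSE) {
  shape <- spec$shape
  center <- (shape + 1) / 2
  semi <- spec$brain_radius_frac * shape
  segments <- grow_vessel_tree(spec)
  if (stroke) segments <- prune_tree(segments, seed = spec$seed + 1L)

  # brain ellipsoid
  u2 <- ((seq_len(shape[1]) - center[1]) / semi[1])^2
  v2 <- ((seq_len(shape[2]) - center[2]) / semi[2])^2
  w2 <- ((seq_len(shape[3]) - center[3]) / semi[3])^2
  R2 <- outer(outer(u2, v2, `+`), w2, `+`)
  brain <- R2 <= 1

  truth <- array(0L, shape)
  truth[brain] <- 1L

  # stamp vessel tubes: a ball of the segment radius at every centerline
  # point (points are ~1 voxel apart, so tubes are contiguous)
  for (seg in segments) {
    offs <- ball_offsets(seg$radius)
    ctr <- round(seg$points)
    for (i in seq_len(nrow(ctr))) {
      vox <- sweep(offs, 2L, ctr[i, ], `+`)
      ok <- vox[, 1] >= 1 & vox[, 1] <= shape[1] &
        vox[, 2] >= 1 & vox[, 2] <= shape[2] &
        vox[, 3] >= 1 & vox[, 3] <= shape[3]
      vox <- vox[ok, , drop = FALSE]
      if (nrow(vox) > 0) truth[vox] <- 2L
    }
  }
  truth[!brain] <- 0L  # vessels never extend outside the brain
  if (!any(truth == 2L))
    stop("rasterize_phantom: vessel tree entirely outside the brain")

  with_seed(spec$seed + 2L, {
    img <- array(0, shape)
    n_t <- sum(truth == 1L)
    n_v <- sum(truth == 2L)
    img[truth == 1L] <- rnorm(n_t, spec$tissue_mu, spec$tissue_sigma)
    img[truth == 2L] <- rnorm(n_v, spec$vessel_mu, spec$vessel_sigma)
    if (spec$bias_amplitude > 0)
      img <- img * bias_field(shape, spec$bias_amplitude)
    if (spec$noise_sigma > 0) {
      noise <- array(rnorm(prod(shape), 0, spec$noise_sigma), shape)
      img[brain] <- img[brain] + noise[brain]
    }
    img[brain] <- pmax(img[brain], 1e-3)  # keep zero exclusive to background
    img[!brain] <- 0
  })

  structure(list(intensity = intensity_volume(img),
                 truth = label_volume(truth),
                 centerlines = lapply(segments, function(s)
                   list(points = s$points, radius = s$radius)),
                 stroke = stroke, seed = spec$seed),
            class = "phantom_case")
}

#' @export
print.phantom_case <- function(x, ...) {
  d <- dim(x$intensity$data)
  nb <- sum(x$truth$data > 0L)
  nv <- sum(x$truth$data == 2L)
  cat(sprintf(
    "phantom_case %dx%dx%d (seed %d%s): %d brain voxels, %d vessel (%.2f%%)\n",
    d[1], d[2], d[3], x$seed, if (x$stroke) ", stroke" else "", nb, nv,
    100 * nv / nb))
  invisible(x)
}

#' Generate a phantom dataset
#'
#' Independent phantom cases with per-case seeds derived from one master
#' seed. A fraction of cases can be made "stroke-like" by pruning a random
#' subtree, emulating the reduced vessel count of stroke angiograms.
#'
#' @param spec a [phantom_spec()] (its `seed` field is ignored here).
#' @param n_cases number of cases (>= 1).
#' @param seed master seed.
#' @param p_stroke probability that a case is a stroke variant.
#' @return list of `phantom_case` objects.
#' @export
generate_dataset <- function(spec, n_cases, seed = 1L, p_stroke = 0) {
  stopifnot(n_cases >= 1L, p_stroke >= 0, p_stroke <= 1)
  case_seeds <- derive_seeds(seed, n_cases)
  stroke <- with_seed(seed + 1L, runif(n_cases) < p_stroke)
  lapply(seq_len(n_cases), function(i) {
    sp <- spec
    sp$seed <- case_seeds[i]
    rasterize_phantom(sp, stroke = stroke[i])
  })
}
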