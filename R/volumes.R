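#' Intensity volume
#'
#' A 3D scalar observation field (e.g., a preprocessed TOF-MRA volume:
#' skull-stripped and bias-corrected, with background voxels exactly zero).
#' Intensities must be finite, non-negative, and not all zero.
#'
#' @param data numeric 3D array.
#' @param spacing per-axis voxel size in mm (length 3).
#' @param affine optional 4x4 voxel-to-world matrix; defaults to a scaled
#'   identity built from `spacing`.
#' @return an object of class `intensity_volume` with elements `data`,
#'   `spacing`, `affine`.
#' @export
intensity_volume <- function(data, spacing = c(1, 1, 1), affine = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("intensity_volume: 'data' must be a 3D array")
  storage.mode(data) <- "double"
  if (!all(is.finite(data)))
    stop("intensity_volume: all intensities must be finite")
  if (any(data < 0))
    stop("intensity_volume: intensities must be non-negative")
  if (!any(data > 0))
    stop("intensity_volume: volume is identically zero")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("intensity_volume: 'spacing' must be 3 positive values")
  if (is.null(affine)) affine <- diag(c(spacing, 1))
  structure(list(data = data, spacing = spacing, affine = affine),
            class = "intensity_volume")
}

#' Label volume
#'
#' A 3D integer class field over `{0, ..., L-1}`. Index 0 is background,
#' 1 brain tissue, 2 vessel in the three-class convention used throughout.
#'
#' @param data integer 3D array of class indices.
#' @param class_names ordered class names; `length(class_names)` is L.
#' @param spacing,affine spatial reference, as [intensity_volume()].
#' @return an object of class `label_volume`.
#' @export
label_volume <- function(data,
                         class_names = c("background", "tissue", "vessel"),
                         spacing = c(1, 1, 1), affine = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("label_volume: 'data' must be a 3D array")
  storage.mode(data) <- "integer"
  L <- length(class_names)
  if (anyNA(data) || any(data < 0L) || any(data >= L))
    stop("label_volume: labels must lie in 0..", L - 1L)
  if (is.null(affine)) affine <- diag(c(spacing, 1))
  structure(list(data = data, class_names = class_names,
                 spacing = as.numeric(spacing), affine = affine),
            class = "label_volume")
}

#' Per-class Gaussian parameters
#'
#' @param mu class mean intensity.
#' @param sigma class standard deviation (> 0).
#' @return an object of class `class_params`.
#' @export
class_params <- function(mu, sigma) {
  stopifnot(is.finite(mu), is.finite(sigma), sigma > 0)
  structure(list(mu = as.numeric(mu), sigma = as.numeric(sigma)),
            class = "class_params")
}

#' @export
print.class_params <- function(x, ...) {
  cat(sprintf("class_params: mu = %.4g, sigma = %.4g\n", x$mu, x$sigma))
  invisible(x)
}

#' @export
print.intensity_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("intensity_volume %dx%dx%d, spacing %s mm, range [%.3g, %.3g]\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 3), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$data)
  tab <- tabulate(x$data + 1L, nbins = length(x$class_names))
  cat(sprintf("label_volume %dx%dx%d: %s\n", d[1], d[2], d[3],
              paste(sprintf("%s=%d", x$class_names, tab), collapse = ", ")))
  invisible(x)
}

# coerce a user-supplied mask (logical array, 0/1 array, or label_volume)
# to a logical array matching `dims`
as_mask <- function(mask, dims) {
  if (inherits(mask, "label_volume")) mask <- mask$data
  if (!is.array(mask) || !identical(dim(mask), as.integer(dims)))
    stop("mask must be a 3D array on the same grid as the volume")
  mask <- array(as.logical(mask != 0), dim = dims)
  if (anyNA(mask)) stop("mask contains NA")
  mask
}
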