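#' Maximum intensity projection
#'
#' Per-pixel maximum of a 3D volume along one anatomical axis. With the
#' grid convention used throughout (dim 1 = left-right, dim 2 =
#' anterior-posterior, dim 3 = inferior-superior), "sagittal" projects
#' along dim 1, "coronal" along dim 2, and "axial" along dim 3. For a
#' binary mask the MIP is the logical OR along the axis.
#'
#' @param x 3D array (or [intensity_volume()] / [label_volume()]).
#' @param axis `"axial"`, `"coronal"`, `"sagittal"`, or 1:3 (the dimension
#'   projected over).
#' @return 2D array.
#' @export
mip <- function(x, axis) {
  if (inherits(x, c("intensity_volume", "label_volume"))) x <- x$data
  if (!is.array(x) || length(dim(x)) != 3L) stop("mip: input must be 3D")
  ax <- mip_axis(axis)
  apply(x, setdiff(1:3, ax), max)
}

mip_axis <- function(axis) {
  if (is.character(axis)) {
    ax <- c(sagittal = 1L, coronal = 2L, axial = 3L)[axis]
    if (is.na(ax)) stop("unknown axis '", axis,
                        "' (use axial, coronal, or sagittal)")
    unname(ax)
  } else if (axis %in% 1:3) {
    as.integer(axis)
  } else {
    stop("axis must be axial/coronal/sagittal or 1:3")
  }
}

mip_axes <- c("axial", "coronal", "sagittal")

#' Binary vessel mask from a label volume
#'
#' @param labels a [label_volume()] (or integer array).
#' @param vessel_class class index treated as vessel (default 2).
#' @return integer 3D array, 1 at vessel voxels.
#' @export
vessel_mask <- function(labels, vessel_class = 2L) {
  lab <- if (inherits(labels, "label_volume")) labels$data else labels
  array(as.integer(lab == vessel_class), dim(lab))
}

#' Pixelwise confusion counts
#'
#' @param pred,ref binary 2D arrays of equal shape; `ref == 1` defines the
#'   positive class.
#' @return list of class `confusion_counts` with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion <- function(pred, ref) {
  if (!identical(dim(pred), dim(ref)))
    stop("confusion: shape mismatch between prediction and reference")
  p <- pred != 0
  r <- ref != 0
  structure(list(tp = sum(p & r), fp = sum(p & !r),
                 tn = sum(!p & !r), fn = sum(!p & r)),
            class = "confusion_counts")
}

#' Binary classification metrics from confusion counts
#'
#' Accuracy `(tp+tn)/total`, sensitivity `tp/(tp+fn)`, specificity
#' `tn/(tn+fp)`, precision `tp/(tp+fp)`, and the Dice similarity
#' coefficient `2tp/(2tp+fp+fn)`. A ratio with zero denominator is
#' reported as `NaN` with a warning, never silently as 0.
#'
#' @param counts a `confusion_counts` object (see [confusion()]).
#' @return named list with `accuracy`, `sensitivity`, `specificity`,
#'   `precision`, `dsc`, all in `[0, 1]` (or `NaN`).
#' @export
metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  total <- tp + fp + tn + fn
  if (total == 0) stop("metrics: empty confusion counts")
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning("metrics: ", what, " undefined (zero denominator)")
      return(NaN)
    }
    num / den
  }
  list(accuracy = (tp + tn) / total,
       sensitivity = safe_div(tp, tp + fn, "sensitivity"),
       specificity = safe_div(tn, tn + fp, "specificity"),
       precision = safe_div(tp, tp + fp, "precision"),
       dsc = safe_div(2 * tp, 2 * tp + fp + fn, "DSC"))
}

#' Keep large connected components of a binary mask
#'
#' Optional post-processing for predicted vessel masks: label 3D connected
#' components (26-connectivity by default) and drop components smaller
#' than `min_size` voxels.
#'
#' @param mask binary 3D array.
#' @param min_size minimum component size in voxels.
#' @param connectivity 6 or 26.
#' @return binary 3D array.
#' @export
largest_components <- function(mask, min_size = 10L, connectivity = 26L) {
  dims <- dim(mask)
  comp <- label_components_cpp(as.logical(mask != 0), as.integer(dims),
                               as.integer(connectivity))
  if (max(comp) == 0L) return(array(0L, dims))
  sizes <- tabulate(comp)
  keep <- which(sizes >= min_size)
  array(as.integer(comp %in% keep), dims)
}

#' Evaluate a segmentation by three-axis MIP comparison
#'
#' Extracts the vessel mask from the predicted labels, optionally
#' post-processes it, projects prediction and reference along the axial,
#' coronal and sagittal axes, and scores each projected pair with
#' [metrics()]. The reference may be a three-class truth [label_volume()],
#' a binary 3D vessel mask, or a named list of pre-computed reference MIPs
#' (`axial`, `coronal`, `sagittal`).
#'
#' @param pred_labels predicted [label_volume()] (or binary 3D mask).
#' @param ref reference (see above).
#' @param postprocess `NULL` (default, none) or a `min_size` integer to
#'   apply [largest_components()] to the predicted mask.
#' @return a `metric_report`: data.frame with rows axial/coronal/sagittal/
#'   mean and columns accuracy, sensitivity, specificity, precision, dsc.
#'   Attribute `confusion` holds the per-axis counts.
#' @export
evaluate_case <- function(pred_labels, ref, postprocess = NULL) {
  pm <- if (inherits(pred_labels, "label_volume"))
    vessel_mask(pred_labels) else array(as.integer(pred_labels != 0),
                                        dim(pred_labels))
  if (!is.null(postprocess))
    pm <- largest_components(pm, min_size = as.integer(postprocess))

  ref_mips <- if (is.list(ref) && !inherits(ref, "label_volume")) {
    if (!all(mip_axes %in% names(ref)))
      stop("evaluate_case: reference MIP list needs axial/coronal/sagittal")
    ref[mip_axes]
  } else {
    rm3 <- if (inherits(ref, "label_volume")) vessel_mask(ref)
           else array(as.integer(ref != 0), dim(ref))
    if (!identical(dim(rm3), dim(pm)))
      stop("evaluate_case: prediction and reference grids differ")
    lapply(stats::setNames(mip_axes, mip_axes), function(a) mip(rm3, a))
  }

  rows <- list()
  conf <- list()
  for (a in mip_axes) {
    cc <- confusion(mip(pm, a), ref_mips[[a]])
    conf[[a]] <- cc
    rows[[a]] <- as.data.frame(metrics(cc))
  }
  rep <- do.call(rbind, rows)
  rep <- rbind(rep, mean = colMeans(rep))
  rep <- cbind(axis = c(mip_axes, "mean"), rep)
  rownames(rep) <- NULL
  attr(rep, "confusion") <- conf
  class(rep) <- c("metric_report", class(rep))
  rep
}

#' Aggregate metric reports across cases
#'
#' Two aggregation orders are reported: `per_case` averages each case's
#' cross-axis mean row (unweighted mean of per-case means), and `pooled`
#' sums the confusion counts over all cases and axes before computing
#' metrics.
#'
#' @param reports list of `metric_report` objects from [evaluate_case()].
#' @return list with `per_case` (named metric means), `pooled` (metrics of
#'   summed counts), and `cases` (per-case mean rows as a data.frame).
#' @export
evaluate_dataset <- function(reports) {
  stopifnot(length(reports) >= 1L)
  means <- do.call(rbind, lapply(reports, function(r)
    r[r$axis == "mean", -1, drop = FALSE]))
  rownames(means) <- NULL
  tot <- list(tp = 0, fp = 0, tn = 0, fn = 0)
  for (r in reports)
    for (cc in attr(r, "confusion"))
      for (f in names(tot)) tot[[f]] <- tot[[f]] + cc[[f]]
  class(tot) <- "confusion_counts"
  list(per_case = colMeans(means), pooled = metrics(tot), cases = means)
}

#' Write a metric report (or several) as CSV
#'
#' Long format: case, axis, metric, value.
#'
#' @param reports one `metric_report` or a list of them.
#' @param path output CSV path.
#' @export
write_metric_report <- function(reports, path) {
  if (inherits(reports, "metric_report")) reports <- list(reports)
  rows <- list()
  for (i in seq_along(reports)) {
    r <- as.data.frame(reports[[i]])
    for (j in seq_len(nrow(r)))
      for (m in c("accuracy", "sensitivity", "specificity", "precision",
                  "dsc"))
        rows[[length(rows) + 1L]] <- data.frame(case = i, axis = r$axis[j],
                                                metric = m,
                                                value = r[[m]][j])
  }
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
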