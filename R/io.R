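#' Read a 3D NIfTI volume
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return an [intensity_volume()] with the file's voxel spacing and
#'   affine; intensities are cast to double.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("read_volume: file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    stop("read_volume: cannot parse NIfTI file '", path,
                         "': ", conditionMessage(e)))
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L)
    arr <- array(arr, dim(arr)[1:3])
  if (length(dim(arr)) != 3L)
    stop("read_volume: expected a 3D volume, got ",
         length(dim(arr)), "D: ", path)
  spacing <- RNifti::pixdim(img)[1:3]
  intensity_volume(array(as.double(arr), dim(arr)), spacing = spacing,
                   affine = unclass(RNifti::xform(img)))
}

#' Read a 3D NIfTI label volume
#'
#' @param path path to a `.nii` or `.nii.gz` file holding integer labels.
#' @param class_names class names (index 0 first).
#' @return a [label_volume()].
#' @export
read_labels <- function(path,
                        class_names = c("background", "tissue", "vessel")) {
  if (!file.exists(path)) stop("read_labels: file not found: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L)
    stop("read_labels: expected a 3D volume: ", path)
  label_volume(array(as.integer(round(arr)), dim(arr)),
               class_names = class_names,
               spacing = RNifti::pixdim(img)[1:3],
               affine = unclass(RNifti::xform(img)))
}

#' Write a volume as NIfTI
#'
#' Intensity volumes are stored as 64-bit float (lossless round-trip),
#' label volumes as unsigned 8-bit; the affine is preserved. Both `.nii` and `.nii.gz` extensions
#' are supported.
#'
#' @param vol an [intensity_volume()] or [label_volume()].
#' @param path output path.
#' @export
write_volume <- function(vol, path) {
  is_label <- inherits(vol, "label_volume")
  if (!is_label && !inherits(vol, "intensity_volume"))
    stop("write_volume: expected an intensity_volume or label_volume")
  img <- RNifti::asNifti(vol$data,
                         datatype = if (is_label) "uint8" else "double")
  img <- RNifti::`sform<-`(img, structure(vol$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}
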