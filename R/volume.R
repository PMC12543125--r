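# Minimal 3D image container: a numeric array plus voxel spacing in mm.
# NIfTI round-tripping goes through RNifti.

#' Construct an image volume
#'
#' @param data 3D numeric array (x, y, z order).
#' @param spacing Voxel spacing in mm, length 3.
#' @return An `rr_volume` object.
#' @export
as_volume <- function(data, spacing) {
  if (length(dim(data)) != 3L) rr_abort("`data` must be a 3D array")
  if (length(spacing) != 3L || any(spacing <= 0)) {
    rr_abort("`spacing` must be 3 positive voxel sizes in mm")
  }
  structure(list(data = data, spacing = as.numeric(spacing)),
            class = "rr_volume")
}

#' @export
print.rr_volume <- function(x, ...) {
  cat(sprintf("<rr_volume> %s voxels, spacing %s mm, range [%.3g, %.3g]\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.rr_volume <- function(x) dim(x$data)

#' Write a volume or label map to NIfTI
#'
#' Writes RAS+ oriented NIfTI with the voxel spacing recorded in the header.
#'
#' @param vol An `rr_volume`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$data, internal = FALSE)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI file as a volume
#'
#' @param path NIfTI file path.
#' @return An `rr_volume`.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  as_volume(array(as.numeric(img), dim = dim(img)[1:3]),
            RNifti::pixdim(img)[1:3])
}
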