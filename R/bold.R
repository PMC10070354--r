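#' BOLD dataset container
#'
#' Lightweight container for a 4D BOLD acquisition: the signal grid, the
#' voxel-to-world (MNI mm) affine, the repetition time and a gray-matter mask.
#' Every preprocessing and GSCORR step consumes this unit.
#'
#' @param data 4D numeric array (x, y, z, time).
#' @param affine 4x4 matrix mapping 0-based voxel indices to MNI mm (RAS).
#' @param tr Repetition time in seconds.
#' @param mask Optional 3D logical array marking gray-matter voxels; defaults
#'   to all voxels.
#' @return An object of class `bold_dataset`.
#' @export
bold_dataset <- function(data, affine, tr, mask = NULL) {
  if (length(dim(data)) != 4L)
    stop("`data` must be a 4D array (x, y, z, time); got ",
         length(dim(data)), " dimensions")
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L))) stop("`affine` must be a 4x4 matrix")
  if (!is.numeric(tr) || length(tr) != 1L || !is.finite(tr) || tr <= 0)
    stop("`tr` must be a single positive number (seconds)")
  gd <- dim(data)[1:3]
  if (is.null(mask)) mask <- array(TRUE, gd)
  if (!all(dim(mask) == gd)) stop("`mask` grid does not match `data` grid")
  structure(
    list(data = data, affine = affine, tr = tr,
         mask = array(as.logical(mask), gd)),
    class = "bold_dataset"
  )
}

#' @export
print.bold_dataset <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold_dataset> %d x %d x %d voxels, %d volumes, TR = %g s\n",
              d[1], d[2], d[3], d[4], x$tr))
  cat(sprintf("  gray-matter mask: %d voxels\n", sum(x$mask)))
  invisible(x)
}

#' Number of volumes (time points) in a BOLD dataset
#' @param bold A [bold_dataset()].
#' @return Integer count of volumes.
#' @export
n_volumes <- function(bold) dim(bold$data)[4L]

#' View a BOLD dataset as a voxels-by-time matrix
#' @param bold A [bold_dataset()].
#' @return Numeric matrix with one row per voxel (grid in column-major order)
#'   and one column per volume.
#' @export
voxel_matrix <- function(bold) matrix(bold$data, ncol = dim(bold$data)[4L])

#' MNI coordinates of every voxel centre
#'
#' Applies the affine to all 0-based voxel indices of a grid.
#'
#' @param grid_dim Integer vector of 3 voxel counts.
#' @param affine 4x4 voxel-to-mm matrix.
#' @return Matrix with `prod(grid_dim)` rows (column-major voxel order) and
#'   columns x, y, z in mm.
#' @export
voxel_coordinates <- function(grid_dim, affine) {
  idx <- as.matrix(expand.grid(x = seq_len(grid_dim[1]) - 1L,
                               y = seq_len(grid_dim[2]) - 1L,
                               z = seq_len(grid_dim[3]) - 1L))
  xyz <- cbind(idx, 1) %*% t(affine)
  colnames(xyz) <- c("x", "y", "z", "w")
  xyz[, 1:3, drop = FALSE]
}

#' Read a 4D NIfTI file into a BOLD dataset
#'
#' The repetition time is taken from the NIfTI header (4th pixdim); a `tr`
#' argument overrides a missing or non-positive header value (the override is
#' reported via a message).
#'
#' @param path Path to a NIfTI file.
#' @param tr Optional TR in seconds, used when the header carries none.
#' @param mask Optional 3D logical array (gray-matter mask).
#' @return A [bold_dataset()].
#' @export
load_bold <- function(path, tr = NULL, mask = NULL) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L)
    stop("`", path, "` is ", length(d), "D; a 4D BOLD NIfTI is required")
  header_tr <- RNifti::pixdim(img)[4]
  if (is.na(header_tr) || header_tr <= 0) {
    if (is.null(tr))
      stop("TR missing from NIfTI header and no `tr` override supplied")
    message("TR absent in header; using configured TR = ", tr, " s")
  } else if (!is.null(tr) && abs(header_tr - tr) > 1e-6) {
    message("overriding header TR (", header_tr, " s) with configured TR = ",
            tr, " s")
  } else {
    tr <- header_tr
  }
  if (is.null(tr)) tr <- header_tr
  bold_dataset(array(as.numeric(img), d), xform_matrix(img), tr, mask)
}

xform_matrix <- function(img) {
  m <- RNifti::xform(img)
  structure(as.numeric(m), dim = c(4L, 4L))
}

#' Write a BOLD dataset to a 4D NIfTI file
#'
#' @param bold A [bold_dataset()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param datatype NIfTI storage type; single-precision float by default.
#' @return `path`, invisibly.
#' @export
write_bold <- function(bold, path, datatype = "float") {
  img <- RNifti::asNifti(bold$data)
  RNifti::sform(img) <- structure(bold$affine, code = 2L)
  RNifti::qform(img) <- structure(bold$affine, code = 2L)
  vox <- sqrt(colSums(bold$affine[1:3, 1:3]^2))
  RNifti::pixdim(img) <- c(vox, bold$tr)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Write a 3D mask or integer label volume to NIfTI
#'
#' @param vol 3D array (logical mask or integer labels).
#' @param affine 4x4 voxel-to-mm matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, affine, path) {
  img <- RNifti::asNifti(array(as.numeric(vol), dim(vol)))
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::qform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = "int16")
  invisible(path)
}
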