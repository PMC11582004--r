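#' 3D volume with a voxel-to-MNI affine
#'
#' Lightweight container for a scalar 3D grid in MNI space. The affine maps
#' 0-based voxel indices (i, j, k) to MNI millimetre coordinates, following
#' the NIfTI sform convention.
#'
#' @param data numeric 3D array.
#' @param affine 4x4 matrix mapping 0-based voxel indices to MNI mm.
#' @param space coordinate-space tag; only "MNI" volumes enter the pipeline.
#' @return An object of class `dat_volume`.
#' @export
new_volume <- function(data, affine, space = "MNI") {
  if (length(dim(data)) != 3L) stop("volume data must be a 3D array")
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L))) stop("affine must be a 4x4 matrix")
  if (abs(det(affine)) < .Machine$double.eps) stop("affine must be invertible")
  if (any(dim(data) < 1L)) stop("grid dimensions must be positive")
  structure(list(data = data, affine = affine, space = space),
            class = "dat_volume")
}

#' Boolean mask on a volume grid
#'
#' @param data logical 3D array.
#' @param affine 4x4 voxel-to-MNI affine shared with companion volumes.
#' @param provenance free-text description of how the mask was derived
#'   (threshold, source).
#' @return An object of class `dat_mask` (also a `dat_volume`).
#' @export
new_mask <- function(data, affine, provenance = "") {
  if (!is.logical(data)) storage.mode(data) <- "logical"
  v <- new_volume(data, affine)
  v$provenance <- provenance
  class(v) <- c("dat_mask", "dat_volume")
  v
}

#' @export
print.dat_volume <- function(x, ...) {
  cat(sprintf("<%s> %s grid, voxel size %s mm\n",
              class(x)[1L], paste(dim(x$data), collapse = "x"),
              paste(signif(voxel_size(x), 4), collapse = "x")))
  invisible(x)
}

#' Voxel edge lengths in mm
#' @param vol a `dat_volume`.
#' @return numeric length-3 vector of voxel sizes along i, j, k.
#' @export
voxel_size <- function(vol) {
  sqrt(colSums(vol$affine[1:3, 1:3]^2))
}

stopifnot_same_geometry <- function(a, b, what = "volumes") {
  if (!identical(dim(a$data), dim(b$data)) ||
      max(abs(a$affine - b$affine)) > 1e-6) {
    stop(sprintf("geometry mismatch between %s (dims %s vs %s)", what,
                 paste(dim(a$data), collapse = "x"),
                 paste(dim(b$data), collapse = "x")))
  }
  invisible(TRUE)
}

#' Map 0-based voxel indices to MNI mm
#'
#' @param vol a `dat_volume`.
#' @param ijk integer matrix (n x 3) or length-3 vector of 0-based indices.
#' @return numeric matrix (n x 3) of MNI coordinates in mm.
#' @export
voxel_to_mni <- function(vol, ijk) {
  ijk <- rbind_coords(ijk)
  xyz1 <- cbind(ijk, 1) %*% t(vol$affine)
  xyz1[, 1:3, drop = FALSE]
}

#' Map MNI mm to nearest 0-based voxel indices
#' @param vol a `dat_volume`.
#' @param xyz numeric matrix (n x 3) or length-3 vector of MNI mm.
#' @return integer matrix (n x 3) of 0-based voxel indices.
#' @export
mni_to_voxel <- function(vol, xyz) {
  xyz <- rbind_coords(xyz)
  ijk <- cbind(xyz, 1) %*% t(solve(vol$affine))
  round(ijk[, 1:3, drop = FALSE])
}

rbind_coords <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  stopifnot(ncol(x) == 3L)
  x
}

#' MNI coordinates of every voxel (or a subset)
#'
#' @param vol a `dat_volume`.
#' @param linear optional 1-based linear (column-major) voxel indices; default
#'   all voxels.
#' @return numeric matrix (n x 3) of MNI mm, rows in the order of `linear`.
#' @export
voxel_grid_mni <- function(vol, linear = NULL) {
  d <- dim(vol$data)
  if (is.null(linear)) linear <- seq_len(prod(d))
  ijk <- arrayInd(linear, d) - 1L
  voxel_to_mni(vol, ijk)
}

#' Read a NIfTI-1 volume from disk
#'
#' @param path path to a .nii or .nii.gz file.
#' @return a `dat_volume` carrying the image data and its sform affine.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- matrix(as.numeric(RNifti::xform(img)), 4L, 4L)
  new_volume(array(as.numeric(img), dim = dim(img)[1:3]), aff)
}

#' Write a volume (or mask) as NIfTI-1
#' @param vol a `dat_volume` or `dat_mask`.
#' @param path output path (.nii or .nii.gz).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  dat <- vol$data
  if (is.logical(dat)) storage.mode(dat) <- "integer"
  img <- RNifti::asNifti(dat)
  img <- RNifti::`sform<-`(img, structure(vol$affine, code = 4L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Mirror a volume across the MNI mid-sagittal plane
#'
#' Flips the volume right-to-left so that the value at MNI (x, y, z) equals
#' the input value at (-x, y, z). Used for participants who trained with the
#' left hand, so the task-relevant striatum is always on the left for group
#' analysis. Implemented as a pure voxel-axis flip (no interpolation), which
#' requires the grid to be symmetric about x = 0 within half a voxel.
#'
#' @param vol a `dat_volume` or `dat_mask`.
#' @return the mirrored volume, same geometry.
#' @export
mirror_volume <- function(vol) {
  A <- vol$affine
  ## which voxel axis carries MNI x, and ensure it is axis-aligned
  ax <- which.max(abs(A[1, 1:3]))
  if (any(abs(A[2:3, ax]) > 1e-6) ||
      any(abs(A[1, setdiff(1:3, ax)]) > 1e-6)) {
    stop("mirror_volume requires an axis-aligned affine along MNI x")
  }
  n <- dim(vol$data)[ax]
  x_first <- A[1, ax] * 0 + A[1, 4]
  x_last <- A[1, ax] * (n - 1) + A[1, 4]
  offset <- abs(x_first + x_last)
  if (offset > abs(A[1, ax]) / 2) {
    stop(sprintf(
      "grid not symmetric about x = 0 (edge coordinates %.2f / %.2f mm, offset %.2f mm)",
      x_first, x_last, offset))
  }
  idx <- rev(seq_len(n))
  out <- vol
  out$data <- switch(ax,
                     vol$data[idx, , , drop = FALSE],
                     vol$data[, idx, , drop = FALSE],
                     vol$data[, , idx, drop = FALSE])
  out
}
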