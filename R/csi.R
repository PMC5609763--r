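#' Chemical shift imaging (CSI) voxel grid
#'
#' A spatial grid of FIDs plus the geometry needed to place voxels in
#' patient coordinates. Voxel indices are 0-based internally (`(0,0,0)` is
#' the first voxel); user-facing tables report 1-based indices. FIDs are
#' stored in row-major voxel order: index `(i, j, k)` maps to list position
#' `i + nx * (j + ny * k) + 1`.
#'
#' @param fids List of [fid_series()] objects, length `prod(dims)`.
#' @param dims Integer vector `(nx, ny, nz)` of voxel counts.
#' @param position Patient-coordinate position (mm) of the centre of voxel
#'   `(0,0,0)`.
#' @param row_dir,col_dir,slice_dir Orthonormal direction unit vectors for
#'   the i, j, k index axes.
#' @param voxel_size Voxel extent (mm) along each axis.
#' @return An object of class `csi_grid`.
#' @export
csi_grid <- function(fids, dims, position = c(0, 0, 0),
                     row_dir = c(1, 0, 0), col_dir = c(0, 1, 0),
                     slice_dir = c(0, 0, 1), voxel_size = c(10, 10, 10)) {
  dims <- as.integer(dims)
  stop_unless(length(dims) == 3 && all(dims >= 1),
              "`dims` must be three voxel counts >= 1.")
  stop_unless(length(fids) == prod(dims),
              sprintf("expected %d FIDs for dims (%s), got %d.",
                      prod(dims), paste(dims, collapse = ","), length(fids)))
  ok <- vapply(fids, inherits, logical(1), what = "fid_series")
  stop_unless(all(ok), "all grid elements must be fid_series objects.")
  R <- cbind(row_dir, col_dir, slice_dir)
  if (max(abs(crossprod(R) - diag(3))) > 1e-6) {
    abort("direction vectors must be orthonormal (within 1e-6).",
          class = "mrsfit_error_validation")
  }
  structure(
    list(fids = fids, dims = dims,
         position = as.numeric(position),
         row_dir = as.numeric(row_dir), col_dir = as.numeric(col_dir),
         slice_dir = as.numeric(slice_dir),
         voxel_size = as.numeric(voxel_size)),
    class = "csi_grid"
  )
}

#' @export
print.csi_grid <- function(x, ...) {
  cat(sprintf("<csi_grid> %d x %d x %d voxels (%d FIDs of %d points), voxel size %s mm\n",
              x$dims[1], x$dims[2], x$dims[3], length(x$fids),
              x$fids[[1]]$n_points,
              paste(signif(x$voxel_size, 4), collapse = " x ")))
  invisible(x)
}

# linear list position (1-based) of 0-based voxel index
voxel_linear_index <- function(grid, index) {
  index <- as.integer(index)
  stop_unless(length(index) == 3, "voxel index must have three entries.")
  if (any(index < 0) || any(index >= grid$dims)) {
    abort(sprintf("voxel index (%s) out of range for dims (%s).",
                  paste(index, collapse = ","),
                  paste(grid$dims, collapse = ",")),
          class = "mrsfit_error_validation")
  }
  index[1] + grid$dims[1] * (index[2] + grid$dims[2] * index[3]) + 1L
}

#' Extract one voxel's FID
#'
#' @param grid A [csi_grid()].
#' @param index 0-based voxel index `(i, j, k)`.
#' @return A [fid_series()].
#' @export
csi_voxel <- function(grid, index) {
  stopifnot(inherits(grid, "csi_grid"))
  grid$fids[[voxel_linear_index(grid, index)]]
}

#' Homogeneous voxel-index-to-patient affine of a CSI grid
#'
#' @param grid A [csi_grid()].
#' @return A 4x4 matrix `A` such that `A %*% c(i, j, k, 1)` is the patient
#'   coordinate (mm, homogeneous) of the centre of 0-based voxel `(i,j,k)`.
#' @export
csi_affine <- function(grid) {
  stopifnot(inherits(grid, "csi_grid"))
  A <- diag(4)
  A[1:3, 1] <- grid$row_dir * grid$voxel_size[1]
  A[1:3, 2] <- grid$col_dir * grid$voxel_size[2]
  A[1:3, 3] <- grid$slice_dir * grid$voxel_size[3]
  A[1:3, 4] <- grid$position
  A
}

#' Patient coordinates of a voxel centre
#'
#' @param grid A [csi_grid()].
#' @param index 0-based voxel index `(i, j, k)`.
#' @return Numeric `(x, y, z)` in mm.
#' @export
voxel_to_patient <- function(grid, index) {
  voxel_linear_index(grid, index)  # validates range
  as.numeric(csi_affine(grid) %*% c(index, 1))[1:3]
}
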