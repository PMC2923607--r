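#' Analysis grid specification
#'
#' Defines the isotropic voxel lattice the likelihood maps live on: voxel
#' size in mm and a bounding box in Talairach mm. The affine is diagonal
#' (RAS-ordered, mm = origin + (index - 1) * voxel), so index/mm round trips
#' are exact.
#'
#' @param voxel_mm Isotropic voxel size in mm (default 2).
#' @param xlim,ylim,zlim mm ranges per axis. The defaults cover the
#'   Talairach brain volume.
#' @return An object of class \code{ale_grid}: voxel size, dimensions,
#'   origin (mm of the first voxel center) and the 4x4 affine.
#' @export
ale_grid <- function(voxel_mm = 2, xlim = c(-70, 70), ylim = c(-104, 68),
                     zlim = c(-50, 78)) {
  stopifnot(voxel_mm > 0, xlim[2] > xlim[1], ylim[2] > ylim[1],
            zlim[2] > zlim[1])
  origin <- c(xlim[1], ylim[1], zlim[1])
  dim <- floor(c(diff(xlim), diff(ylim), diff(zlim)) / voxel_mm) + 1L
  affine <- diag(c(rep(voxel_mm, 3), 1))
  affine[1:3, 4] <- origin  # NIfTI convention: voxel (0,0,0) -> origin mm
  structure(list(voxel_mm = voxel_mm, dim = as.integer(dim),
                 origin = origin, affine = affine),
            class = "ale_grid")
}

#' @export
print.ale_grid <- function(x, ...) {
  cat(sprintf("ALE grid: %d x %d x %d voxels at %g mm (origin %g, %g, %g mm)\n",
              x$dim[1], x$dim[2], x$dim[3], x$voxel_mm,
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Convert voxel indices to mm coordinates
#'
#' @param grid An \code{ale_grid}.
#' @param ijk Integer voxel indices (1-based), length-3 vector or n x 3
#'   matrix.
#' @return mm coordinates, same shape as input.
#' @export
vox2mm <- function(grid, ijk) {
  ijk <- .as_coord_matrix(ijk)
  out <- sweep((ijk - 1) * grid$voxel_mm, 2, grid$origin, "+")
  .restore_coord_shape(out, ijk)
}

#' Convert mm coordinates to nearest voxel indices
#'
#' @param grid An \code{ale_grid}.
#' @param mm mm coordinates, length-3 vector or n x 3 matrix.
#' @return 1-based voxel indices (rounded to nearest), same shape as input.
#' @export
mm2vox <- function(grid, mm) {
  mm <- .as_coord_matrix(mm)
  out <- round(sweep(mm, 2, grid$origin, "-") / grid$voxel_mm) + 1
  .restore_coord_shape(out, mm)
}

#' Built-in procedural brain mask
#'
#' A smooth ellipsoid approximation of the Talairach brain volume, generated
#' on the analysis grid. It is a self-contained stand-in for a real binary
#' brain mask: analyses of real corpora should supply a proper mask NIfTI
#' via [read_mask()], but the ellipsoid keeps simulations and tests free of
#' external files. Semi-axes 66 x 86 x 62 mm around center (0, -18, 12) mm,
#' enclosing the usual Talairach bounding box.
#'
#' @param grid An \code{ale_grid}.
#' @return Logical 3D array of dimension \code{grid$dim}.
#' @export
ellipsoid_mask <- function(grid) {
  ctr <- c(0, -18, 12)
  semi <- c(66, 86, 62)
  xs <- (grid$origin[1] + (seq_len(grid$dim[1]) - 1) * grid$voxel_mm - ctr[1]) / semi[1]
  ys <- (grid$origin[2] + (seq_len(grid$dim[2]) - 1) * grid$voxel_mm - ctr[2]) / semi[2]
  zs <- (grid$origin[3] + (seq_len(grid$dim[3]) - 1) * grid$voxel_mm - ctr[3]) / semi[3]
  d2 <- outer(outer(xs^2, ys^2, "+"), zs^2, "+")
  d2 <= 1
}

#' Read a brain mask from a NIfTI file
#'
#' The image is read with RNifti and resampled onto the analysis grid by
#' nearest-neighbour lookup through the image's qform/sform affine; voxels
#' with value > 0.5 are in-mask.
#'
#' @param path NIfTI file (.nii or .nii.gz).
#' @param grid Target \code{ale_grid}.
#' @return Logical 3D array of dimension \code{grid$dim}.
#' @export
read_mask <- function(path, grid) {
  img <- RNifti::readNifti(path)
  xf <- RNifti::xform(img)
  inv <- solve(rbind(xf, c(0, 0, 0, 1)))
  ijk <- as.matrix(expand.grid(i = seq_len(grid$dim[1]),
                               j = seq_len(grid$dim[2]),
                               k = seq_len(grid$dim[3])))
  mm <- vox2mm(grid, ijk)
  src <- round(cbind(mm, 1) %*% t(inv[1:3, ])) + 1  # RNifti voxels are 0-based
  arr <- as.array(img)
  d <- dim(arr)
  ok <- src[, 1] >= 1 & src[, 1] <= d[1] & src[, 2] >= 1 & src[, 2] <= d[2] &
    src[, 3] >= 1 & src[, 3] <= d[3]
  vals <- numeric(nrow(src))
  vals[ok] <- arr[src[ok, , drop = FALSE]]
  array(vals > 0.5, dim = grid$dim)
}

#' Write a likelihood or label map as NIfTI-1
#'
#' @param values 3D array on the grid.
#' @param grid The \code{ale_grid} the values live on.
#' @param path Output path (.nii or .nii.gz).
#' @export
write_map_nifti <- function(values, grid, path) {
  img <- RNifti::asNifti(array(as.numeric(values), dim = grid$dim))
  RNifti::qform(img) <- structure(grid$affine, code = 2L)
  RNifti::sform(img) <- structure(grid$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}
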