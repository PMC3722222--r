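#' Voxel grid of a common volume space
#'
#' A `volume_grid` describes the sampling lattice shared by all volumes in an
#' analysis: the number of voxels per axis and the affine matrix mapping
#' 0-based voxel indices (voxel centres) to world coordinates in millimetres.
#' Every mask, component map and atlas in the package carries its grid, and
#' operations refuse to combine objects whose grids differ.
#'
#' @param shape Integer vector of length 3, voxels per axis (each >= 1).
#' @param affine 4x4 invertible matrix mapping 0-based voxel indices to world
#'   millimetre coordinates. Defaults to an identity (1 mm isotropic) affine.
#' @return An object of class `volume_grid` with fields `shape`, `affine` and
#'   `voxel_size` (mm per axis, derived from the affine columns).
#' @examples
#' g <- volume_grid(c(16, 16, 4))
#' g$voxel_size
#' @export
volume_grid <- function(shape, affine = NULL) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(!is.finite(shape)) || any(shape < 1L)) {
    stop_validation("grid shape must be three integers >= 1")
  }
  if (is.null(affine)) affine <- diag(4)
  affine <- unname(as.matrix(affine))
  if (!all(dim(affine) == c(4L, 4L)) || any(!is.finite(affine))) {
    stop_validation("affine must be a finite 4x4 matrix")
  }
  det_a <- det(affine)
  if (!is.finite(det_a) || abs(det_a) < 1e-12) {
    stop_validation("affine must be invertible")
  }
  voxel_size <- sqrt(colSums(affine[1:3, 1:3, drop = FALSE]^2))
  structure(
    list(shape = shape, affine = affine, voxel_size = voxel_size),
    class = "volume_grid"
  )
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid %s, voxel size %s mm>\n",
              paste(x$shape, collapse = "x"),
              paste(signif(x$voxel_size, 4), collapse = "x")))
  invisible(x)
}

#' @export
format.volume_grid <- function(x, ...) {
  paste(x$shape, collapse = "x")
}

grids_equal <- function(a, b, tol = 1e-6) {
  identical(a$shape, b$shape) && max(abs(a$affine - b$affine)) <= tol
}

check_same_grid <- function(a, b, what = "objects") {
  if (!grids_equal(a, b)) {
    stop_validation("%s are defined on different grids (%s vs %s)",
                    what, format(a), format(b))
  }
  invisible(TRUE)
}

#' Map world coordinates to 0-based voxel indices
#'
#' Applies the inverse affine and rounds half up per axis, so a world point is
#' attributed to the voxel whose centre is nearest. Points may fall outside
#' the grid; see `voxel_in_grid()`.
#'
#' @param grid A [volume_grid()].
#' @param points Numeric matrix with 3 columns (world mm), or a length-3
#'   vector.
#' @return Integer matrix of 0-based voxel indices, one row per point.
#' @export
world_to_voxel <- function(grid, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3L)
  stopifnot(ncol(points) == 3L)
  inv <- solve(grid$affine)
  h <- cbind(points, 1) %*% t(inv)
  ## round half up: floor(x + 0.5), the package's stated containment rule
  idx <- floor(h[, 1:3, drop = FALSE] + 0.5)
  storage.mode(idx) <- "integer"
  idx
}

#' Map 0-based voxel indices to world coordinates (voxel centres)
#' @param grid A [volume_grid()].
#' @param idx Integer matrix of 0-based voxel indices (3 columns) or a
#'   length-3 vector.
#' @return Numeric matrix of world mm coordinates.
#' @export
voxel_to_world <- function(grid, idx) {
  if (is.null(dim(idx))) idx <- matrix(idx, ncol = 3L)
  h <- cbind(idx, 1) %*% t(grid$affine)
  h[, 1:3, drop = FALSE]
}

voxel_in_grid <- function(grid, idx) {
  idx[, 1] >= 0L & idx[, 1] < grid$shape[1] &
    idx[, 2] >= 0L & idx[, 2] < grid$shape[2] &
    idx[, 3] >= 0L & idx[, 3] < grid$shape[3]
}
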