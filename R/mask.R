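#' Binary voxel mask
#'
#' A boolean footprint over a [volume_grid()]: the in-brain mask, a
#' thresholded network map, an atlas parcel, or a ring-family union.
#'
#' @param grid A [volume_grid()].
#' @param values Logical array matching `grid$shape` (numeric arrays are
#'   binarised as `!= 0`).
#' @return An object of class `binary_mask` with fields `grid` and `values`.
#' @export
binary_mask <- function(grid, values) {
  if (!inherits(grid, "volume_grid")) stop_validation("grid must be a volume_grid")
  if (is.numeric(values)) {
    if (any(!is.finite(values))) stop_validation("mask values must be finite")
    values <- values != 0
  }
  values <- as.logical(values)
  if (anyNA(values)) stop_validation("mask values must not contain NA")
  if (length(values) != prod(grid$shape)) {
    stop_validation("mask has %d values but grid %s has %d voxels",
                    length(values), format(grid), prod(grid$shape))
  }
  dim(values) <- grid$shape
  structure(list(grid = grid, values = values), class = "binary_mask")
}

#' Number of true voxels in a mask
#' @param mask A [binary_mask()].
#' @return Integer count.
#' @export
mask_size <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  sum(mask$values)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask %s, %d true voxels>\n", format(x$grid), mask_size(x)))
  invisible(x)
}

mask_union <- function(masks) {
  stopifnot(length(masks) >= 1L)
  grid <- masks[[1]]$grid
  v <- masks[[1]]$values
  for (m in masks[-1]) {
    check_same_grid(grid, m$grid, "masks")
    v <- v | m$values
  }
  binary_mask(grid, v)
}

## Shift a logical array by (dx, dy, dz); voxels shifted in from outside are
## FALSE.  Used for dilation-style adjacency tests.
shift_array <- function(vals, dx, dy, dz) {
  d <- dim(vals)
  out <- array(FALSE, d)
  x0 <- max(1, 1 + dx); x1 <- min(d[1], d[1] + dx)
  y0 <- max(1, 1 + dy); y1 <- min(d[2], d[2] + dy)
  z0 <- max(1, 1 + dz); z1 <- min(d[3], d[3] + dz)
  if (x0 > x1 || y0 > y1 || z0 > z1) return(out)
  xs <- x0:x1; ys <- y0:y1; zs <- z0:z1
  out[xs, ys, zs] <- vals[xs - dx, ys - dy, zs - dz, drop = FALSE]
  out
}

connectivity_offsets <- function(connectivity) {
  if (!connectivity %in% c(6, 26)) {
    stop_validation("connectivity must be 6 or 26, got %s", connectivity)
  }
  off <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  off <- off[!(off$dx == 0 & off$dy == 0 & off$dz == 0), ]
  if (connectivity == 6) {
    off <- off[abs(off$dx) + abs(off$dy) + abs(off$dz) == 1, ]
  }
  as.matrix(off)
}

## One-step dilation of a logical array under the given connectivity.
dilate_array <- function(vals, connectivity = 6) {
  off <- connectivity_offsets(connectivity)
  out <- vals
  for (i in seq_len(nrow(off))) {
    out <- out | shift_array(vals, off[i, 1], off[i, 2], off[i, 3])
  }
  out
}

## Label connected components of a logical array by iterative frontier
## expansion.  Returns an integer array (0 = background) plus the count.
label_components <- function(vals, connectivity = 6) {
  off <- connectivity_offsets(connectivity)
  labels <- array(0L, dim(vals))
  remaining <- vals
  n <- 0L
  while (any(remaining)) {
    n <- n + 1L
    seed <- array(FALSE, dim(vals))
    seed[which(remaining)[1]] <- TRUE
    comp <- seed
    repeat {
      grown <- comp
      for (i in seq_len(nrow(off))) {
        grown <- grown | (shift_array(comp, off[i, 1], off[i, 2], off[i, 3]) & remaining)
      }
      if (identical(grown, comp)) break
      comp <- grown
    }
    labels[comp] <- n
    remaining <- remaining & !comp
  }
  list(labels = labels, n = n)
}

## TRUE if any voxel of mask a is adjacent (or identical) to a voxel of b.
masks_adjacent <- function(a, b, connectivity = 6) {
  check_same_grid(a$grid, b$grid, "masks")
  if (any(a$values & b$values)) return(TRUE)
  any(dilate_array(a$values, connectivity) & b$values)
}

#' Mirror a mask about the mid-plane of one axis
#'
#' Reflects voxel indices about the grid mid-plane (index i becomes
#' n + 1 - i along the chosen axis). Used for hemispheric-symmetry scoring.
#'
#' @param mask A [binary_mask()].
#' @param axis Axis index, 1 (x), 2 (y) or 3 (z).
#' @return The mirrored [binary_mask()].
#' @export
mirror_mask <- function(mask, axis = 1L) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!axis %in% 1:3) stop_validation("midline axis must be 1, 2 or 3")
  v <- mask$values
  idx <- rep(list(quote(expr = )), 3)
  idx[[axis]] <- rev(seq_len(dim(v)[axis]))
  out <- do.call(`[`, c(list(v), idx, list(drop = FALSE)))
  binary_mask(mask$grid, out)
}

dice_coefficient <- function(a, b) {
  check_same_grid(a$grid, b$grid, "masks")
  na <- mask_size(a)
  nb <- mask_size(b)
  if (na + nb == 0L) return(NaN)
  2 * sum(a$values & b$values) / (na + nb)
}
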