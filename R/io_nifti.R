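#' Read a NIfTI volume
#'
#' Reads a 3D or 4D NIfTI-1 volume and returns the data together with its
#' [volume_grid()] (shape and voxel-to-world affine). 4D data are ordered
#' (x, y, z, t).
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A list with elements `grid` ([volume_grid()]) and `data` (numeric
#'   3D or 4D array).
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop_format("cannot read volume, no such file: %s", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) {
                    stop_format("failed to read volume '%s': %s", path, conditionMessage(e))
                  })
  data <- as.array(img)
  attributes(data) <- list(dim = dim(data))
  if (!length(dim(data)) %in% c(3L, 4L)) {
    stop_format("volume '%s' is %dD; expected 3D or 4D", path, length(dim(data)))
  }
  if (any(!is.finite(data))) {
    stop_validation("volume '%s' contains non-finite voxels", path)
  }
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = dim(aff))
  grid <- volume_grid(dim(data)[1:3], aff)
  list(grid = grid, data = data)
}

#' Write a NIfTI volume
#'
#' Data are written at double precision so that write/read round-trips are
#' bitwise exact.
#'
#' @param grid A [volume_grid()].
#' @param data Numeric 3D or 4D array whose first three dimensions match the
#'   grid shape.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(grid, data, path) {
  data <- as.array(data)
  if (!length(dim(data)) %in% c(3L, 4L) || !all(dim(data)[1:3] == grid$shape)) {
    stop_validation("data dimensions %s do not match grid %s",
                    paste(dim(data), collapse = "x"), format(grid))
  }
  storage.mode(data) <- "double"
  img <- RNifti::asNifti(data)
  aff <- structure(grid$affine, code = 2L)
  img <- RNifti::`sform<-`(img, value = aff)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read a binary mask from a NIfTI volume
#' @param path Path to a 3D NIfTI file; non-zero voxels become TRUE.
#' @return A [binary_mask()].
#' @export
read_mask <- function(path) {
  vol <- read_volume(path)
  if (length(dim(vol$data)) != 3L) stop_format("mask '%s' must be 3D", path)
  binary_mask(vol$grid, vol$data != 0)
}

#' Write a binary mask as a NIfTI volume (1 = true, 0 = false)
#' @param mask A [binary_mask()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  write_volume(mask$grid, array(as.double(mask$values), mask$grid$shape), path)
}
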