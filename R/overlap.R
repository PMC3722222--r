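#' Overlap-count matrix between network masks and a reference atlas
#'
#' Integer matrix of shared-voxel counts: rows are network (RSN) labels,
#' columns are reference unit names (TBNs, Brodmann areas, or Brodmann-area
#' families). Shared voxels are the unit the analysis works in throughout;
#' row-normalised variants are available via [normalize_overlap()] but are
#' never used by the clustering defaults.
#'
#' @param counts Non-negative integer matrix with row and column names.
#' @return An object of class `overlap_matrix` (an integer matrix).
#' @export
overlap_matrix <- function(counts) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop_validation("overlap matrix must have row and column names")
  }
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != floor(counts))) {
    stop_validation("overlap counts must be non-negative integers")
  }
  storage.mode(counts) <- "integer"
  structure(counts, class = c("overlap_matrix", "matrix", "array"))
}

#' @export
print.overlap_matrix <- function(x, ...) {
  cat(sprintf("<overlap_matrix %d networks x %d units>\n", nrow(x), ncol(x)))
  print(unclass(x), ...)
  invisible(x)
}

#' Count voxels shared by two masks
#' @param a,b [binary_mask()] objects on the same grid.
#' @return Integer count of voxels true in both.
#' @export
shared_voxels <- function(a, b) {
  stopifnot(inherits(a, "binary_mask"), inherits(b, "binary_mask"))
  check_same_grid(a$grid, b$grid, "masks")
  sum(a$values & b$values)
}

#' Build the full network-by-reference overlap matrix
#'
#' @param rsns Ranked list of [rsn_class()] objects (or a named list of
#'   [binary_mask()]s); row order is preserved.
#' @param atlas A [reference_atlas()]; column order follows the atlas units.
#' @return An [overlap_matrix()].
#' @export
build_overlap_matrix <- function(rsns, atlas) {
  if (length(rsns) < 1L) stop_validation("no networks supplied")
  if (!inherits(atlas, "reference_atlas") || atlas_n_units(atlas) < 1L) {
    stop_validation("atlas must be a non-empty reference_atlas")
  }
  masks <- lapply(rsns, function(r) {
    if (inherits(r, "rsn_class")) r$mask else r
  })
  row_labels <- names(rsns) %||% vapply(rsns, function(r) {
    if (inherits(r, "rsn_class")) as.character(r$rank) else NA_character_
  }, "")
  if (anyNA(row_labels)) stop_validation("network masks must be named or ranked")
  for (m in masks) check_same_grid(m$grid, atlas$grid, "network and atlas")
  ## stack footprints and use one crossprod instead of a voxel loop
  A <- vapply(masks, function(m) as.double(m$values), numeric(prod(atlas$grid$shape)))
  B <- vapply(atlas$units, function(u) as.double(u$values), numeric(prod(atlas$grid$shape)))
  counts <- crossprod(A, B)
  dimnames(counts) <- list(row_labels, names(atlas$units))
  overlap_matrix(counts)
}

#' Row-normalise an overlap matrix
#' @param x An [overlap_matrix()].
#' @return Numeric matrix of row proportions (rows summing to 1; all-zero
#'   rows stay zero).
#' @export
normalize_overlap <- function(x) {
  stopifnot(inherits(x, "overlap_matrix"))
  m <- unclass(x)
  storage.mode(m) <- "double"
  rs <- rowSums(m)
  rs[rs == 0] <- 1
  sweep(m, 1, rs, "/")
}

#' Write an overlap matrix as TSV with row and column headers
#' @param x An [overlap_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_overlap_matrix <- function(x, path) {
  stopifnot(inherits(x, "overlap_matrix"))
  df <- data.frame(label = rownames(x), unclass(x), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an overlap matrix written by [write_overlap_matrix()]
#' @param path TSV path.
#' @return An [overlap_matrix()].
#' @export
read_overlap_matrix <- function(path) {
  if (!file.exists(path)) stop_format("no such file: %s", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          colClasses = NA, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  overlap_matrix(m)
}
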