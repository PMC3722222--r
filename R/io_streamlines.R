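#' Tractography streamline
#'
#' An ordered 3D polyline in world millimetre coordinates.
#'
#' @param points Numeric matrix with 3 columns and at least 2 rows; finite,
#'   with consecutive points distinct.
#' @return An object of class `streamline` (the point matrix).
#' @export
streamline <- function(points) {
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop_validation("streamline points must have 3 columns")
  if (nrow(points) < 2L) stop_validation("streamline must have at least 2 points")
  if (any(!is.finite(points))) stop_validation("streamline coordinates must be finite")
  steps <- diff(points)
  if (any(rowSums(abs(steps)) == 0)) {
    stop_validation("consecutive streamline points must be distinct")
  }
  structure(points, class = "streamline")
}

#' @export
print.streamline <- function(x, ...) {
  cat(sprintf("<streamline, %d points, %.1f mm>\n", nrow(x),
              sum(sqrt(rowSums(diff(unclass(x))^2)))))
  invisible(x)
}

streamline_format <- function(path) {
  if (grepl("\\.trk$", path, ignore.case = TRUE)) "trk" else "text"
}

#' Read streamlines from TRK or plain polyline text
#'
#' TrackVis `.trk` files store points in voxel-mm coordinates; on read they
#' are converted to world millimetres through the header's voxel-to-world
#' affine (voxel index = point / voxel size - 1/2, then the affine), so
#' downstream code sees a single coordinate convention. Any other extension
#' is parsed as whitespace-delimited text: one point per line, already in
#' world mm, blank lines separating streamlines.
#'
#' Streamlines with fewer than 2 points are dropped with a warning.
#'
#' @param path Input file.
#' @return List of [streamline()] objects (possibly empty).
#' @export
read_streamlines <- function(path) {
  if (!file.exists(path)) stop_format("cannot read streamlines, no such file: %s", path)
  raw_lists <- switch(streamline_format(path),
                      trk = read_trk_points(path),
                      text = read_polyline_text(path))
  short <- vapply(raw_lists, nrow, 1L) < 2L
  if (any(short)) {
    warning(sprintf("dropped %d streamline(s) with fewer than 2 points", sum(short)))
    raw_lists <- raw_lists[!short]
  }
  lapply(raw_lists, streamline)
}

read_polyline_text <- function(path) {
  lines <- readLines(path)
  out <- list()
  cur <- list()
  flush <- function() {
    if (length(cur) > 0L) out[[length(out) + 1L]] <<- do.call(rbind, cur)
    cur <<- list()
  }
  for (ln in lines) {
    if (!nzchar(trimws(ln))) {
      flush()
    } else {
      vals <- suppressWarnings(as.numeric(strsplit(trimws(ln), "[[:space:]]+")[[1]]))
      if (length(vals) != 3L || anyNA(vals)) {
        stop_format("bad polyline line in '%s': %s", path, ln)
      }
      cur[[length(cur) + 1L]] <- vals
    }
  }
  flush()
  out
}

## TRK header layout (TrackVis format, version 2), 1000 bytes.
read_trk_points <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  id <- readBin(con, "raw", 6L)
  if (!identical(rawToChar(id[1:5]), "TRACK")) {
    stop_format("'%s' is not a TRK file", path)
  }
  dim3 <- readBin(con, "integer", 3L, size = 2L)
  voxel_size <- readBin(con, "double", 3L, size = 4L)
  readBin(con, "double", 3L, size = 4L)           # origin, unused by TrackVis
  n_scalars <- readBin(con, "integer", 1L, size = 2L)
  readBin(con, "raw", 200L)                        # scalar names
  n_properties <- readBin(con, "integer", 1L, size = 2L)
  readBin(con, "raw", 200L)                        # property names
  vox_to_ras <- matrix(readBin(con, "double", 16L, size = 4L), 4L, 4L, byrow = TRUE)
  readBin(con, "raw", 444L + 4L + 4L + 24L + 2L + 6L)  # reserved .. padding
  n_count <- readBin(con, "integer", 1L, size = 4L)
  version <- readBin(con, "integer", 1L, size = 4L)
  hdr_size <- readBin(con, "integer", 1L, size = 4L)
  if (!is.finite(hdr_size) || hdr_size != 1000L) {
    stop_format("'%s' has TRK header size %s, expected 1000", path, hdr_size)
  }
  if (all(vox_to_ras == 0)) {
    warning("TRK file has no voxel-to-world transform; assuming identity")
    vox_to_ras <- diag(4)
    vox_to_ras[cbind(1:3, 1:3)] <- voxel_size
  }
  if (any(voxel_size <= 0)) voxel_size <- rep(1, 3)
  out <- list()
  repeat {
    npts <- readBin(con, "integer", 1L, size = 4L)
    if (length(npts) == 0L) break
    vals <- readBin(con, "double", npts * (3L + n_scalars), size = 4L)
    if (n_properties > 0L) readBin(con, "double", n_properties, size = 4L)
    pts <- matrix(vals, ncol = 3L + n_scalars, byrow = TRUE)[, 1:3, drop = FALSE]
    ## voxmm -> voxel index -> world
    vox <- sweep(pts, 2, voxel_size, "/") - 0.5
    world <- cbind(vox, 1) %*% t(vox_to_ras)
    out[[length(out) + 1L]] <- world[, 1:3, drop = FALSE]
  }
  if (version >= 2L && is.finite(n_count) && n_count > 0L && length(out) != n_count) {
    warning(sprintf("TRK header declares %d streamlines, found %d", n_count, length(out)))
  }
  out
}

#' Write streamlines to TRK or plain polyline text
#'
#' The inverse of [read_streamlines()]: world-mm points are converted to
#' TrackVis voxel-mm coordinates through `grid` for `.trk` output; text
#' output keeps world mm.
#'
#' @param lines List of [streamline()] objects.
#' @param path Output file; extension selects the format.
#' @param grid [volume_grid()] providing the voxel-to-world transform
#'   (required for `.trk`).
#' @return `path`, invisibly.
#' @export
write_streamlines <- function(lines, path, grid = NULL) {
  stopifnot(is.list(lines))
  if (streamline_format(path) == "text") {
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_along(lines)) {
      pts <- unclass(lines[[i]])
      writeLines(apply(pts, 1, function(p) paste(format(p, digits = 10), collapse = " ")), con)
      if (i < length(lines)) writeLines("", con)
    }
    return(invisible(path))
  }
  if (is.null(grid)) stop_validation("writing TRK requires a volume_grid")
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("TRACK", con, nchars = 5L, eos = NULL)
  writeBin(as.raw(0L), con)
  writeBin(as.integer(grid$shape), con, size = 2L)
  writeBin(as.double(grid$voxel_size), con, size = 4L)
  writeBin(rep(0, 3), con, size = 4L)              # origin
  writeBin(0L, con, size = 2L)                      # n_scalars
  writeBin(raw(200L), con)
  writeBin(0L, con, size = 2L)                      # n_properties
  writeBin(raw(200L), con)
  writeBin(as.double(t(grid$affine)), con, size = 4L)
  writeBin(raw(444L), con)                          # reserved
  writeChar("LPS", con, nchars = 3L, eos = NULL); writeBin(as.raw(0L), con)
  writeBin(raw(4L), con)                            # pad2
  writeBin(rep(0, 6), con, size = 4L)               # image_orientation_patient
  writeBin(raw(2L), con)                            # pad1
  writeBin(raw(6L), con)                            # invert/swap flags
  writeBin(length(lines), con, size = 4L)
  writeBin(2L, con, size = 4L)                      # version
  writeBin(1000L, con, size = 4L)
  inv <- solve(grid$affine)
  for (sl in lines) {
    pts <- unclass(sl)
    vox <- cbind(pts, 1) %*% t(inv)
    voxmm <- sweep(vox[, 1:3, drop = FALSE] + 0.5, 2, grid$voxel_size, "*")
    writeBin(nrow(pts), con, size = 4L)
    writeBin(as.double(t(voxmm)), con, size = 4L)
  }
  invisible(path)
}
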