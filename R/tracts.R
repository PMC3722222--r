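#' Filter streamlines by a ring mask
#'
#' Keeps the streamlines whose termini fall inside the mask: a world-mm
#' endpoint lies in a voxel when its nearest voxel centre (inverse affine,
#' rounding half up per axis) is a true in-grid voxel. Only the first and
#' last point of each streamline are tested, so the result is independent of
#' the point density along the path; input order is preserved.
#'
#' @param lines List of [streamline()] objects.
#' @param mask [binary_mask()] defining the ROI.
#' @param mode `"both-endpoints"` (default; both termini inside — fibres
#'   that end within the ring) or `"either-endpoint"`.
#' @return List with `kept` (the retained streamlines), and `summary`
#'   (list: `n_input`, `n_kept`, `mode`).
#' @export
filter_streamlines <- function(lines, mask, mode = c("both-endpoints", "either-endpoint")) {
  mode <- match.arg(mode)
  stopifnot(inherits(mask, "binary_mask"))
  sh <- mask$grid$shape
  inside <- function(p) {
    idx <- world_to_voxel(mask$grid, p)
    ok <- voxel_in_grid(mask$grid, idx)
    res <- logical(nrow(idx))
    if (any(ok)) {
      lin <- idx[ok, 1] + 1L + sh[1] * (idx[ok, 2] + idx[ok, 3] * sh[2])
      res[ok] <- mask$values[lin]
    }
    res
  }
  keep <- vapply(lines, function(sl) {
    pts <- unclass(sl)
    ends <- inside(pts[c(1L, nrow(pts)), , drop = FALSE])
    if (mode == "both-endpoints") all(ends) else any(ends)
  }, logical(1))
  list(kept = lines[keep],
       summary = list(n_input = length(lines), n_kept = sum(keep), mode = mode))
}
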