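#' Named reference mask set (atlas)
#'
#' An ordered collection of named [binary_mask()] units sharing one grid:
#' a task-based-network mask set, a Brodmann label atlas, or a phantom
#' parcellation. Units may overlap (TBN-style) or partition the volume
#' (label-atlas style); no partition is assumed.
#'
#' @param grid A [volume_grid()].
#' @param units Named list of [binary_mask()] objects, all on `grid`, with
#'   unique names.
#' @return An object of class `reference_atlas`.
#' @export
reference_atlas <- function(grid, units) {
  if (!inherits(grid, "volume_grid")) stop_validation("grid must be a volume_grid")
  if (length(units) < 1L) stop_validation("atlas must contain at least one unit")
  nm <- names(units)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm)) {
    stop_validation("atlas units must have unique non-empty names")
  }
  for (u in units) {
    if (!inherits(u, "binary_mask")) stop_validation("atlas units must be binary masks")
    check_same_grid(grid, u$grid, "atlas units")
  }
  structure(list(grid = grid, units = units), class = "reference_atlas")
}

#' @export
print.reference_atlas <- function(x, ...) {
  cat(sprintf("<reference_atlas %s, %d units: %s%s>\n",
              format(x$grid), length(x$units),
              paste(utils::head(names(x$units), 6), collapse = ", "),
              if (length(x$units) > 6) ", ..." else ""))
  invisible(x)
}

#' Number of units in an atlas
#' @param atlas A [reference_atlas()].
#' @return Integer count.
#' @export
atlas_n_units <- function(atlas) length(atlas$units)

#' Convert an atlas to an integer label volume
#'
#' Units are written in order; later units overwrite earlier ones where they
#' overlap, so the conversion is lossless only for disjoint unit sets.
#'
#' @param atlas A [reference_atlas()].
#' @return Integer array over the grid; 0 is background, unit i has label i.
#' @export
atlas_label_array <- function(atlas) {
  lab <- array(0L, atlas$grid$shape)
  for (i in seq_along(atlas$units)) {
    lab[atlas$units[[i]]$values] <- i
  }
  lab
}

#' Build an atlas from an integer label volume and a name map
#' @param grid A [volume_grid()].
#' @param labels Integer array over the grid (0 = background).
#' @param names Character vector: `names[i]` names label value i.
#' @return A [reference_atlas()].
#' @export
atlas_from_labels <- function(grid, labels, names) {
  labels <- as.integer(labels)
  dim(labels) <- grid$shape
  ids <- sort(unique(labels[labels > 0L]))
  if (length(names) < max(ids, 0L)) {
    stop_validation("label volume uses label %d but only %d names supplied",
                    max(ids), length(names))
  }
  units <- lapply(ids, function(i) binary_mask(grid, labels == i))
  names(units) <- names[ids]
  reference_atlas(grid, units)
}

#' Write an atlas as a NIfTI label volume plus a JSON name map
#' @param atlas A [reference_atlas()].
#' @param path Path of the NIfTI file to write; the name map is written next
#'   to it with extension `.labels.json`.
#' @return `path`, invisibly.
#' @export
write_atlas <- function(atlas, path) {
  write_volume(atlas$grid, atlas_label_array(atlas), path)
  jsonlite::write_json(
    as.list(stats::setNames(seq_along(atlas$units), names(atlas$units))),
    sub("\\.nii(\\.gz)?$", "", path, ignore.case = TRUE) |> paste0(".labels.json"),
    auto_unbox = TRUE
  )
  invisible(path)
}

#' Read an atlas written by [write_atlas()]
#' @param path Path of the NIfTI label volume.
#' @return A [reference_atlas()].
#' @export
read_atlas <- function(path) {
  vol <- read_volume(path)
  json <- paste0(sub("\\.nii(\\.gz)?$", "", path, ignore.case = TRUE), ".labels.json")
  if (!file.exists(json)) stop_format("atlas name map not found: %s", json)
  nm <- jsonlite::read_json(json)
  ord <- order(unlist(nm))
  atlas_from_labels(vol$grid, vol$data, names(nm)[ord])
}
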