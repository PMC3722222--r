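#' Assign networks to the VSA / PTF families
#'
#' Combines two or more clusterings of the same networks (e.g. one from the
#' task-based-network overlap matrix and one or two from the Brodmann
#' matrices). Within each clustering, a cluster is labelled VSA when the
#' majority of its rows' overlap mass falls on sensory-flagged reference
#' units (visual / somatomotor / auditory), PTF otherwise. A network is
#' `intermediate` when the clusterings disagree about its family, or when
#' its own overlap mass is balanced: its per-row family-mass difference
#' |sensory - association| / total falls below `margin` in some matrix.
#'
#' The per-network balance score is that minimum mass difference (0 when
#' the clusterings disagree), so `intermediate` is exactly `balance < margin`.
#'
#' @param clusterings Named list of [clustering_result()] objects over the
#'   same row labels.
#' @param matrices Named list of [overlap_matrix()] objects, parallel to
#'   `clusterings` (same names, same row labels).
#' @param sensory_units Named list (parallel to `matrices`) of character
#'   vectors: the column names flagged as sensorimotor reference units.
#' @param margin Balance margin in (0, 1); default 0.30.
#' @return An object of class `family_model`: list with `family_of_cluster`
#'   (per clustering), `rsn_family` (VSA / PTF / intermediate per network),
#'   and `balance_scores`.
#' @export
assign_families <- function(clusterings, matrices, sensory_units, margin = 0.30) {
  if (length(clusterings) < 2L) stop_validation("need at least two clusterings")
  if (!identical(names(clusterings), names(matrices)) ||
      !identical(names(clusterings), names(sensory_units))) {
    stop_validation("clusterings, matrices and sensory_units must share names")
  }
  labs <- names(clusterings[[1]]$assignment)
  for (cl in clusterings) {
    if (!setequal(names(cl$assignment), labs)) {
      stop_validation("clusterings cover different network sets")
    }
  }
  fam_of_cluster <- list()
  fam_by_matrix <- matrix("", length(labs), length(clusterings),
                          dimnames = list(labs, names(clusterings)))
  balance_by_matrix <- matrix(NA_real_, length(labs), length(clusterings),
                              dimnames = list(labs, names(clusterings)))
  for (nm in names(clusterings)) {
    M <- unclass(matrices[[nm]])
    storage.mode(M) <- "double"
    if (!setequal(rownames(M), labs)) {
      stop_validation("matrix '%s' rows do not match the clustering", nm)
    }
    M <- M[labs, , drop = FALSE]
    sens <- colnames(M) %in% sensory_units[[nm]]
    if (!any(sens) && length(sensory_units[[nm]]) > 0L) {
      stop_validation("sensory units of '%s' match no matrix column", nm)
    }
    asg <- clusterings[[nm]]$assignment[labs]
    row_sens <- rowSums(M[, sens, drop = FALSE])
    row_tot <- rowSums(M)
    fams <- character(max(asg))
    for (c in seq_len(max(asg))) {
      rows <- asg == c
      if (!any(rows)) next
      frac <- sum(row_sens[rows]) / max(sum(row_tot[rows]), 1e-12)
      fams[c] <- if (frac > 0.5) "VSA" else "PTF"
    }
    fam_of_cluster[[nm]] <- fams
    fam_by_matrix[, nm] <- fams[asg]
    balance_by_matrix[, nm] <- abs(2 * row_sens / pmax(row_tot, 1e-12) - 1)
  }
  discordant <- apply(fam_by_matrix, 1, function(f) length(unique(f)) > 1L)
  balance <- pmin(apply(balance_by_matrix, 1, min), ifelse(discordant, 0, 1))
  family <- ifelse(balance < margin, "intermediate", fam_by_matrix[, 1])
  structure(list(family_of_cluster = fam_of_cluster,
                 rsn_family = stats::setNames(family, labs),
                 balance_scores = stats::setNames(balance, labs),
                 margin = margin,
                 family_by_matrix = fam_by_matrix),
            class = "family_model")
}

#' @export
print.family_model <- function(x, ...) {
  tab <- table(x$rsn_family)
  cat(sprintf("<family_model: %s>\n",
              paste(sprintf("%s = %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Count connected components of a mask footprint
#'
#' @param mask Non-empty [binary_mask()].
#' @param connectivity 6 (face adjacency, default) or 26.
#' @return Integer component count.
#' @export
footprint_continuity <- function(mask, connectivity = 6) {
  stopifnot(inherits(mask, "binary_mask"))
  if (mask_size(mask) == 0L) stop_validation("mask is empty")
  label_components(mask$values, connectivity)$n
}

#' Test whether a VSA mask encloses an island within a domain
#'
#' Flood-fills the complement of `vsa` inside `domain` (6-connectivity)
#' starting from the island; the island is enclosed exactly when its
#' component never reaches the domain boundary. A boundary voxel is a domain
#' voxel with an in-grid 6-neighbour outside the domain — the grid's edge
#' itself acts as a wall, so the domain must include a surround strictly
#' inside the grid for escapes to be detectable.
#'
#' @param vsa [binary_mask()] of the candidate enclosing ring.
#' @param island Non-empty [binary_mask()] disjoint from `vsa`.
#' @param domain [binary_mask()] within which filling happens; must contain
#'   the island.
#' @return TRUE if enclosed, FALSE otherwise.
#' @export
enclosure_test <- function(vsa, island, domain) {
  check_same_grid(vsa$grid, island$grid, "masks")
  check_same_grid(vsa$grid, domain$grid, "masks")
  if (any(island$values & vsa$values)) {
    stop_validation("island overlaps the enclosing mask")
  }
  if (!all(island$values <= domain$values)) {
    stop_validation("island must lie inside the domain")
  }
  if (mask_size(island) == 0L) stop_validation("island is empty")
  free <- domain$values & !vsa$values
  ## component of the free space containing the island
  comp <- island$values & free
  if (!any(comp)) stop_validation("island lies entirely on excluded voxels")
  repeat {
    grown <- comp | (dilate_array(comp, 6) & free)
    if (identical(grown, comp)) break
    comp <- grown
  }
  boundary <- domain$values & dilate_array(!domain$values, 6)
  !any(comp & boundary)
}

#' Hemispheric symmetry score of a mask
#'
#' Dice coefficient between the mask and its mirror image about the grid
#' mid-plane of the chosen axis: 1 for a perfectly mirror-symmetric
#' footprint, 0 for one entirely within one half with no homotopic overlap.
#'
#' @param mask Non-empty [binary_mask()].
#' @param midline_axis Axis index (1 = x, the left-right axis by default).
#' @return Dice in \[0, 1\].
#' @export
symmetry_score <- function(mask, midline_axis = 1L) {
  stopifnot(inherits(mask, "binary_mask"))
  if (mask_size(mask) == 0L) stop_validation("mask is empty")
  dice_coefficient(mask, mirror_mask(mask, midline_axis))
}

#' Verify that ordered sectors close into a ring
#'
#' Returns the sector ordering when every consecutive pair — including last
#' back to first — is voxel-adjacent under the chosen connectivity, and the
#' cycle has at least 3 sectors; otherwise an empty character vector.
#'
#' @param family_masks Named list of pairwise-disjoint [binary_mask()]
#'   sectors, in candidate cycle order.
#' @param connectivity 6 (default) or 26.
#' @return Character vector of sector names (the cycle) or `character(0)`.
#' @export
sector_cycle <- function(family_masks, connectivity = 6) {
  n <- length(family_masks)
  if (n < 1L) stop_validation("no sectors supplied")
  nm <- names(family_masks) %||% as.character(seq_len(n))
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (shared_voxels(family_masks[[i]], family_masks[[j]]) > 0L) {
        stop_validation("sectors '%s' and '%s' overlap", nm[i], nm[j])
      }
    }
  }
  if (n < 3L) return(character(0))
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    if (!masks_adjacent(family_masks[[i]], family_masks[[j]], connectivity)) {
      return(character(0))
    }
  }
  nm
}

#' Full topological report for a family pair
#'
#' Computes the headline ring diagnostics in one call: component counts of
#' the two family unions, island enclosure by the VSA union, the VSA sector
#' cycle, and per-family mirror-symmetry Dice.
#'
#' @param vsa_masks Named list of VSA sector masks in cycle order.
#' @param ptf_masks Named list of PTF masks (island first by convention).
#' @param island [binary_mask()] of the enclosed island (or NULL to skip).
#' @param domain [binary_mask()] for the enclosure test.
#' @param connectivity 6 or 26.
#' @param midline_axis Mirror axis for symmetry.
#' @return An object of class `ring_report`: list with `n_components_vsa`,
#'   `n_components_ptf`, `enclosure_found`, `sector_cycle`, `symmetry`
#'   (named Dice per family).
#' @export
ring_report <- function(vsa_masks, ptf_masks, island = NULL, domain = NULL,
                        connectivity = 6, midline_axis = 1L) {
  vsa_union <- mask_union(vsa_masks)
  ptf_union <- mask_union(ptf_masks)
  enclosed <- if (!is.null(island) && !is.null(domain)) {
    enclosure_test(vsa_union, island, domain)
  } else {
    NA
  }
  structure(list(
    n_components_vsa = footprint_continuity(vsa_union, connectivity),
    n_components_ptf = footprint_continuity(ptf_union, connectivity),
    enclosure_found = enclosed,
    sector_cycle = sector_cycle(vsa_masks, connectivity),
    symmetry = c(VSA = symmetry_score(vsa_union, midline_axis),
                 PTF = symmetry_score(ptf_union, midline_axis))
  ), class = "ring_report")
}

#' @export
print.ring_report <- function(x, ...) {
  cat(sprintf(paste0("<ring_report: VSA components %d, PTF components %d, ",
                     "enclosure %s, cycle %s, symmetry VSA %.2f / PTF %.2f>\n"),
              x$n_components_vsa, x$n_components_ptf,
              as.character(x$enclosure_found),
              if (length(x$sector_cycle)) paste(x$sector_cycle, collapse = ">") else "none",
              x$symmetry["VSA"], x$symmetry["PTF"]))
  invisible(x)
}
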