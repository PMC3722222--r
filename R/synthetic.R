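#' Planted-network specification for the subject simulator
#'
#' @param name Network name.
#' @param footprint Non-empty [binary_mask()]: the spatial support of the
#'   network.
#' @param prevalence Fraction of subjects (in \[0, 1\]) expressing the
#'   network; the planted analogue of class representativeness.
#' @param amplitude Positive signal scale (arbitrary units); with unit-variance
#'   time courses the per-voxel signal s.d. inside the footprint equals
#'   `amplitude`.
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(name, footprint, prevalence, amplitude = 1) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!inherits(footprint, "binary_mask") || mask_size(footprint) == 0L) {
    stop_validation("network footprint must be a non-empty binary_mask")
  }
  if (!is.numeric(prevalence) || prevalence < 0 || prevalence > 1) {
    stop_validation("prevalence must be in [0, 1]")
  }
  if (!is.numeric(amplitude) || amplitude <= 0) {
    stop_validation("amplitude must be positive")
  }
  structure(list(name = name, footprint = footprint,
                 prevalence = prevalence, amplitude = amplitude),
            class = "network_spec")
}

#' Cluster-membership table
#'
#' Holds a partition (or near-partition) of network labels into named
#' clusters. Labels listed in more than one cluster are kept and flagged as
#' duplicates, never silently dropped; [resolve_duplicates()] applies an
#' explicit resolution map.
#'
#' @param clusters Named list of character vectors of row labels.
#' @return An object of class `membership_table` with fields `rows` (unique
#'   labels, in first-appearance order), `clusters`, and `duplicates`.
#' @export
membership_table <- function(clusters) {
  if (length(clusters) < 1L || is.null(names(clusters))) {
    stop_validation("clusters must be a non-empty named list")
  }
  clusters <- lapply(clusters, as.character)
  all_rows <- unlist(clusters, use.names = FALSE)
  dup <- unique(all_rows[duplicated(all_rows)])
  structure(list(rows = unique(all_rows), clusters = clusters, duplicates = dup),
            class = "membership_table")
}

#' @export
print.membership_table <- function(x, ...) {
  cat(sprintf("<membership_table: %d rows in %d clusters%s>\n",
              length(x$rows), length(x$clusters),
              if (length(x$duplicates)) {
                paste0("; duplicated: ", paste(x$duplicates, collapse = ", "))
              } else ""))
  invisible(x)
}

#' Resolve duplicated rows of a membership table
#' @param table A [membership_table()].
#' @param map Named character vector: `map[label]` is the name of the cluster
#'   that keeps the label; it is removed from all others.
#' @return A duplicate-free [membership_table()].
#' @export
resolve_duplicates <- function(table, map) {
  stopifnot(inherits(table, "membership_table"))
  unresolved <- setdiff(table$duplicates, names(map))
  if (length(unresolved) > 0L) {
    stop_validation("duplicated rows without resolution: %s",
                    paste(unresolved, collapse = ", "))
  }
  cl <- table$clusters
  for (lab in names(map)) {
    keep <- as.character(map[[lab]])
    if (!keep %in% names(cl) || !lab %in% cl[[keep]]) {
      stop_validation("resolution map sends '%s' to cluster '%s' which does not list it",
                      lab, keep)
    }
    for (cn in setdiff(names(cl), keep)) cl[[cn]] <- setdiff(cl[[cn]], lab)
  }
  membership_table(cl)
}

#' Flat assignment vector of a membership table
#' @param table A duplicate-free [membership_table()].
#' @return Named character vector mapping row label to cluster name.
#' @export
membership_assignment <- function(table) {
  stopifnot(inherits(table, "membership_table"))
  if (length(table$duplicates) > 0L) {
    stop_validation("membership table has duplicated rows: %s",
                    paste(table$duplicates, collapse = ", "))
  }
  out <- character(0)
  for (cn in names(table$clusters)) {
    out[table$clusters[[cn]]] <- cn
  }
  out[table$rows]
}

#' Write / read a membership table as two-column TSV
#' @param table A [membership_table()].
#' @param path TSV path (`row`, `cluster` columns; duplicated rows appear once
#'   per listing cluster).
#' @return `path` (write) or a [membership_table()] (read).
#' @export
write_membership_table <- function(table, path) {
  df <- do.call(rbind, lapply(names(table$clusters), function(cn) {
    data.frame(row = table$clusters[[cn]], cluster = cn)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_membership_table
#' @export
read_membership_table <- function(path) {
  if (!file.exists(path)) stop_format("no such file: %s", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  cl <- split(df$row, df$cluster)
  ## keep cluster order of first appearance in the file, not alphabetical
  cl <- cl[unique(df$cluster)]
  membership_table(cl)
}

#' Generate a phantom parcellation with a ring-and-island layout
#'
#' Builds a toy cortical parcellation whose geometry mirrors the dual-ring
#' corticotopy the pipeline is designed to detect: six ring parcels forming a
#' closed cycle of pairwise face-adjacent sectors around a central island
#' parcel it does not touch, plus mutually non-adjacent scattered parcels
#' outside the ring. The layout is mirror-symmetric about the x mid-plane,
#' and a `domain` mask (the toy cortical sheet, inset from the grid edge so
#' escape can be detected) is attached for enclosure testing.
#'
#' @param grid A [volume_grid()]; in-plane extent at least 12x12.
#' @param layout List of layout parameters: `n_ring` (6, or 1 for the
#'   degenerate single whole-grid parcel), `thickness` (ring wall thickness,
#'   voxels, default 2), `n_scattered` (0, 2 or 4 corner parcels, default 4).
#' @param seed Integer seed (the layout is deterministic; the seed is part of
#'   the generator interface for forward compatibility).
#' @return A [reference_atlas()] with attribute `layout`: a list with
#'   `ring` (sector names in cycle order), `island`, `scattered`, `domain`
#'   ([binary_mask()]), and `families` (the planted VSA/PTF family of each
#'   unit).
#' @export
make_phantom_atlas <- function(grid, layout = list(), seed = 1L) {
  stopifnot(inherits(grid, "volume_grid"))
  n_ring <- layout$n_ring %||% 6L
  t <- layout$thickness %||% 2L
  n_scattered <- layout$n_scattered %||% 4L
  nx <- grid$shape[1]; ny <- grid$shape[2]; nz <- grid$shape[3]

  if (n_ring == 1L) {
    ## degenerate layout: one parcel covering the whole grid
    units <- list(whole = binary_mask(grid, array(TRUE, grid$shape)))
    atlas <- reference_atlas(grid, units)
    attr(atlas, "layout") <- list(ring = character(0), island = NULL,
                                  scattered = character(0),
                                  domain = units$whole,
                                  families = c(whole = "VSA"))
    return(atlas)
  }
  if (n_ring != 6L) stop_config("layout supports n_ring = 6 (or 1), got %s", n_ring)
  if (!n_scattered %in% c(0L, 2L, 4L)) {
    stop_config("n_scattered must be 0, 2 or 4, got %s", n_scattered)
  }
  x0 <- 2L; x1 <- nx - 3L; y0 <- 2L; y1 <- ny - 3L   # 0-based frame bounds
  if (nx < 12L || ny < 12L || x1 - x0 < 2 * t + 3 || y1 - y0 < 2 * t + 3) {
    stop_config("grid %s too small for a %d-sector ring of thickness %d",
                format(grid), n_ring, t)
  }
  midx <- (x0 + x1 - 1L) %/% 2L                        # split so mirror swaps halves

  in_box <- function(xa, xb, ya, yb) {
    v <- array(FALSE, grid$shape)
    v[(xa:xb) + 1L, (ya:yb) + 1L, seq_len(nz)] <- TRUE
    v
  }
  sectors <- list(
    W  = in_box(x0, x0 + t - 1L, y0 + t, y1 - t),
    NW = in_box(x0, midx, y1 - t + 1L, y1),
    NE = in_box(midx + 1L, x1, y1 - t + 1L, y1),
    E  = in_box(x1 - t + 1L, x1, y0 + t, y1 - t),
    SE = in_box(midx + 1L, x1, y0, y0 + t - 1L),
    SW = in_box(x0, midx, y0, y0 + t - 1L)
  )
  ## (corners of the frame belong to the top/bottom sectors by construction)

  ## island: centred block inside the hole, separated from the ring by >= 1
  hx0 <- x0 + t; hx1 <- x1 - t; hy0 <- y0 + t; hy1 <- y1 - t
  ix0 <- hx0 + 2L; ix1 <- hx1 - 2L; iy0 <- hy0 + 2L; iy1 <- hy1 - 2L
  if (ix1 < ix0 || iy1 < iy0) {
    stop_config("grid %s too small to fit an island inside the ring", format(grid))
  }
  island <- in_box(ix0, ix1, iy0, iy1)

  corners <- list(
    scattered_1 = in_box(0L, 1L, 0L, 1L),
    scattered_2 = in_box(nx - 2L, nx - 1L, 0L, 1L),
    scattered_3 = in_box(0L, 1L, ny - 2L, ny - 1L),
    scattered_4 = in_box(nx - 2L, nx - 1L, ny - 2L, ny - 1L)
  )[seq_len(n_scattered)]

  units <- c(lapply(sectors, binary_mask, grid = grid),
             list(island = binary_mask(grid, island)),
             lapply(corners, binary_mask, grid = grid))
  names(units) <- c(paste0("ring_", names(sectors)), "island", names(corners))

  vals <- lapply(units, function(u) u$values)
  total <- Reduce(`+`, lapply(vals, function(v) v + 0L))
  if (max(total) > 1L) stop_config("internal layout error: overlapping parcels")
  if (any(vapply(units, mask_size, 1L) < 2L)) {
    stop_config("layout produces parcels with fewer than 2 voxels")
  }

  domain <- array(FALSE, grid$shape)
  domain[(1:(nx - 2L)) + 1L, (1:(ny - 2L)) + 1L, seq_len(nz)] <- TRUE

  ring_names <- paste0("ring_", names(sectors))
  fams <- c(stats::setNames(rep("VSA", length(ring_names)), ring_names),
            island = "PTF",
            stats::setNames(rep("PTF", length(corners)), names(corners)))
  atlas <- reference_atlas(grid, units)
  attr(atlas, "layout") <- list(ring = ring_names, island = "island",
                                scattered = names(corners),
                                domain = binary_mask(grid, domain),
                                families = fams)
  atlas
}

#' Simulate multi-subject 4D series with planted networks
#'
#' Each subject expresses each network independently with probability equal
#' to its prevalence. An expressed network contributes
#' `amplitude * footprint x time-course`, where the time course is an i.i.d.
#' standard-normal series (one draw per timepoint; no autocorrelation —
#' the downstream spatial analysis does not depend on temporal structure).
#' I.i.d. Gaussian noise of s.d. `noise_sd` is added everywhere, so the
#' per-voxel SNR inside a footprint is `amplitude / noise_sd`.
#'
#' @param networks List of [network_spec()] objects sharing one grid.
#' @param n_subjects Number of subjects (>= 2).
#' @param n_timepoints Number of timepoints (>= 10).
#' @param noise_sd Noise standard deviation (>= 0; 0 gives the noiseless
#'   limit used by degenerate fixtures).
#' @param seed Integer seed; the full output is bit-reproducible.
#' @return A list with `subjects` (list of 4D arrays), `presence` (logical
#'   n_subjects x n_networks ground-truth inclusion table), and `grid`.
#' @export
simulate_subjects <- function(networks, n_subjects, n_timepoints, noise_sd, seed) {
  if (length(networks) < 1L) stop_validation("at least one network required")
  for (n in networks) stopifnot(inherits(n, "network_spec"))
  grid <- networks[[1]]$footprint$grid
  for (n in networks[-1]) {
    check_same_grid(grid, n$footprint$grid, "network footprints")
  }
  if (!is_count(n_subjects) || n_subjects < 2) stop_validation("n_subjects must be >= 2")
  if (!is_count(n_timepoints) || n_timepoints < 10) stop_validation("n_timepoints must be >= 10")
  if (!is.numeric(noise_sd) || noise_sd < 0) stop_validation("noise_sd must be >= 0")
  nv <- prod(grid$shape)
  with_seed(seed, {
    presence <- matrix(FALSE, n_subjects, length(networks),
                       dimnames = list(NULL, vapply(networks, `[[`, "", "name")))
    for (j in seq_along(networks)) {
      presence[, j] <- stats::runif(n_subjects) < networks[[j]]$prevalence
    }
    subjects <- vector("list", n_subjects)
    for (s in seq_len(n_subjects)) {
      x <- matrix(stats::rnorm(nv * n_timepoints, sd = noise_sd), nv, n_timepoints)
      for (j in seq_along(networks)) {
        if (presence[s, j]) {
          net <- networks[[j]]
          tc <- stats::rnorm(n_timepoints)
          x <- x + net$amplitude * as.double(net$footprint$values) %o% tc
        }
      }
      dim(x) <- c(grid$shape, n_timepoints)
      subjects[[s]] <- x
    }
    list(subjects = subjects, presence = presence, grid = grid)
  })
}

#' Generate a block-structured overlap-count fixture
#'
#' Produces an integer overlap matrix whose rows follow a membership table:
#' entry (r, c) is Poisson(`high_mean`) when column c belongs to the block of
#' r's cluster and Poisson(`low_mean`) otherwise. By default clusters receive
#' contiguous, disjoint, near-equal column blocks (requiring at least one
#' column per cluster); an explicit `blocks` list (cluster name -> column
#' indices or names) overrides this, allowing overlapping but distinct
#' per-cluster column sets when there are more clusters than columns.
#'
#' @param table A duplicate-free [membership_table()] (duplicates are a
#'   validation error; resolve them first).
#' @param n_columns Number of reference columns.
#' @param high_mean,low_mean Poisson means inside / outside blocks
#'   (`high_mean > low_mean > 0`, or `low_mean = 0` for exact zeros).
#' @param seed Integer seed.
#' @param blocks Optional named list overriding block assignment.
#' @param column_names Optional column names (default `unit<j>`).
#' @return An [overlap_matrix()] with attribute `blocks` (named list of
#'   column-name vectors per cluster).
#' @export
fixture_overlap_matrix <- function(table, n_columns, high_mean, low_mean, seed,
                                   blocks = NULL, column_names = NULL) {
  stopifnot(inherits(table, "membership_table"))
  if (length(table$duplicates) > 0L) {
    stop_validation("duplicated rows without resolution: %s",
                    paste(table$duplicates, collapse = ", "))
  }
  if (!is_count(n_columns)) stop_validation("n_columns must be a positive count")
  if (!(high_mean > low_mean) || low_mean < 0) {
    stop_validation("need high_mean > low_mean >= 0")
  }
  column_names <- column_names %||% paste0("unit", seq_len(n_columns))
  if (length(column_names) != n_columns) {
    stop_validation("column_names must have length n_columns")
  }
  k <- length(table$clusters)
  if (is.null(blocks)) {
    if (k > n_columns) {
      stop_config("%d clusters cannot receive disjoint blocks of %d columns; supply blocks",
                  k, n_columns)
    }
    sizes <- rep(n_columns %/% k, k)
    sizes[seq_len(n_columns %% k)] <- sizes[seq_len(n_columns %% k)] + 1L
    ends <- cumsum(sizes)
    blocks <- lapply(seq_len(k), function(i) column_names[(ends[i] - sizes[i] + 1L):ends[i]])
    names(blocks) <- names(table$clusters)
  } else {
    blocks <- lapply(blocks, function(b) {
      if (is.numeric(b)) column_names[b] else as.character(b)
    })
    if (!setequal(names(blocks), names(table$clusters))) {
      stop_validation("blocks must name exactly the clusters of the table")
    }
    if (!all(unlist(blocks) %in% column_names)) {
      stop_validation("blocks refer to unknown columns")
    }
  }
  rows <- unlist(table$clusters, use.names = FALSE)
  row_cluster <- rep(names(table$clusters), lengths(table$clusters))
  counts <- with_seed(seed, {
    m <- matrix(0L, length(rows), n_columns, dimnames = list(rows, column_names))
    for (i in seq_along(rows)) {
      in_block <- column_names %in% blocks[[row_cluster[i]]]
      m[i, ] <- stats::rpois(n_columns, ifelse(in_block, high_mean, low_mean))
    }
    m
  })
  out <- overlap_matrix(counts)
  attr(out, "blocks") <- blocks
  out
}
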