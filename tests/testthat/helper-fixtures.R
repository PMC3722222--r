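## Shared builders and independent oracles for the test suite.  Oracles are
## deliberately naive (voxel loops, exhaustive enumeration, from-definition
## formulas) and never call the implementation they check.

tiny_grid <- function(shape = c(6, 6, 6), affine = NULL) {
  volume_grid(shape, affine)
}

## mask from a set of 1-based linear voxel indices
mask_from_indices <- function(grid, idx) {
  v <- array(FALSE, grid$shape)
  v[idx] <- TRUE
  binary_mask(grid, v)
}

random_mask <- function(grid, p = 0.3, seed = 1) {
  withr::with_seed(seed, {
    binary_mask(grid, array(runif(prod(grid$shape)) < p, grid$shape))
  })
}

random_streamlines <- function(n, seed = 1, extent = 10) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      npts <- sample(2:8, 1)
      streamline(matrix(runif(npts * 3, 0, extent), ncol = 3))
    })
  })
}

## build a z-scored component_map from an arbitrary in-brain vector
make_map <- function(values, brain, subject_id = "s1", index = 1L) {
  z <- values - mean(values)
  z <- z / stats::sd(z)
  component_map(subject_id, index, z, brain)
}

## --- independent oracles -------------------------------------------------

## from-definition Benjamini-Hochberg: find the largest k with
## p_(k) <= k * q / m and reject everything at or below that order statistic
bh_oracle <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  k <- max(c(0, which(ps <= seq_len(m) * q / m)))
  reject <- logical(m)
  if (k > 0) reject[ord[seq_len(k)]] <- TRUE
  reject
}

## from-definition weighted Newman-Girvan modularity
modularity_oracle <- function(W, part) {
  total <- sum(W) / 2
  q <- 0
  for (c in unique(part)) {
    inc <- part == c
    q <- q + sum(W[inc, inc]) / 2 / total - (sum(W[inc, ]) / (2 * total))^2
  }
  q
}

## enumerate all set partitions of 1..n (restricted-growth strings)
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxid) {
    i <- length(prefix) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible(NULL))
    }
    for (g in seq_len(maxid + 1L)) {
      rec(c(prefix, g), max(maxid, g))
    }
  }
  rec(integer(0), 0L)
  out
}

## exhaustive-search maximum-modularity partition
best_partition_oracle <- function(W) {
  n <- nrow(W)
  parts <- all_partitions(n)
  qs <- vapply(parts, function(p) modularity_oracle(W, p), numeric(1))
  list(Q = max(qs), partition = parts[[which.max(qs)]])
}

## naive voxel-loop overlap count
shared_voxels_oracle <- function(a, b) {
  n <- 0L
  for (i in seq_along(a$values)) {
    if (a$values[i] && b$values[i]) n <- n + 1L
  }
  n
}

## flood-fill component count via repeated scanning over explicit neighbour
## lists (independent of the package's shift-based labelling)
components_oracle <- function(mask, connectivity = 6) {
  d <- dim(mask$values)
  idx <- which(mask$values)
  if (length(idx) == 0) return(0L)
  coord <- arrayInd(idx, d)
  key <- function(xyz) paste(xyz, collapse = ",")
  in_set <- new.env()
  for (i in seq_len(nrow(coord))) assign(key(coord[i, ]), i, envir = in_set)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  if (connectivity == 6) offs <- offs[abs(offs$dx) + abs(offs$dy) + abs(offs$dz) == 1, ]
  seen <- logical(nrow(coord))
  ncomp <- 0L
  for (s in seq_len(nrow(coord))) {
    if (seen[s]) next
    ncomp <- ncomp + 1L
    stack <- s
    seen[s] <- TRUE
    while (length(stack) > 0) {
      cur <- stack[length(stack)]; stack <- stack[-length(stack)]
      for (r in seq_len(nrow(offs))) {
        nb <- coord[cur, ] + c(offs$dx[r], offs$dy[r], offs$dz[r])
        if (any(nb < 1) || any(nb > d)) next
        j <- mget(key(nb), envir = in_set, ifnotfound = list(NULL))[[1]]
        if (!is.null(j) && !seen[j]) {
          seen[j] <- TRUE
          stack <- c(stack, j)
        }
      }
    }
  }
  ncomp
}

## per-endpoint containment recheck for streamline filtering
filter_oracle <- function(lines, mask, mode) {
  inv <- solve(mask$grid$affine)
  point_in <- function(p) {
    v <- (inv %*% c(p, 1))[1:3]
    ix <- floor(v + 0.5)
    if (any(ix < 0) || any(ix >= mask$grid$shape)) return(FALSE)
    mask$values[ix[1] + 1, ix[2] + 1, ix[3] + 1]
  }
  vapply(lines, function(sl) {
    pts <- unclass(sl)
    a <- point_in(pts[1, ]); b <- point_in(pts[nrow(pts), ])
    if (mode == "both-endpoints") a && b else a || b
  }, logical(1))
}
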