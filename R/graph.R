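#' Weighted profile graph over overlap-matrix rows
#'
#' Nodes are networks (matrix rows); edge weight is the cosine similarity of
#' the two row profiles with negative values clipped to zero, and edges
#' weaker than the mean positive weight are removed, which sparsifies the
#' graph before community detection. All-zero rows give isolated nodes
#' (logged via message). No self-loops.
#'
#' @param matrix An [overlap_matrix()] or named numeric matrix, >= 2 rows.
#' @return An object of class `profile_graph`: list with `weights`
#'   (symmetric matrix, 0 = no edge) and `nodes`.
#' @export
profile_graph <- function(matrix) {
  X <- unclass(matrix)
  storage.mode(X) <- "double"
  if (nrow(X) < 2L) stop_validation("need at least 2 rows")
  labs <- rownames(X) %||% as.character(seq_len(nrow(X)))
  nrm <- sqrt(rowSums(X^2))
  zero_rows <- nrm == 0
  if (any(zero_rows)) {
    message("all-zero profile rows left isolated: ",
            paste(labs[zero_rows], collapse = ", "))
    nrm[zero_rows] <- 1
  }
  Xn <- X / nrm
  W <- Xn %*% t(Xn)
  W[W < 0] <- 0
  diag(W) <- 0
  W[zero_rows, ] <- 0
  W[, zero_rows] <- 0
  pos <- W[upper.tri(W)]
  pos <- pos[pos > 0]
  if (length(pos) > 0L) {
    thr <- mean(pos)
    W[W < thr - 1e-12] <- 0   # tolerance so ties with the mean survive
  }
  dimnames(W) <- list(labs, labs)
  structure(list(weights = W, nodes = labs), class = "profile_graph")
}

#' @export
print.profile_graph <- function(x, ...) {
  cat(sprintf("<profile_graph: %d nodes, %d edges>\n", length(x$nodes),
              sum(x$weights[upper.tri(x$weights)] > 0)))
  invisible(x)
}

#' Community partition of a graph
#' @param assignment Named vector: node -> community id.
#' @param modularity_Q Newman-Girvan modularity of the partition on its graph.
#' @return An object of class `community_partition`.
#' @export
community_partition <- function(assignment, modularity_Q) {
  if (is.null(names(assignment))) stop_validation("assignment must be named by node")
  if (modularity_Q > 1 + 1e-12) stop_validation("modularity cannot exceed 1")
  labs <- names(assignment)
  assignment <- as.integer(as.factor(assignment))
  names(assignment) <- labs
  structure(list(assignment = assignment, modularity_Q = modularity_Q),
            class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("<community_partition: %d communities, Q = %.4f>\n",
              length(unique(x$assignment)), x$modularity_Q))
  invisible(x)
}

#' Weighted Newman-Girvan modularity
#'
#' Q = sum over communities of (within-community weight / W) minus
#' (community strength / 2W)^2, with W the total edge weight: the fraction
#' of weight falling within groups minus its expectation when edges are
#' placed at random with the same strengths. The one-community partition
#' has Q = 0 on any graph.
#'
#' @param graph A [profile_graph()] (or any object with a `weights` matrix).
#' @param partition Named vector (node -> community) covering all nodes, or
#'   a [community_partition()].
#' @return Q (at most 1).
#' @export
modularity <- function(graph, partition) {
  W <- graph$weights
  if (inherits(partition, "community_partition")) partition <- partition$assignment
  if (!setequal(names(partition), rownames(W))) {
    stop_validation("partition must cover exactly the graph's nodes")
  }
  total <- sum(W) / 2
  if (total <= 0) stop_validation("graph has no edges; modularity undefined")
  part <- partition[rownames(W)]
  Q <- 0
  for (c in unique(part)) {
    in_c <- part == c
    w_in <- sum(W[in_c, in_c]) / 2
    s_c <- sum(W[in_c, ])
    Q <- Q + w_in / total - (s_c / (2 * total))^2
  }
  Q
}

#' Greedy modularity community detection
#'
#' Agglomerative maximisation of Q: starting from singleton communities,
#' repeatedly merge the pair with the largest positive modularity gain; a
#' node-moving refinement pass then relocates single nodes while any move
#' improves Q. On small graphs with clear structure this attains the
#' exhaustive-search optimum.
#'
#' @param graph A [profile_graph()].
#' @return A [community_partition()].
#' @export
detect_communities <- function(graph) {
  W <- graph$weights
  n <- nrow(W)
  if (n < 1L) stop_validation("graph must have at least one node")
  part <- seq_len(n)
  total <- sum(W) / 2
  if (total <= 0) {
    return(community_partition(stats::setNames(part, rownames(W)), 0))
  }
  strength <- rowSums(W)
  delta_q <- function(part, a, b) {
    ia <- part == a; ib <- part == b
    w_ab <- sum(W[ia, ib])
    s_a <- sum(strength[ia]); s_b <- sum(strength[ib])
    w_ab / total - s_a * s_b / (2 * total^2)
  }
  repeat {
    ids <- unique(part)
    if (length(ids) == 1L) break
    best <- c(NA, NA); best_dq <- 1e-12
    for (i in seq_along(ids)) {
      for (j in seq_len(i - 1L)) {
        dq <- delta_q(part, ids[i], ids[j])
        if (dq > best_dq) { best_dq <- dq; best <- c(ids[i], ids[j]) }
      }
    }
    if (is.na(best[1])) break
    part[part == best[1]] <- best[2]
  }
  ## node-moving refinement
  improved <- TRUE
  while (improved) {
    improved <- FALSE
    for (v in seq_len(n)) {
      cur <- part[v]
      cands <- setdiff(unique(c(part, max(part) + 1L)), cur)
      base_q <- modularity(graph, stats::setNames(part, rownames(W)))
      for (cc in cands) {
        trial <- part
        trial[v] <- cc
        q <- modularity(graph, stats::setNames(trial, rownames(W)))
        if (q > base_q + 1e-12) {
          part <- trial
          base_q <- q
          improved <- TRUE
        }
      }
    }
  }
  part <- as.integer(as.factor(part))
  Q <- modularity(graph, stats::setNames(part, rownames(W)))
  community_partition(stats::setNames(part, rownames(W)), Q)
}

## Maximum-trace one-to-one matching of a square matrix by bitmask dynamic
## programming over columns; returns the column assigned to each row.
max_trace_assignment <- function(M) {
  n <- nrow(M)
  if (n > 20L) stop_validation("assignment matching supports up to 20 labels")
  full <- bitwShiftL(1L, n) - 1L
  best <- rep(-Inf, full + 1L)
  choice <- matrix(NA_integer_, n, full + 1L)
  best[1L] <- 0
  masks_by_count <- split(0:full, vapply(0:full, function(m) sum(bitwAnd(m, bitwShiftL(1L, 0:(n - 1))) > 0), 1))
  for (row in seq_len(n)) {
    for (m in masks_by_count[[as.character(row - 1L)]]) {
      if (!is.finite(best[m + 1L])) next
      for (col in seq_len(n)) {
        bit <- bitwShiftL(1L, col - 1L)
        if (bitwAnd(m, bit) == 0L) {
          nm <- bitwOr(m, bit)
          val <- best[m + 1L] + M[row, col]
          if (val > best[nm + 1L]) {
            best[nm + 1L] <- val
            choice[row, nm + 1L] <- col
          }
        }
      }
    }
  }
  assign <- integer(n)
  m <- full
  for (row in rev(seq_len(n))) {
    col <- choice[row, m + 1L]
    assign[row] <- col
    m <- bitwAnd(m, bitwNot(bitwShiftL(1L, col - 1L)))
  }
  list(assignment = assign, value = best[full + 1L])
}

#' Concordance between a mixture clustering and a community partition
#'
#' Builds the cluster x community confusion matrix, matches labels
#' one-to-one by maximum trace on the zero-padded square matrix (optimal
#' assignment), and reports accuracy = matched agreements / n.
#'
#' @param a A [clustering_result()].
#' @param b A [community_partition()] (or another clustering result).
#' @return An object of class `concordance_summary`: list with `confusion`
#'   (after optimal matching, rows reordered to the matched community) and
#'   `accuracy`.
#' @export
concordance_accuracy <- function(a, b) {
  la <- a$assignment
  lb <- b$assignment
  if (!setequal(names(la), names(lb))) {
    stop_validation("the two partitions label different row sets")
  }
  lb <- lb[names(la)]
  ka <- max(la); kb <- max(lb)
  k <- max(ka, kb)
  conf <- matrix(0L, k, k)
  for (i in seq_along(la)) conf[la[i], lb[i]] <- conf[la[i], lb[i]] + 1L
  sol <- max_trace_assignment(conf)
  acc <- sol$value / length(la)
  matched <- conf[, sol$assignment, drop = FALSE][seq_len(ka), seq_len(kb), drop = FALSE]
  dimnames(matched) <- list(cluster = paste0("C", seq_len(ka)),
                            community = paste0("M", seq_len(kb)))
  structure(list(confusion = matched, accuracy = acc),
            class = "concordance_summary")
}

#' @export
print.concordance_summary <- function(x, ...) {
  cat(sprintf("<concordance_summary: accuracy %.3f>\n", x$accuracy))
  print(x$confusion)
  invisible(x)
}
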