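named_matrix <- function(x, labs) {
  dimnames(x) <- list(labs, labs)
  x
}

graph_from_weights <- function(W) {
  labs <- rownames(W) %||% paste0("n", seq_len(nrow(W)))
  dimnames(W) <- list(labs, labs)
  structure(list(weights = W, nodes = labs), class = "profile_graph")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

two_triangles <- function() {
  W <- matrix(0, 6, 6)
  W[1, 2] <- W[2, 3] <- W[1, 3] <- 1
  W[4, 5] <- W[5, 6] <- W[4, 6] <- 1
  graph_from_weights(W + t(W))
}

test_that("profile graphs encode cosine similarity with mean-weight sparsification", {
  X <- rbind(a = c(1, 0, 0, 2), b = c(2, 0, 0, 4), c = c(0, 3, 0, 0), d = c(0, 6, 0, 0))
  colnames(X) <- paste0("u", 1:4)
  g <- profile_graph(X)
  expect_equal(g$weights["a", "b"], 1, tolerance = 1e-12)
  expect_equal(g$weights["c", "d"], 1, tolerance = 1e-12)
  expect_equal(g$weights["a", "c"], 0)           # orthogonal: no edge
  expect_equal(sum(g$weights > 0), 4)            # two disjoint (undirected) edges
  expect_true(all(diag(g$weights) == 0))
  ## zero rows become isolated nodes, with a message
  X2 <- rbind(X, e = c(0, 0, 0, 0))
  expect_message(g2 <- profile_graph(X2), "isolated")
  expect_true(all(g2$weights["e", ] == 0))
})

test_that("modularity matches closed forms and a from-definition oracle", {
  tg <- two_triangles()
  one <- stats::setNames(rep(1, 6), tg$nodes)
  expect_equal(modularity(tg, one), 0)
  split <- stats::setNames(c(1, 1, 1, 2, 2, 2), tg$nodes)
  expect_equal(modularity(tg, split), 0.5)
  for (i in 1:10) {
    W <- withr::with_seed(i, {
      A <- matrix(runif(36), 6, 6) * (matrix(runif(36), 6, 6) < 0.5)
      A <- A + t(A); diag(A) <- 0; A
    })
    g <- graph_from_weights(W)
    part <- withr::with_seed(100 + i, stats::setNames(sample(1:3, 6, TRUE), g$nodes))
    expect_equal(modularity(g, part), modularity_oracle(W, unname(part)),
                 tolerance = 1e-12)
  }
  expect_error(modularity(graph_from_weights(matrix(0, 2, 2)),
                          stats::setNames(1:2, c("n1", "n2"))), "no edges")
})

test_that("modularity agrees with igraph on weighted graphs", {
  skip_if_not_installed("igraph")
  for (i in 1:5) {
    W <- withr::with_seed(40 + i, {
      A <- matrix(runif(49), 7, 7) * (matrix(runif(49), 7, 7) < 0.6)
      A <- A + t(A); diag(A) <- 0; A
    })
    g <- graph_from_weights(W)
    part <- withr::with_seed(60 + i, sample(1:3, 7, TRUE))
    ig <- igraph::graph_from_adjacency_matrix(W, mode = "undirected", weighted = TRUE)
    expect_equal(modularity(g, stats::setNames(part, g$nodes)),
                 igraph::modularity(ig, part, weights = igraph::E(ig)$weight),
                 tolerance = 1e-12)
  }
})

test_that("community detection finds planted structure and the trivial limit", {
  tg <- two_triangles()
  res <- detect_communities(tg)
  expect_equal(length(unique(res$assignment)), 2)
  expect_equal(res$modularity_Q, 0.5)
  expect_length(unique(res$assignment[1:3]), 1)
  expect_length(unique(res$assignment[4:6]), 1)
  ## complete uniform graph: no structure, one community
  K <- matrix(1, 5, 5); diag(K) <- 0
  res2 <- detect_communities(graph_from_weights(K))
  expect_equal(length(unique(res2$assignment)), 1)
  ## detected Q never below the trivial partition's 0
  expect_gte(res2$modularity_Q, 0)
})

test_that("greedy detection equals exhaustive search on the small-graph battery", {
  battery <- list(two_triangles()$weights)
  ## planted 2-block weighted graphs
  for (i in 1:6) {
    W <- withr::with_seed(200 + i, {
      n <- sample(5:8, 1)
      cut <- sample(2:(n - 2), 1)
      A <- matrix(runif(n * n, 0, 0.15), n, n)
      A[1:cut, 1:cut] <- A[1:cut, 1:cut] + runif(cut^2, 0.6, 1)
      A[(cut + 1):n, (cut + 1):n] <- A[(cut + 1):n, (cut + 1):n] + runif((n - cut)^2, 0.6, 1)
      A <- (A + t(A)) / 2; diag(A) <- 0; A
    })
    battery[[length(battery) + 1]] <- W
  }
  ## barbell: two triangles joined by one weak edge
  Wb <- two_triangles()$weights; Wb[3, 4] <- Wb[4, 3] <- 0.2
  battery[[length(battery) + 1]] <- Wb
  for (W in battery) {
    g <- graph_from_weights(W)
    got <- detect_communities(g)
    opt <- best_partition_oracle(W)
    expect_equal(got$modularity_Q, opt$Q, tolerance = 1e-10)
  }
})

test_that("concordance accuracy: identity, worst case, and one-off partitions", {
  labs <- paste0("r", 1:4)
  a <- clustering_result(stats::setNames(c(1, 1, 2, 2), labs))
  expect_equal(concordance_accuracy(a, a)$accuracy, 1.0)
  singletons <- clustering_result(stats::setNames(1:4, labs))
  lump <- community_partition(stats::setNames(rep(1, 4), labs), 0)
  expect_equal(concordance_accuracy(singletons, lump)$accuracy, 0.25)
  labs30 <- paste0("r", 1:30)
  p1 <- stats::setNames(rep(1:3, each = 10), labs30)
  p2 <- p1; p2[30] <- 1
  expect_equal(concordance_accuracy(clustering_result(p1),
                                    community_partition(p2, 0.1))$accuracy, 29 / 30)
  expect_error(concordance_accuracy(a, community_partition(
    stats::setNames(1:2, c("x", "y")), 0)), "different row sets")
})

test_that("EM clusters and communities agree on a planted two-block fixture", {
  tab <- membership_table(list(A = paste0("a", 1:5), B = paste0("b", 1:5)))
  m <- fixture_overlap_matrix(tab, 8, 500, 10, seed = 31)
  em <- em_mixture_cluster(m, 6, 5, seed = 4)
  comm <- detect_communities(profile_graph(m))
  expect_equal(length(unique(comm$assignment)), em$n_clusters)
  expect_equal(concordance_accuracy(em, comm)$accuracy, 1.0)
})
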