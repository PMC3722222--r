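test_that("degenerate phantom layout yields a single whole-grid parcel", {
  g <- volume_grid(c(6, 6, 2))
  atlas <- make_phantom_atlas(g, layout = list(n_ring = 1))
  expect_equal(atlas_n_units(atlas), 1)
  expect_equal(mask_size(atlas$units[[1]]), prod(g$shape))
})

test_that("phantom ring parcels form a single 6-cycle of face-adjacent sectors", {
  g <- volume_grid(c(16, 16, 4))
  atlas <- make_phantom_atlas(g)
  lay <- attr(atlas, "layout")
  expect_length(lay$ring, 6)
  ## exhaustive voxel-neighbour scan builds the sector adjacency graph
  adj <- matrix(FALSE, 6, 6, dimnames = list(lay$ring, lay$ring))
  d <- g$shape
  labels <- array(0L, d)
  for (i in seq_along(lay$ring)) labels[atlas$units[[lay$ring[i]]]$values] <- i
  for (v in which(labels > 0)) {
    xyz <- arrayInd(v, d)
    for (step in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                      c(0, 0, 1), c(0, 0, -1))) {
      nb <- xyz + step
      if (any(nb < 1) || any(nb > d)) next
      l2 <- labels[nb[1], nb[2], nb[3]]
      if (l2 > 0 && l2 != labels[v]) adj[labels[v], l2] <- TRUE
    }
  }
  degrees <- rowSums(adj)
  expect_true(all(degrees == 2))             # every sector touches exactly 2
  ## consecutive sectors (cyclically) are adjacent
  for (i in 1:6) {
    expect_true(adj[i, if (i == 6) 1 else i + 1])
  }
})

test_that("phantom parcels are disjoint, scattered parcels non-adjacent, layout deterministic", {
  g <- volume_grid(c(16, 16, 4))
  a1 <- make_phantom_atlas(g, seed = 5)
  a2 <- make_phantom_atlas(g, seed = 5)
  expect_identical(atlas_label_array(a1), atlas_label_array(a2))
  total <- Reduce(`+`, lapply(a1$units, function(u) u$values + 0L))
  expect_lte(max(total), 1L)
  lay <- attr(a1, "layout")
  sc <- a1$units[lay$scattered]
  for (i in seq_along(sc)) {
    for (j in seq_len(i - 1)) {
      expect_false(ringscape:::masks_adjacent(sc[[i]], sc[[j]]))
    }
  }
  expect_error(make_phantom_atlas(volume_grid(c(8, 8, 2))), "configuration error")
})

test_that("noiseless single-network subjects have rank-1 footprint structure", {
  g <- tiny_grid(c(5, 5, 2))
  fp <- mask_from_indices(g, 1:10)
  sim <- simulate_subjects(list(network_spec("n", fp, 1)), 3, 12, noise_sd = 0, seed = 2)
  expect_true(all(sim$presence))
  for (x in sim$subjects) {
    M <- matrix(x, ncol = 12)
    expect_equal(sum(svd(M)$d > 1e-10), 1)   # rank 1
    expect_true(all(M[!as.vector(fp$values), ] == 0))
    expect_true(all(abs(M[as.vector(fp$values), 1]) > 0))
  }
})

test_that("prevalence boundaries and inclusion rates behave", {
  g <- tiny_grid(c(4, 4, 2))
  fp <- mask_from_indices(g, 1:6)
  sim0 <- simulate_subjects(list(network_spec("n", fp, 0)), 5, 10, 0.1, seed = 1)
  expect_false(any(sim0$presence))
  ## empirical inclusion within the analytic binomial 99% interval of 0.5
  sim <- simulate_subjects(list(network_spec("n", fp, 0.5)), 100, 10, 0.1, seed = 42)
  band <- qbinom(c(0.005, 0.995), 100, 0.5)
  expect_gte(sum(sim$presence), band[1])
  expect_lte(sum(sim$presence), band[2])
  ## bit-reproducible under a fixed seed
  sim2 <- simulate_subjects(list(network_spec("n", fp, 0.5)), 100, 10, 0.1, seed = 42)
  expect_identical(sim$subjects, sim2$subjects)
  expect_identical(sim$presence, sim2$presence)
})

test_that("simulator validates its inputs", {
  g <- tiny_grid(c(4, 4, 2)); g2 <- tiny_grid(c(4, 4, 3))
  n1 <- network_spec("a", mask_from_indices(g, 1:4), 0.5)
  n2 <- network_spec("b", mask_from_indices(g2, 1:4), 0.5)
  expect_error(simulate_subjects(list(n1, n2), 5, 10, 1, 1), "different grids")
  expect_error(simulate_subjects(list(n1), 1, 10, 1, 1), "n_subjects")
  expect_error(simulate_subjects(list(n1), 5, 5, 1, 1), "n_timepoints")
  expect_error(network_spec("z", mask_from_indices(g, integer(0)), 0.5), "non-empty")
  expect_error(network_spec("z", mask_from_indices(g, 1:3), 1.5), "prevalence")
})

test_that("fixture overlap matrices realise the block structure", {
  tab <- membership_table(list(A = c("r1", "r2"), B = c("r3", "r4", "r5")))
  m0 <- fixture_overlap_matrix(tab, 6, high_mean = 500, low_mean = 0, seed = 1)
  blocks <- attr(m0, "blocks")
  for (r in rownames(m0)) {
    cl <- if (r %in% tab$clusters$A) "A" else "B"
    expect_true(all(m0[r, setdiff(colnames(m0), blocks[[cl]])] == 0))
    expect_true(all(m0[r, blocks[[cl]]] > 0))
  }
  ## one cluster containing all rows: identically distributed rows
  tab1 <- membership_table(list(only = paste0("r", 1:4)))
  m1 <- fixture_overlap_matrix(tab1, 5, 100, 10, seed = 2)
  expect_identical(unname(attr(m1, "blocks")$only), colnames(m1))
  ## reproducible
  expect_identical(unclass(fixture_overlap_matrix(tab, 6, 500, 10, seed = 9)),
                   unclass(fixture_overlap_matrix(tab, 6, 500, 10, seed = 9)))
})

test_that("bundled TBN fixture matches the printed memberships", {
  tab <- bundled_membership("tbn")
  expect_equal(unname(lengths(tab$clusters)), c(4, 4, 1, 2, 3, 16))
  expect_setequal(tab$rows, as.character(setdiff(1:32, c(10, 12))))
  m <- bundled_overlap_fixture("tbn", seed = 1)
  expect_equal(dim(m), c(30L, 18L))
  ## rows with a high block must exceed the all-low expectation in row sum
  low_only_expect <- 18 * 10
  expect_true(all(rowSums(m) > low_only_expect + 6 * sqrt(low_only_expect)))
})

test_that("duplicate rows are flagged, resolvable, and rejected when unresolved", {
  printed <- bundled_membership("baf", resolved = FALSE)
  expect_setequal(printed$duplicates, c("18", "20"))
  expect_error(fixture_overlap_matrix(printed, 7, 500, 10, 1),
               "duplicated rows.*18")
  resolved <- bundled_membership("baf", resolved = TRUE)
  expect_length(resolved$duplicates, 0)
  expect_equal(resolved$clusters[["3"]], "18")
  expect_equal(resolved$clusters[["4"]], "20")
  expect_false("18" %in% resolved$clusters[["6"]])
  expect_length(resolved$rows, 30)
  ## more clusters than columns without explicit blocks is a config error
  expect_error(fixture_overlap_matrix(resolved, 7, 500, 10, 1),
               "configuration error")
})

test_that("membership tables round-trip through TSV", {
  tab <- membership_table(list(x = c("1", "2"), y = "3"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_membership_table(tab, f)
  back <- read_membership_table(f)
  expect_identical(back$clusters, tab$clusters)
})
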