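brain_of <- function(g) binary_mask(g, array(TRUE, g$shape))

test_that("spatial similarity is a correlation with the expected fixed points", {
  g <- tiny_grid(c(5, 1, 1))
  brain <- brain_of(g)
  a <- make_map(c(1, 2, 3, 4, 5), brain)
  b <- make_map(c(2, 4, 6, 8, 10), brain, subject_id = "s2")
  neg <- make_map(-c(1, 2, 3, 4, 5), brain, subject_id = "s3")
  expect_equal(spatial_similarity(a, a), 1)
  expect_equal(spatial_similarity(a, neg), -1)
  expect_equal(spatial_similarity(a, b), 1)
  g2 <- tiny_grid(c(5, 1, 2))
  c2 <- make_map(rnorm(10), brain_of(g2))
  expect_error(spatial_similarity(a, c2), "different grids")
})

test_that("identical maps across two subjects form one fully representative class", {
  g <- tiny_grid(c(4, 4, 2))
  brain <- brain_of(g)
  v <- withr::with_seed(1, rnorm(32))
  comps <- list(make_map(v, brain, "s1"), make_map(v, brain, "s2"))
  classes <- cluster_components(comps, 0.25)
  expect_length(classes, 1)
  expect_equal(classes[[1]]$representativeness, 1.0)
  expect_length(classes[[1]]$members, 2)
})

test_that("orthogonal planted maps across 10 subjects recover the ground truth", {
  g <- tiny_grid(c(6, 6, 2))
  brain <- brain_of(g)
  base1 <- withr::with_seed(2, rnorm(72))
  base2 <- withr::with_seed(3, rnorm(72))
  base2 <- base2 - base1 * sum(base1 * base2) / sum(base1^2)   # orthogonalise
  comps <- list(); truth <- integer(0)
  for (s in 1:10) {
    which_net <- 1 + (s %% 2)
    noise <- withr::with_seed(100 + s, rnorm(72, sd = 0.1))
    comps[[s]] <- make_map((if (which_net == 1) base1 else base2) + noise,
                           brain, paste0("s", s))
    truth[s] <- which_net
  }
  classes <- cluster_components(comps, 0.25)
  expect_length(classes, 2)
  got <- integer(10)
  for (k in seq_along(classes)) {
    for (m in classes[[k]]$members) {
      got[as.integer(sub("s", "", m$subject_id))] <- k
    }
  }
  expect_true(all(table(got, truth) %in% c(0, 5)))   # perfect split
})

test_that("the degenerate cut limit isolates every component", {
  g <- tiny_grid(c(4, 4, 2))
  brain <- brain_of(g)
  comps <- lapply(1:4, function(s) {
    make_map(withr::with_seed(s, rnorm(32)), brain, paste0("s", s))
  })
  classes <- cluster_components(comps, cut_similarity = 0.999)
  expect_length(classes, 4)
})

test_that("the 10% rule keeps and drops classes at the documented boundary", {
  g <- tiny_grid(c(4, 2, 1))
  brain <- brain_of(g)
  mk_class <- function(n_members, idx) {
    members <- lapply(seq_len(n_members), function(s) {
      make_map(withr::with_seed(idx * 1000 + s, rnorm(8)), brain, paste0("s", s))
    })
    rsn_class(members, n_subjects = 198, creation_index = idx)
  }
  kept <- select_representative(list(mk_class(20, 1), mk_class(19, 2)), min_R = 0.10)
  expect_length(kept, 1)
  expect_equal(kept[[1]]$representativeness, 20 / 198, tolerance = 1e-12)
  allk <- select_representative(list(mk_class(20, 1), mk_class(19, 2)), min_R = 0)
  expect_length(allk, 2)
  ## ranks: decreasing R, tie by creation index; invariant to member order
  ranks <- vapply(allk, `[[`, 1L, "rank")
  expect_equal(ranks, 1:2)
})

test_that("group t-map handles zero variance and controls FDR", {
  g <- tiny_grid(c(5, 4, 1))
  brain <- brain_of(g)
  ## identical members: strictly positive region survives, zero region not
  v <- c(rep(2, 6), rep(0, 14))
  v <- v - mean(v); v <- v / sd(v)
  members <- lapply(1:3, function(s) component_map(paste0("s", s), 1, v, brain))
  cls <- group_tmap(rsn_class(members, 3, 1), q = 0.05)
  expect_identical(as.vector(cls$mask$values), v > 0)
  ## all-noise class: surviving fraction stays near the nominal level
  fracs <- vapply(1:20, function(rep) {
    members <- lapply(1:10, function(s) {
      make_map(withr::with_seed(rep * 100 + s, rnorm(20)), brain, paste0("s", s))
    })
    mean(group_tmap(rsn_class(members, 10, 1), q = 0.05)$mask$values)
  }, numeric(1))
  expect_lte(mean(fracs), 0.05 + 2 * sd(fracs) / sqrt(20) + 1e-12)
  expect_error(group_tmap(rsn_class(members[1], 10, 1)), "statistics error")
})

test_that("BH on the worked 5-value example rejects exactly the first three", {
  p <- c(0.01, 0.02, 0.03, 0.20, 0.90)
  expect_identical(ringscape:::bh_reject(p, 0.05), c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_identical(ringscape:::bh_reject(p, 0.05), bh_oracle(p, 0.05))
})

test_that("population matching: identity, disjointness, and a permuted control", {
  g <- tiny_grid(c(6, 6, 2))
  brain <- brain_of(g)
  mk_rsns <- function(masks) {
    lapply(seq_along(masks), function(i) {
      members <- lapply(1:2, function(s) {
        make_map(withr::with_seed(i * 10 + s, rnorm(72)), brain, paste0("s", s))
      })
      cls <- rsn_class(members, 2, i)
      cls$mask <- masks[[i]]
      cls$rank <- i
      cls
    })
  }
  masks <- list(mask_from_indices(g, 1:20), mask_from_indices(g, 31:50))
  same <- match_populations(mk_rsns(masks), mk_rsns(masks))
  expect_equal(same$similarity_pct, c(100, 100))
  expect_equal(same$rankA, same$rankB)
  disj <- match_populations(mk_rsns(list(mask_from_indices(g, 1:10))),
                            mk_rsns(list(mask_from_indices(g, 11:20))))
  expect_equal(disj$similarity_pct, 0)
  ## two populations from the same planted networks beat a permuted control
  g2 <- volume_grid(c(12, 12, 6))
  mk_from_sim <- function(seed) {
    specs <- list(
      network_spec("a", mask_from_indices(g2, 1:150), 1),
      network_spec("b", mask_from_indices(g2, 400:600), 1)
    )
    sim <- simulate_subjects(specs, 6, 30, noise_sd = 1, seed = seed)
    brain2 <- brain_of(g2)
    comps <- unlist(lapply(1:6, function(s) {
      decompose_subject(sim$subjects[[s]], brain2, 3, seed = seed + s,
                        subject_id = paste0("s", s))
    }), recursive = FALSE)
    classes <- cluster_components(comps, 0.25, n_subjects = 6)
    classes <- lapply(Filter(function(c) length(c$members) >= 2, classes), group_tmap)
    select_representative(classes, 0.3)
  }
  popA <- mk_from_sim(21)
  popB <- mk_from_sim(22)
  matched <- match_populations(popA, popB)
  matched_rates <- matched$similarity_pct[!is.na(matched$rankA) & !is.na(matched$rankB)]
  ## permuted control: average off-diagonal Jaccard of deliberately wrong pairs
  wrong <- mean(vapply(seq_along(popA), function(i) {
    j <- (i %% length(popB)) + 1
    inter <- shared_voxels(popA[[i]]$mask, popB[[j]]$mask)
    100 * inter / (mask_size(popA[[i]]$mask) + mask_size(popB[[j]]$mask) - inter)
  }, numeric(1)))
  expect_gt(mean(matched_rates), wrong)
})

test_that("representativeness is invariant to subject order", {
  g <- tiny_grid(c(4, 4, 1))
  brain <- brain_of(g)
  v <- withr::with_seed(5, rnorm(16))
  comps <- lapply(1:6, function(s) make_map(v + withr::with_seed(50 + s, rnorm(16, sd = .05)),
                                            brain, paste0("s", s)))
  r1 <- cluster_components(comps, 0.25)[[1]]$representativeness
  r2 <- cluster_components(rev(comps), 0.25)[[1]]$representativeness
  expect_equal(r1, r2)
})
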