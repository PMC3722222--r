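test_that("shared voxels: idempotence, disjointness, direct intersection", {
  g <- tiny_grid(c(5, 5, 1))
  a <- mask_from_indices(g, 1:10)
  b <- mask_from_indices(g, 6:20)
  expect_equal(shared_voxels(a, a), mask_size(a))
  expect_equal(shared_voxels(a, mask_from_indices(g, 21:25)), 0)
  expect_equal(shared_voxels(a, b), 5)
  expect_error(shared_voxels(a, mask_from_indices(tiny_grid(c(5, 5, 2)), 1:3)),
               "different grids")
})

test_that("overlap matrices: one-hot rows, partition conservation, symmetry bound", {
  g <- tiny_grid(c(4, 4, 2))
  u1 <- mask_from_indices(g, 1:10)
  u2 <- mask_from_indices(g, 11:20)
  u3 <- mask_from_indices(g, 21:32)
  atlas <- reference_atlas(g, list(a = u1, b = u2, c = u3))
  m <- build_overlap_matrix(list(r1 = u1), atlas)
  expect_equal(unname(unclass(m)[1, ]), c(10L, 0L, 0L))
  whole <- mask_from_indices(g, 1:32)
  m2 <- build_overlap_matrix(list(all = whole), atlas)
  expect_equal(unname(unclass(m2)[1, ]), c(10L, 10L, 12L))
  expect_equal(sum(m2), prod(g$shape))
  for (j in 1:3) {
    expect_lte(m2[1, j], min(mask_size(whole), mask_size(atlas$units[[j]])))
  }
})

test_that("overlap matrix equals a brute-force voxel recount on random instances", {
  for (i in 1:50) {
    g <- tiny_grid(c(6, 5, 4))
    rsns <- list(x = random_mask(g, 0.3, seed = i),
                 y = random_mask(g, 0.5, seed = 100 + i))
    atlas <- reference_atlas(g, list(u = random_mask(g, 0.4, seed = 200 + i),
                                     v = random_mask(g, 0.2, seed = 300 + i)))
    m <- build_overlap_matrix(rsns, atlas)
    for (r in 1:2) {
      for (c in 1:2) {
        expect_identical(m[r, c], shared_voxels_oracle(rsns[[r]], atlas$units[[c]]))
      }
    }
  }
})

test_that("overlap counts are invariant under voxel relabelling", {
  g <- tiny_grid(c(4, 4, 4))
  a <- random_mask(g, 0.4, seed = 9)
  b <- random_mask(g, 0.4, seed = 10)
  perm <- withr::with_seed(11, sample(64))
  ap <- binary_mask(g, array(a$values[perm], g$shape))
  bp <- binary_mask(g, array(b$values[perm], g$shape))
  expect_equal(shared_voxels(a, b), shared_voxels(ap, bp))
})

test_that("row normalisation gives proportions without touching counts", {
  g <- tiny_grid(c(4, 4, 1))
  atlas <- reference_atlas(g, list(a = mask_from_indices(g, 1:8),
                                   b = mask_from_indices(g, 9:16)))
  m <- build_overlap_matrix(list(r = mask_from_indices(g, 5:12)), atlas)
  nm <- normalize_overlap(m)
  expect_equal(rowSums(nm), c(r = 1))
  expect_s3_class(m, "overlap_matrix")
})

test_that("overlap matrices round-trip through TSV", {
  g <- tiny_grid(c(4, 4, 2))
  atlas <- reference_atlas(g, list(`20*` = random_mask(g, .3, 1),
                                   BA17 = random_mask(g, .3, 2)))
  m <- build_overlap_matrix(list(`1` = random_mask(g, .4, 3),
                                 `2` = random_mask(g, .4, 4)), atlas)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_overlap_matrix(m, f)
  back <- read_overlap_matrix(f)
  expect_identical(unclass(back), unclass(m))
})

toy_ba_atlas <- function(extra_missing = character(0)) {
  ## one tiny disjoint parcel per Brodmann area used by the regroupings
  needed <- c(1:11, 17:25, 28:32, 34:38, 41:47, 20)
  needed <- sort(unique(needed))
  needed <- setdiff(needed, as.integer(sub("BA", "", extra_missing)))
  g <- tiny_grid(c(10, 10, 2))
  units <- list()
  for (i in seq_along(needed)) {
    sz <- if (needed[i] == 20) 7 else if (needed[i] == 38) 5 else 2
    start <- 1 + sum(vapply(seq_len(i - 1), function(j) {
      if (needed[j] == 20) 7L else if (needed[j] == 38) 5L else 2L
    }, 1L))
    units[[paste0("BA", needed[i])]] <- mask_from_indices(g, start:(start + sz - 1))
  }
  reference_atlas(g, units)
}

test_that("Brodmann regrouping applies exactly the five merges", {
  atlas <- toy_ba_atlas()
  merged <- regroup_brodmann(atlas)
  expect_true(all(c("20*", "41*", "28*", "32*", "23*") %in% names(merged$units)))
  expect_equal(mask_size(merged$units[["20*"]]), 7 + 5)     # BA20 + BA38, disjoint
  expect_equal(mask_size(merged$units[["41*"]]),
               mask_size(atlas$units$BA41) + mask_size(atlas$units$BA42))
  consumed <- c("BA20", "BA38", "BA41", "BA42", "BA28", "BA34", "BA35", "BA36",
                "BA32", "BA24", "BA25", "BA23", "BA29", "BA30", "BA31")
  expect_false(any(consumed %in% names(merged$units)))
  ## pass-through areas untouched
  expect_identical(merged$units$BA17$values, atlas$units$BA17$values)
  ## idempotent
  expect_identical(names(regroup_brodmann(merged)$units), names(merged$units))
  expect_error(regroup_brodmann(toy_ba_atlas("BA34")), "configuration error.*BA34")
})

test_that("Brodmann families follow the seven published definitions", {
  atlas <- toy_ba_atlas()
  fams <- suppressMessages(brodmann_families(atlas))
  expect_identical(names(fams$units), paste0("BAF", 1:7))
  expect_equal(mask_size(fams$units$BAF7),
               sum(vapply(paste0("BA", 17:19), function(n) mask_size(atlas$units[[n]]), 1L)))
  expect_equal(mask_size(fams$units$BAF6),
               sum(vapply(paste0("BA", 2:6), function(n) mask_size(atlas$units[[n]]), 1L)))
  total_fam <- mask_size(ringscape:::mask_union(fams$units))
  total_in <- mask_size(ringscape:::mask_union(atlas$units))
  expect_lte(total_fam, total_in)
  expect_message(brodmann_families(atlas), "excluded")
  expect_error(brodmann_families(toy_ba_atlas("BA46")), "configuration error.*BA46")
})
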