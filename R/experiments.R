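## Self-contained benchmark experiments at the package's reference study
## conditions.  Tests and scripts/acceptance.R both call these, so the
## numbers they report are always produced by the same code path.

#' Planted-network recovery experiment for the group pipeline
#'
#' Simulates a population of subjects with three planted networks at
#' prevalences 0.6, 0.3 and 0.05 (per-voxel SNR 1), runs per-subject spatial
#' ICA and cross-subject clustering with the 10% representativeness rule,
#' and matches retained classes back to the planted footprints by centroid
#' correlation. The reference conditions are 50 subjects on a 12x12x6 grid,
#' 40 timepoints, K = 8 components.
#'
#' @param seed Integer seed.
#' @param n_subjects Population size; default 50.
#' @param prevalences Planted prevalences; default `c(0.6, 0.3, 0.05)`.
#' @param n_timepoints Timepoints per subject; default 40.
#' @param noise_sd Noise s.d.; with amplitude 1 this sets per-voxel SNR
#'   (default 1).
#' @param K Components per subject; default 8.
#' @param cut_similarity,min_R Group-clustering parameters (defaults 0.25,
#'   0.10).
#' @param match_threshold Centroid-to-footprint correlation above which a
#'   retained class counts as recovering a planted network; default 0.5.
#' @return A data frame with one row per planted network: `network`,
#'   `planted` (prevalence), `realized` (ground-truth inclusion fraction),
#'   `recovered` (logical), `R_est` (representativeness of the matching
#'   class, NA if none), `retained` (passed the 10% rule).
#' @export
recovery_experiment <- function(seed, n_subjects = 50L,
                                prevalences = c(0.6, 0.3, 0.05),
                                n_timepoints = 40L, noise_sd = 1, K = 8L,
                                cut_similarity = 0.25, min_R = 0.10,
                                match_threshold = 0.5) {
  grid <- volume_grid(c(12L, 12L, 6L))
  slab <- function(x0, x1) {
    v <- array(FALSE, grid$shape)
    v[x0:x1, 3:10, 2:5] <- TRUE
    binary_mask(grid, v)
  }
  xs <- list(c(1L, 4L), c(5L, 8L), c(9L, 12L))
  networks <- lapply(seq_along(prevalences), function(j) {
    network_spec(paste0("net", j), slab(xs[[j]][1], xs[[j]][2]),
                 prevalence = prevalences[j], amplitude = 1)
  })
  sim <- simulate_subjects(networks, n_subjects, n_timepoints, noise_sd,
                           seed = derive_seed(seed, 11L))
  brain <- binary_mask(grid, array(TRUE, grid$shape))
  comps <- list()
  for (s in seq_len(n_subjects)) {
    comps <- c(comps, decompose_subject(sim$subjects[[s]], brain, K,
                                        seed = derive_seed(seed, 500L + s),
                                        subject_id = sprintf("s%03d", s),
                                        ica_restarts = 1L))
  }
  classes <- cluster_components(comps, cut_similarity, n_subjects = n_subjects)
  retained <- select_representative(classes, min_R)
  fmat <- vapply(networks, function(n) as.double(n$footprint$values),
                 numeric(prod(grid$shape)))
  out <- data.frame(
    network = vapply(networks, `[[`, "", "name"),
    planted = prevalences,
    realized = colMeans(sim$presence),
    recovered = FALSE, R_est = NA_real_, retained = FALSE
  )
  for (j in seq_along(networks)) {
    best <- match_threshold; best_R <- NA_real_
    for (r in retained) {
      centroid <- rowMeans(vapply(r$members, `[[`,
                                  numeric(length(r$members[[1]]$zmap)), "zmap"))
      cc <- stats::cor(centroid, fmat[, j])
      if (is.finite(cc) && cc > best) { best <- cc; best_R <- r$representativeness }
    }
    if (!is.na(best_R)) {
      out$recovered[j] <- TRUE
      out$R_est[j] <- best_R
      out$retained[j] <- TRUE
    }
  }
  out
}

#' Model-order sweep of the mixture clustering on a bundled fixture
#'
#' Regenerates the bundled block fixture for each seed and records the model
#' order chosen by the BIC scan.
#'
#' @param reference `"tbn"`, `"ba"` or `"baf"` (see
#'   [bundled_overlap_fixture()]).
#' @param seeds Integer vector of seeds (fixture and fit seeds derive from
#'   each entry).
#' @param max_components,restarts Passed to [em_mixture_cluster()].
#' @return Integer vector of selected orders, one per seed.
#' @export
model_order_sweep <- function(reference, seeds, max_components = 12L, restarts = 10L) {
  vapply(seeds, function(s) {
    m <- bundled_overlap_fixture(reference, seed = s)
    em_mixture_cluster(m, max_components, restarts,
                       seed = derive_seed(s, 77L))$n_clusters
  }, integer(1))
}

#' Family concordance on the bundled membership tables
#'
#' Builds the three bundled overlap fixtures, converts the bundled printed
#' membership tables to hard clusterings, and runs [assign_families()].
#'
#' @param seed Seed for the fixture matrices; default 1.
#' @param margin Intermediate margin; default 0.30.
#' @return The [assign_families()] family model.
#' @export
concordance_experiment <- function(seed = 1L, margin = 0.30) {
  parts <- lapply(c(tbn = "tbn", ba = "ba", baf = "baf"), function(ref) {
    m <- bundled_overlap_fixture(ref, seed = seed)
    list(m = m, cl = membership_to_clustering(attr(m, "table")),
         sens = attr(m, "sensory"))
  })
  assign_families(
    clusterings = lapply(parts, `[[`, "cl"),
    matrices = lapply(parts, `[[`, "m"),
    sensory_units = lapply(parts, `[[`, "sens"),
    margin = margin
  )
}

#' Ring-topology report of the reference phantom
#'
#' Builds the default 16x16x4 phantom parcellation and reports the planted
#' family topology: VSA continuity and sector cycle, PTF discontinuity,
#' island enclosure, mirror symmetry.
#'
#' @param seed Phantom seed; default 1 (the layout is deterministic).
#' @return A [ring_report()].
#' @export
phantom_ring_experiment <- function(seed = 1L) {
  phantom <- make_phantom_atlas(volume_grid(c(16L, 16L, 4L)), seed = seed)
  layout <- attr(phantom, "layout")
  ring_report(
    vsa_masks = phantom$units[layout$ring],
    ptf_masks = phantom$units[c(layout$island, layout$scattered)],
    island = phantom$units[[layout$island]],
    domain = layout$domain
  )
}
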