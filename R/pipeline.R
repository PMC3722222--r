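#' Pipeline configuration
#'
#' Assembles (or loads from YAML) the full parameter set of the synthetic
#' end-to-end run, with explicit defaults for every stage so that a config
#' round-trips losslessly and two runs from the same config are identical.
#'
#' @param ... Named overrides of the defaults, or a single `file` argument
#'   naming a YAML file of overrides.
#' @return An object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(...) {
  args <- list(...)
  if (!is.null(args$file)) {
    overrides <- yaml::read_yaml(args$file)
    args$file <- NULL
    args <- utils::modifyList(overrides, args)
  }
  defaults <- list(
    seed = 1L,
    grid_shape = c(16L, 16L, 4L),
    n_subjects = 30L,
    n_timepoints = 40L,
    noise_sd = 1,
    amplitude = 1,
    prevalence = 0.9,
    K = 10L,
    cut_similarity = 0.25,
    min_R = 0.10,
    q = 0.05,
    max_components = 12L,
    restarts = 10L,
    connectivity = 6L,
    margin = 0.30,
    n_scattered = 4L,
    out_dir = NULL,
    write_volumes = TRUE
  )
  unknown <- setdiff(names(args), names(defaults))
  if (length(unknown) > 0L) {
    stop_config("unknown config field(s): %s", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, args)
  structure(cfg, class = "pipeline_config")
}

#' Write a pipeline config as YAML
#' @param config A [pipeline_config()].
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

## Cheap stable content hash (FNV-1a over the deparsed object) for manifests.
## Output paths are excluded: two runs of the same analysis into different
## directories are the same computation.
config_hash <- function(x) {
  x <- unclass(x)
  x$out_dir <- NULL
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 2166136261 %% 2^31
  for (b in bytes) h <- ((bitwXor(as.integer(h), b)) * 16777619) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' Run the full synthetic corticotopy pipeline
#'
#' Executes simulate -> per-subject ICA -> group clustering with the 10%
#' rule and FDR t-maps -> overlap matrix against the phantom parcellation ->
#' mixture clustering plus community detection -> family assignment -> ring
#' topology report, writing every stage's artifacts and a machine-readable
#' summary under `config$out_dir`. The phantom's planted families also get
#' a ground-truth ring report, so recovered and planted topology can be
#' compared. Identical configs produce identical summaries.
#'
#' @param config A [pipeline_config()]; `out_dir` is required.
#' @return The summary, invisibly (a named list, also written as
#'   `summary.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  for (field in c("out_dir")) {
    if (is.null(config[[field]])) stop_config("config missing field '%s'", field)
  }
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  grid <- volume_grid(config$grid_shape)
  seed <- as.integer(config$seed)

  ## stage 1: phantom parcellation + ground truth
  phantom <- make_phantom_atlas(grid, list(n_scattered = config$n_scattered),
                                seed = derive_seed(seed, 1L))
  layout <- attr(phantom, "layout")
  if (config$write_volumes) write_atlas(phantom, file.path(out, "phantom_atlas.nii.gz"))

  ## stage 2: subjects with planted networks
  networks <- lapply(names(phantom$units), function(nm) {
    network_spec(nm, phantom$units[[nm]], prevalence = config$prevalence,
                 amplitude = config$amplitude)
  })
  sim <- simulate_subjects(networks, config$n_subjects, config$n_timepoints,
                           config$noise_sd, seed = derive_seed(seed, 2L))
  if (config$write_volumes) {
    for (s in seq_along(sim$subjects)) {
      write_volume(grid, sim$subjects[[s]],
                   file.path(out, sprintf("subject_%02d.nii.gz", s)))
    }
  }

  ## stage 3: per-subject spatial ICA
  brain <- binary_mask(grid, array(TRUE, grid$shape))
  components <- list()
  for (s in seq_along(sim$subjects)) {
    maps <- decompose_subject(sim$subjects[[s]], brain, config$K,
                              seed = derive_seed(seed, 100L + s),
                              subject_id = sprintf("s%02d", s))
    components <- c(components, maps)
  }

  ## stage 4: group classes, 10% rule, FDR masks
  classes <- cluster_components(components, config$cut_similarity,
                                n_subjects = config$n_subjects)
  classes <- lapply(classes, function(cl) {
    if (length(cl$members) >= 2L) group_tmap(cl, config$q) else cl
  })
  rsns <- select_representative(classes, config$min_R)
  if (length(rsns) < 2L) {
    stop_statistics("pipeline retained %d classes; need >= 2 to continue", length(rsns))
  }
  manifest_rsn <- data.frame(
    rank = vapply(rsns, `[[`, 1L, "rank"),
    R = vapply(rsns, `[[`, 1, "representativeness"),
    n_members = vapply(rsns, function(r) length(r$members), 1L),
    mask_size = vapply(rsns, function(r) mask_size(r$mask), 1L)
  )
  utils::write.table(manifest_rsn, file.path(out, "rsn_manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (config$write_volumes) {
    for (r in rsns) write_mask(r$mask, file.path(out, sprintf("rsn_%02d.nii.gz", r$rank)))
  }

  ## stage 5: overlap matrix against the phantom units
  names(rsns) <- vapply(rsns, function(r) as.character(r$rank), "")
  ov <- build_overlap_matrix(rsns, phantom)
  write_overlap_matrix(ov, file.path(out, "rsn_x_phantom.tsv"))

  ## stage 6: mixture clustering and community detection on the profiles
  em <- em_mixture_cluster(ov, config$max_components, config$restarts,
                           seed = derive_seed(seed, 3L))
  graph <- profile_graph(ov)
  comm <- detect_communities(graph)
  conc <- concordance_accuracy(em, comm)

  ## stage 7: families from the two clustering routes
  sensory <- layout$ring
  fam <- assign_families(
    clusterings = list(mixture = em, community = comm),
    matrices = list(mixture = ov, community = ov),
    sensory_units = list(mixture = sensory, community = sensory),
    margin = config$margin
  )

  ## stage 8: ring topology, planted and recovered
  planted_report <- ring_report(
    vsa_masks = phantom$units[layout$ring],
    ptf_masks = phantom$units[c(layout$island, layout$scattered)],
    island = phantom$units[[layout$island]],
    domain = layout$domain,
    connectivity = config$connectivity
  )
  ## map each recovered RSN to its best phantom unit to order VSA sectors
  best_unit <- names(phantom$units)[apply(unclass(ov), 1, which.max)]
  vsa_rsns <- names(fam$rsn_family)[fam$rsn_family == "VSA"]
  ptf_rsns <- names(fam$rsn_family)[fam$rsn_family != "VSA"]
  recovered_report <- NULL
  if (length(vsa_rsns) >= 3L && length(ptf_rsns) >= 1L) {
    sector_of <- stats::setNames(best_unit, rownames(ov))[vsa_rsns]
    ord <- order(match(sector_of, layout$ring))
    vsa_masks <- stats::setNames(lapply(rsns[vsa_rsns], `[[`, "mask"), vsa_rsns)[ord]
    ptf_masks <- stats::setNames(lapply(rsns[ptf_rsns], `[[`, "mask"), ptf_rsns)
    recovered_report <- tryCatch(
      ring_report(vsa_masks, ptf_masks, connectivity = config$connectivity),
      error = function(e) NULL
    )
  }

  summary <- list(
    config_hash = config_hash(config),
    seed = seed,
    n_components = length(components),
    n_classes = length(classes),
    n_retained = length(rsns),
    representativeness = stats::setNames(manifest_rsn$R, manifest_rsn$rank),
    n_clusters_mixture = em$n_clusters,
    n_communities = length(unique(comm$assignment)),
    modularity_Q = comm$modularity_Q,
    concordance_accuracy = conc$accuracy,
    families = as.list(fam$rsn_family),
    planted_ring = list(
      n_components_vsa = planted_report$n_components_vsa,
      n_components_ptf = planted_report$n_components_ptf,
      enclosure_found = planted_report$enclosure_found,
      sector_cycle = planted_report$sector_cycle,
      symmetry = as.list(planted_report$symmetry)
    ),
    recovered_ring = if (is.null(recovered_report)) NULL else list(
      n_components_vsa = recovered_report$n_components_vsa,
      n_components_ptf = recovered_report$n_components_ptf,
      sector_cycle = recovered_report$sector_cycle,
      symmetry = as.list(recovered_report$symmetry)
    )
  )
  manifest <- list(parameters = unclass(config), derived_seeds = list(
    phantom = derive_seed(seed, 1L), subjects = derive_seed(seed, 2L),
    mixture = derive_seed(seed, 3L)
  ), config_hash = config_hash(config))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(summary)
}
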