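#' Cross-subject RSN class
#'
#' A class of matching spatial components across subjects: at most one
#' component per subject, a representativeness score R (member count over
#' subject count), a group t-map with its FDR-thresholded mask, and a rank.
#'
#' @param members Named list of [component_map()] objects, one per subject
#'   (names are subject ids).
#' @param n_subjects Total subjects in the population.
#' @param creation_index Index recording class creation order (tie-break).
#' @return An object of class `rsn_class` with fields `members`,
#'   `representativeness`, `tmap` (NULL until [group_tmap()]), `mask`,
#'   `rank` (NA until [select_representative()]), and `creation_index`.
#' @export
rsn_class <- function(members, n_subjects, creation_index = NA_integer_) {
  ids <- vapply(members, function(m) as.character(m$subject_id), "")
  if (anyDuplicated(ids)) {
    stop_validation("an RSN class may keep at most one component per subject")
  }
  names(members) <- ids
  structure(list(members = members,
                 representativeness = length(members) / n_subjects,
                 n_subjects = n_subjects,
                 tmap = NULL, mask = NULL, rank = NA_integer_,
                 creation_index = as.integer(creation_index)),
            class = "rsn_class")
}

#' @export
print.rsn_class <- function(x, ...) {
  cat(sprintf("<rsn_class rank %s, R = %.3f (%d/%d subjects)%s>\n",
              ifelse(is.na(x$rank), "?", x$rank), x$representativeness,
              length(x$members), x$n_subjects,
              if (!is.null(x$mask)) sprintf(", mask %d voxels", mask_size(x$mask)) else ""))
  invisible(x)
}

#' Spatial similarity between two component maps
#'
#' Pearson correlation of the z-maps over the shared brain mask. Symmetric,
#' 1 for a map with itself, -1 for a map and its negation.
#'
#' @param a,b [component_map()] objects on the same grid and brain mask.
#' @return Correlation in \[-1, 1\].
#' @export
spatial_similarity <- function(a, b) {
  stopifnot(inherits(a, "component_map"), inherits(b, "component_map"))
  check_same_grid(a$brain_mask$grid, b$brain_mask$grid, "component maps")
  if (!identical(a$brain_mask$values, b$brain_mask$values)) {
    stop_validation("component maps use different brain masks")
  }
  stats::cor(a$zmap, b$zmap)
}

#' Cluster component maps across subjects into RSN classes
#'
#' Average-linkage agglomeration on distance 1 - similarity (Pearson
#' correlation of z-maps), with the tree cut where linkage distance exceeds
#' 1 - `cut_similarity`. Every component is assigned to exactly one
#' pre-threshold class; within a class, a subject contributing several
#' components keeps only the one most similar to the class centroid as
#' member, so class representativeness counts subjects, not components.
#'
#' @param components List of [component_map()] objects from >= 2 subjects.
#' @param cut_similarity Similarity threshold in (0, 1); default 0.25.
#' @param n_subjects Total population size; defaults to the number of
#'   distinct subject ids present.
#' @return List of [rsn_class()] objects (pre-threshold, unranked), each
#'   with an `assigned` attribute listing the indices of all components in
#'   the class.
#' @export
cluster_components <- function(components, cut_similarity = 0.25, n_subjects = NULL) {
  if (length(components) < 1L) stop_validation("no components supplied")
  subj <- vapply(components, function(m) as.character(m$subject_id), "")
  if (is.null(n_subjects)) n_subjects <- length(unique(subj))
  if (length(unique(subj)) < 2L) stop_validation("need components from >= 2 subjects")
  if (cut_similarity <= 0 || cut_similarity >= 1) {
    stop_validation("cut_similarity must be in (0, 1)")
  }
  Z <- vapply(components, `[[`, numeric(length(components[[1]]$zmap)), "zmap")
  S <- stats::cor(Z)
  d <- stats::as.dist(1 - S)
  if (length(components) == 1L) {
    cl <- 1L
  } else {
    hc <- stats::hclust(d, method = "average")
    cl <- stats::cutree(hc, h = 1 - cut_similarity)
  }
  classes <- list()
  for (k in sort(unique(cl))) {
    idx <- which(cl == k)
    centroid <- rowMeans(Z[, idx, drop = FALSE])
    keep <- integer(0)
    for (s in unique(subj[idx])) {
      cand <- idx[subj[idx] == s]
      if (length(cand) > 1L) {
        sim <- apply(Z[, cand, drop = FALSE], 2, stats::cor, y = centroid)
        cand <- cand[which.max(sim)]
      }
      keep <- c(keep, cand)
    }
    cls <- rsn_class(components[keep], n_subjects, creation_index = length(classes) + 1L)
    attr(cls, "assigned") <- idx
    classes[[length(classes) + 1L]] <- cls
  }
  classes
}

#' Retain representative classes and rank them
#'
#' Keeps exactly the classes whose representativeness R is at least `min_R`
#' (the "10% rule" by default) and assigns ranks by decreasing R, breaking
#' ties by larger mask size (0 if no mask yet), then lower creation index.
#'
#' @param classes List of [rsn_class()] objects.
#' @param min_R Minimum representativeness in (0, 1]; default 0.10.
#' @return Ranked list of retained [rsn_class()] objects (possibly empty),
#'   ordered by rank.
#' @export
select_representative <- function(classes, min_R = 0.10) {
  if (!is.numeric(min_R) || min_R < 0 || min_R > 1) {
    stop_validation("min_R must be in [0, 1]")
  }
  R <- vapply(classes, `[[`, 1, "representativeness")
  keep <- which(R + 1e-12 >= min_R)
  if (length(keep) == 0L) return(list())
  msize <- vapply(classes[keep], function(c) {
    if (is.null(c$mask)) 0L else mask_size(c$mask)
  }, 1L)
  cidx <- vapply(classes[keep], `[[`, 1L, "creation_index")
  ord <- order(-R[keep], -msize, cidx)
  out <- classes[keep][ord]
  for (i in seq_along(out)) out[[i]]$rank <- i
  out
}

## Benjamini-Hochberg rejection set at level q (via the adjusted p-values of
## stats::p.adjust, which implements the step-up rule).
bh_reject <- function(p, q) {
  stats::p.adjust(p, method = "BH") <= q
}

#' Group t-map and FDR-thresholded mask of an RSN class
#'
#' Voxelwise one-sample t statistic of the member z-maps against zero,
#' one-sided p-values, Benjamini-Hochberg control at level `q` over in-brain
#' voxels. Zero-variance voxels are handled exactly: a strictly positive
#' mean gives p = 0 (t = +Inf), a zero mean gives t = 0 (p = 1/2), a
#' negative mean gives p = 1, so degenerate noiseless inputs behave.
#'
#' @param cls An [rsn_class()] with >= 2 members.
#' @param q FDR level, default 0.05.
#' @return The class with `tmap` (in-brain t values) and `mask`
#'   ([binary_mask()] of surviving voxels) filled in.
#' @export
group_tmap <- function(cls, q = 0.05) {
  stopifnot(inherits(cls, "rsn_class"))
  n <- length(cls$members)
  if (n < 2L) stop_statistics("group t-map needs >= 2 members, have %d", n)
  Z <- vapply(cls$members, `[[`, numeric(length(cls$members[[1]]$zmap)), "zmap")
  mu <- rowMeans(Z)
  sdv <- apply(Z, 1, stats::sd)
  tv <- ifelse(sdv > 0, mu / (sdv / sqrt(n)),
               ifelse(mu > 0, Inf, ifelse(mu < 0, -Inf, 0)))
  p <- ifelse(is.finite(tv), stats::pt(tv, df = n - 1, lower.tail = FALSE),
              ifelse(tv > 0, 0, 1))
  surv <- bh_reject(p, q)
  brain <- cls$members[[1]]$brain_mask
  vals <- array(FALSE, brain$grid$shape)
  vals[brain$values] <- surv
  cls$tmap <- tv
  cls$mask <- binary_mask(brain$grid, vals)
  cls
}

#' Match RSN sets between two populations
#'
#' Greedy one-to-one matching of thresholded masks by decreasing Jaccard
#' overlap; the similarity rate of a matched pair is the Jaccard index
#' |A and B| / |A or B| expressed in percent. Unmatched leftovers are
#' reported with NA partner and 0 rate.
#'
#' @param rsnsA,rsnsB Ranked lists of [rsn_class()] objects with masks, on a
#'   shared grid.
#' @return A data frame with columns `rankA`, `rankB`, `similarity_pct`.
#' @export
match_populations <- function(rsnsA, rsnsB) {
  if (length(rsnsA) < 1L || length(rsnsB) < 1L) {
    stop_validation("both RSN lists must be non-empty")
  }
  for (r in c(rsnsA, rsnsB)) {
    if (is.null(r$mask)) stop_validation("all classes need thresholded masks")
  }
  check_same_grid(rsnsA[[1]]$mask$grid, rsnsB[[1]]$mask$grid, "populations")
  J <- matrix(0, length(rsnsA), length(rsnsB))
  for (i in seq_along(rsnsA)) {
    for (j in seq_along(rsnsB)) {
      inter <- shared_voxels(rsnsA[[i]]$mask, rsnsB[[j]]$mask)
      uni <- mask_size(rsnsA[[i]]$mask) + mask_size(rsnsB[[j]]$mask) - inter
      J[i, j] <- if (uni > 0) inter / uni else 0
    }
  }
  rank_of <- function(r, i) if (is.na(r$rank)) i else r$rank
  out <- data.frame(rankA = integer(0), rankB = integer(0), similarity_pct = numeric(0))
  avail_a <- seq_along(rsnsA); avail_b <- seq_along(rsnsB)
  while (length(avail_a) > 0L && length(avail_b) > 0L) {
    sub <- J[avail_a, avail_b, drop = FALSE]
    best <- arrayInd(which.max(sub), dim(sub))
    i <- avail_a[best[1]]; j <- avail_b[best[2]]
    out <- rbind(out, data.frame(rankA = rank_of(rsnsA[[i]], i),
                                 rankB = rank_of(rsnsB[[j]], j),
                                 similarity_pct = 100 * J[i, j]))
    avail_a <- setdiff(avail_a, i); avail_b <- setdiff(avail_b, j)
  }
  for (i in avail_a) {
    out <- rbind(out, data.frame(rankA = rank_of(rsnsA[[i]], i), rankB = NA,
                                 similarity_pct = 0))
  }
  for (j in avail_b) {
    out <- rbind(out, data.frame(rankA = NA, rankB = rank_of(rsnsB[[j]], j),
                                 similarity_pct = 0))
  }
  out
}
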