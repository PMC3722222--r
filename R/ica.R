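#' Spatial component map of one subject
#'
#' One spatial map from a subject's ICA decomposition, z-scored over the
#' in-brain mask (mean 0, s.d. 1) with sign fixed so that the map skewness is
#' non-negative ("activation" is positive).
#'
#' @param subject_id Subject identifier.
#' @param index Component number within the subject's decomposition.
#' @param zmap Numeric vector of in-brain voxel values (z units).
#' @param brain_mask [binary_mask()] the map is defined over.
#' @return An object of class `component_map`.
#' @export
component_map <- function(subject_id, index, zmap, brain_mask) {
  stopifnot(inherits(brain_mask, "binary_mask"))
  if (length(zmap) != mask_size(brain_mask)) {
    stop_validation("zmap has %d values but mask has %d voxels",
                    length(zmap), mask_size(brain_mask))
  }
  if (any(!is.finite(zmap))) stop_validation("component map must be finite")
  if (abs(mean(zmap)) > 1e-6 || abs(stats::sd(zmap) - 1) > 1e-6) {
    stop_validation("component map must be z-scored over the brain mask")
  }
  structure(list(subject_id = subject_id, index = as.integer(index),
                 zmap = as.double(zmap), brain_mask = brain_mask),
            class = "component_map")
}

#' @export
print.component_map <- function(x, ...) {
  cat(sprintf("<component_map subject %s #%d, %d voxels>\n",
              x$subject_id, x$index, length(x$zmap)))
  invisible(x)
}

## z-score a vector to machine precision (two-pass for numerical safety)
zscore <- function(x) {
  x <- x - mean(x)
  s <- sqrt(sum(x^2) / (length(x) - 1))
  if (s == 0) stop_statistics("cannot z-score a constant map")
  x / s
}

sample_skewness <- function(x) {
  x <- x - mean(x)
  m2 <- mean(x^2)
  if (m2 == 0) return(0)
  mean(x^3) / m2^1.5
}

## Fixed-point (FastICA-style) estimation of an orthogonal unmixing rotation
## in the whitened space, with the tanh contrast and symmetric decorrelation.
## The symmetric fixed-point map has saddle points (mixtures of
## similarly-distributed sources), so several seeded initial rotations are
## run and the one with the largest negentropy proxy is kept.
fastica_rotation <- function(Y, K, max_iter = 500L, tol = 1e-5, restarts = 5L) {
  n <- nrow(Y)
  sym_decorrelate <- function(W) {
    e <- eigen(W %*% t(W), symmetric = TRUE)
    solve_sqrt <- e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-12)), K) %*% t(e$vectors)
    solve_sqrt %*% W
  }
  logcosh_gauss <- 0.3745672     # E[log cosh(Z)] for standard normal Z
  best_W <- NULL; best_score <- -Inf
  for (r in seq_len(restarts)) {
    W <- sym_decorrelate(qr.Q(qr(matrix(stats::rnorm(K * K), K, K))))
    for (iter in seq_len(max_iter)) {
      S <- Y %*% t(W)            # n x K source estimates
      G <- tanh(S)
      Gp <- colMeans(1 - G^2)    # E[g'(s)] per component
      W_new <- crossprod(G, Y) / n - diag(Gp, K) %*% W
      W_new <- sym_decorrelate(W_new)
      delta <- max(abs(1 - abs(rowSums(W_new * W))))
      W <- W_new
      if (delta < tol) break
    }
    S <- Y %*% t(W)
    score <- sum((colMeans(log(cosh(S))) - logcosh_gauss)^2)
    if (score > best_score) { best_score <- score; best_W <- W }
  }
  best_W
}

#' Decompose a subject's 4D series into spatial independent components
#'
#' Spatial ICA of one subject: the in-brain voxel-by-time matrix is centred,
#' whitened by truncated SVD to `K` dimensions, and rotated by fixed-point
#' negentropy maximisation (tanh contrast, symmetric decorrelation, seeded
#' initial rotation, at most 500 iterations, tolerance 1e-5). Each resulting
#' spatial map is z-scored over the brain mask and sign-flipped to
#' non-negative skewness, making the maps and their one-sided thresholding
#' reproducible.
#'
#' @param series 4D numeric array (x, y, z, t) on the mask's grid.
#' @param brain_mask [binary_mask()] of in-brain voxels.
#' @param K Number of components; must not exceed the number of timepoints
#'   nor of in-brain voxels.
#' @param seed Integer seed for the initial rotation.
#' @param subject_id Identifier attached to the returned maps.
#' @param ica_restarts Seeded initial rotations tried by the fixed-point
#'   iteration (the best by negentropy proxy is kept); default 3. One is
#'   usually enough at population scale, where cross-subject clustering
#'   absorbs occasional per-subject convergence misses.
#' @return List of `K` [component_map()] objects; pairwise spatial
#'   correlations are zero to numerical precision.
#' @export
decompose_subject <- function(series, brain_mask, K, seed, subject_id = "s1",
                              ica_restarts = 3L) {
  series <- as.array(series)
  if (length(dim(series)) != 4L) stop_validation("series must be a 4D array")
  if (!all(dim(series)[1:3] == brain_mask$grid$shape)) {
    stop_validation("series dimensions %s do not match grid %s",
                    paste(dim(series), collapse = "x"), format(brain_mask$grid))
  }
  if (any(!is.finite(series))) stop_validation("series must be finite")
  n_t <- dim(series)[4]
  nvox <- mask_size(brain_mask)
  if (!is_count(K) || K > min(n_t, nvox)) {
    stop_config("K = %s must be a count <= min(n_timepoints = %d, n_voxels = %d)",
                K, n_t, nvox)
  }
  X <- matrix(series, ncol = n_t)[as.vector(brain_mask$values), , drop = FALSE]
  X <- sweep(X, 2, colMeans(X))          # centre each timepoint map
  X <- X - rowMeans(X)                   # and each voxel's time series
  sv <- svd(X, nu = K, nv = 0)
  if (sv$d[K] < 1e-10 * max(sv$d[1], 1e-300) || sv$d[1] == 0) {
    stop_statistics("series is degenerate: rank below K = %d", K)
  }
  Y <- sv$u * sqrt(nvox - 1)             # whitened: unit-variance, orthogonal
  W <- with_seed(seed, fastica_rotation(Y, K, restarts = ica_restarts))
  S <- Y %*% t(W)
  maps <- lapply(seq_len(K), function(k) {
    z <- zscore(S[, k])
    if (sample_skewness(z) < 0) z <- -z
    component_map(subject_id, k, z, brain_mask)
  })
  maps
}

#' Variance explained by the leading K-dimensional subspace of a series
#'
#' Utility for checking decomposition adequacy; monotone non-decreasing in K.
#'
#' @inheritParams decompose_subject
#' @return Fraction of (voxel- and time-centred) variance captured.
#' @export
subspace_variance <- function(series, brain_mask, K) {
  series <- as.array(series)
  n_t <- dim(series)[4]
  X <- matrix(series, ncol = n_t)[as.vector(brain_mask$values), , drop = FALSE]
  X <- sweep(X, 2, colMeans(X))
  X <- X - rowMeans(X)
  d2 <- svd(X, nu = 0, nv = 0)$d^2
  sum(d2[seq_len(min(K, length(d2)))]) / sum(d2)
}
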