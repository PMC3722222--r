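#' Clustering result of overlap profiles
#'
#' @param assignment Named vector/factor: row label -> cluster id (1..k).
#' @param responsibilities Row x cluster matrix of posterior weights (rows
#'   sum to 1); one-hot for hard partitions.
#' @param log_evidence Model score; for the mixture fit, -BIC/2 of the
#'   selected model.
#' @param loglik Maximised log-likelihood (NA for hard partitions).
#' @return An object of class `clustering_result` with `assignment`,
#'   `n_clusters` (non-empty clusters), `responsibilities`, `log_evidence`.
#' @export
clustering_result <- function(assignment, responsibilities = NULL,
                              log_evidence = NA_real_, loglik = NA_real_) {
  labs <- names(assignment)
  if (is.null(labs)) stop_validation("assignment must be named by row label")
  assignment <- as.integer(as.factor(assignment))
  names(assignment) <- labs
  if (is.null(responsibilities)) {
    k <- max(assignment)
    responsibilities <- matrix(0, length(assignment), k,
                               dimnames = list(labs, NULL))
    responsibilities[cbind(seq_along(assignment), assignment)] <- 1
  }
  if (max(abs(rowSums(responsibilities) - 1)) > 1e-8) {
    stop_validation("responsibility rows must sum to 1")
  }
  structure(list(assignment = assignment,
                 n_clusters = length(unique(assignment)),
                 responsibilities = responsibilities,
                 log_evidence = log_evidence,
                 loglik = loglik),
            class = "clustering_result")
}

#' @export
print.clustering_result <- function(x, ...) {
  cat(sprintf("<clustering_result: %d rows in %d clusters>\n",
              length(x$assignment), x$n_clusters))
  invisible(x)
}

#' Convert a membership table to a hard clustering result
#' @param table A duplicate-free [membership_table()].
#' @return A [clustering_result()] with one-hot responsibilities.
#' @export
membership_to_clustering <- function(table) {
  asg <- membership_assignment(table)
  clustering_result(stats::setNames(match(asg, names(table$clusters)), names(asg)))
}

## One EM fit of a diagonal-covariance Gaussian mixture.  Means initialised
## on k distinct data rows (seeded k-means++ style spread), variances on the
## data variance; relative log-likelihood tolerance 1e-8, at most 1000
## iterations.  The log-likelihood is non-decreasing across iterations by
## construction of EM.  The variance floor (1e-2, i.e. 1% of the variance of
## the column-standardised data) regularises the likelihood: without it,
## components collapsing onto single rows make the likelihood unbounded and
## the BIC order scan degenerates to the cap.
em_fit <- function(X, k, var_floor = 1e-2, tol = 1e-8, max_iter = 1000L,
                   trace = FALSE) {
  n <- nrow(X); d <- ncol(X)
  ll_path <- numeric(0)
  ## spread initial means over the data (k-means++ seeding)
  centers <- matrix(0, k, d)
  first <- sample.int(n, 1L)
  centers[1, ] <- X[first, ]
  if (k > 1L) {
    for (j in 2:k) {
      d2 <- apply(X, 1, function(r) {
        min(colSums((t(centers[1:(j - 1), , drop = FALSE]) - r)^2))
      })
      if (sum(d2) == 0) {
        centers[j, ] <- X[sample.int(n, 1L), ]
      } else {
        centers[j, ] <- X[sample.int(n, 1L, prob = d2), ]
      }
    }
  }
  vars <- matrix(pmax(apply(X, 2, stats::var), var_floor), k, d, byrow = TRUE)
  w <- rep(1 / k, k)
  loglik <- -Inf
  for (iter in seq_len(max_iter)) {
    ## E step: log densities, row-wise soft-max
    logd <- vapply(seq_len(k), function(j) {
      -0.5 * colSums((t(X) - centers[j, ])^2 / vars[j, ]) -
        0.5 * sum(log(2 * pi * vars[j, ])) + log(w[j])
    }, numeric(n))
    m <- apply(logd, 1, max)
    pr <- exp(logd - m)
    rs <- rowSums(pr)
    ll <- sum(m + log(rs))
    if (trace) ll_path <- c(ll_path, ll)
    resp <- pr / rs
    ## M step
    nk <- colSums(resp)
    nk <- pmax(nk, 1e-12)
    w <- nk / n
    centers <- crossprod(resp, X) / nk
    for (j in seq_len(k)) {
      diff2 <- sweep(X, 2, centers[j, ])^2
      vars[j, ] <- pmax(colSums(resp[, j] * diff2) / nk[j], var_floor)
    }
    if (is.finite(loglik) && ll - loglik < tol * abs(ll)) {
      loglik <- ll
      break
    }
    loglik <- ll
  }
  npar <- (k - 1) + 2 * k * d
  bic <- -2 * loglik + npar * log(n)
  out <- list(loglik = loglik, bic = bic, resp = resp, k = k)
  if (trace) out$ll_path <- ll_path
  out
}

#' Cluster overlap profiles with a Gaussian mixture and automatic order
#'
#' Rows (network overlap profiles) are standardised per column, then a
#' diagonal-covariance Gaussian mixture is fitted by EM at every model order
#' k = 1..`max_components` with `restarts` seeded initialisations each; the
#' order is chosen by minimum BIC and empty clusters (no row assigned by
#' maximum responsibility) are removed. Deterministic given `seed`.
#'
#' @param matrix An [overlap_matrix()] (or plain named numeric matrix) with
#'   >= 2 rows.
#' @param max_components Largest model order scanned (capped at the row
#'   count); default 12.
#' @param restarts Seeded EM initialisations per order; default 10.
#' @param seed Integer seed.
#' @param var_floor Per-dimension variance floor, as a fraction of the unit
#'   column variance after standardisation; default 1e-2 (regularises
#'   against single-row spike components).
#' @return A [clustering_result()]; `log_evidence` is -BIC/2 of the
#'   selected model.
#' @export
em_mixture_cluster <- function(matrix, max_components = 12L, restarts = 10L, seed = 1L,
                               var_floor = 1e-2) {
  X <- unclass(matrix)
  storage.mode(X) <- "double"
  if (any(!is.finite(X))) stop_validation("overlap matrix must be finite")
  if (nrow(X) < 2L) stop_validation("need at least 2 rows to cluster")
  max_components <- min(max_components, nrow(X))
  if (!is_count(max_components) || !is_count(restarts)) {
    stop_validation("max_components and restarts must be positive counts")
  }
  labs <- rownames(X) %||% as.character(seq_len(nrow(X)))
  ## standardise per column; constant columns carry no signal and are zeroed
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  best <- NULL
  for (k in seq_len(max_components)) {
    for (r in seq_len(restarts)) {
      fit <- with_seed(derive_seed(seed, k * 1000L + r),
                       em_fit(Xs, k, var_floor = var_floor))
      if (is.null(best) || fit$bic < best$bic - 1e-9) best <- fit
    }
  }
  asg <- max.col(best$resp, ties.method = "first")
  used <- sort(unique(asg))
  asg <- match(asg, used)                 # drop empty clusters, renumber
  resp <- best$resp[, used, drop = FALSE]
  resp <- resp / rowSums(resp)
  rownames(resp) <- labs
  clustering_result(stats::setNames(asg, labs), resp,
                    log_evidence = -best$bic / 2, loglik = best$loglik)
}
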