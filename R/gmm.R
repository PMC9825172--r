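# Model-based clustering of Fourier features: Gaussian mixture with full
# covariances fitted by EM (compiled core), BIC model selection over a K
# range, and relabeling against a reference cohort classification.

#' Fit a Gaussian mixture model to Fourier features
#'
#' EM with full covariance matrices and a ridge of
#' `ridge_scale * trace(S)/d` on each covariance update. The best of
#' `n_restarts` seeded random initializations (by log-likelihood) is
#' returned; results are deterministic given `seed`.
#'
#' @param features a `fourier_features` object or a numeric matrix.
#' @param K number of mixture components.
#' @param n_restarts number of random restarts (default 20).
#' @param seed integer seed; mandatory.
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   convergence tolerance.
#' @param ridge_scale covariance ridge scale (default 1e-6).
#' @return Object of class `mixture_model`: `K`, `weights`, `means`
#'   (K x d), `covs` (d x d x K), `loglik`, `bic` (= 2 logL - p ln n,
#'   maximized), `labels` (hard assignment, named by gene id),
#'   `converged`, `n_restarts`, `seed`.
#' @export
fit_mixture <- function(features, K, n_restarts = 20L, seed,
                        max_iter = 300L, tol = 1e-8, ridge_scale = 1e-6) {
  if (missing(seed)) stop("seed is mandatory")
  X <- if (inherits(features, "fourier_features")) features$features
       else as.matrix(features)
  n <- nrow(X); d <- ncol(X)
  if (n <= K * (d + 1))
    stop("too few observations (", n, ") for K = ", K, " in ", d, " dims")
  set.seed(seed)
  gcov <- stats::cov(X)
  gcov <- gcov + diag(ridge_scale * sum(diag(gcov)) / d + 1e-12, d)
  best <- NULL
  for (r in seq_len(max(1L, n_restarts))) {
    means0 <- X[sample.int(n, K), , drop = FALSE]
    covs0 <- array(gcov, dim = c(d, d, K))
    fit <- .gmm_em_cpp(X, means0, covs0, rep(1 / K, K),
                       max_iter, tol, ridge_scale)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (!best$converged)
    warning("EM did not converge within ", max_iter,
            " iterations; returning best model so far")
  p <- (K - 1) + K * d + K * d * (d + 1) / 2
  labels <- max.col(best$responsibilities)
  names(labels) <- rownames(X)
  structure(list(K = K, weights = as.numeric(best$weights),
                 means = best$means, covs = best$covs,
                 loglik = best$loglik,
                 bic = 2 * best$loglik - p * log(n),
                 labels = labels, converged = best$converged,
                 n_restarts = n_restarts, seed = seed),
            class = "mixture_model")
}

#' @export
print.mixture_model <- function(x, ...) {
  cat("mixture_model: K =", x$K, " logL =", format(x$loglik),
      " BIC =", format(x$bic),
      if (!x$converged) " [not converged]", "\n")
  invisible(x)
}

#' Select the number of clusters by maximal BIC
#'
#' Fits a Gaussian mixture for every K in `K_range` and selects the one
#' with maximal BIC (`2 logL - p ln n`); exact ties are broken toward the
#' smaller K.
#'
#' @inheritParams fit_mixture
#' @param K_range candidate cluster numbers (default 2:10).
#' @return Object of class `clustering_result`: `labels` (gene ->
#'   cluster), `K`, `bic_by_k` (data.frame K, loglik, bic, converged),
#'   `model` (the selected [fit_mixture()] model), `excluded` (carried
#'   over from the features).
#' @export
select_k <- function(features, K_range = 2:10, n_restarts = 20L, seed,
                     max_iter = 300L, tol = 1e-8, ridge_scale = 1e-6) {
  if (missing(seed)) stop("seed is mandatory")
  K_range <- sort(unique(as.integer(K_range)))
  fits <- lapply(seq_along(K_range), function(i) {
    fit_mixture(features, K_range[i], n_restarts = n_restarts,
                seed = seed + i - 1L, max_iter = max_iter, tol = tol,
                ridge_scale = ridge_scale)
  })
  bic_by_k <- data.frame(K = K_range,
                         loglik = vapply(fits, `[[`, 0, "loglik"),
                         bic = vapply(fits, `[[`, 0, "bic"),
                         converged = vapply(fits, `[[`, TRUE, "converged"))
  best <- which.max(bic_by_k$bic)     # first max = smallest K on ties
  model <- fits[[best]]
  structure(list(labels = model$labels, K = model$K,
                 bic_by_k = bic_by_k, model = model,
                 excluded = if (inherits(features, "fourier_features"))
                   features$excluded else NULL),
            class = "clustering_result")
}

#' @export
print.clustering_result <- function(x, ...) {
  cat("clustering_result: K = ", x$K, " (max BIC over ",
      paste(range(x$bic_by_k$K), collapse = ".."), "); ",
      length(x$labels), " items\n", sep = "")
  invisible(x)
}

#' Sort clusters against a reference classification
#'
#' Greedy assignment: among all (cluster, reference class) pairs, the pair
#' with the smallest hypergeometric enrichment p-value over the shared
#' items is assigned first, the cluster inheriting that class's rank;
#' the procedure repeats over unassigned clusters and unused classes.
#' Leftover clusters are appended in decreasing size order.
#'
#' @param labels named vector (item -> cluster).
#' @param reference named character vector (item -> reference class); rank
#'   of a class is its order of first appearance unless it is a factor.
#' @return A data.frame `cluster`, `ref_class` (NA for appended clusters),
#'   `rank`, `p` (NA for appended clusters), ordered by rank. Use the
#'   `rank` column to relabel/color clusters.
#' @export
sort_clusters_by_reference <- function(labels, reference) {
  shared <- intersect(names(labels), names(reference))
  if (length(shared) == 0) stop("no shared items")
  la <- as.character(labels[shared])
  rf <- as.character(reference[shared])
  ref_levels <- if (is.factor(reference)) levels(reference)
                else unique(as.character(reference))
  clusters <- unique(la)
  N <- length(shared)
  pmat <- matrix(NA_real_, length(clusters), length(ref_levels),
                 dimnames = list(clusters, ref_levels))
  for (cl in clusters) for (rc in ref_levels) {
    x <- sum(la == cl & rf == rc)
    pmat[cl, rc] <- hypergeom_tests(x, sum(la == cl), sum(rf == rc),
                                    N)$p_enrich
  }
  assigned <- character(0); used <- character(0)
  res <- list()
  while (length(assigned) < length(clusters) &&
         length(used) < length(ref_levels)) {
    sub <- pmat[setdiff(clusters, assigned), setdiff(ref_levels, used),
                drop = FALSE]
    ij <- which(sub == min(sub), arr.ind = TRUE)[1, ]
    cl <- rownames(sub)[ij[1]]; rc <- colnames(sub)[ij[2]]
    res[[length(res) + 1L]] <-
      data.frame(cluster = cl, ref_class = rc,
                 rank = match(rc, ref_levels), p = sub[ij[1], ij[2]],
                 stringsAsFactors = FALSE)
    assigned <- c(assigned, cl); used <- c(used, rc)
  }
  left <- setdiff(clusters, assigned)
  if (length(left)) {
    sizes <- vapply(left, function(cl) sum(la == cl), 0)
    left <- left[order(-sizes)]
    res[[length(res) + 1L]] <-
      data.frame(cluster = left, ref_class = NA_character_,
                 rank = length(ref_levels) + seq_along(left),
                 p = NA_real_, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  out[order(out$rank), , drop = FALSE]
}
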