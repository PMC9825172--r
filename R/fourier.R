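# Fourier-feature transform chain: arcsinh -> DFT -> component
# normalization -> stacked Re/Im feature matrix.

#' Arcsinh transform
#'
#' Variance-stabilizing transform `ln(x + sqrt(x^2 + 1))` applied to
#' non-negative expression values; approximately `ln(2x)` for large `x`
#' and linear near 0.
#'
#' @param x non-negative numeric vector or matrix.
#' @return Transformed values, same shape as `x`.
#' @export
arcsinh_transform <- function(x) {
  if (any(!is.finite(x)) || any(x < 0))
    stop("arcsinh_transform requires finite non-negative input")
  asinh(x)
}

#' Discrete Fourier transform components
#'
#' Computes `X_k = sum_t x_t exp(-2 pi i k t / N)` and returns the
#' non-redundant components `k = 0 .. floor(N/2)`.
#'
#' @param x real-valued series of length N >= 4.
#' @return Complex vector named "0", "1", ..., "floor(N/2)".
#' @export
dft_components <- function(x) {
  n <- length(x)
  if (n < 4) stop("series must have length >= 4")
  X <- fft(x)[seq_len(n %/% 2 + 1)]
  names(X) <- as.character(seq_len(n %/% 2 + 1) - 1L)
  X
}

#' Normalize DFT components by the mean amplitude of the other components
#'
#' Each component `k >= 1` is divided by the mean of the amplitudes
#' `|X_j|` over all other non-DC components (`j >= 1`, `j != k`). If that
#' denominator is 0 for any requested component the series carries no
#' usable signal and is flagged for exclusion.
#'
#' @param X complex vector of DFT components `0 .. floor(N/2)` as returned
#'   by [dft_components()].
#' @param m number of leading components to return (k = 1..m).
#' @return Complex vector `X'_1 .. X'_m`, or `NULL` if any normalization
#'   denominator is 0 (the caller routes the gene to `excluded_genes`).
#' @export
normalize_components <- function(X, m = 6L) {
  K <- length(X) - 1L                   # non-DC components available
  if (m > K) stop("m exceeds available components")
  amp <- Mod(X[-1])                     # |X_1| .. |X_K|
  tot <- sum(amp)
  denom <- (tot - amp) / (K - 1)        # mean over j >= 1, j != k
  if (any(denom[seq_len(m)] == 0)) return(NULL)
  Xn <- X[1 + seq_len(m)] / denom[seq_len(m)]
  names(Xn) <- as.character(seq_len(m))
  Xn
}

#' Build Fourier features for clustering
#'
#' Per gene: arcsinh transform of the (optionally subset) TPM series,
#' DFT, component normalization, then stacking of the real and imaginary
#' parts of components 1..m into a feature row
#' (Re X'_1, Im X'_1, ..., Re X'_m, Im X'_m). Genes whose total signal is
#' below `min_total_signal`, or whose normalization denominator is 0, are
#' excluded and reported.
#'
#' @param mat an [expression_matrix] in TPM.
#' @param sample_subset indices (or sample ids) of the samples to use, in
#'   time order; default all samples.
#' @param m number of DFT components (default 6).
#' @param min_total_signal minimum summed TPM over the series (default 1).
#' @return List of class `fourier_features`: `features` (numeric matrix,
#'   2m columns), `gene_ids`, `m`, and `excluded` (data.frame gene_id,
#'   reason).
#' @export
build_features <- function(mat, sample_subset = NULL, m = 6L,
                           min_total_signal = 1) {
  stopifnot(inherits(mat, "expression_matrix"))
  if (mat$unit != "TPM") stop("build_features expects TPM input")
  vals <- mat$values
  if (!is.null(sample_subset)) vals <- vals[, sample_subset, drop = FALSE]
  n <- ncol(vals)
  if (m > n %/% 2) stop("m exceeds floor(N/2) for N = ", n, " samples")
  excluded <- list()
  feats <- matrix(NA_real_, nrow(vals), 2L * m)
  keep <- logical(nrow(vals))
  for (i in seq_len(nrow(vals))) {
    x <- vals[i, ]
    if (sum(x) < min_total_signal) {
      excluded[[length(excluded) + 1L]] <-
        data.frame(gene_id = rownames(vals)[i], reason = "low_signal")
      next
    }
    Xn <- normalize_components(dft_components(arcsinh_transform(x)), m)
    if (is.null(Xn)) {
      excluded[[length(excluded) + 1L]] <-
        data.frame(gene_id = rownames(vals)[i], reason = "zero_denominator")
      next
    }
    feats[i, ] <- as.vector(rbind(Re(Xn), Im(Xn)))
    keep[i] <- TRUE
  }
  features <- feats[keep, , drop = FALSE]
  rownames(features) <- rownames(vals)[keep]
  colnames(features) <- as.vector(rbind(paste0("Re", seq_len(m)),
                                        paste0("Im", seq_len(m))))
  structure(list(features = features, gene_ids = rownames(features),
                 m = m,
                 excluded = if (length(excluded)) do.call(rbind, excluded)
                   else data.frame(gene_id = character(0),
                                   reason = character(0))),
            class = "fourier_features")
}

#' Per-gene log2 profile relative to the pre-induction mean
#'
#' `value_i = log2((x_i + delta) / (mean(x_pre) + delta))` with a
#' pseudocount `delta` (default 0.5 TPM) shared with the TU-level
#' response statistics.
#'
#' @param mat an [expression_matrix].
#' @param pre_indices indices of the pre-induction samples (default 1:2).
#' @param delta pseudocount in the unit of `mat`.
#' @return Numeric matrix of log2 ratios, same shape as `mat$values`.
#' @export
log2_rel_profile <- function(mat, pre_indices = 1:2, delta = 0.5) {
  stopifnot(inherits(mat, "expression_matrix"))
  pre <- rowMeans(mat$values[, pre_indices, drop = FALSE])
  log2((mat$values + delta) / (pre + delta))
}
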