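# Transcription-unit level statistics: gene->TU aggregation, seeded
# k-means transfer of the gene clustering, immediate-response labeling,
# 5'->3' fold-change gradients, TPM and delta-delta-Ct utilities.

#' Aggregate gene expression to transcription units
#'
#' The TU series is the mean over its member coding genes' series. TUs
#' with no quantified member gene are excluded and reported in the
#' `excluded_tus` attribute.
#'
#' @param mat an [expression_matrix].
#' @param tus a [tu_table].
#' @return An [expression_matrix] with TU ids as rows (same samples and
#'   unit), attribute `excluded_tus` listing TUs without quantified genes.
#' @export
aggregate_to_tu <- function(mat, tus) {
  stopifnot(inherits(mat, "expression_matrix"))
  keep <- logical(nrow(tus))
  vals <- matrix(NA_real_, nrow(tus), ncol(mat$values))
  for (i in seq_len(nrow(tus))) {
    gs <- intersect(tus$genes[[i]], rownames(mat$values))
    if (length(gs) == 0) next
    keep[i] <- TRUE
    vals[i, ] <- colMeans(mat$values[gs, , drop = FALSE])
  }
  vals <- vals[keep, , drop = FALSE]
  rownames(vals) <- tus$tu_id[keep]
  out <- expression_matrix(vals, mat$samples, unit = mat$unit)
  attr(out, "excluded_tus") <- tus$tu_id[!keep]
  out
}

#' Seeded Lloyd k-means with fixed centers
#'
#' Lloyd's algorithm initialized exactly at the supplied centers
#' (typically the mean vectors of the gene-level mixture model), Euclidean
#' metric, run to convergence; K is fixed, no re-selection. Clusters that
#' become (or start) empty keep their center and are reported.
#'
#' @param features a `fourier_features` object or numeric matrix; must be
#'   built with the same transform chain and component range as the
#'   gene-level features.
#' @param centers numeric matrix K x d of starting centers.
#' @param max_iter,tol iteration cap and center-movement tolerance.
#' @return List of class `kmeans_seeded`: `labels` (named, 1..K),
#'   `centers` (final), `iterations`, `empty_clusters` (integer vector).
#' @export
kmeans_seeded <- function(features, centers, max_iter = 300L, tol = 1e-8) {
  X <- if (inherits(features, "fourier_features")) features$features
       else as.matrix(features)
  centers <- as.matrix(centers)
  if (ncol(X) != ncol(centers))
    stop("dimension mismatch: features have ", ncol(X),
         " columns, centers ", ncol(centers))
  K <- nrow(centers)
  assign_nearest <- function(C) {
    d2 <- outer(rowSums(X^2), rep(1, K)) - 2 * X %*% t(C) +
      outer(rep(1, nrow(X)), rowSums(C^2))
    max.col(-d2, ties.method = "first")
  }
  lab <- assign_nearest(centers)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    newC <- centers
    for (k in seq_len(K)) {
      idx <- lab == k
      if (any(idx)) newC[k, ] <- colMeans(X[idx, , drop = FALSE])
    }
    shift <- max(rowSums((newC - centers)^2))
    centers <- newC
    newlab <- assign_nearest(centers)
    if ((shift < tol && all(newlab == lab)) || iter >= max_iter) {
      lab <- newlab
      break
    }
    lab <- newlab
  }
  names(lab) <- rownames(X)
  empty <- setdiff(seq_len(K), unique(lab))
  if (length(empty))
    message("kmeans_seeded: empty cluster(s): ",
            paste(empty, collapse = ", "))
  structure(list(labels = lab, centers = centers, iterations = iter,
                 empty_clusters = empty),
            class = "kmeans_seeded")
}

#' Immediate transcriptional response labels
#'
#' The response ratio is `log2((mean(post) + delta) / (mean(pre) +
#' delta))`; items with a ratio below `-theta` are labeled "down", above
#' `+theta` "up", all others "nc" (strict inequalities, so a ratio of
#' exactly +/-theta is "nc"). The gene-level
#' default threshold is `theta = 0.01`, the TU-level default 0.15.
#'
#' @param mat an [expression_matrix] (genes or TUs in rows).
#' @param pre,post column indices of the pre- and post-induction samples.
#' @param theta response threshold on the log2 ratio.
#' @param delta pseudocount (same unit as `mat`).
#' @return A data.frame `item_id`, `r`, `label` with attribute `theta`.
#' @export
immediate_response <- function(mat, pre = 1:2, post = 3:4, theta = 0.01,
                               delta = 0.5) {
  stopifnot(inherits(mat, "expression_matrix"))
  mpre <- rowMeans(mat$values[, pre, drop = FALSE])
  mpost <- rowMeans(mat$values[, post, drop = FALSE])
  r <- log2((mpost + delta) / (mpre + delta))
  label <- ifelse(r < -theta, "down", ifelse(r > theta, "up", "nc"))
  out <- data.frame(item_id = rownames(mat$values), r = r, label = label,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "theta") <- theta
  out
}

#' 5'->3' fold-change gradient along transcription units
#'
#' Per TU and contrast: `delta = log2fc(first gene) - log2fc(last gene)`
#' (first and last in transcription order), so a positive value means the
#' downstream gene responds less / more negatively than the upstream
#' gene. TUs with fewer than `min_genes` members are skipped; TUs whose
#' first or last gene is missing from the fold-change table are skipped
#' and reported.
#'
#' @param fc an `fc_table` (see [read_foldchanges()]).
#' @param tus a [tu_table].
#' @param min_genes minimum TU size (paper figures use 4, supplementary 2).
#' @return A data.frame `tu_id`, `contrast`, `delta`, `n_genes`, with
#'   attribute `skipped_tus` (missing fold-change entries).
#' @export
tu_gradient <- function(fc, tus, min_genes = 4L) {
  contrasts <- unique(fc$contrast)
  rows <- list(); skipped <- character(0)
  for (i in seq_len(nrow(tus))) {
    gs <- tus$genes[[i]]
    if (length(gs) < min_genes) next
    for (ct in contrasts) {
      sub <- fc[fc$contrast == ct, ]
      first <- sub$log2fc[match(gs[1], sub$gene_id)]
      last <- sub$log2fc[match(gs[length(gs)], sub$gene_id)]
      if (is.na(first) || is.na(last)) {
        skipped <- c(skipped, paste0(tus$tu_id[i], ":", ct))
        next
      }
      rows[[length(rows) + 1L]] <-
        data.frame(tu_id = tus$tu_id[i], contrast = ct,
                   delta = first - last, n_genes = length(gs),
                   stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
    else data.frame(tu_id = character(0), contrast = character(0),
                    delta = numeric(0), n_genes = integer(0))
  attr(out, "skipped_tus") <- unique(skipped)
  out
}

#' TPM normalization
#'
#' `rate_g = counts_g / (length_g / 1000)`;
#' `TPM_g = rate_g / sum(rate) * 1e6` per sample, so every column sums to
#' one million.
#'
#' @param counts an [expression_matrix] with unit "counts".
#' @param gene_lengths named numeric vector of gene lengths in nt.
#' @return An [expression_matrix] with unit "TPM".
#' @export
tpm <- function(counts, gene_lengths) {
  stopifnot(inherits(counts, "expression_matrix"))
  if (counts$unit != "counts") stop("tpm expects a counts matrix")
  lens <- gene_lengths[rownames(counts$values)]
  if (any(is.na(lens)))
    stop("missing gene length for: ",
         paste(rownames(counts$values)[is.na(lens)][1], collapse = ", "))
  if (any(lens <= 0)) stop("gene lengths must be positive")
  rate <- counts$values / (lens / 1000)
  tot <- colSums(rate)
  if (any(tot == 0))
    stop("zero-count sample column: ",
         colnames(counts$values)[which(tot == 0)[1]])
  vals <- sweep(rate, 2, tot, "/") * 1e6
  expression_matrix(vals, counts$samples, unit = "TPM")
}

#' Relative quantification by the delta-delta-Ct method
#'
#' `dCt = Ct_target - Ct_reference_gene` within each state; the raw
#' `ddCt = dCt_sample - dCt_reference_state`, and the reported log2 fold
#' change is `-ddCt`, so that a drop in target Ct (more transcript) gives
#' a positive value.
#'
#' @param ct_target_sample,ct_ref_sample Ct values of target and reference
#'   gene in the sample state.
#' @param ct_target_reference,ct_ref_reference Ct values in the reference
#'   state (pre-induction time point or control strain).
#' @return List with `delta_delta_ct` and `log2_fold_change`.
#' @export
delta_delta_ct <- function(ct_target_sample, ct_ref_sample,
                           ct_target_reference, ct_ref_reference) {
  ddct <- (ct_target_sample - ct_ref_sample) -
    (ct_target_reference - ct_ref_reference)
  list(delta_delta_ct = ddct, log2_fold_change = -ddct)
}
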