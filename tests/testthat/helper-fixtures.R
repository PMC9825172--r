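# Shared fixture builders; everything is generated in code at test time.

# tiny expression matrix with explicit values
make_expr <- function(values, times = NULL, unit = "TPM") {
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    rownames(values) <- paste0("g", seq_len(nrow(values)))
  if (is.null(times)) times <- seq_len(ncol(values))
  expression_matrix(values,
                    data.frame(sample_id = paste0("s", seq_len(ncol(values))),
                               time_h = times),
                    unit = unit)
}

# one-replicon genome with a single TU
make_single_tu <- function(seq, strand = "+", tss, replicon = "chr",
                           replicon_class = "chromosome",
                           genes = list("gA")) {
  list(genome = genome(setNames(seq, replicon)),
       tus = tu_table("TU1", replicon, replicon_class, strand, tss, genes))
}

# promoter scenario with the stochastic decorations switched off, for
# exact planting-arithmetic checks
plain_promoter_scenario <- function(...) {
  promoter_scenario(..., repeat_decay = 1,
                    jitter_offsets = 0L, jitter_probs = 1)
}

# adjusted Rand index (mclust's implementation, used as independent oracle)
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# two well-separated Gaussian blobs in d dimensions with known labels
make_blobs <- function(n_per = 50, d = 4, sep = 10, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per * d), n_per),
             matrix(rnorm(n_per * d, mean = sep), n_per))
  rownames(X) <- paste0("i", seq_len(2 * n_per))
  list(X = X, truth = rep(1:2, each = n_per))
}
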