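# TSS-anchored promoter structure analysis: motif indicator vectors,
# aligned occurrence matrices, windowed frequency profiles with
# per-position hypergeometric tests, autocorrelation periodicity, PWMs
# with Jensen-Shannon divergence and a permutation test, and
# discriminator statistics.

#' Built-in motif definitions
#'
#' * `GC` (k = 1): base is G or C.
#' * `AT2` (k = 2): dinucleotide step in \{AA, AT, TT\} (the A-tract
#'   dinucleotides, excluding the TpA step).
#' * `TpA` (k = 2): the TA step ("twist capacitor").
#' * `ATRACT4` (k = 4): 4-mer over \{A,T\} whose three steps are all AT2,
#'   i.e. \{AAAA, AAAT, AATT, ATTT, TTTT\}.
#'
#' Any window containing N never matches.
#'
#' @param name motif name.
#' @return List of class `motif_def` with `name`, `k` and `patterns`
#'   (the matching k-mer set).
#' @export
motif_def <- function(name = c("GC", "AT2", "TpA", "ATRACT4")) {
  name <- match.arg(name)
  patterns <- switch(name,
    GC = c("G", "C"),
    AT2 = c("AA", "AT", "TT"),
    TpA = "TA",
    ATRACT4 = ATRACT4_SET)
  structure(list(name = name, k = nchar(patterns[1]), patterns = patterns),
            class = "motif_def")
}

#' Motif occurrence indicator vector
#'
#' Converts a sequence into a vector of 0/1 of length
#' `nchar(seq) - k + 1`, where 1 marks a k-mer matching the motif
#' (occurrence position = first base of the k-mer). Overlapping
#' occurrences are all counted.
#'
#' @param seq a nucleotide string.
#' @param motif a [motif_def()].
#' @return Integer 0/1 vector.
#' @export
motif_indicator <- function(seq, motif) {
  n <- nchar(seq)
  k <- motif$k
  if (n < k) stop("sequence shorter than motif")
  starts <- seq_len(n - k + 1L)
  kmers <- substring(seq, starts, starts + k - 1L)
  as.integer(kmers %in% motif$patterns)
}

#' Align motif indicators of TSS windows into an occurrence matrix
#'
#' Only transcription units on chromosome replicons are considered. Each
#' included TU contributes one row; column `p` is 1 iff a motif
#' occurrence starts at sense-strand relative position `p`
#' (p in -upstream .. downstream - k). Out-of-bounds TUs are excluded
#' and counted.
#'
#' @param g a [genome].
#' @param tus a [tu_table].
#' @param motif a [motif_def()].
#' @param upstream,downstream window extent around the TSS.
#' @return Object of class `aligned_occurrence`: binary matrix `occ`
#'   (rows = TU ids, columns named by relative position), `motif`,
#'   `upstream`, `downstream`, `n_excluded`.
#' @export
align_at_tss <- function(g, tus, motif, upstream, downstream) {
  tus <- tus[tus$replicon_class == "chromosome", , drop = FALSE]
  if (nrow(tus) == 0) stop("no chromosome transcription units")
  win <- tss_windows(g, tus, upstream, downstream)
  inc <- !win$excluded
  if (!any(inc)) stop("all TSS windows out of bounds")
  occ <- t(vapply(win$seq[inc],
                  function(s) motif_indicator(s, motif),
                  integer(upstream + downstream - motif$k + 1L)))
  rownames(occ) <- win$tu_id[inc]
  colnames(occ) <- as.character(seq(-upstream, by = 1L,
                                    length.out = ncol(occ)))
  structure(list(occ = occ, motif = motif, upstream = upstream,
                 downstream = downstream,
                 n_excluded = sum(win$excluded)),
            class = "aligned_occurrence")
}

# column indices of the w-window centered at position index i:
# relative positions p - ceiling(w/2) + 1 .. p + floor(w/2)
# (even w centered asymmetrically, e.g. 66 -> -32..+33)
window_slots <- function(n_pos, w) {
  lo <- seq_len(n_pos) - ceiling(w / 2) + 1L
  hi <- seq_len(n_pos) + floor(w / 2)
  ok <- lo >= 1L & hi <= n_pos
  list(lo = lo, hi = hi, ok = ok)
}

#' Windowed motif frequency profile
#'
#' Frequency (%) of motif occurrence in `w`-bp windows surrounding each
#' position, over a subset of TUs:
#' `freq(p) = 100 * (occurrences in window) / (w * n_subset)`. Only
#' positions whose window lies fully inside the aligned range are
#' reported.
#'
#' @param aligned an `aligned_occurrence` from [align_at_tss()].
#' @param subset TU ids (default: all rows).
#' @param w window width in bp (5 or 66 in the standard profiles).
#' @return Data.frame `position`, `freq`.
#' @export
windowed_frequency <- function(aligned, subset = NULL, w = 5L) {
  occ <- aligned$occ
  if (!is.null(subset)) occ <- occ[rownames(occ) %in% subset, ,
                                   drop = FALSE]
  if (nrow(occ) == 0) stop("empty TU subset")
  colsum <- colSums(occ)
  cs <- cumsum(c(0, colsum))
  ws <- window_slots(ncol(occ), w)
  counts <- cs[ws$hi[ws$ok] + 1L] - cs[ws$lo[ws$ok]]
  data.frame(position = as.integer(colnames(occ))[ws$ok],
             freq = 100 * counts / (w * nrow(occ)))
}

#' Per-position enrichment and deprivation tests
#'
#' At every position with a complete `w`-window, the motif occurrences of
#' the cluster TUs inside the window are tested against the same window
#' over all TUs by cumulative hypergeometric tests: universe
#' `N = n_all * w` slots with `K` total occurrences; `n = n_cluster * w`
#' draws with `x` observed occurrences. Glyph sizes for plotting scale
#' with `-log2(p)` capped at the series' minimal p-value, and glyphs are
#' emitted at every 3rd (w = 5) or 10th (w = 66) position.
#'
#' @inheritParams windowed_frequency
#' @param subset TU ids of the cluster.
#' @return Data.frame `position`, `freq`, `x`, `p_enrich`, `p_deplete`,
#'   `direction` ("enriched"/"deprived" by the smaller p), `glyph_size`,
#'   `glyph_show`.
#' @export
positional_tests <- function(aligned, subset, w = 5L) {
  occ_all <- aligned$occ
  occ_cl <- occ_all[rownames(occ_all) %in% subset, , drop = FALSE]
  if (nrow(occ_cl) == 0) stop("empty TU subset")
  ws <- window_slots(ncol(occ_all), w)
  cs_all <- cumsum(c(0, colSums(occ_all)))
  cs_cl <- cumsum(c(0, colSums(occ_cl)))
  K <- cs_all[ws$hi[ws$ok] + 1L] - cs_all[ws$lo[ws$ok]]
  x <- cs_cl[ws$hi[ws$ok] + 1L] - cs_cl[ws$lo[ws$ok]]
  N <- nrow(occ_all) * w
  n <- nrow(occ_cl) * w
  ht <- hypergeom_tests(x, n, K, N)
  p <- pmin(ht$p_enrich, ht$p_deplete)
  pcap <- min(p)
  stride <- if (w >= 10) 10L else 3L
  pos <- as.integer(colnames(occ_all))[ws$ok]
  data.frame(position = pos,
             freq = 100 * x / n,
             x = x,
             p_enrich = ht$p_enrich, p_deplete = ht$p_deplete,
             direction = ifelse(ht$p_enrich <= ht$p_deplete,
                                "enriched", "deprived"),
             glyph_size = -log2(pmax(p, pcap)),
             glyph_show = (seq_along(pos) - 1L) %% stride == 0L)
}

#' Autocorrelation periodicity of a motif indicator over promoters
#'
#' Concatenates the sense-strand indicator vectors of a promoter region
#' over a TU subset and computes the autocorrelation function up to
#' `max_lag`, masking all products that would span a promoter boundary.
#' The dominant period is the lag with maximal ACF within `period_range`,
#' refined by parabolic interpolation through the neighboring lags.
#'
#' @param g a [genome].
#' @param tus a [tu_table] (chromosome TUs are used).
#' @param motif a [motif_def()] (default AT2).
#' @param region relative region `c(from, to)` (default c(-200, -1)).
#' @param max_lag maximal lag (default 30).
#' @param period_range lag range searched for the dominant period.
#' @return List of class `acf_periodicity`: `acf` (data.frame lag, r),
#'   `period` (parabolic-refined), `n_tu`, `n_occurrences`.
#' @export
acf_periodicity <- function(g, tus, motif = motif_def("AT2"),
                            region = c(-200, -1), max_lag = 30L,
                            period_range = c(6L, 15L)) {
  stopifnot(region[1] < region[2], region[2] <= 0)
  U <- -region[1]
  D <- region[2] + 1L       # window covers region[1] .. region[2]
  tus <- tus[tus$replicon_class == "chromosome", , drop = FALSE]
  win <- tss_windows(g, tus, U, D)
  seqs <- win$seq[!win$excluded]
  if (length(seqs) == 0) stop("no TSS windows in bounds")
  ind <- lapply(seqs, motif_indicator, motif = motif)
  xall <- unlist(ind)
  if (sum(xall) == 0) stop("no occurrences of motif ", motif$name)
  xbar <- mean(xall)
  denom <- sum((xall - xbar)^2)
  r <- vapply(seq_len(max_lag), function(l) {
    s <- 0
    for (x in ind) {
      m <- length(x)
      if (m > l) s <- s + sum((x[1:(m - l)] - xbar) * (x[(l + 1):m] - xbar))
    }
    s / denom
  }, 0)
  lags <- seq_len(max_lag)
  in_range <- lags >= period_range[1] & lags <= period_range[2]
  l0 <- lags[in_range][which.max(r[in_range])]
  # parabola through (l0-1, l0, l0+1)
  period <- l0
  if (l0 > 1 && l0 < max_lag) {
    rm1 <- r[l0 - 1]; r0 <- r[l0]; rp1 <- r[l0 + 1]
    den <- rm1 - 2 * r0 + rp1
    if (den < 0) period <- l0 + 0.5 * (rm1 - rp1) / den
  }
  structure(list(acf = data.frame(lag = lags, r = r), period = period,
                 n_tu = length(seqs), n_occurrences = sum(xall)),
            class = "acf_periodicity")
}

#' Build a position weight matrix
#'
#' `prob(b, p) = (count(b, p) + pseudocount) / (n + 4 * pseudocount)`,
#' so every column sums to 1.
#'
#' @param seqs character vector of equal-length sequences.
#' @param pseudocount added per base (default 0.5).
#' @return Object of class `pwm`: `prob` (4 x L matrix, rows A, C, G, T),
#'   `n_sequences`.
#' @export
build_pwm <- function(seqs, pseudocount = 0.5) {
  if (length(seqs) == 0) stop("no sequences")
  L <- unique(nchar(seqs))
  if (length(L) != 1) stop("sequences must have equal length")
  bases <- c("A", "C", "G", "T")
  mat <- matrix(0, 4, L, dimnames = list(bases, NULL))
  chars <- do.call(rbind, strsplit(seqs, ""))
  for (p in seq_len(L)) {
    tab <- table(factor(chars[, p], levels = bases))
    mat[, p] <- (as.numeric(tab) + pseudocount) /
      (length(seqs) + 4 * pseudocount)
  }
  structure(list(prob = mat, n_sequences = length(seqs)), class = "pwm")
}

kl_bits <- function(p, q) {
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / q[nz]))
}

#' Jensen-Shannon divergence between two PWMs
#'
#' Per position: `JSD(P, Q) = KL(P||M)/2 + KL(Q||M)/2` with
#' `M = (P + Q)/2`, log base 2, hence bounded in `[0, 1]` bits.
#'
#' @param pwm1,pwm2 [build_pwm()] objects (or 4 x L probability
#'   matrices) over the same positions.
#' @return Numeric vector of per-position JSD values (bits).
#' @export
js_divergence <- function(pwm1, pwm2) {
  P <- if (inherits(pwm1, "pwm")) pwm1$prob else as.matrix(pwm1)
  Q <- if (inherits(pwm2, "pwm")) pwm2$prob else as.matrix(pwm2)
  if (!identical(dim(P), dim(Q))) stop("PWMs differ in dimensions")
  vapply(seq_len(ncol(P)), function(j) {
    M <- (P[, j] + Q[, j]) / 2
    0.5 * kl_bits(P[, j], M) + 0.5 * kl_bits(Q[, j], M)
  }, 0)
}

#' Permutation test for per-position PWM divergence
#'
#' Permutes the group labels of the pooled sequences `B` times
#' (preserving group sizes), rebuilds both PWMs and their per-position
#' JSD each time, and reports
#' `p = (1 + #\{JSD_perm >= JSD_obs\}) / (B + 1)` per position.
#'
#' @param seqs1,seqs2 equal-length sequence sets for the two groups.
#' @param B number of permutations (default 1000).
#' @param seed integer seed; mandatory.
#' @param pseudocount passed to [build_pwm()].
#' @return Data.frame `position`, `jsd`, `p`.
#' @export
jsd_permutation_test <- function(seqs1, seqs2, B = 1000L, seed,
                                 pseudocount = 0.5) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  obs <- js_divergence(build_pwm(seqs1, pseudocount),
                       build_pwm(seqs2, pseudocount))
  pool <- c(seqs1, seqs2)
  n1 <- length(seqs1)
  ge <- rep(0L, length(obs))
  for (b in seq_len(B)) {
    idx <- sample.int(length(pool), n1)
    jsd <- js_divergence(build_pwm(pool[idx], pseudocount),
                         build_pwm(pool[-idx], pseudocount))
    ge <- ge + (jsd >= obs)
  }
  data.frame(position = seq_along(obs), jsd = obs,
             p = (1 + ge) / (B + 1))
}

#' Discriminator region statistics
#'
#' Per TU subset (e.g. a response cluster): the mean G+C fraction over
#' the discriminator positions -6..-3 and the fraction of TUs with a T
#' at position -7, with cumulative hypergeometric enrichment/deprivation
#' tests of the cluster's base counts against all chromosome TUs.
#'
#' @param g a [genome].
#' @param tus a [tu_table].
#' @param clusters named vector (tu_id -> cluster); default: one cluster
#'   "all".
#' @return Data.frame per cluster: `cluster`, `n_tu`, `gc_disc`
#'   (fraction), `t_minus7` (fraction), `p_gc_enrich`, `p_gc_deplete`,
#'   `p_t7_enrich`, `p_t7_deplete`.
#' @export
discriminator_stats <- function(g, tus, clusters = NULL) {
  tus <- tus[tus$replicon_class == "chromosome", , drop = FALSE]
  win <- tss_windows(g, tus, upstream = 8L, downstream = 0L)
  win <- win[!win$excluded, , drop = FALSE]
  if (nrow(win) == 0) stop("no TSS windows in bounds")
  # window covers -8..-1; string index i (1-based) = position i - 9
  disc <- substring(win$seq, 3L, 6L)            # positions -6..-3
  t7 <- substring(win$seq, 2L, 2L) == "T"       # position -7
  gc_count <- nchar(gsub("[^GC]", "", disc))
  if (is.null(clusters))
    clusters <- setNames(rep("all", nrow(win)), win$tu_id)
  cl <- as.character(clusters[win$tu_id])
  keep <- !is.na(cl)
  win <- win[keep, ]; disc <- disc[keep]; t7 <- t7[keep]
  gc_count <- gc_count[keep]; cl <- cl[keep]
  N_gc <- 4L * length(disc); K_gc <- sum(gc_count)
  N_t7 <- length(t7); K_t7 <- sum(t7)
  rows <- lapply(unique(cl), function(k) {
    idx <- cl == k
    x_gc <- sum(gc_count[idx]); n_gc <- 4L * sum(idx)
    x_t7 <- sum(t7[idx]); n_t7 <- sum(idx)
    h_gc <- hypergeom_tests(x_gc, n_gc, K_gc, N_gc)
    h_t7 <- hypergeom_tests(x_t7, n_t7, K_t7, N_t7)
    data.frame(cluster = k, n_tu = sum(idx),
               gc_disc = x_gc / n_gc, t_minus7 = x_t7 / n_t7,
               p_gc_enrich = h_gc$p_enrich, p_gc_deplete = h_gc$p_deplete,
               p_t7_enrich = h_t7$p_enrich, p_t7_deplete = h_t7$p_deplete,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
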