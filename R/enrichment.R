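# Cross-classification enrichment tables (cumulative hypergeometric
# tests), Welch t-statistic profiles of numeric values by cluster, the
# iterative row-sorting procedure, and the table-rendering contract.

#' Cumulative hypergeometric enrichment and deprivation tests
#'
#' For an overlap count `x` between a row class of size `n_draw` and a
#' column class of size `K_succ` in a universe of size `N`:
#' `p_enrich = P(X >= x)` and `p_deplete = P(X <= x)` with
#' `X ~ Hypergeometric(N, K_succ, n_draw)`.
#'
#' @param x observed overlap count(s).
#' @param n_draw row-class size(s).
#' @param K_succ column-class size(s).
#' @param N universe size.
#' @return List with numeric vectors `p_enrich` and `p_deplete`.
#' @export
hypergeom_tests <- function(x, n_draw, K_succ, N) {
  if (any(x < 0) || any(x > pmin(n_draw, K_succ)))
    stop("x must be in [0, min(n_draw, K_succ)]")
  if (any(n_draw > N) || any(K_succ > N)) stop("class sizes exceed N")
  list(p_enrich = phyper(x - 1, K_succ, N - K_succ, n_draw,
                         lower.tail = FALSE),
       p_deplete = phyper(x, K_succ, N - K_succ, n_draw))
}

#' Cross-tabulate two classifications
#'
#' Restricted to the items present in both classifications; computes the
#' overlap counts, margins and per-cell hypergeometric enrichment /
#' deprivation p-values, plus Benjamini-Hochberg adjusted enrichment
#' p-values as an extra (the sorting and rendering contracts use the raw
#' p-values).
#'
#' @param classA,classB named vectors (item -> class). `classA` defines
#'   the table rows.
#' @return Object of class `overlap_table`: `counts`, `p_enrich`,
#'   `p_deplete`, `p_enrich_bh`, `row_margin`, `col_margin`, `N`;
#'   `row_order` and `cut_row` are filled by [sort_overlaps()].
#' @export
cross_tabulate <- function(classA, classB) {
  shared <- intersect(names(classA), names(classB))
  if (length(shared) == 0) stop("no shared items")
  a <- as.character(classA[shared]); b <- as.character(classB[shared])
  a_lev <- if (is.factor(classA)) levels(classA) else unique(a)
  b_lev <- if (is.factor(classB)) levels(classB) else unique(b)
  counts <- table(factor(a, a_lev), factor(b, b_lev))
  counts <- matrix(as.integer(counts), nrow = length(a_lev),
                   dimnames = list(a_lev, b_lev))
  N <- length(shared)
  rm_ <- rowSums(counts); cm <- colSums(counts)
  pe <- pd <- matrix(NA_real_, nrow(counts), ncol(counts),
                     dimnames = dimnames(counts))
  for (i in seq_len(nrow(counts))) {
    ht <- hypergeom_tests(counts[i, ], rm_[i], cm, N)
    pe[i, ] <- ht$p_enrich; pd[i, ] <- ht$p_deplete
  }
  structure(list(counts = counts, p_enrich = pe, p_deplete = pd,
                 p_enrich_bh = matrix(stats::p.adjust(pe, "BH"),
                                      nrow(pe), dimnames = dimnames(pe)),
                 row_margin = rm_, col_margin = cm, N = N,
                 row_order = rownames(counts), cut_row = nrow(counts)),
            class = "overlap_table")
}

#' @export
print.overlap_table <- function(x, ...) {
  cat("overlap_table:", nrow(x$counts), "x", ncol(x$counts),
      "classes, N =", x$N, "shared items\n")
  print(x$counts)
  invisible(x)
}

#' Welch t-statistic profile of numeric values by cluster
#'
#' For every cluster and contrast, a two-sided Welch two-sample t-test of
#' the in-cluster values against all other values. Positive t encodes
#' upregulation of the cluster relative to the rest.
#'
#' @param values numeric matrix (items x contrasts) or data.frame with
#'   item ids as rownames.
#' @param classification named vector (item -> cluster).
#' @return Object of class `t_profile`: data.frame `cluster`, `contrast`,
#'   `t`, `p`, `n_in`, `n_out`.
#' @export
t_profile <- function(values, classification) {
  values <- as.matrix(values)
  shared <- intersect(rownames(values), names(classification))
  if (length(shared) == 0) stop("no shared items")
  values <- values[shared, , drop = FALSE]
  cl <- as.character(classification[shared])
  clusters <- if (is.factor(classification)) levels(classification)
              else unique(cl)
  rows <- list()
  for (k in clusters) for (j in seq_len(ncol(values))) {
    vin <- values[cl == k, j]; vout <- values[cl != k, j]
    tt <- tryCatch(t.test(vin, vout),
                   error = function(e) NULL)
    if (is.null(tt)) {          # degenerate: essentially constant data
      dm <- mean(vin) - mean(vout)
      tt <- list(statistic = if (dm == 0) 0 else sign(dm) * Inf,
                 p.value = if (dm == 0) 1 else 0)
    }
    rows[[length(rows) + 1L]] <-
      data.frame(cluster = k,
                 contrast = colnames(values)[j] %||% as.character(j),
                 t = unname(tt$statistic), p = tt$p.value,
                 n_in = length(vin), n_out = length(vout),
                 stringsAsFactors = FALSE)
  }
  structure(do.call(rbind, rows), class = c("t_profile", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Iterative sorting of an overlap table
#'
#' Iterates over the table columns in the given order; among the rows not
#' yet placed, those enriched at `p_enrich <= p_sort` in the current
#' column are appended to the output, sorted by increasing p-value. Rows
#' never placed end up below the "red line" (`cut_row`) in their original
#' order, or are dropped.
#'
#' @param table an `overlap_table` from [cross_tabulate()].
#' @param p_sort enrichment p-value threshold for placing a row.
#' @param column_order columns to iterate over (names or indices);
#'   default all columns left to right.
#' @param drop_remainder drop unplaced rows instead of keeping them below
#'   the cut line.
#' @return The table with `row_order` and `cut_row` set (`cut_row` =
#'   number of placed rows).
#' @export
sort_overlaps <- function(table, p_sort = 0.01, column_order = NULL,
                          drop_remainder = FALSE) {
  stopifnot(inherits(table, "overlap_table"))
  cols <- if (is.null(column_order)) colnames(table$counts)
          else colnames(table$counts[, column_order, drop = FALSE])
  remaining <- rownames(table$counts)
  placed <- character(0)
  for (cc in cols) {
    p <- table$p_enrich[remaining, cc]
    hit <- remaining[p <= p_sort]
    hit <- hit[order(table$p_enrich[hit, cc])]
    placed <- c(placed, hit)
    remaining <- setdiff(remaining, hit)
  }
  table$cut_row <- length(placed)
  table$row_order <- if (drop_remainder) placed else c(placed, remaining)
  table
}

#' Render an enrichment or t-profile table as a style sheet
#'
#' Emits one row per cell with the displayed text, background intensity,
#' hue and text color, so any plotting layer can draw the profile:
#' intensity = `min(1, log2(p) / log2(p_min))` (white at p = 1, full
#' color at p <= p_min); hue is black for categorical overlap tests and
#' red (t < 0) or blue (t > 0) for t-profiles; text is white iff
#' p <= p_txt.
#'
#' @param x an `overlap_table` or `t_profile`.
#' @param p_min p-value mapped to full color intensity.
#' @param p_txt p-value cutoff switching text color to white.
#' @return A data.frame `row`, `col`, `text`, `intensity`, `hue`,
#'   `text_color`; overlap tables follow their `row_order` and carry a
#'   logical `below_cut` column.
#' @export
render_profile <- function(x, p_min = 1e-10, p_txt = 1e-5) {
  intensity <- function(p) pmin(1, log2(p) / log2(p_min))
  if (inherits(x, "overlap_table")) {
    rows <- x$row_order
    grid <- expand.grid(row = rows, col = colnames(x$counts),
                        stringsAsFactors = FALSE)
    p <- x$p_enrich[cbind(grid$row, grid$col)]
    data.frame(grid,
               text = as.character(x$counts[cbind(grid$row, grid$col)]),
               intensity = intensity(p), hue = "black",
               text_color = ifelse(p <= p_txt, "white", "black"),
               below_cut = match(grid$row, rows) > x$cut_row,
               stringsAsFactors = FALSE)
  } else if (inherits(x, "t_profile")) {
    data.frame(row = x$cluster, col = x$contrast,
               text = as.character(round(x$t)),
               intensity = intensity(x$p),
               hue = ifelse(x$t < 0, "red", "blue"),
               text_color = ifelse(x$p <= p_txt, "white", "black"),
               stringsAsFactors = FALSE)
  } else stop("x must be an overlap_table or t_profile")
}
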