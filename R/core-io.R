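#' @useDynLib supercoilr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats fft phyper rnorm runif rlnorm sd t.test var setNames
#' @importFrom utils read.delim write.table packageVersion
NULL

# Internal coordinate convention: 0-based half-open on the forward strand.
# All TSV interfaces carry 1-based inclusive coordinates.

#' Construct a genome object
#'
#' A genome is a named character vector of uppercase nucleotide sequences
#' (one element per replicon) over the alphabet A, C, G, T, N.
#'
#' @param sequences named character vector of nucleotide sequences.
#' @return An object of class `genome`.
#' @export
genome <- function(sequences) {
  if (length(sequences) == 0)
    stop("genome must contain at least one replicon")
  if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
    stop("all replicons must be named")
  if (anyDuplicated(names(sequences)))
    stop("duplicated replicon names: ",
         paste(unique(names(sequences)[duplicated(names(sequences))]),
               collapse = ", "))
  sequences <- toupper(sequences)
  sequences <- gsub("U", "T", sequences, fixed = TRUE)
  bad <- gsub("[ACGTN]", "", sequences)
  if (any(nzchar(bad))) {
    i <- which(nzchar(bad))[1]
    stop("replicon '", names(sequences)[i],
         "' contains invalid character(s): '",
         paste(unique(strsplit(bad[i], "")[[1]]), collapse = "', '"), "'")
  }
  structure(sequences, class = "genome")
}

#' Read a genome from a FASTA file
#'
#' Sequences are uppercased, U is converted to T, and any character outside
#' A, C, G, T, N raises an error naming the offending record.
#'
#' @param path path to a FASTA file.
#' @return A [genome] object; replicon order follows the file.
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  seqs <- tryCatch(Biostrings::readBStringSet(path),
                   error = function(e) stop("malformed FASTA in '", path,
                                            "': ", conditionMessage(e)))
  if (length(seqs) == 0) stop("no records in FASTA file: ", path)
  x <- as.character(seqs)
  # keep only the first word of each header, as common for FASTA ids
  names(x) <- sub("\\s.*$", "", names(seqs))
  if (any(!nzchar(x))) {
    stop("empty sequence for record '", names(x)[which(!nzchar(x))[1]], "'")
  }
  for (i in seq_along(x)) {
    ok <- tryCatch({ genome(x[i]); TRUE }, error = function(e) e)
    if (!isTRUE(ok))
      stop("record '", names(x)[i], "': ", conditionMessage(ok))
  }
  genome(x)
}

#' Write a genome to a FASTA file
#'
#' @param g a [genome] object.
#' @param path output path.
#' @param width line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(g, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(g)) {
    writeLines(paste0(">", nm), con)
    s <- unclass(g)[[nm]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

reverse_complement <- function(x) {
  chartr("ACGTN", "TGCAN", vapply(
    x, function(s) paste(rev(strsplit(s, "")[[1]]), collapse = ""), "",
    USE.NAMES = FALSE))
}

#' Construct a transcription-unit table
#'
#' A TU table is a data.frame with one row per transcription unit:
#' `tu_id`, `replicon`, `replicon_class` ("chromosome" or "plasmid"),
#' `strand` ("+" or "-"), `tss` (internal 0-based coordinate of the first
#' transcribed base) and `genes` (a list column of gene ids in 5'->3'
#' transcription order).
#'
#' @param tu_id,replicon,replicon_class,strand character vectors.
#' @param tss integer vector, 0-based internal coordinates.
#' @param genes list of character vectors (ordered member genes).
#' @return A data.frame of class `tu_table`.
#' @export
tu_table <- function(tu_id, replicon, replicon_class, strand, tss, genes) {
  if (anyDuplicated(tu_id))
    stop("duplicate tu_id: ",
         paste(unique(tu_id[duplicated(tu_id)]), collapse = ", "))
  if (!all(strand %in% c("+", "-")))
    stop("unknown strand symbol: ",
         paste(unique(strand[!strand %in% c("+", "-")]), collapse = ", "))
  if (!all(replicon_class %in% c("chromosome", "plasmid")))
    stop("replicon_class must be 'chromosome' or 'plasmid'")
  genes <- lapply(genes, as.character)
  if (any(vapply(genes, length, 0L) < 1L))
    stop("every TU must have at least one gene")
  dup <- vapply(genes, anyDuplicated, 0L) > 0L
  if (any(dup))
    stop("duplicated genes within TU: ", paste(tu_id[dup], collapse = ", "))
  df <- data.frame(tu_id = as.character(tu_id),
                   replicon = as.character(replicon),
                   replicon_class = as.character(replicon_class),
                   strand = as.character(strand),
                   tss = as.integer(tss),
                   stringsAsFactors = FALSE)
  df$genes <- genes
  class(df) <- c("tu_table", "data.frame")
  df
}

#' Read a transcription-unit table from TSV
#'
#' Expected header columns: `tu_id`, `replicon`, `replicon_class`,
#' `strand`, `tss_1based`, `genes` (comma-joined in 5'->3' order). The
#' 1-based TSS is converted to the internal 0-based convention.
#'
#' @param path path to the TSV file.
#' @return A [tu_table].
#' @export
read_tu_table <- function(path) {
  df <- read_tsv_checked(path)
  need <- c("tu_id", "replicon", "replicon_class", "strand",
            "tss_1based", "genes")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("TU table '", path, "' lacks column(s): ",
         paste(miss, collapse = ", "))
  tss1 <- suppressWarnings(as.numeric(df$tss_1based))
  if (any(is.na(tss1)))
    stop("non-numeric tss_1based in row ", which(is.na(tss1))[1])
  tu_table(df$tu_id, df$replicon, df$replicon_class, df$strand,
           tss = as.integer(tss1) - 1L,
           genes = strsplit(df$genes, ",", fixed = TRUE))
}

#' Write a transcription-unit table to TSV
#'
#' @param tus a [tu_table].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tu_table <- function(tus, path) {
  out <- data.frame(tu_id = tus$tu_id, replicon = tus$replicon,
                    replicon_class = tus$replicon_class,
                    strand = tus$strand,
                    tss_1based = tus$tss + 1L,
                    genes = vapply(tus$genes, paste, "", collapse = ","),
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct an expression matrix
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids); all values >= 0.
#' @param samples data.frame with columns `sample_id`, `time_h` and
#'   optionally `replicate`; one row per column of `values`, times
#'   non-decreasing.
#' @param unit one of "counts", "TPM", "arcsinh_TPM".
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, samples,
                              unit = c("TPM", "counts", "arcsinh_TPM")) {
  unit <- match.arg(unit)
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop("values must have gene ids as rownames")
  if (anyDuplicated(rownames(values))) stop("duplicated gene ids")
  if (any(!is.finite(values)) || any(values < 0))
    stop("expression values must be finite and non-negative")
  if (!all(c("sample_id", "time_h") %in% names(samples)))
    stop("samples must have columns sample_id and time_h")
  if (anyDuplicated(samples$sample_id)) stop("duplicated sample ids")
  if (nrow(samples) != ncol(values))
    stop("samples rows (", nrow(samples), ") != value columns (",
         ncol(values), ")")
  if (is.unsorted(samples$time_h))
    stop("sample times must be non-decreasing")
  colnames(values) <- samples$sample_id
  structure(list(values = values,
                 samples = as.data.frame(samples),
                 unit = unit),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix: ", nrow(x$values), " genes x ",
      ncol(x$values), " samples [", x$unit, "], t = ",
      min(x$samples$time_h), "..", max(x$samples$time_h), " h\n", sep = "")
  invisible(x)
}

#' Read an expression matrix from TSV
#'
#' The expression table has `gene_id` as its first column and one column
#' per sample; the companion samples table has columns `sample_id`,
#' `time_h` (and optionally `replicate`). Missing cells ("", "NA") are
#' interpreted as 0 with a warning, following the convention that missing
#' values at individual time points are read as 0 TPM.
#'
#' @param path path to the expression TSV.
#' @param samples either a data.frame or a path to the samples TSV.
#' @param unit expression unit of the stored values.
#' @return An [expression_matrix].
#' @export
read_expression_tsv <- function(path, samples, unit = "TPM") {
  df <- read_tsv_checked(path, as_character = TRUE)
  if (names(df)[1] != "gene_id")
    stop("first column of '", path, "' must be gene_id")
  if (is.character(samples)) samples <- read_tsv_checked(samples)
  ids <- df$gene_id
  vals <- as.matrix(df[, -1, drop = FALSE])
  missing_cells <- vals == "" | toupper(vals) == "NA" | is.na(vals)
  if (any(missing_cells)) {
    warning(sum(missing_cells),
            " missing expression cell(s) interpreted as 0")
    vals[missing_cells] <- "0"
  }
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  if (any(is.na(num))) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop("non-numeric expression cell at row ", bad[1], " (gene ",
         ids[bad[1]], "), column '", colnames(vals)[bad[2]], "'")
  }
  rownames(num) <- ids
  colnames(num) <- colnames(vals)
  num <- num[, as.character(samples$sample_id), drop = FALSE]
  expression_matrix(num, samples, unit = unit)
}

#' Write an expression matrix (and its sample table) to TSV
#'
#' @param mat an [expression_matrix].
#' @param path output path for the expression table.
#' @param samples_path optional output path for the samples table.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(mat, path, samples_path = NULL) {
  out <- data.frame(gene_id = rownames(mat$values),
                    mat$values, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(samples_path))
    write.table(mat$samples, samples_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(path)
}

#' Read a classification from TSV
#'
#' Columns: `item_id`, `class`. Each item must have exactly one label.
#'
#' @param path path to the TSV file.
#' @return Named character vector (item id -> class label).
#' @export
read_classification <- function(path) {
  df <- read_tsv_checked(path, as_character = TRUE)
  if (!all(c("item_id", "class") %in% names(df)))
    stop("classification '", path, "' needs columns item_id and class")
  if (anyDuplicated(df$item_id))
    stop("items with more than one label: ",
         paste(unique(df$item_id[duplicated(df$item_id)]), collapse = ", "))
  setNames(as.character(df$class), df$item_id)
}

#' Write a classification to TSV
#'
#' @param cls named character vector (item id -> class label).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_classification <- function(cls, path) {
  write.table(data.frame(item_id = names(cls), class = unname(cls)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a log2 fold-change table from TSV
#'
#' Long format with columns `gene_id`, `contrast`, `log2fc` and optionally
#' `se`. `NA` fold changes are rejected: no imputation rule applies to
#' differential-expression output.
#'
#' @param path path to the TSV file.
#' @return A data.frame of class `fc_table`.
#' @export
read_foldchanges <- function(path) {
  df <- read_tsv_checked(path, as_character = TRUE)
  need <- c("gene_id", "contrast", "log2fc")
  if (!all(need %in% names(df)))
    stop("fold-change table '", path, "' needs columns ",
         paste(need, collapse = ", "))
  fc <- suppressWarnings(as.numeric(df$log2fc))
  if (any(is.na(fc)))
    stop("missing or non-numeric log2fc at row ", which(is.na(fc))[1],
         " (gene ", df$gene_id[which(is.na(fc))[1]], ")")
  out <- data.frame(gene_id = df$gene_id, contrast = df$contrast,
                    log2fc = fc, stringsAsFactors = FALSE)
  if ("se" %in% names(df)) {
    se <- suppressWarnings(as.numeric(df$se))
    if (any(!is.na(se) & se < 0)) stop("negative standard errors")
    out$se <- se
  }
  if (anyDuplicated(out[c("gene_id", "contrast")]))
    stop("duplicated gene/contrast rows")
  class(out) <- c("fc_table", "data.frame")
  out
}

#' Write a fold-change table to TSV
#'
#' @param fc an `fc_table` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_foldchanges <- function(fc, path) {
  write.table(as.data.frame(fc), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

# shared TSV reader: UTF-8, tab separated, '#' comments, mandatory header
read_tsv_checked <- function(path, as_character = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE, check.names = FALSE,
                   colClasses = if (as_character) "character" else NA,
                   fileEncoding = "UTF-8")
  if (ncol(df) < 1) stop("no columns in ", path)
  df
}

#' Extract a TSS-anchored window from the genome
#'
#' Returns the sense-strand sequence covering relative positions
#' `-upstream .. downstream - 1`, where relative position 0 is the first
#' transcribed base (the TSS). Character `i` (1-based) of the returned
#' string is relative position `i - upstream - 1`. Minus-strand windows
#' are reverse complemented so the result always reads 5'->3' on the
#' sense strand.
#'
#' @param g a [genome] object.
#' @param replicon replicon name.
#' @param strand "+" or "-".
#' @param tss internal 0-based TSS coordinate.
#' @param upstream,downstream window extent in nt (both >= 0).
#' @return The window string, or `NA_character_` if the window overruns
#'   the replicon (such TUs are excluded, never truncated).
#' @export
tss_window <- function(g, replicon, strand, tss, upstream, downstream) {
  if (!replicon %in% names(g)) stop("unknown replicon: ", replicon)
  s <- unclass(g)[[replicon]]
  n <- nchar(s)
  if (strand == "+") {
    lo <- tss - upstream            # 0-based half-open [lo, hi)
    hi <- tss + downstream
    if (lo < 0 || hi > n) return(NA_character_)
    substr(s, lo + 1L, hi)
  } else if (strand == "-") {
    lo <- tss - downstream + 1L
    hi <- tss + upstream + 1L
    if (lo < 0 || hi > n) return(NA_character_)
    reverse_complement(substr(s, lo + 1L, hi))
  } else stop("unknown strand symbol: ", strand)
}

#' Extract TSS windows for a whole TU table
#'
#' @inheritParams tss_window
#' @param tus a [tu_table].
#' @return A data.frame with columns `tu_id`, `seq` and logical
#'   `excluded` (window out of replicon bounds). An attribute
#'   `n_excluded` counts the excluded TUs.
#' @export
tss_windows <- function(g, tus, upstream, downstream) {
  seqs <- vapply(seq_len(nrow(tus)), function(i) {
    tss_window(g, tus$replicon[i], tus$strand[i], tus$tss[i],
               upstream, downstream)
  }, "")
  out <- data.frame(tu_id = tus$tu_id, seq = seqs,
                    excluded = is.na(seqs), stringsAsFactors = FALSE)
  attr(out, "n_excluded") <- sum(out$excluded)
  out
}
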