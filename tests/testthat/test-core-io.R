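test_that("FASTA reading normalizes case, converts U, rejects bad alphabet", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">c", "acgt"), fa)
  g <- read_genome_fasta(fa)
  expect_equal(unname(unclass(g)["c"]), "ACGT")

  writeLines(c(">c", "ACGU"), fa)
  expect_equal(unname(unclass(read_genome_fasta(fa))["c"]), "ACGT")

  writeLines(c(">c", "ACGX"), fa)
  expect_error(read_genome_fasta(fa), "X")

  writeLines(c(">r1", "AAA", ">r2", "CCC"), fa)
  g2 <- read_genome_fasta(fa)
  expect_equal(names(g2), c("r1", "r2"))
})

test_that("genome round-trips through FASTA", {
  g <- genome(c(chrA = "ACGTACGTTTT", p1 = "GGGCC"))
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_genome_fasta(g, fa, width = 4)
  expect_identical(unclass(read_genome_fasta(fa)), unclass(g))
})

test_that("TU table applies the 1-based to 0-based TSS rule", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("tu_id\treplicon\treplicon_class\tstrand\ttss_1based\tgenes",
               "TU1\tchr\tchromosome\t+\t101\tgA,gB"), tsv)
  tus <- read_tu_table(tsv)
  expect_equal(tus$tss, 100L)
  expect_equal(tus$genes[[1]], c("gA", "gB"))

  writeLines(c("tu_id\treplicon\treplicon_class\tstrand\ttss_1based\tgenes",
               "TU1\tchr\tchromosome\t.\t101\tgA"), tsv)
  expect_error(read_tu_table(tsv), "strand")

  writeLines(c("tu_id\treplicon\treplicon_class\tstrand\ttss_1based\tgenes",
               "TU1\tchr\tchromosome\t+\t101\tgA",
               "TU1\tchr\tchromosome\t-\t201\tgB"), tsv)
  expect_error(read_tu_table(tsv), "TU1")
})

test_that("TU table round-trips through TSV", {
  tus <- tu_table(c("TU1", "TU2"), c("chr", "chr"),
                  c("chromosome", "plasmid"), c("+", "-"),
                  c(100L, 250L), list(c("gA", "gB"), "gC"))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_tu_table(tus, tsv)
  back <- read_tu_table(tsv)
  expect_equal(back$tss, tus$tss)
  expect_equal(back$genes, tus$genes)
  expect_equal(back$strand, tus$strand)
})

test_that("expression TSV round-trips; missing cells become 0 with warning", {
  mat <- make_expr(matrix(c(1.5, 2, 0, 7.25), 2))
  ex <- withr::local_tempfile(fileext = ".tsv")
  sm <- withr::local_tempfile(fileext = ".tsv")
  write_expression_tsv(mat, ex, sm)
  back <- read_expression_tsv(ex, sm)
  expect_equal(back$values, mat$values)
  expect_equal(back$samples$time_h, mat$samples$time_h)

  writeLines(c("gene_id\ts1\ts2", "g1\tNA\t2", "g2\t3\t"), ex)
  expect_warning(b2 <- read_expression_tsv(ex, sm), "0")
  expect_equal(unname(b2$values[, 1]), c(0, 3))
  expect_equal(unname(b2$values[, 2]), c(2, 0))

  writeLines(c("gene_id\ts1\ts2", "g1\tfoo\t2", "g2\t3\t4"), ex)
  expect_error(read_expression_tsv(ex, sm), "row 1.*s1")
})

test_that("fold-change table rejects missing values, round-trips otherwise", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tcontrast\tlog2fc", "gA\tkd\t1.5", "gB\tkd\tNA"),
             tsv)
  expect_error(read_foldchanges(tsv), "gB")

  fc <- data.frame(gene_id = c("gA", "gB"), contrast = "kd",
                   log2fc = c(1.5, -0.25))
  write_foldchanges(fc, tsv)
  back <- read_foldchanges(tsv)
  expect_equal(back$log2fc, fc$log2fc)
})

test_that("classification enforces one label per item and round-trips", {
  cls <- c(gA = "c1", gB = "c2")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_classification(cls, tsv)
  expect_identical(read_classification(tsv), cls)
  writeLines(c("item_id\tclass", "gA\tc1", "gA\tc2"), tsv)
  expect_error(read_classification(tsv), "gA")
})

test_that("tss_window slices and orients per the coordinate convention", {
  g <- genome(c(chr = "AACGTT"))
  # + strand: genome[tss-U : tss+D)
  expect_equal(tss_window(g, "chr", "+", tss = 2, 2, 2), "AACG")
  # - strand: reverse complement of genome[tss-D+1 : tss+U+1)
  expect_equal(tss_window(g, "chr", "-", tss = 3, 2, 2), "AACG")
  # out of bounds -> NA (exclusion, not truncation)
  expect_true(is.na(tss_window(g, "chr", "+", tss = 1, 2, 2)))
  expect_error(tss_window(g, "chr", ".", 2, 1, 1), "strand")
})

test_that("tss_window is strand-symmetric for palindromic planted sites", {
  # brute-force oracle on random genomes: plant the same palindrome as the
  # sense context of a + TU and of a - TU; sense windows must agree
  set.seed(11)
  pal <- "ACGT"  # reverse complement of itself
  for (rep in 1:20) {
    bg <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
    s <- bg
    substr(s, 21, 24) <- pal          # occupies 0-based 20..23
    g <- genome(c(chr = s))
    wplus <- tss_window(g, "chr", "+", tss = 24, upstream = 4,
                        downstream = 0)
    wminus <- tss_window(g, "chr", "-", tss = 19, upstream = 4,
                         downstream = 0)
    expect_equal(wplus, pal)
    expect_equal(wminus, pal)
  }
})

test_that("tss_windows flags out-of-bounds TUs and counts them", {
  fix <- make_single_tu("AAAAAAAA", tss = 3)
  tus <- rbind(fix$tus,
               tu_table("TU2", "chr", "chromosome", "+", 6L, list("gB")))
  win <- tss_windows(fix$genome, tus, upstream = 3, downstream = 3)
  expect_false(win$excluded[1])
  expect_true(win$excluded[2])      # 6+3 overruns length 8
  expect_equal(attr(win, "n_excluded"), 1L)
})
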