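test_that("motif indicators implement the motif grammar", {
  expect_equal(motif_indicator("AATT", motif_def("ATRACT4")), 1L)
  expect_equal(motif_indicator("ATAT", motif_def("ATRACT4")), 0L)  # TpA step
  expect_equal(motif_indicator("GATAC", motif_def("TpA")),
               c(0L, 0L, 1L, 0L))  # TA starts at the third base
  expect_equal(motif_indicator("GCAT", motif_def("GC")),
               c(1L, 1L, 0L, 0L))
  expect_equal(motif_indicator("AANA", motif_def("AT2")), c(1L, 0L, 0L))
  expect_equal(sort(motif_def("ATRACT4")$patterns),
               c("AAAA", "AAAT", "AATT", "ATTT", "TTTT"))
})

test_that("align_at_tss marks planted occurrences at their relative position", {
  psc <- plain_promoter_scenario(n_tu = 20, plant_prob = 1, n_repeats = 1,
                                 seed = 13)
  gen <- simulate_genome(psc)
  g <- plant_promoter_motifs(gen$genome, gen$tus, psc)
  al <- align_at_tss(g, gen$tus, motif_def("ATRACT4"), 100, 50)
  expect_true(all(al$occ[, "-10"] == 1L))
  expect_equal(nrow(al$occ), 20)
  expect_equal(colnames(al$occ)[1], "-100")
  expect_error(align_at_tss(g, gen$tus[0, ], motif_def("AT2"), 10, 5))
})

test_that("align_at_tss keeps only chromosome TUs and excludes OOB windows", {
  g <- genome(c(chr = strrep("ACGT", 50), pl = strrep("ACGT", 50)))
  tus <- tu_table(c("T1", "T2", "T3"), c("chr", "pl", "chr"),
                  c("chromosome", "plasmid", "chromosome"),
                  c("+", "+", "+"), c(100L, 100L, 2L),
                  list("g1", "g2", "g3"))
  al <- align_at_tss(g, tus, motif_def("GC"), 20, 10)
  expect_equal(rownames(al$occ), "T1")     # T2 plasmid, T3 out of bounds
  expect_equal(al$n_excluded, 1L)
})

test_that("minus-strand TUs with the same sense sequence give identical rows", {
  s <- strrep("C", 40)
  sense <- paste0(strrep("G", 10), "AAAATTTT", strrep("G", 12))
  gplus <- s; substr(gplus, 11, 40) <- substr(sense, 1, 30)
  gminus <- paste0(strrep("C", 10),
                   supercoilr:::reverse_complement(sense))
  g <- genome(c(chr = paste0(gplus, gminus)))
  tus <- tu_table(c("P", "M"), "chr", "chromosome", c("+", "-"),
                  c(30L, 59L), list("g1", "g2"))
  al <- align_at_tss(g, tus, motif_def("ATRACT4"), 20, 5)
  expect_equal(unname(al$occ["P", ]), unname(al$occ["M", ]))
  expect_true(any(al$occ["P", ] == 1))
})

test_that("windowed_frequency implements the centered-window kernel", {
  occ <- matrix(1L, 4, 20,
                dimnames = list(paste0("t", 1:4), as.character(-10:9)))
  al <- structure(list(occ = occ, upstream = 10, downstream = 10),
                  class = "aligned_occurrence")
  wf <- windowed_frequency(al, w = 5)
  expect_true(all(wf$freq == 100))

  occ1 <- matrix(0L, 1, 20, dimnames = list("t1", as.character(-10:9)))
  occ1[1, "0"] <- 1L
  al1 <- structure(list(occ = occ1), class = "aligned_occurrence")
  wf1 <- windowed_frequency(al1, w = 5)
  hit <- wf1$freq > 0
  expect_equal(sum(hit), 5)                   # 5 consecutive positions
  expect_equal(unique(wf1$freq[hit]), 100 / 5)
  expect_equal(wf1$position[hit], -2:2)       # window p-2..p+2 covers 0

  # w = 1 equals the raw column mean
  wfr <- windowed_frequency(al1, w = 1)
  expect_equal(wfr$freq, 100 * as.numeric(occ1[1, ]))
})

test_that("positional tests flag the planted position as most enriched", {
  psc <- plain_promoter_scenario(n_tu = 60, plant_prob = 1, n_repeats = 1,
                                 seed = 17)
  gen <- simulate_genome(psc)
  g <- plant_promoter_motifs(gen$genome, gen$tus, psc)
  al <- align_at_tss(g, gen$tus, motif_def("ATRACT4"), 100, 50)
  # cluster = first half of TUs; unplanted background comparison needs a
  # contrast, so replant only the cluster on a fresh genome
  cl <- gen$tus$tu_id[1:30]
  psc0 <- plain_promoter_scenario(n_tu = 60, plant_prob = 0, seed = 17)
  g0 <- simulate_genome(psc0)$genome
  tus <- gen$tus
  half <- plant_promoter_motifs(g0, tus[tus$tu_id %in% cl, ], psc)
  al2 <- align_at_tss(half, tus, motif_def("ATRACT4"), 100, 50)
  pt <- positional_tests(al2, cl, w = 5)
  # all plants sit at -10; the 5 bp window makes -12..-8 share the signal
  expect_lte(abs(pt$position[which.min(pt$p_enrich)] + 10), 2)
  expect_lt(pt$p_enrich[pt$position == -10], 1e-10)
  expect_equal(pt$direction[pt$position == -10], "enriched")
  # glyph thinning stride: every 3rd position for w = 5
  expect_equal(which(pt$glyph_show), seq(1, nrow(pt), by = 3))
  # cluster = all TUs: the draw is the whole universe, no signal possible
  pt_all <- positional_tests(al2, tus$tu_id, w = 5)
  expect_true(all(pt_all$p_enrich == 1))
  expect_true(all(pt_all$p_deplete == 1))
})

test_that("acf_periodicity recovers strict and planted periods", {
  # strictly periodic indicator with period 10 via planted tracts
  psc <- plain_promoter_scenario(n_tu = 40, upstream = 120,
                                 plant_prob = 1, pitch = 10,
                                 n_repeats = 8, seed = 19)
  gen <- simulate_genome(psc)
  g <- plant_promoter_motifs(gen$genome, gen$tus, psc)
  ac <- acf_periodicity(g, gen$tus, motif_def("ATRACT4"),
                        region = c(-120, -1))
  expect_equal(ac$period, 10, tolerance = 0.02)  # relative: +/-0.2 bp

  # all-zero indicator errors
  g0 <- genome(c(chr = strrep("G", 4000)))
  tus <- tu_table("T1", "chr", "chromosome", "+", 3000L, list("g1"))
  expect_error(acf_periodicity(g0, tus, motif_def("AT2"),
                               region = c(-200, -1)), "no occurrences")
})

test_that("PWM probabilities include the pseudocount and sum to one", {
  p1 <- build_pwm("A")
  expect_equal(as.numeric(p1$prob["A", 1]), 1.5 / 3)
  expect_equal(unname(colSums(p1$prob)), 1)
  set.seed(23)
  seqs <- vapply(1:500, function(i)
    paste(sample(c("A", "C", "G", "T"), 10, TRUE), collapse = ""), "")
  pw <- build_pwm(seqs)
  expect_equal(unname(colSums(pw$prob)), rep(1, 10))
  expect_true(all(abs(pw$prob - 0.25) < 0.1))
  expect_error(build_pwm(c("AA", "AAA")), "equal length")
})

test_that("JS divergence matches closed forms and the entropy oracle", {
  P <- matrix(c(1, 0, 0, 0), 4, 1, dimnames = list(c("A", "C", "G", "T")))
  Q <- matrix(c(0, 1, 0, 0), 4, 1, dimnames = list(c("A", "C", "G", "T")))
  expect_equal(js_divergence(P, P), 0)
  expect_equal(js_divergence(P, Q), 1)
  set.seed(29)
  A <- matrix(rexp(40), 4); A <- sweep(A, 2, colSums(A), "/")
  B <- matrix(rexp(40), 4); B <- sweep(B, 2, colSums(B), "/")
  expect_equal(js_divergence(A, B), js_divergence(B, A))
  # independent oracle: JSD = H(M) - (H(P) + H(Q))/2
  H <- function(p) { nz <- p > 0; -sum(p[nz] * log2(p[nz])) }
  oracle <- vapply(1:10, function(j)
    H((A[, j] + B[, j]) / 2) - (H(A[, j]) + H(B[, j])) / 2, 0)
  expect_equal(js_divergence(A, B), oracle, tolerance = 1e-12)
})

test_that("JSD permutation test behaves at its extremes", {
  set.seed(31)
  seqs <- vapply(1:12, function(i)
    paste(sample(c("A", "C", "G", "T"), 6, TRUE), collapse = ""), "")
  # duplicated set: observed JSD is 0, no permutation can exceed... p ~ 1
  pt <- jsd_permutation_test(seqs, seqs, B = 99, seed = 1)
  expect_true(all(pt$p > 0.5))
  # disjoint fixed letters: observed divergence maximal, p = 1/(B+1)
  pt2 <- jsd_permutation_test(rep("AAAA", 10), rep("TTTT", 10),
                              B = 99, seed = 2)
  expect_equal(pt2$p, rep(1 / 100, 4))
})

test_that("discriminator statistics read the -7 and -6..-3 positions", {
  g <- genome(c(chr = strrep("T", 200)))
  tus <- tu_table("T1", "chr", "chromosome", "+", 100L, list("g1"))
  ds <- discriminator_stats(g, tus)
  expect_equal(ds$gc_disc, 0)
  expect_equal(ds$t_minus7, 1)

  # planted AT-rich discriminator in 'up' group vs GC-rich background
  mk <- function(core, n) {
    # build n promoters with the 8 bp window -8..-1 = core
    s <- strrep("G", 40 * n)
    tss <- integer(n)
    for (i in seq_len(n)) {
      tss[i] <- 40 * i - 10
      substr(s, tss[i] - 7, tss[i]) <- core   # 1-based: positions -8..-1
    }
    list(s = s, tss = tss)
  }
  up <- mk("GTAATTAG", 20)
  g2 <- genome(c(chr = up$s))
  tus2 <- tu_table(paste0("U", 1:20), "chr", "chromosome",
                   rep("+", 20), up$tss, as.list(paste0("g", 1:20)))
  ds2 <- discriminator_stats(g2, tus2)
  expect_equal(ds2$gc_disc, 0)    # AATT at -6..-3
  expect_equal(ds2$t_minus7, 1)   # T at -7
})
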