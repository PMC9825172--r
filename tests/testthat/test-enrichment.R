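# exact hypergeometric tail by enumeration over choose() — independent of
# the phyper implementation used by the package
enum_tails <- function(x, n_draw, K_succ, N) {
  support <- max(0, n_draw + K_succ - N):min(n_draw, K_succ)
  pmf <- choose(K_succ, support) * choose(N - K_succ, n_draw - support) /
    choose(N, n_draw)
  list(p_enrich = sum(pmf[support >= x]), p_deplete = sum(pmf[support <= x]))
}

test_that("hypergeometric tails match exact enumeration (small cases)", {
  # closed-form spot check: N=10, K=5, n=4, x=4 -> C(5,4)/C(10,4) = 5/210
  ht <- hypergeom_tests(4, 4, 5, 10)
  expect_equal(ht$p_enrich, 5 / 210)
  # x = 0: enrichment is certain, depletion equals P(X = 0)
  h0 <- hypergeom_tests(0, 4, 5, 10)
  expect_equal(h0$p_enrich, 1)
  expect_equal(h0$p_deplete, enum_tails(0, 4, 5, 10)$p_deplete)
  # identity p_enrich + p_deplete = 1 + P(X = x)
  expect_equal(ht$p_enrich + ht$p_deplete,
               1 + stats::dhyper(4, 5, 5, 4))
  expect_error(hypergeom_tests(5, 4, 5, 10), "min")
})

test_that("cross_tabulate builds counts, margins and diagonal identity", {
  cls <- setNames(rep(c("a", "b", "c"), times = c(5, 3, 2)), paste0("i", 1:10))
  ot <- cross_tabulate(cls, cls)
  expect_equal(diag(ot$counts), c(a = 5L, b = 3L, c = 2L))
  expect_equal(sum(ot$counts), 10L)
  expect_equal(unname(ot$row_margin), c(5L, 3L, 2L))
  expect_equal(unname(ot$col_margin), c(5L, 3L, 2L))

  other <- setNames(rep("x", 3), paste0("j", 1:3))
  expect_error(cross_tabulate(cls, other), "no shared items")
})

test_that("t_profile matches the explicit Welch formula to 1e-10", {
  set.seed(21)
  vals <- matrix(rnorm(80), 40, 2,
                 dimnames = list(paste0("i", 1:40), c("c1", "c2")))
  cls <- setNames(rep(c("k1", "k2"), 20), rownames(vals))
  tp <- t_profile(vals, cls)
  for (r in seq_len(nrow(tp))) {
    vin <- vals[cls == tp$cluster[r], tp$contrast[r]]
    vout <- vals[cls != tp$cluster[r], tp$contrast[r]]
    se <- sqrt(var(vin) / length(vin) + var(vout) / length(vout))
    tstat <- (mean(vin) - mean(vout)) / se
    df <- se^4 / ((var(vin) / length(vin))^2 / (length(vin) - 1) +
                  (var(vout) / length(vout))^2 / (length(vout) - 1))
    expect_equal(tp$t[r], tstat, tolerance = 1e-10)
    expect_equal(tp$p[r], 2 * stats::pt(-abs(tstat), df),
                 tolerance = 1e-10)
    expect_equal(tp$n_in[r] + tp$n_out[r], 40L)
  }
})

test_that("t_profile handles identical and degenerate groups", {
  vals <- matrix(rep(c(1, 2), each = 4), 8, 1,
                 dimnames = list(paste0("i", 1:8), "c"))
  cls <- setNames(rep(c("k1", "k2"), each = 4), rownames(vals))
  # constant within groups, shifted: t -> +/-Inf, p -> 0
  tp <- t_profile(vals, cls)
  expect_equal(tp$t[tp$cluster == "k1"], -Inf)
  expect_equal(tp$p, c(0, 0))
  # identical distributions -> t = 0
  same <- matrix(rep(1:4, 2), 8, 1,
                 dimnames = list(paste0("i", 1:8), "c"))
  tp2 <- t_profile(same, cls)
  expect_equal(tp2$t, c(0, 0))
})

test_that("sort_overlaps reproduces the hand-simulated ordering", {
  # 3 rows x 2 cols with known enrichment p-values
  ot <- structure(list(
    counts = matrix(1L, 3, 2, dimnames = list(c("r1", "r2", "r3"),
                                              c("c1", "c2"))),
    p_enrich = matrix(c(1e-6, 0.2, 0.9, 0.5, 1e-4, 0.9), 3, 2,
                      dimnames = list(c("r1", "r2", "r3"), c("c1", "c2"))),
    p_deplete = matrix(1, 3, 2), N = 6L), class = "overlap_table")
  s <- sort_overlaps(ot, p_sort = 0.01)
  expect_equal(s$row_order, c("r1", "r2", "r3"))
  expect_equal(s$cut_row, 2L)

  # p_sort = 1: all rows placed by column 1 ascending p
  s1 <- sort_overlaps(ot, p_sort = 1)
  expect_equal(s1$row_order, c("r1", "r2", "r3"))
  expect_equal(s1$cut_row, 3L)

  # nothing passes: all below the line, original order
  s0 <- sort_overlaps(ot, p_sort = 1e-10)
  expect_equal(s0$row_order, c("r1", "r2", "r3"))
  expect_equal(s0$cut_row, 0L)
  expect_equal(sort_overlaps(ot, p_sort = 0.01,
                             drop_remainder = TRUE)$row_order,
               c("r1", "r2"))
})

test_that("sorted order above the cut is invariant to input row order", {
  set.seed(33)
  a <- setNames(sample(letters[1:4], 120, TRUE), paste0("i", 1:120))
  b <- setNames(sample(LETTERS[1:3], 120, TRUE), paste0("i", 1:120))
  ot <- cross_tabulate(a, b)
  s <- sort_overlaps(ot, p_sort = 0.5)
  perm <- sample(nrow(ot$counts))
  ot2 <- ot
  for (f in c("counts", "p_enrich", "p_deplete", "p_enrich_bh"))
    ot2[[f]] <- ot2[[f]][perm, , drop = FALSE]
  ot2$row_margin <- ot2$row_margin[perm]
  s2 <- sort_overlaps(ot2, p_sort = 0.5)
  top <- seq_len(s$cut_row)
  expect_equal(s2$row_order[top], s$row_order[top])
})

test_that("render_profile maps p-values to the style contract", {
  cls <- setNames(rep(c("a", "b"), each = 10), paste0("i", 1:20))
  ot <- cross_tabulate(cls, cls)
  st <- render_profile(ot, p_min = 1e-10, p_txt = 1e-5)
  # p = 1 -> intensity 0 (white)
  expect_equal(st$intensity[st$row == "a" & st$col == "b"], 0)
  expect_true(all(st$intensity >= 0 & st$intensity <= 1))
  expect_true(all(st$hue == "black"))
  # full color at p <= p_min (clamped)
  st2 <- render_profile(ot, p_min = 0.9)
  expect_true(any(st2$intensity == 1))
  # t-profiles: red for t < 0, blue for t > 0
  vals <- matrix(c(rep(0, 10), rep(5, 10)), 20, 1,
                 dimnames = list(names(cls), "c"))
  stt <- render_profile(t_profile(vals, cls))
  expect_equal(stt$hue[stt$row == "a"], "red")
  expect_equal(stt$hue[stt$row == "b"], "blue")
})
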