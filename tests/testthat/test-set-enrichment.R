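# Permutation overlap test, interval relocation test, hypergeometric ORA.

test_that("overlap_fraction computes intersection sizes and fractions", {
  s <- gene_set("t", c("a", "b", "c"))
  expect_equal(overlap_fraction(c("A", "B", "C"), s)$fraction, 1.0)
  expect_equal(overlap_fraction(c("x", "y"), s)$fraction, 0.0)
  # 18 of 107 genes -> 0.168..., reported as 17% at integer rounding
  q <- c(paste0("hit", 1:18), paste0("miss", 1:89))
  t2 <- gene_set("t2", paste0("hit", 1:50))
  r <- overlap_fraction(q, t2)
  expect_identical(r$n_overlap, 18L)
  expect_equal(round(r$fraction, 3), 0.168)
  expect_identical(round(100 * r$fraction), 17)
  expect_error(overlap_fraction(character(), s), "empty")
})

test_that("exhaustive enumeration yields exact permutation p-values", {
  bg <- paste0("g", 1:6)
  target <- gene_set("t", c("g1", "g2"))
  r <- permutation_overlap_test(c("g1", "g2"), target, bg, n_perm = 999, seed = 1)
  expect_identical(r$method, "exhaustive")
  expect_identical(r$n_perm, 15L)              # C(6,2) draws
  expect_equal(r$empirical_p, 1 / 15)

  # overlap >= 2 with target of 3 in a 5-gene universe: C(3,2)/C(5,2) = 0.3
  bg5 <- paste0("g", 1:5)
  t3 <- gene_set("t3", c("g1", "g2", "g3"))
  r2 <- permutation_overlap_test(c("g1", "g2"), t3, bg5, seed = 1)
  expect_equal(r2$empirical_p, 0.3)
})

test_that("target covering the whole background gives p = 1", {
  bg <- paste0("g", 1:30)
  target <- gene_set("t", bg)
  r <- permutation_overlap_test(paste0("g", 1:5), target, bg, n_perm = 99,
                                seed = 1)
  expect_equal(r$empirical_p, 1.0)
  expect_identical(r$n_overlap, 5L)
})

test_that("empirical p is monotone non-increasing in the observed overlap", {
  bg <- paste0("g", 1:200)
  target <- gene_set("t", paste0("g", 1:40))
  in_target <- paste0("g", 1:10)
  outside <- paste0("g", 101:110)
  ps <- vapply(0:10, function(k) {
    q <- c(head(in_target, k), head(outside, 10 - k))
    permutation_overlap_test(q, target, bg, n_perm = 499, seed = 7)$empirical_p
  }, numeric(1))
  expect_true(all(diff(ps) <= 0))
})

test_that("sampled p-values converge to the exhaustive enumeration", {
  bg <- paste0("g", 1:12)
  target <- gene_set("t", paste0("g", 1:4))
  q <- c("g1", "g2", "g9")
  exact <- permutation_overlap_test(q, target, bg, seed = 1)
  expect_identical(exact$method, "exhaustive")
  sampled <- permutation_overlap_test(q, target, bg, n_perm = 4999, seed = 5,
                                      exhaustive_limit = 1)
  expect_identical(sampled$method, "sampled")
  se <- sqrt(exact$empirical_p * (1 - exact$empirical_p) / 4999)
  expect_lt(abs(sampled$empirical_p - exact$empirical_p), 3 * se + 1 / 5000)
})

test_that("query genes outside the background are named in the error", {
  bg <- paste0("g", 1:10)
  expect_error(
    permutation_overlap_test(c("g1", "zz"), gene_set("t", "g1"), bg),
    "ZZ")
  expect_error(
    permutation_overlap_test("g1", gene_set("t", "nope"), bg),
    "no gene with the background")
})

test_that("interval test: target covering all genes is never enriched", {
  genes <- gene_intervals(paste0("g", 1:20), "chr1",
                          start = seq(0L, by = 50000L, length.out = 20),
                          end = seq(0L, by = 50000L, length.out = 20) + 20000L)
  ints <- data.frame(chrom = "chr1", start = c(10000L, 500000L),
                     end = c(120000L, 620000L))
  r <- interval_enrichment_test(ints, gene_set("all", genes$gene_id), genes,
                                n_perm = 49, seed = 1,
                                chrom_lengths = c(chr1 = 1e6))
  expect_identical(r$statistic, 2L)
  expect_equal(r$empirical_p, 1.0)
})

test_that("interval relocation p matches the exhaustive placement oracle", {
  # 10 kb chromosome, two 1 kb genes; only one is in the target set.  A 1 kb
  # interval overlapping one gene relocates uniformly over placements that
  # also cover one gene, so ~half of the null placements hit the target.
  genes <- gene_intervals(c("T1", "N1"), "chrS", start = c(1000L, 6000L),
                          end = c(2000L, 7000L))
  ints <- data.frame(chrom = "chrS", start = 1500L, end = 2500L)
  r <- interval_enrichment_test(ints, gene_set("t", "T1"), genes,
                                n_perm = 999, seed = 3,
                                chrom_lengths = c(chrS = 10000))
  expect_identical(r$statistic, 1L)
  # exhaustive oracle over every start: placements covering exactly one gene
  hits <- 0L; valid <- 0L
  for (s in 0:9000) {
    n_t <- as.integer(s < 2000 && s + 1000 > 1000)
    n_n <- as.integer(s < 7000 && s + 1000 > 6000)
    if (n_t + n_n == 1L) { valid <- valid + 1L; hits <- hits + n_t }
  }
  p_oracle <- hits / valid
  se <- sqrt(p_oracle * (1 - p_oracle) / 999)
  expect_lt(abs(r$empirical_p - p_oracle), 3 * se + 1 / 1000)
})

test_that("intervals longer than their chromosome are rejected", {
  genes <- gene_intervals("g1", "chr1", 0L, 1000L)
  ints <- data.frame(chrom = "chr1", start = 0L, end = 2e6)
  expect_error(
    interval_enrichment_test(ints, gene_set("t", "g1"), genes, n_perm = 9,
                             chrom_lengths = c(chr1 = 1e6)),
    "longer than its chromosome")
})

test_that("hypergeometric ORA: exact small case, BH arithmetic, flags", {
  # query of 3 drawn entirely from a 5-gene set inside a 10-gene background:
  # upper-tail p = C(5,3)/C(10,3) = 10/120
  bg <- c(paste0("in", 1:5), paste0("out", 1:5))
  sets <- list(gene_set("hit", paste0("in", 1:5)),
               gene_set("none", paste0("out", 1:5)),
               gene_set("alien", c("q1", "q2")))
  expect_warning(tab <- hypergeometric_ora(paste0("in", 1:3), sets, bg),
                 "'alien' has no background member")
  expect_identical(nrow(tab), 2L)
  expect_equal(tab$p[tab$set == "hit"], choose(5, 3) / choose(10, 3))
  expect_identical(tab$n_overlap[tab$set == "none"], 0L)
  expect_false(tab$at_least_two[tab$set == "none"])
  expect_true(tab$at_least_two[tab$set == "hit"])
  # BH wiring: q column is the BH adjustment of the p column
  expect_equal(tab$q, stats::p.adjust(tab$p, method = "BH"))
})

test_that("fixed seed reproduces enrichment results exactly", {
  bg <- paste0("g", 1:500)
  target <- gene_set("t", paste0("g", 1:50))
  q <- paste0("g", seq(5, 250, by = 5))
  r1 <- permutation_overlap_test(q, target, bg, n_perm = 199, seed = 42)
  r2 <- permutation_overlap_test(q, target, bg, n_perm = 199, seed = 42)
  expect_identical(r1, r2)
})
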