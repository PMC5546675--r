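# Synthetic-data generator: marker maps, implanted autozygous segments,
# planted exome variants with truth tiers, and enrichable gene sets.

test_that("marker count is forced by density and positions strictly increase", {
  cfg <- sim_config(chrom_lengths = c(chrA = 1e7), marker_density = 1e-4,
                    seed = 11)
  map <- simulate_marker_map(cfg)
  expect_identical(nrow(map), 1000L)
  expect_true(all(diff(map$pos) > 0))
  expect_true(all(map$freq >= 0 & map$freq <= 1))
})

test_that("a chromosome too short for the density yields a warning and no markers", {
  cfg <- sim_config(chrom_lengths = c(big = 1e6, tiny = 100), marker_density = 1e-3,
                    seed = 2)
  expect_warning(map <- simulate_marker_map(cfg), "'tiny' receives 0 markers")
  expect_false("tiny" %in% map$chrom)
})

test_that("fixed seed + config reproduce the generator outputs exactly", {
  cfg <- sim_config(n_samples = 6, chrom_lengths = c(chr1 = 5e6),
                    inbred_fraction = 0.5, seed = 33)
  m1 <- simulate_marker_map(cfg); m2 <- simulate_marker_map(cfg)
  expect_identical(m1, m2)
  c1 <- simulate_cohort(cfg, m1); c2 <- simulate_cohort(cfg, m2)
  expect_identical(c1$genotypes$calls, c2$genotypes$calls)
  expect_identical(c1$truth$segments, c2$truth$segments)
  genes <- simulate_gene_intervals(cfg)
  v1 <- simulate_exome_variants(c1$truth, genes, cfg)
  v2 <- simulate_exome_variants(c2$truth, genes, cfg)
  expect_identical(v1$variants, v2$variants)
  expect_identical(v1$truth_variants, v2$truth_variants)
})

test_that("config validation rejects out-of-range rates and shapes", {
  expect_error(sim_config(genotype_error_rate = 1.5), "probability")
  expect_error(sim_config(chrom_lengths = numeric()), "non-empty")
  expect_error(sim_config(chrom_lengths = c(1e6)), "named")
  expect_error(sim_config(marker_density = 0), "positive")
  expect_error(sim_config(rare_af_range = c(0.1, 0.01)), "increasing pair")
})

test_that("with zero error and missing rates implanted segments carry no het calls", {
  cfg <- sim_config(n_samples = 8, chrom_lengths = c(chr1 = 2e7),
                    inbred_fraction = 0.5, genotype_error_rate = 0,
                    missing_rate = 0, seed = 5)
  map <- simulate_marker_map(cfg)
  co <- simulate_cohort(cfg, map)
  segs <- co$truth$segments
  expect_gt(nrow(segs), 0L)
  for (k in seq_len(nrow(segs))) {
    si <- match(segs$sample[k], co$genotypes$sample_ids)
    j <- which(map$chrom == segs$chrom[k] & map$pos >= segs$start[k] &
                 map$pos < segs$end[k])
    g <- co$genotypes$calls[si, j]
    expect_true(all(g %in% c(0L, 2L)))
  }
  # truth segments are sorted and non-overlapping per sample
  for (s in unique(segs$sample)) {
    ss <- segs[segs$sample == s & segs$chrom == segs$chrom[1], , drop = FALSE]
    if (nrow(ss) > 1L) expect_true(all(ss$start[-1] >= ss$end[-nrow(ss)]))
  }
})

test_that("outbred background matches the Hardy-Weinberg heterozygosity closed form", {
  cfg <- sim_config(n_samples = 12, chrom_lengths = c(chr1 = 5e6),
                    marker_density = 1e-3, inbred_fraction = 0, seed = 17)
  map <- simulate_marker_map(cfg)
  co <- simulate_cohort(cfg, map)
  expect_identical(nrow(co$truth$segments), 0L)
  h <- 2 * map$freq * (1 - map$freq)
  expected <- mean(h)
  three_sd <- 3 * sqrt(sum(h * (1 - h))) / nrow(map)
  for (si in seq_len(12))
    expect_lt(abs(mean(co$genotypes$calls[si, ] == 1L) - expected), three_sd)
})

test_that("allele frequencies pinned at 0.5 give ~50% heterozygotes under HWE", {
  cfg <- sim_config(n_samples = 4, chrom_lengths = c(chr1 = 5e6),
                    marker_density = 2e-3, allele_freq_dist = c(5000, 5000),
                    inbred_fraction = 0, seed = 23)
  map <- simulate_marker_map(cfg)
  co <- simulate_cohort(cfg, map)
  expect_equal(mean(co$genotypes$calls == 1L), 0.5, tolerance = 0.02)
})

test_that("zero variant rates produce an empty annotated variant list", {
  cfg <- sim_config(n_samples = 4, chrom_lengths = c(chr1 = 5e6),
                    variant_rate_in_roh = 0, variant_rate_outside = 0, seed = 3)
  map <- simulate_marker_map(cfg)
  co <- simulate_cohort(cfg, map)
  genes <- simulate_gene_intervals(cfg)
  ex <- simulate_exome_variants(co$truth, genes, cfg)
  expect_identical(nrow(ex$variants), 0L)
  expect_identical(nrow(ex$truth_variants), 0L)
})

test_that("planted truth tiers respect the filtration rules by construction", {
  cfg <- sim_config(n_samples = 10, chrom_lengths = c(chr1 = 3e7, chr2 = 3e7),
                    inbred_fraction = 0.5, seed = 71)
  map <- simulate_marker_map(cfg)
  co <- simulate_cohort(cfg, map)
  genes <- simulate_gene_intervals(cfg)
  ex <- simulate_exome_variants(co$truth, genes, cfg)
  v <- as.data.frame(ex$variants)
  v$key <- paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")
  tr <- ex$truth_variants
  j <- match(paste(tr$sample, tr$key), paste(v$sample, v$key))
  expect_false(anyNA(j))
  vv <- v[j, ]

  best <- tr$tier == "best_candidate"
  expect_gt(sum(best), 0L)
  # never reported homozygous in any database
  nh <- cbind(vv$nhom_db1, vv$nhom_db2, vv$nhom_db3)[best, , drop = FALSE]
  expect_true(all(is.na(nh) | nh == 0L))
  # inside an implanted segment longer than 3 Mb
  segs <- co$truth$segments
  for (i in which(best)) {
    hit <- segs$sample == vv$sample[i] & segs$chrom == vv$chrom[i] &
      segs$start <= vv$pos[i] & segs$end > vv$pos[i]
    expect_true(any(hit))
    expect_gt(max(segs$end[hit] - segs$start[hit]), 3e6)
  }
  # a drawn homozygote count above zero always demotes from best-candidate
  any_hom <- rowSums(cbind(vv$nhom_db1, vv$nhom_db2, vv$nhom_db3) > 0,
                     na.rm = TRUE) > 0
  expect_true(all(tr$tier[any_hom] != "best_candidate"))
  # LFF-and-above tiers are homozygous, functional, low-frequency
  lffish <- tr$tier %in% c("LFF", "LFF_D", "best_candidate")
  expect_true(all(vv$zygosity[lffish] == "hom_alt"))
  expect_true(all(vv$consequence[lffish] != "synonymous"))
  af_max <- apply(cbind(vv$af_db1, vv$af_db2, vv$af_db3), 1,
                  function(x) if (all(is.na(x))) 0 else max(x, na.rm = TRUE))
  expect_true(all(af_max[lffish] < 0.05))
})

test_that("variants planted in no gene are intergenic and non-candidate", {
  cfg <- sim_config(n_samples = 6, chrom_lengths = c(chr1 = 2e7),
                    inbred_fraction = 0.5, gene_density = 2e-6, seed = 19)
  map <- simulate_marker_map(cfg)
  co <- simulate_cohort(cfg, map)
  genes <- simulate_gene_intervals(cfg)
  ex <- simulate_exome_variants(co$truth, genes, cfg)
  inter <- ex$variants$gene_id == "intergenic"
  expect_gt(sum(inter), 0L)
  expect_true(all(ex$truth_variants$tier[inter] == "non_candidate"))
})

test_that("gene-set generator honours enrichment, size bounds and the null", {
  universe <- paste0("G", 1:500)
  query <- paste0("G", 1:10)
  s <- simulate_gene_sets(universe, set_size = 100, enrichment = 1,
                          query = query, seed = 1)
  expect_true(all(query %in% s$members))
  expect_identical(length(s$members), 100L)

  s_all <- simulate_gene_sets(universe, set_size = 500, seed = 1)
  expect_setequal(s_all$members, universe)
  expect_error(simulate_gene_sets(universe, set_size = 501),
               "exceeds universe size")

  # enrichment 0: mean query overlap across seeds matches the hypergeometric
  # expectation |query| * set_size / |universe|
  ov <- vapply(1:200, function(seed) {
    st <- simulate_gene_sets(universe, set_size = 100, enrichment = 0,
                             seed = seed)
    sum(query %in% st$members)
  }, numeric(1))
  expected <- 10 * 100 / 500
  se <- sqrt(10 * 0.2 * 0.8 / 200)    # binomial-ish SE of the mean
  expect_lt(abs(mean(ov) - expected), 3 * se)
})
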