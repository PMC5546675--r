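# The filtration cascade: flags, ROH context, tiers, cohort summary, Ti/Tv.

test_that("blacklist and low-copy CNV overlap set the exclusion flags", {
  v <- make_variants(
    make_variant(sample = "s1", pos = 100L, ref = "A", alt = "AT",
                 consequence = "frameshift"),
    make_variant(sample = "s1", pos = 5000L),
    make_variant(sample = "s2", pos = 5000L))
  bl <- data.frame(chrom = "chr1", pos = 100L, ref = "A", alt = "AT")
  cnv <- data.frame(sample = "s1", chrom = "chr1", start = 4000L, end = 6000L,
                    copy_number = 1L)
  out <- apply_blacklist_and_cnv(v, bl, cnv)
  expect_identical(out$in_blacklist, c(TRUE, FALSE, FALSE))
  expect_identical(out$in_cnv, c(FALSE, TRUE, FALSE))  # CNV is sample-specific

  a <- tier_variants(out)
  expect_identical(a$exclusion_reason[1], "blacklist")
  expect_identical(a$exclusion_reason[2], "possible hemizygosity")
  expect_identical(a$tier[3], "best_candidate")

  # copy-neutral CNV does not flag
  cnv2 <- cnv; cnv2$copy_number <- 2L
  expect_false(any(apply_blacklist_and_cnv(v, NULL, cnv2)$in_cnv))
  # empty lists leave variants unchanged
  expect_identical(apply_blacklist_and_cnv(v, NULL, NULL), v)
})

test_that("ROH context assignment respects the half-open boundary", {
  segs <- data.frame(sample = "s1", chrom = "chr1",
                     start = 1000000L, end = 7900000L, length = 6900000L,
                     n_snps = 1000L, n_het = 0L, n_missing = 0L,
                     stringsAsFactors = FALSE)
  v <- make_variants(
    make_variant(sample = "s1", pos = 5000000L, roh_length = NA_real_),
    make_variant(sample = "s1", pos = 7899999L, roh_length = NA_real_),  # last bp in
    make_variant(sample = "s1", pos = 7900000L, roh_length = NA_real_),  # 1 bp past
    make_variant(sample = "s1", pos = 1000000L, roh_length = NA_real_),  # first bp
    make_variant(sample = "s2", pos = 5000000L, roh_length = NA_real_))  # other sample
  out <- assign_roh_context(v, segs)
  expect_equal(out$roh_length,
               c(6900000, 6900000, NA, 6900000, NA))
})

test_that("context assignment matches a naive containment sweep on synthetic data", {
  cfg <- sim_config(n_samples = 8, chrom_lengths = c(chr1 = 2e7, chr2 = 2e7),
                    inbred_fraction = 0.5, seed = 29)
  map <- simulate_marker_map(cfg)
  co <- simulate_cohort(cfg, map)
  genes <- simulate_gene_intervals(cfg)
  ex <- simulate_exome_variants(co$truth, genes, cfg)
  runs <- detect_rohs(co$genotypes, roh_params())
  got <- assign_roh_context(ex$variants, runs)$roh_length
  expect_equal(got, oracle_roh_context(ex$variants, runs))
})

test_that("the reference best-candidate rows tier as best candidates", {
  a <- tier_variants(table3_fixture())
  expect_identical(sum(a$is_best), 4L)
  expect_setequal(a$gene_id[a$is_best], c("MEGF8", "ANO2", "GAD1", "FMN1"))
  # MEGF8: tolerated SIFT but damaging PP2 + MT passes the 2-of-3 consensus
  megf8 <- a[a$gene_id == "MEGF8", ]
  expect_true(megf8$is_lff_d && megf8$is_best)
})

test_that("single-rule failures exclude with the expected reasons", {
  common <- tier_variants(make_variant(af_db1 = 0.2))
  expect_identical(common$tier, "in_roh")
  expect_identical(common$exclusion_reason, "MAF >= 0.05")

  syn <- tier_variants(make_variant(consequence = "synonymous"))
  expect_identical(syn$exclusion_reason, "non-functional consequence")

  short_roh <- tier_variants(make_variant(roh_length = 5e5))
  expect_match(short_roh$exclusion_reason, "not in ROH")

  no_roh <- tier_variants(make_variant(roh_length = NA_real_))
  expect_identical(no_roh$tier, "excluded")

  miss <- tier_variants(make_variant(zygosity = "missing"))
  expect_identical(miss$tier, "excluded")
  expect_identical(miss$exclusion_reason, "missing genotype")

  het <- tier_variants(make_variant(zygosity = "het"))
  expect_identical(het$exclusion_reason, "not homozygous")
})

test_that("best-candidate gating: ROH size, rarity and database homozygotes", {
  # damaging + novel but ROH exactly 3 Mb: not strictly greater -> LFF_D only
  at3 <- tier_variants(make_variant(roh_length = 3e6))
  expect_identical(at3$tier, "LFF_D")
  # moderately rare (>= 1e-4) is not "extremely rare"
  mod <- tier_variants(make_variant(af_db1 = 5e-4))
  expect_identical(mod$tier, "LFF_D")
  # one database homozygote kills best-candidate
  hom1 <- tier_variants(make_variant(nhom_db2 = 1L))
  expect_identical(hom1$tier, "LFF_D")
  # extremely rare (< 1e-4), never homozygous, ROH > 3 Mb -> best
  ok <- tier_variants(make_variant(af_db3 = 6.64e-5, nhom_db1 = 0L,
                                   nhom_db2 = 0L, nhom_db3 = 0L))
  expect_identical(ok$tier, "best_candidate")
})

test_that("tier set inclusions hold on random synthetic variant tables", {
  cfg <- sim_config(n_samples = 8, chrom_lengths = c(chr1 = 3e7),
                    inbred_fraction = 0.6, seed = 37)
  map <- simulate_marker_map(cfg)
  co <- simulate_cohort(cfg, map)
  genes <- simulate_gene_intervals(cfg)
  ex <- simulate_exome_variants(co$truth, genes, cfg)
  v <- assign_roh_context(ex$variants, detect_rohs(co$genotypes, roh_params()))
  a <- tier_variants(v)
  expect_true(all(!a$is_best | a$is_lff_d))
  expect_true(all(!a$is_lff_d | a$is_lff))
  expect_true(all(!a$is_lff_brain | a$is_lff))
  expect_true(all(!a$is_lff | a$in_roh))
  # every non-LFF variant carries exactly one machine-readable reason
  expect_identical(sum(!is.na(a$exclusion_reason)), sum(!a$is_lff))

  # row order never affects the tiering (predicates are conjunctive)
  perm <- sample(nrow(v))
  a2 <- tier_variants(v[perm, ])
  key <- function(x) paste(x$sample, x$key)
  expect_identical(a2$tier[order(key(a2))], a$tier[order(key(a))])
})

test_that("cohort summary uses distinct-variant semantics in the All row", {
  # two samples share one variant: All counts it once
  shared <- make_variant(sample = "pA", chrom = "chr9", pos = 777L)
  shared2 <- shared; shared2$sample <- "pB"
  own <- make_variant(sample = "pB", chrom = "chr9", pos = 999L)
  a <- tier_variants(make_variants(shared, shared2, own))
  tt <- summarize_tiers(a)
  per_sample_sum <- sum(tt$n_lff[tt$sample != "All"])
  expect_identical(per_sample_sum, 3L)
  expect_identical(tt$n_lff[tt$sample == "All"], 2L)   # sum - 1
})

test_that("Ti/Tv counts transitions over transversions and handles edge cases", {
  v <- data.frame(ref = c("A", "C", "A", "G"), alt = c("G", "T", "C", "T"))
  expect_equal(compute_titv(v), 1.0)

  v2 <- data.frame(ref = c(rep("A", 60), rep("A", 24)),
                   alt = c(rep("G", 60), rep("T", 24)))
  expect_equal(compute_titv(v2), 2.5)

  all_ti <- data.frame(ref = "A", alt = "G")
  expect_warning(r <- compute_titv(all_ti), "no transversions")
  expect_true(is.na(r))

  indels <- data.frame(ref = c("A", "AT"), alt = c("AT", "A"))
  expect_warning(r2 <- compute_titv(indels), "no SNVs")
  expect_true(is.na(r2))
})
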