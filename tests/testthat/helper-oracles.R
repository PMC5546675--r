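# Brute-force oracles and fixture builders, implemented independently of the
# package's vectorized code paths (naive loops, declarative scans).

# Naive re-derivation of the scanning-window ROH rules: explicit per-window
# loops, declarative end trimming, then the run-level filters.
oracle_detect_rohs <- function(gm, params = roh_params()) {
  out <- list()
  for (s in seq_along(gm$sample_ids)) {
    for (chr in unique(gm$map$chrom)) {
      idx <- which(gm$map$chrom == chr)
      pos <- gm$map$pos[idx]
      g <- gm$calls[s, idx]
      # split into gap-free blocks
      cut <- which(diff(pos) > params$max_gap)
      starts <- c(1, cut + 1)
      ends <- c(cut, length(idx))
      for (bi in seq_along(starts)) {
        sel <- starts[bi]:ends[bi]
        runs <- oracle_scan_block(g[sel], pos[sel], params)
        for (r in runs)
          out[[length(out) + 1L]] <- data.frame(
            sample = gm$sample_ids[s], chrom = chr, start = r$start,
            end = r$end, length = r$length, n_snps = r$n_snps,
            n_het = r$n_het, n_missing = r$n_missing,
            stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(sample = character(), chrom = character(),
                      start = integer(), end = integer(), length = integer(),
                      n_snps = integer(), n_het = integer(),
                      n_missing = integer(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$sample, res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

oracle_scan_block <- function(g, pos, params) {
  n <- length(g)
  w <- min(params$window_snps, n)
  n_win <- n - w + 1L
  win_hom <- logical(n_win)
  for (st in seq_len(n_win)) {
    win <- g[st:(st + w - 1L)]
    win_hom[st] <- sum(win == 1L) <= params$max_het_in_run &&
      sum(win == -9L) <= params$max_missing_in_run
  }
  flag <- logical(n)
  for (i in seq_len(n)) {
    cov <- max(1L, i - w + 1L):min(i, n_win)
    flag[i] <- mean(win_hom[cov]) > params$window_threshold
  }

  runs <- list()
  i <- 1L
  while (i <= n) {
    if (!flag[i]) { i <- i + 1L; next }
    j <- i
    while (j < n && flag[j + 1L]) j <- j + 1L

    a <- i; b <- j
    ok <- TRUE
    if (params$end_refine) {
      hw <- ceiling(w / 2)
      # declarative left end: smallest homozygous index with no het inside
      # its terminal half-window (windows clipped at the untrimmed right end)
      a <- NA_integer_
      for (cand in i:j) {
        win <- cand:min(cand + hw - 1L, j)
        if (g[cand] %in% c(0L, 2L) && !any(g[win] == 1L)) { a <- cand; break }
      }
      if (is.na(a)) ok <- FALSE
      if (ok) {
        b <- NA_integer_
        for (cand in j:a) {
          win <- max(cand - hw + 1L, a):cand
          if (g[cand] %in% c(0L, 2L) && !any(g[win] == 1L)) { b <- cand; break }
        }
        if (is.na(b)) ok <- FALSE
      }
    }
    if (ok) {
      n_snps <- b - a + 1L
      len <- pos[b] + 1L - pos[a]
      if (n_snps >= params$min_snps && len >= params$min_length &&
          len / n_snps <= params$min_density)
        runs[[length(runs) + 1L]] <- list(
          start = pos[a], end = pos[b] + 1L, length = len, n_snps = n_snps,
          n_het = sum(g[a:b] == 1L), n_missing = sum(g[a:b] == -9L))
    }
    i <- j + 1L
  }
  runs
}

# O(n * m) containment sweep for variant -> ROH assignment.
oracle_roh_context <- function(variants, segments) {
  out <- rep(NA_real_, nrow(variants))
  for (i in seq_len(nrow(variants))) {
    for (k in seq_len(nrow(segments))) {
      if (variants$sample[i] == segments$sample[k] &&
          variants$chrom[i] == segments$chrom[k] &&
          variants$pos[i] >= segments$start[k] &&
          variants$pos[i] < segments$end[k]) {
        out[i] <- segments$length[k]
        break
      }
    }
  }
  out
}

# Naive per-sample gene-in-ROH recount (interval sweep).
oracle_genes_in_rohs <- function(segments, genes, sample) {
  segs <- segments[segments$sample == sample, , drop = FALSE]
  hit <- character()
  for (gi in seq_len(nrow(genes))) {
    for (k in seq_len(nrow(segs))) {
      if (genes$chrom[gi] == segs$chrom[k] &&
          genes$start[gi] < segs$end[k] && genes$end[gi] > segs$start[k]) {
        hit <- c(hit, genes$gene_id[gi])
        break
      }
    }
  }
  length(unique(hit))
}

# Random genotype fixture for oracle-equivalence sweeps: mixes homozygous
# stretches with noisy regions so qualifying and failing runs both occur.
random_roh_fixture <- function(n_markers, seed, spacing_mean = 5000) {
  set.seed(seed)
  gaps <- pmax(1, round(rexp(n_markers, 1 / spacing_mean)))
  pos <- cumsum(gaps)
  g <- integer(n_markers)
  i <- 1L
  while (i <= n_markers) {
    run_len <- min(sample(5:120, 1), n_markers - i + 1L)
    block <- i:(i + run_len - 1L)
    kind <- sample(c("hom", "noisy"), 1)
    if (kind == "hom") {
      g[block] <- sample(c(0L, 2L), run_len, replace = TRUE)
      flip <- runif(run_len) < 0.02
      g[block][flip] <- 1L
      mis <- runif(run_len) < 0.02
      g[block][mis] <- -9L
    } else {
      g[block] <- sample(c(0L, 1L, 2L, -9L), run_len, replace = TRUE,
                         prob = c(0.35, 0.4, 0.2, 0.05))
    }
    i <- i + run_len
  }
  map <- marker_map(chrom = "chr1", pos = pos - 1L)
  genotype_matrix(matrix(g, nrow = 1), map, sample_ids = "S1")
}

# Roh params scaled to the small fixtures used in oracle sweeps.
small_roh_params <- function(min_length = 5e4, ...) {
  roh_params(min_length = min_length, min_snps = 10, window_snps = 10,
             max_missing_in_run = 2, min_density = 5e4, max_gap = 5e4,
             long_threshold = 2e5, ...)
}

# Minimal annotated-variant row builder with sensible defaults (a damaging
# missense homozygote inside a long ROH); override any field by name.
make_variant <- function(...) {
  base <- list(
    sample = "P1", chrom = "chr1", pos = 1000L, ref = "A", alt = "G",
    zygosity = "hom_alt", gene_id = "GENE1", transcript = "NM_000001",
    consequence = "missense", sift_score = 0.01, pp2_score = 0.99,
    mt_score = 1, phylop = 5, af_db1 = NA_real_, af_db2 = NA_real_,
    af_db3 = NA_real_, nhom_db1 = NA_integer_, nhom_db2 = NA_integer_,
    nhom_db3 = NA_integer_, fpkm_brain = 10, roh_length = 6e6,
    in_blacklist = FALSE, in_cnv = FALSE)
  over <- list(...)
  base[names(over)] <- over
  annotated_variants(as.data.frame(base, stringsAsFactors = FALSE))
}

# Bind several make_variant() rows.
make_variants <- function(...) {
  rows <- list(...)
  out <- do.call(rbind, lapply(rows, as.data.frame))
  annotated_variants(out)
}

# Reference best-candidate fixture: four variant rows with known annotations,
# frequencies and ROH sizes that must all reach the best-candidate tier
# (1-based positions converted here).  One row carries a tolerated SIFT call,
# exercising the 2-of-3 damaging consensus.
table3_fixture <- function() {
  make_variants(
    make_variant(sample = "P2", chrom = "chr19", pos = 42840266L - 1L,
                 ref = "G", alt = "A", gene_id = "MEGF8",
                 transcript = "NM_001271938", sift_score = 0.90,
                 pp2_score = 0.999, mt_score = 1, phylop = 5.141,
                 roh_length = 3.3e6),
    make_variant(sample = "P3", chrom = "chr12", pos = 5963280L - 1L,
                 ref = "G", alt = "A", gene_id = "ANO2",
                 transcript = "NM_001278596", sift_score = 0.00,
                 pp2_score = 1.000, mt_score = 1, phylop = 4.955,
                 af_db3 = 0.0000664, nhom_db1 = 0L, nhom_db2 = 0L,
                 nhom_db3 = 0L, roh_length = 6.9e6),
    make_variant(sample = "P6", chrom = "chr2", pos = 171687546L - 1L,
                 ref = "A", alt = "G", gene_id = "GAD1",
                 transcript = "NM_000817", sift_score = 0.02,
                 pp2_score = 0.986, mt_score = 1, phylop = 8.962,
                 roh_length = 5.8e6),
    make_variant(sample = "P7", chrom = "chr15", pos = 33256378L - 1L,
                 ref = "G", alt = "C", gene_id = "FMN1",
                 transcript = "NM_001103184", sift_score = 0.06,
                 pp2_score = 1.00, mt_score = 0.99, phylop = 9.435,
                 af_db3 = 0.00000828, nhom_db1 = 0L, nhom_db2 = 0L,
                 nhom_db3 = 0L, roh_length = 4.0e6))
}

# Seven-patient cohort fixture with fixed per-patient tier counts: builds,
# for each patient, the stated number of in-ROH / LFF / brain / damaging /
# best-candidate variants with no gene shared across patients.
table2_fixture <- function() {
  counts <- data.frame(
    patient = paste0("P", 1:7),
    variants = c(1064L, 1561L, 1217L, 991L, 1988L, 1711L, 1579L),
    lff = c(15L, 27L, 24L, 7L, 24L, 9L, 14L),
    lff_genes = c(15L, 25L, 16L, 7L, 21L, 9L, 14L),
    brain = c(6L, 14L, 7L, 3L, 13L, 5L, 8L),
    brain_genes = c(6L, 14L, 7L, 3L, 11L, 5L, 8L),
    lffd = c(7L, 14L, 4L, 3L, 9L, 2L, 6L),
    best = c(0L, 1L, 1L, 0L, 0L, 1L, 1L))
  rows <- list()
  pos <- 0L
  for (i in seq_len(nrow(counts))) {
    p <- counts$patient[i]
    n_lff <- counts$lff[i]
    n_genes <- counts$lff_genes[i]
    n_brain_g <- counts$brain_genes[i]
    # brain expression is a gene-level property: a doubled gene contributes
    # two brain variants.  Doubled genes are drawn from the brain list first
    # (brain variants - brain genes of them) and non-brain genes for the rest.
    n_extra <- n_lff - n_genes
    db <- counts$brain[i] - n_brain_g            # doubled brain genes
    gene_names <- sprintf("%s_G%02d", p, seq_len(n_genes))
    brain_pool <- gene_names[seq_len(n_brain_g)]
    nonbrain_pool <- setdiff(gene_names, brain_pool)
    extras <- c(brain_pool[seq_len(db)], nonbrain_pool[seq_len(n_extra - db)])
    gene_of <- c(gene_names, extras[!is.na(extras)])
    brain_gene <- gene_of %in% brain_pool
    stopifnot(length(gene_of) == n_lff,
              sum(brain_gene) == counts$brain[i])  # fixture consistency
    for (v in seq_len(n_lff)) {
      pos <- pos + 10L
      damaging <- v <= counts$lffd[i]
      best <- v <= counts$best[i]
      rows[[length(rows) + 1L]] <- data.frame(
        sample = p, chrom = "chr1", pos = pos, ref = "A", alt = "G",
        zygosity = "hom_alt", gene_id = gene_of[v],
        consequence = "missense",
        sift_score = if (damaging) 0.0 else 0.5,
        pp2_score = if (damaging) 1.0 else 0.1,
        mt_score = if (damaging) 1.0 else 0.1,
        af_db1 = if (best) NA_real_ else 0.01,
        fpkm_brain = if (brain_gene[v]) 5 else 0.2,
        roh_length = if (best) 5e6 else 2e6,
        stringsAsFactors = FALSE)
    }
    # non-LFF in-ROH filler: synonymous homozygotes in their own genes
    for (v in seq_len(counts$variants[i] - n_lff)) {
      pos <- pos + 10L
      rows[[length(rows) + 1L]] <- data.frame(
        sample = p, chrom = "chr1", pos = pos, ref = "A", alt = "G",
        zygosity = "hom_alt", gene_id = sprintf("%s_SYN%04d", p, v),
        consequence = "synonymous", sift_score = NA_real_,
        pp2_score = NA_real_, mt_score = NA_real_, af_db1 = 0.2,
        fpkm_brain = 0.1, roh_length = 2e6, stringsAsFactors = FALSE)
    }
  }
  annotated_variants(data.table::rbindlist(rows, fill = TRUE))
}
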