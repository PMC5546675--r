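# synthetic_data: genotype panels with implanted autozygous segments, matching
# annotated exome variants, gene maps and gene sets, with ground truth for
# every generated structure.  The generator emulates the study design this
# package implements: a cohort genotyped on a dense SNP array in which a
# minority of subjects carry several multi-Mb autozygous segments from recent
# inbreeding, and whole-exome variant calls concentrated in genes, with rare
# damaging homozygous variants planted inside the segments.

# Planting margins: candidate variants are kept clear of gate boundaries so
# that truth tiers are stable under the one-marker boundary uncertainty of
# ROH detection (see the methods vignette).
.LFF_SEG_MIN <- 1.2e6     # plant LFF-tier variants only in segments >= 1.2 Mb
.BEST_SEG_MIN <- 3.5e6    # plant best candidates only in segments > 3.5 Mb
.SEG_EDGE_MARGIN <- 1e4   # keep candidate variants 10 kb off segment edges

#' Simulation configuration
#'
#' Defaults describe a scaled-down cohort: 30 subjects, three 50 Mb
#' chromosomes, one marker per kb with Beta(3, 3) allele frequencies
#' (array-like common-SNP ascertainment), 7/30 of subjects inbred with a
#' Poisson(5) number of Exponential(8 Mb) autozygous segments, and exome
#' variants at 10 per Mb inside and outside ROHs.
#'
#' @param n_samples number of subjects.
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param marker_density markers per bp.
#' @param allele_freq_dist `c(alpha, beta)` of the Beta distribution for
#'   marker allele frequencies.
#' @param inbred_fraction proportion of subjects given autozygous segments.
#' @param segments_per_inbred mean segment count per inbred subject (Poisson).
#' @param segment_length_mean mean segment length in bp (Exponential).
#' @param genotype_error_rate probability a truly homozygous call inside a
#'   segment is rendered heterozygous.
#' @param missing_rate per-call missing probability inside segments.
#' @param variant_rate_in_roh,variant_rate_outside planted exome variants per
#'   Mb inside / outside implanted segments.
#' @param rare_af_range `c(min, max)` database AF for planted rare variants
#'   (log-uniform; "novel" is represented as absent from all databases).
#' @param titv target transition/transversion ratio of planted SNVs.
#' @param gene_density genes per bp of the simulated gene map.
#' @param gene_length_mean mean gene length in bp.
#' @param tier_probs sampling weights for the intended tier of each in-ROH
#'   variant (`non_candidate`, `LFF`, `LFF_D`, `best_candidate`).
#' @param seed master RNG seed; every generator derives a deterministic
#'   per-stage sub-seed from it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 30,
                       chrom_lengths = c(chr1 = 5e7, chr2 = 5e7, chr3 = 5e7),
                       marker_density = 1e-3,
                       allele_freq_dist = c(3, 3),
                       inbred_fraction = 7 / 30,
                       segments_per_inbred = 5,
                       segment_length_mean = 8e6,
                       genotype_error_rate = 0.002,
                       missing_rate = 0.01,
                       variant_rate_in_roh = 10,
                       variant_rate_outside = 10,
                       rare_af_range = c(1e-8, 1e-4),
                       titv = 2.5,
                       gene_density = 1e-5,
                       gene_length_mean = 3e4,
                       tier_probs = c(non_candidate = 0.92, LFF = 0.05,
                                      LFF_D = 0.02, best_candidate = 0.01),
                       seed = 1L) {
  .check_pos(n_samples, "n_samples")
  if (length(chrom_lengths) == 0L) .stopf("`chrom_lengths` must be non-empty")
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths))))
    .stopf("`chrom_lengths` must be a named vector")
  if (any(chrom_lengths <= 0)) .stopf("chromosome lengths must be positive")
  .check_pos(marker_density, "marker_density")
  if (length(allele_freq_dist) != 2L || any(allele_freq_dist <= 0))
    .stopf("`allele_freq_dist` must be two positive Beta parameters")
  .check_prob(inbred_fraction, "inbred_fraction")
  .check_pos(segments_per_inbred, "segments_per_inbred")
  .check_pos(segment_length_mean, "segment_length_mean")
  .check_prob(genotype_error_rate, "genotype_error_rate")
  .check_prob(missing_rate, "missing_rate")
  .check_pos(variant_rate_in_roh, "variant_rate_in_roh", strict = FALSE)
  .check_pos(variant_rate_outside, "variant_rate_outside", strict = FALSE)
  if (length(rare_af_range) != 2L || any(rare_af_range < 0) ||
      rare_af_range[1] > rare_af_range[2] || rare_af_range[2] > 1)
    .stopf("`rare_af_range` must be an increasing pair in [0, 1]")
  .check_pos(titv, "titv")
  .check_pos(gene_density, "gene_density")
  .check_pos(gene_length_mean, "gene_length_mean")
  if (length(tier_probs) != 4L || any(tier_probs < 0) || sum(tier_probs) <= 0)
    .stopf("`tier_probs` must be four non-negative weights")
  structure(list(n_samples = as.integer(n_samples),
                 chrom_lengths = chrom_lengths,
                 marker_density = marker_density,
                 allele_freq_dist = allele_freq_dist,
                 inbred_fraction = inbred_fraction,
                 segments_per_inbred = segments_per_inbred,
                 segment_length_mean = segment_length_mean,
                 genotype_error_rate = genotype_error_rate,
                 missing_rate = missing_rate,
                 variant_rate_in_roh = variant_rate_in_roh,
                 variant_rate_outside = variant_rate_outside,
                 rare_af_range = rare_af_range,
                 titv = titv,
                 gene_density = gene_density,
                 gene_length_mean = gene_length_mean,
                 tier_probs = tier_probs,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a marker map
#'
#' Draws `round(length * marker_density)` distinct marker positions per
#' chromosome and a Beta-distributed allele frequency per marker.
#'
#' @param config a [sim_config()].
#' @return A [marker_map()].
#' @export
simulate_marker_map <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.stage_seed(config$seed, "marker_map"))
  pieces <- list()
  for (chr in names(config$chrom_lengths)) {
    L <- config$chrom_lengths[[chr]]
    n <- round(L * config$marker_density)
    if (n == 0L) {
      .warnf("chromosome '%s' receives 0 markers at density %g", chr,
             config$marker_density)
      next
    }
    pos <- sort(sample.int(L, n)) - 1L
    freq <- stats::rbeta(n, config$allele_freq_dist[1], config$allele_freq_dist[2])
    ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1L),
                  character(1))
    pieces[[chr]] <- data.frame(chrom = chr, pos = pos, a1 = ref, a2 = alt,
                                freq = freq, stringsAsFactors = FALSE)
  }
  if (length(pieces) == 0L)
    .stopf("no chromosome received any marker; increase `marker_density`")
  df <- do.call(rbind, pieces)
  marker_map(df$chrom, df$pos, a1 = df$a1, a2 = df$a2, freq = df$freq)
}

#' Simulate a gene map
#'
#' Places non-overlapping gene intervals (Exponential lengths) along each
#' chromosome at the configured density.
#'
#' @param config a [sim_config()].
#' @return A sorted gene interval table (see [gene_intervals()]).
#' @export
simulate_gene_intervals <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.stage_seed(config$seed, "genes"))
  pieces <- list()
  gid <- 0L
  for (chr in names(config$chrom_lengths)) {
    L <- config$chrom_lengths[[chr]]
    n <- round(L * config$gene_density)
    if (n == 0L) next
    starts <- sort(sample.int(L - 1L, n)) - 1L
    lens <- pmax(1000, round(stats::rexp(n, 1 / config$gene_length_mean)))
    ends <- pmin(starts + lens, c(starts[-1L], L))  # clip at the next gene
    keep <- starts < ends
    ids <- sprintf("GENE%05d", gid + seq_len(sum(keep)))
    gid <- gid + sum(keep)
    pieces[[chr]] <- data.frame(gene_id = ids, chrom = chr,
                                start = starts[keep], end = ends[keep],
                                stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, pieces)
  gene_intervals(df$gene_id, df$chrom, df$start, df$end)
}

#' Simulate a genotyped cohort with implanted autozygous segments
#'
#' Outside implanted segments genotypes are drawn from Hardy-Weinberg
#' equilibrium at each marker's allele frequency.  Inside a segment the
#' subject is homozygous for one allele drawn by its frequency, then perturbed
#' by `genotype_error_rate` (hom rendered het) and `missing_rate`.  Segments
#' drawn beyond a chromosome end are truncated (recorded in the truth).
#'
#' @param config a [sim_config()].
#' @param map a [marker_map()] (typically from [simulate_marker_map()]).
#' @return list with `genotypes` (a [genotype_matrix()]) and `truth`
#'   (class `truth_records`: `$samples`, `$segments` with columns
#'   `sample, chrom, start, end, truncated`).
#' @export
simulate_cohort <- function(config, map) {
  stopifnot(inherits(config, "sim_config"), inherits(map, "marker_map"))
  set.seed(.stage_seed(config$seed, "cohort"))
  n <- config$n_samples
  m <- nrow(map)
  samples <- sprintf("S%03d", seq_len(n))

  n_inbred <- round(config$inbred_fraction * n)
  inbred <- sort(sample.int(n, n_inbred))

  # draw, truncate and merge implanted segments per inbred subject
  seg_rows <- list()
  chr_names <- names(config$chrom_lengths)
  chr_w <- config$chrom_lengths / sum(config$chrom_lengths)
  for (si in inbred) {
    k <- stats::rpois(1L, config$segments_per_inbred)
    if (k == 0L) next
    chrom <- sample(chr_names, k, replace = TRUE, prob = chr_w)
    len <- round(stats::rexp(k, 1 / config$segment_length_mean))
    L <- config$chrom_lengths[chrom]
    start <- floor(stats::runif(k, 0, pmax(1, L - len)))
    end <- start + len
    truncated <- end > L
    end <- pmin(end, L)
    keep <- start < end
    if (!any(keep)) next
    gr <- GenomicRanges::reduce(.gr0(chrom[keep], start[keep], end[keep]),
                                with.revmap = TRUE)
    merged_trunc <- vapply(gr$revmap, function(ix) any(truncated[keep][ix]),
                           logical(1))
    seg_rows[[length(seg_rows) + 1L]] <- data.frame(
      sample = samples[si],
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      truncated = merged_trunc, stringsAsFactors = FALSE)
  }
  segments <- if (length(seg_rows) > 0L) do.call(rbind, seg_rows) else
    data.frame(sample = character(), chrom = character(), start = integer(),
               end = integer(), truncated = logical(), stringsAsFactors = FALSE)
  segments <- segments[order(segments$sample, segments$chrom, segments$start), ,
                       drop = FALSE]
  rownames(segments) <- NULL

  # HWE background for everyone
  calls <- matrix(stats::rbinom(n * m, 2L, rep(map$freq, each = n)), nrow = n)

  # overwrite implanted segments with perturbed homozygous calls
  if (nrow(segments) > 0L) {
    row_of <- match(segments$sample, samples)
    for (k in seq_len(nrow(segments))) {
      j <- which(map$chrom == segments$chrom[k] &
                 map$pos >= segments$start[k] & map$pos < segments$end[k])
      if (length(j) == 0L) next
      g <- 2L * stats::rbinom(length(j), 1L, map$freq[j])
      err <- stats::runif(length(j)) < config$genotype_error_rate
      g[err] <- 1L
      mis <- stats::runif(length(j)) < config$missing_rate
      g[mis] <- -9L
      calls[row_of[k], j] <- g
    }
  }

  truth <- structure(list(samples = samples, segments = segments),
                     class = "truth_records")
  list(genotypes = genotype_matrix(calls, map, sample_ids = samples),
       truth = truth)
}

## ---- exome variants --------------------------------------------------------

#' @noRd
#' Independent (generator-side) evaluation of the tier a planted annotation
#' earns under the filtration rules, given the length of its containing truth
#' segment (NA outside segments).  Deliberately a separate code path from
#' tier_variants(), so truth labels and the pipeline can cross-check.
.truth_tier <- function(zygosity, consequence, af, nhom, n_damaging, seg_len) {
  if (zygosity != "hom_alt") return("non_candidate")
  if (is.na(seg_len) || seg_len < 1e6) return("non_candidate")
  if (!consequence %in% FUNCTIONAL_CONSEQUENCES) return("non_candidate")
  reported <- af[!is.na(af)]
  if (length(reported) > 0L && max(reported) >= 0.05) return("non_candidate")
  if (n_damaging < 2L) return("LFF")
  novel <- length(reported) == 0L
  rare <- novel || max(reported) < 1e-4
  never_hom <- all(is.na(nhom) | nhom == 0L)
  if (seg_len > 3e6 && rare && never_hom) return("best_candidate")
  "LFF_D"
}

#' @noRd
#' Draw predictor scores yielding exactly `n_d` damaging calls among
#' SIFT/PP2/MT (damaging picks which predictors at random).
.draw_predictors <- function(n_d) {
  which_d <- rep(FALSE, 3L)
  if (n_d > 0L) which_d[sample.int(3L, n_d)] <- TRUE
  c(sift = if (which_d[1]) stats::runif(1, 0, 0.049) else stats::runif(1, 0.05, 1),
    pp2  = if (which_d[2]) stats::runif(1, 0.957, 1) else stats::runif(1, 0, 0.95),
    mt   = if (which_d[3]) stats::runif(1, 0.5, 1)  else stats::runif(1, 0, 0.49))
}

#' @noRd
#' Damaging-consensus draw per the generator's model: each predictor damaging
#' independently with probability 0.9, forced to at least 2 of 3.
.draw_damaging_count <- function() max(2L, stats::rbinom(1L, 3L, 0.9))

#' @noRd Ref/alt pair with the configured transition probability.
.draw_alleles <- function(titv) {
  ref <- sample(c("A", "C", "G", "T"), 1L)
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  if (stats::runif(1) < titv / (titv + 1)) alt <- transition[[ref]]
  else alt <- sample(setdiff(c("A", "C", "G", "T"), c(ref, transition[[ref]])), 1L)
  c(ref, alt)
}

#' Simulate annotated exome variants with planted candidate tiers
#'
#' Variants are planted at the configured per-Mb rates inside and outside each
#' subject's implanted segments.  Candidate-tier variants (LFF and above) are
#' placed inside genes, away from segment edges, and receive annotations
#' constructed to earn their tier; non-candidates receive one deterministic
#' blocking feature (synonymous consequence, common allele frequency, or
#' heterozygous call).  A variant whose drawn annotation conflicts with the
#' requested tier (e.g. a database homozygote count above zero) has its truth
#' tier downgraded accordingly.  Positions falling in no gene are recorded as
#' intergenic and forced non-candidate.
#'
#' @param truth `truth_records` from [simulate_cohort()].
#' @param genes gene interval table.
#' @param config a [sim_config()].
#' @return list with `variants` (an [annotated_variants()] table) and
#'   `truth_variants` (`sample, key, tier`).
#' @export
simulate_exome_variants <- function(truth, genes, config) {
  stopifnot(inherits(truth, "truth_records"), inherits(config, "sim_config"))
  if (nrow(genes) == 0L || any(genes$start >= genes$end))
    .stopf("`genes` must be a non-degenerate gene interval table")
  set.seed(.stage_seed(config$seed, "variants"))
  genome_len <- sum(config$chrom_lengths)
  rows <- list()

  gene_at <- function(chrom, pos) {
    j <- which(genes$chrom == chrom & genes$start <= pos & genes$end > pos)
    if (length(j) == 0L) NA_integer_ else j[1L]
  }

  for (s in truth$samples) {
    segs <- truth$segments[truth$segments$sample == s, , drop = FALSE]
    seg_total <- if (nrow(segs) > 0L) sum(segs$end - segs$start) else 0

    plant <- function(region_chrom, region_start, region_end, seg_len) {
      # intended tier for one in-ROH variant; demoted if the segment cannot
      # host the tier (length margins) -- the demotion is part of the truth
      tier <- sample(names(config$tier_probs), 1L, prob = config$tier_probs)
      if (tier == "best_candidate" && seg_len <= .BEST_SEG_MIN) tier <- "LFF_D"
      if (tier %in% c("LFF", "LFF_D") && seg_len < .LFF_SEG_MIN) tier <- "non_candidate"
      if (tier != "non_candidate") {
        lo <- region_start + .SEG_EDGE_MARGIN
        hi <- region_end - .SEG_EDGE_MARGIN
        cand <- which(genes$chrom == region_chrom & genes$end > lo & genes$start < hi)
        if (length(cand) == 0L) tier <- "non_candidate"
        else {
          w <- pmin(genes$end[cand], hi) - pmax(genes$start[cand], lo)
          gi <- cand[sample.int(length(cand), 1L, prob = w)]
          pos <- floor(stats::runif(1, max(genes$start[gi], lo),
                                    min(genes$end[gi], hi)))
        }
      }
      if (tier == "non_candidate")
        pos <- floor(stats::runif(1, region_start, region_end))
      .make_variant(s, region_chrom, pos, tier, seg_len, config, genes, gene_at)
    }

    # inside implanted segments
    if (nrow(segs) > 0L) {
      for (k in seq_len(nrow(segs))) {
        seg_len <- segs$end[k] - segs$start[k]
        n_v <- stats::rpois(1L, config$variant_rate_in_roh * seg_len / 1e6)
        for (v in seq_len(n_v))
          rows[[length(rows) + 1L]] <-
            plant(segs$chrom[k], segs$start[k], segs$end[k], seg_len)
      }
    }

    # outside segments: uniform over the genome, rejecting segment hits
    n_out <- stats::rpois(1L, config$variant_rate_outside *
                                (genome_len - seg_total) / 1e6)
    chr_w <- config$chrom_lengths / genome_len
    for (v in seq_len(n_out)) {
      repeat {
        chrom <- sample(names(config$chrom_lengths), 1L, prob = chr_w)
        pos <- floor(stats::runif(1, 0, config$chrom_lengths[[chrom]]))
        inside <- nrow(segs) > 0L && any(segs$chrom == chrom & segs$start <= pos &
                                         segs$end > pos)
        if (!inside) break
      }
      rows[[length(rows) + 1L]] <-
        .make_variant(s, chrom, pos, "non_candidate", NA_real_, config, genes,
                      gene_at)
    }
  }

  if (length(rows) == 0L) {
    empty <- annotated_variants(data.frame(
      sample = character(), chrom = character(), pos = integer(),
      ref = character(), alt = character(), zygosity = character(),
      gene_id = character(), consequence = character(), stringsAsFactors = FALSE))
    return(list(variants = empty,
                truth_variants = data.frame(sample = character(), key = character(),
                                            tier = character(),
                                            stringsAsFactors = FALSE)))
  }
  df <- as.data.frame(data.table::rbindlist(rows))
  # drop accidental duplicate positions within a sample
  df <- df[!duplicated(df[, c("sample", "chrom", "pos")]), , drop = FALSE]
  variants <- annotated_variants(df[, setdiff(names(df), "tier"), drop = FALSE])
  truth_variants <- data.frame(
    sample = df$sample,
    key = .variant_key(df$chrom, df$pos, df$ref, df$alt),
    tier = df$tier, stringsAsFactors = FALSE)
  list(variants = variants, truth_variants = truth_variants)
}

#' @noRd
#' Build one variant row with annotations earning `tier`; the recorded truth
#' tier is re-evaluated from the drawn annotation by .truth_tier().
.make_variant <- function(s, chrom, pos, tier, seg_len, config, genes, gene_at) {
  al <- .draw_alleles(config$titv)
  gi <- gene_at(chrom, pos)
  intergenic <- is.na(gi)
  if (intergenic) tier <- "non_candidate"

  zyg <- "hom_alt"
  consequence <- "missense"
  af <- c(NA_real_, NA_real_, NA_real_)
  nhom <- c(NA_integer_, NA_integer_, NA_integer_)
  n_d <- 0L
  fpkm <- if (stats::runif(1) < 0.5)
    exp(stats::runif(1, log(1.5), log(100))) else stats::runif(1, 0, 0.9)

  draw_rare_af <- function() {
    lo <- max(config$rare_af_range[1], 1e-8)
    hi <- max(config$rare_af_range[2], lo * 1.0001)
    exp(stats::runif(1, log(lo), log(hi)))
  }

  if (tier == "non_candidate") {
    # one deterministic blocking feature; everything else free
    block <- if (intergenic) "intergenic" else
      sample(c("synonymous", "common_af", "het"), 1L)
    zyg <- if (!is.na(seg_len)) {
      if (stats::runif(1) < 0.8) "hom_alt" else "het"
    } else if (stats::runif(1) < 0.4) "hom_alt" else "het"
    consequence <- sample(c("missense", "synonymous", "other"), 1L,
                          prob = c(0.4, 0.4, 0.2))
    af <- stats::rbeta(3, config$allele_freq_dist[1], config$allele_freq_dist[2])
    nhom <- stats::rpois(3, 5)
    n_d <- sample(0:3, 1L)
    if (block == "intergenic") consequence <- "other"
    if (block == "synonymous") consequence <- "synonymous"
    if (block == "common_af") {
      consequence <- sample(FUNCTIONAL_CONSEQUENCES, 1L)
      af[1] <- stats::runif(1, 0.06, 0.5)
    }
    if (block == "het") {
      zyg <- "het"
      consequence <- sample(FUNCTIONAL_CONSEQUENCES, 1L)
    }
  } else if (tier == "LFF") {
    consequence <- sample(FUNCTIONAL_CONSEQUENCES, 1L,
                          prob = c(0.7, 0.08, 0.02, 0.02, 0.08, 0.06, 0.04))
    af <- stats::runif(3, 1e-3, 0.049)
    nhom <- stats::rpois(3, 1)
    n_d <- sample(0:1, 1L)
  } else if (tier == "LFF_D") {
    consequence <- sample(FUNCTIONAL_CONSEQUENCES, 1L,
                          prob = c(0.7, 0.08, 0.02, 0.02, 0.08, 0.06, 0.04))
    n_d <- .draw_damaging_count()
    if (!is.na(seg_len) && seg_len > 3e6) {
      # must be blocked from best-candidate: moderately rare or seen homozygous
      if (stats::runif(1) < 0.5) {
        af <- c(stats::runif(1, 2e-4, 0.04), NA_real_, NA_real_)
        nhom <- c(0L, NA_integer_, NA_integer_)
      } else {
        af <- c(draw_rare_af(), NA_real_, NA_real_)
        nhom <- c(1L + stats::rpois(1L, 1), NA_integer_, NA_integer_)
      }
    } else {
      af <- c(stats::runif(1, 1e-4, 0.04), NA_real_, NA_real_)
      nhom <- c(0L, NA_integer_, NA_integer_)
    }
  } else if (tier == "best_candidate") {
    consequence <- "missense"
    n_d <- .draw_damaging_count()
    if (stats::runif(1) < 0.5) {
      af <- c(NA_real_, NA_real_, NA_real_)      # novel
      nhom <- c(NA_integer_, NA_integer_, NA_integer_)
    } else {
      af <- c(draw_rare_af(), NA_real_, NA_real_)
      nhom <- c(0L, 0L, 0L)
    }
  }

  pred <- .draw_predictors(n_d)
  phylop <- if (n_d >= 2L) stats::runif(1, 2, 10) else stats::runif(1, -2, 3)
  truth <- .truth_tier(zyg, consequence, af, nhom, n_d, seg_len)

  data.frame(
    sample = s, chrom = chrom, pos = as.integer(pos), ref = al[1], alt = al[2],
    zygosity = zyg,
    gene_id = if (intergenic) "intergenic" else genes$gene_id[gi],
    transcript = if (intergenic) NA_character_ else
      sprintf("NM_%06d", gi),
    consequence = consequence,
    sift_score = unname(pred["sift"]), pp2_score = unname(pred["pp2"]),
    mt_score = unname(pred["mt"]), phylop = phylop,
    af_db1 = af[1], af_db2 = af[2], af_db3 = af[3],
    nhom_db1 = as.integer(nhom[1]), nhom_db2 = as.integer(nhom[2]),
    nhom_db3 = as.integer(nhom[3]),
    fpkm_brain = fpkm, tier = truth, stringsAsFactors = FALSE)
}

#' Simulate a gene set with controllable query enrichment
#'
#' Builds a named gene set of `set_size` members from `universe`.  When
#' `enrichment > 0` and a `query` list is supplied, `ceiling(enrichment *
#' length(query))` query genes are forced into the set; the remainder is drawn
#' uniformly from the rest of the universe (so at `enrichment = 0` the overlap
#' with any query follows the hypergeometric null).
#'
#' @param universe character vector of gene ids.
#' @param set_size number of members (`<= length(universe)`).
#' @param enrichment fraction of `query` forced into the set, in `[0, 1]`.
#' @param query optional character vector of query gene ids.
#' @param seed RNG seed.
#' @param name,description set metadata.
#' @return A [gene_set()].
#' @export
simulate_gene_sets <- function(universe, set_size, enrichment = 0,
                               query = NULL, seed = 1L,
                               name = "sim_set", description = "simulated") {
  universe <- unique(as.character(universe))
  if (set_size > length(universe))
    .stopf("set_size (%d) exceeds universe size (%d)", set_size, length(universe))
  .check_prob(enrichment, "enrichment")
  set.seed(as.integer(seed))
  forced <- character()
  if (enrichment > 0 && !is.null(query) && length(query) > 0L) {
    query <- unique(as.character(query))
    n_forced <- min(ceiling(enrichment * length(query)), length(query), set_size)
    forced <- sample(query, n_forced)
  }
  rest <- setdiff(universe, forced)
  fill <- sample(rest, set_size - length(forced))
  gene_set(name, c(forced, fill), description = description)
}
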