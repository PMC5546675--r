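# variant_prioritization: the filtration cascade over annotated variants
# inside ROHs -- LFF (low-frequency functional homozygous) -> brain-expressed
# -> LFF-D (damaging consensus) -> best candidate -- with blacklist and
# CNV/hemizygosity exclusions and Ti/Tv QC.

#' Tier parameters of the filtration cascade
#'
#' @param maf_max LFF requires every reported database AF below this (0.05).
#' @param roh_min LFF requires the containing ROH to be at least this long (1 Mb).
#' @param best_roh_min best candidates require a ROH strictly longer than this (3 Mb).
#' @param rare_af_max "extremely rare": maximum reported AF below this (1e-4)
#'   when the variant is not novel (absent from all databases).
#' @param fpkm_min brain-expressed means FPKM strictly above this (1).
#' @param damaging_min predictors (of SIFT, PolyPhen-2 HDIV, MutationTaster)
#'   that must call damaging for the LFF-D consensus (2 of 3).
#' @param functional_consequences consequence classes counted as functional.
#' @return list of class `tier_params`.
#' @export
tier_params <- function(maf_max = 0.05, roh_min = 1e6, best_roh_min = 3e6,
                        rare_af_max = 1e-4, fpkm_min = 1, damaging_min = 2,
                        functional_consequences = FUNCTIONAL_CONSEQUENCES) {
  .check_prob(maf_max, "maf_max")
  .check_pos(roh_min, "roh_min")
  .check_pos(best_roh_min, "best_roh_min")
  .check_prob(rare_af_max, "rare_af_max")
  .check_pos(fpkm_min, "fpkm_min", strict = FALSE)
  .check_pos(damaging_min, "damaging_min")
  structure(list(maf_max = maf_max, roh_min = roh_min,
                 best_roh_min = best_roh_min, rare_af_max = rare_af_max,
                 fpkm_min = fpkm_min, damaging_min = damaging_min,
                 functional_consequences = functional_consequences),
            class = "tier_params")
}

#' Flag blacklisted variants and variants in possible-hemizygosity CNVs
#'
#' `in_blacklist` is set by exact (chrom, pos, ref, alt) match against the
#' false-positive list; `in_cnv` is set when the variant position falls in a
#' same-sample CNV interval with copy number below 2, where an apparently
#' homozygous call may in fact be hemizygous.
#'
#' @param variants an [annotated_variants()] table.
#' @param blacklist `NULL`, a character vector of `chrom:pos:ref:alt` keys
#'   (0-based pos), or a data.frame with those four columns.
#' @param cnvs `NULL` or a CNV table from [read_cnvs()].
#' @return The variants with `in_blacklist` / `in_cnv` updated.
#' @export
apply_blacklist_and_cnv <- function(variants, blacklist = NULL, cnvs = NULL) {
  v <- variants
  if (!is.null(blacklist)) {
    keys <- if (is.character(blacklist)) blacklist else
      .variant_key(blacklist$chrom, blacklist$pos, blacklist$ref, blacklist$alt)
    v$in_blacklist <- .variant_key(v$chrom, v$pos, v$ref, v$alt) %in% keys
  }
  if (!is.null(cnvs) && nrow(cnvs) > 0L) {
    loss <- cnvs[cnvs$copy_number < 2L, , drop = FALSE]
    v$in_cnv <- FALSE
    if (nrow(loss) > 0L) {
      ov <- GenomicRanges::findOverlaps(
        .gr0(v$chrom, v$pos, v$pos + 1L),
        .gr0(loss$chrom, loss$start, loss$end))
      same <- v$sample[S4Vectors::queryHits(ov)] ==
        loss$sample[S4Vectors::subjectHits(ov)]
      v$in_cnv[unique(S4Vectors::queryHits(ov)[same])] <- TRUE
    }
  }
  v
}

#' Attach the containing ROH length to each variant
#'
#' A variant at position p is inside a same-sample segment `[start, end)` when
#' `start <= p < end`; `roh_length` is that segment's length, `NA` otherwise.
#'
#' @param variants an [annotated_variants()] table.
#' @param segments ROH segments from [detect_rohs()] (per-sample sorted,
#'   disjoint).
#' @return The variants with `roh_length` filled in.
#' @export
assign_roh_context <- function(variants, segments) {
  v <- variants
  v$roh_length <- NA_real_
  if (nrow(v) == 0L || is.null(segments) || nrow(segments) == 0L) return(v)
  ov <- GenomicRanges::findOverlaps(
    .gr0(v$chrom, v$pos, v$pos + 1L),
    .gr0(segments$chrom, segments$start, segments$end))
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  same <- v$sample[qh] == segments$sample[sh]
  v$roh_length[qh[same]] <- segments$length[sh[same]]
  v
}

#' Tier variants through the filtration cascade
#'
#' A variant is **LFF** when it is homozygous for the alternate allele, inside
#' a ROH of at least `roh_min`, has a functional consequence, every reported
#' database AF below `maf_max`, and is neither blacklisted nor in a
#' possible-hemizygosity CNV.  **LFF-brain** additionally requires brain
#' expression above `fpkm_min`; **LFF-D** requires at least `damaging_min` of
#' the three predictors to call damaging; a **best candidate** is an LFF-D
#' variant in a ROH strictly longer than `best_roh_min` that is novel (absent
#' from all databases) or rarer than `rare_af_max`, and never reported
#' homozygous (reported homozygote counts all zero; absent counts are treated
#' as zero).
#'
#' @param variants an [annotated_variants()] table with ROH context assigned
#'   and flags applied.
#' @param params a [tier_params()].
#' @return `data.frame` with one row per variant: `sample, key, gene_id`,
#'   logical columns `in_roh, is_lff, is_lff_brain, is_lff_d, is_best`, the
#'   highest `tier` reached (`excluded`, `in_roh`, `LFF`, `LFF_brain`,
#'   `LFF_D`, `best_candidate`) and, for non-LFF variants, a single
#'   machine-readable `exclusion_reason`.
#' @export
tier_variants <- function(variants, params = tier_params()) {
  v <- variants
  n <- nrow(v)
  af <- cbind(v$af_db1, v$af_db2, v$af_db3)
  nhom <- cbind(v$nhom_db1, v$nhom_db2, v$nhom_db3)
  max_af <- apply(af, 1L, function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE))
  novel <- is.na(max_af)
  n_damaging <- rowSums(cbind(v$sift_call == "D", v$pp2_call == "D",
                              v$mt_call == "D"), na.rm = TRUE)

  zyg_ok <- v$zygosity == "hom_alt"
  in_roh <- !is.na(v$roh_length) & v$zygosity != "missing"
  roh_ok <- !is.na(v$roh_length) & v$roh_length >= params$roh_min
  func_ok <- v$consequence %in% params$functional_consequences
  maf_ok <- novel | max_af < params$maf_max
  flags_ok <- !v$in_blacklist & !v$in_cnv

  is_lff <- zyg_ok & roh_ok & func_ok & maf_ok & flags_ok &
    v$zygosity != "missing"
  is_brain <- is_lff & !is.na(v$fpkm_brain) & v$fpkm_brain > params$fpkm_min
  is_d <- is_lff & n_damaging >= params$damaging_min
  rare_ok <- novel | max_af < params$rare_af_max
  never_hom <- rowSums(nhom > 0L, na.rm = TRUE) == 0L
  is_best <- is_d & !is.na(v$roh_length) & v$roh_length > params$best_roh_min &
    rare_ok & never_hom

  # one reason per non-LFF variant, in a fixed report order (the predicates
  # are conjunctive, so tiers themselves are order-independent)
  reason <- rep(NA_character_, n)
  fill <- function(cond, msg) {
    take <- !is_lff & is.na(reason) & cond
    reason[take] <<- msg
  }
  fill(v$zygosity == "missing", "missing genotype")
  fill(v$in_blacklist, "blacklist")
  fill(v$in_cnv, "possible hemizygosity")
  fill(!roh_ok, sprintf("not in ROH >= %g bp", params$roh_min))
  fill(!zyg_ok, "not homozygous")
  fill(!func_ok, "non-functional consequence")
  fill(!maf_ok, sprintf("MAF >= %g", params$maf_max))

  tier <- rep("excluded", n)
  tier[in_roh] <- "in_roh"
  tier[is_lff] <- "LFF"
  tier[is_brain] <- "LFF_brain"
  tier[is_d] <- "LFF_D"
  tier[is_best] <- "best_candidate"

  data.frame(sample = v$sample,
             key = .variant_key(v$chrom, v$pos, v$ref, v$alt),
             gene_id = v$gene_id,
             in_roh = in_roh, is_lff = is_lff, is_lff_brain = is_brain,
             is_lff_d = is_d, is_best = is_best, tier = tier,
             exclusion_reason = reason, stringsAsFactors = FALSE)
}

#' Cohort tier summary (per-sample counts plus a distinct-count "All" row)
#'
#' Counts, per sample, the variants in ROH regions and the variants (and
#' distinct genes) at each tier.  The `All` row counts DISTINCT variant keys
#' and genes across samples: a variant shared by two subjects counts once.
#'
#' @param assignments output of [tier_variants()].
#' @return `data.frame` with columns `sample, n_variants, n_lff,
#'   n_lff_genes, n_brain, n_brain_genes, n_lffd, n_lffd_genes, n_best`;
#'   the final row has `sample == "All"`.
#' @export
summarize_tiers <- function(assignments) {
  a <- assignments
  count_block <- function(rows) {
    sub <- a[rows, , drop = FALSE]
    genes_of <- function(sel) length(unique(sub$gene_id[sel]))
    data.frame(
      n_variants = sum(sub$in_roh),
      n_lff = sum(sub$is_lff), n_lff_genes = genes_of(sub$is_lff),
      n_brain = sum(sub$is_lff_brain), n_brain_genes = genes_of(sub$is_lff_brain),
      n_lffd = sum(sub$is_lff_d), n_lffd_genes = genes_of(sub$is_lff_d),
      n_best = sum(sub$is_best))
  }
  samples <- sort(unique(a$sample))
  per <- do.call(rbind, lapply(samples, function(s) count_block(a$sample == s)))
  per <- cbind(sample = samples, per, stringsAsFactors = FALSE)

  dedup <- a[!duplicated(a$key), , drop = FALSE]
  # distinct semantics: recount tiers over unique variant keys
  all_row <- data.frame(
    sample = "All",
    n_variants = length(unique(a$key[a$in_roh])),
    n_lff = length(unique(a$key[a$is_lff])),
    n_lff_genes = length(unique(a$gene_id[a$is_lff])),
    n_brain = length(unique(a$key[a$is_lff_brain])),
    n_brain_genes = length(unique(a$gene_id[a$is_lff_brain])),
    n_lffd = length(unique(a$key[a$is_lff_d])),
    n_lffd_genes = length(unique(a$gene_id[a$is_lff_d])),
    n_best = length(unique(a$key[a$is_best])),
    stringsAsFactors = FALSE)
  rbind(per, all_row)
}

#' Transition/transversion ratio of SNVs
#'
#' Transitions are A<->G and C<->T; everything else among single-nucleotide
#' changes is a transversion.  Indels and multi-nucleotide records are
#' ignored.  Returns `NA` with a warning when no transversion is observed.
#'
#' @param variants an [annotated_variants()] table (or any data.frame with
#'   `ref` and `alt` columns).
#' @return A single number (or `NA`).
#' @export
compute_titv <- function(variants) {
  nt <- c("A", "C", "G", "T")
  snv <- variants$ref %in% nt & variants$alt %in% nt & variants$ref != variants$alt
  if (!any(snv)) {
    .warnf("no SNVs found; Ti/Tv undefined")
    return(NA_real_)
  }
  ref <- variants$ref[snv]; alt <- variants$alt[snv]
  ti <- (ref == "A" & alt == "G") | (ref == "G" & alt == "A") |
        (ref == "C" & alt == "T") | (ref == "T" & alt == "C")
  if (all(ti)) {
    .warnf("no transversions observed; Ti/Tv undefined")
    return(NA_real_)
  }
  sum(ti) / sum(!ti)
}
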