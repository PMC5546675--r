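# pipeline_report: orchestrate simulate -> ROH -> prioritize -> enrich as one
# seeded, configured run, and render the survey-style report tables.

#' Pipeline run configuration
#'
#' Either a [sim_config()] (everything is simulated) or paths to the inputs:
#' a genotype panel, a variant VCF + annotation TSV, a gene BED and a gene-set
#' GMT (optionally a blacklist TSV and CNV TSV).
#'
#' @param sim a [sim_config()], or `NULL` when real inputs are given.
#' @param genotypes_path,genotypes_format genotype panel (see [read_genotypes()]).
#' @param variants_vcf,variants_tsv annotated variant inputs.
#' @param genes_bed gene intervals BED.
#' @param sets_gmt gene sets GMT.
#' @param blacklist_tsv optional false-positive variant list
#'   (`chrom pos ref alt`, 1-based pos, header).
#' @param cnvs_tsv optional CNV table (see [read_cnvs()]).
#' @param roh a [roh_params()].
#' @param tiers a [tier_params()].
#' @param n_perm permutations for the enrichment stage.
#' @param out_dir output directory (created on run).
#' @param seed master seed; each stage derives a deterministic sub-seed.
#' @return list of class `run_config`.
#' @export
run_config <- function(sim = NULL, genotypes_path = NULL,
                       genotypes_format = "ped", variants_vcf = NULL,
                       variants_tsv = NULL, genes_bed = NULL, sets_gmt = NULL,
                       blacklist_tsv = NULL, cnvs_tsv = NULL,
                       roh = roh_params(), tiers = tier_params(),
                       n_perm = 9999, out_dir = "autozyg_run", seed = 1L) {
  if (is.null(sim)) {
    need <- c(genotypes_path = genotypes_path, variants_vcf = variants_vcf,
              variants_tsv = variants_tsv, genes_bed = genes_bed,
              sets_gmt = sets_gmt)
    if (length(need) < 5L)
      .stopf("without `sim`, all of genotypes_path, variants_vcf, variants_tsv, genes_bed, sets_gmt are required")
    for (nm in names(need)) if (!file.exists(need[[nm]]))
      .stopf("input file for `%s` not found: %s", nm, need[[nm]])
  } else if (!inherits(sim, "sim_config")) .stopf("`sim` must be a sim_config()")
  for (p in c(blacklist_tsv, cnvs_tsv)) if (!is.null(p) && !file.exists(p))
    .stopf("input file not found: %s", p)
  structure(list(sim = sim, genotypes_path = genotypes_path,
                 genotypes_format = genotypes_format,
                 variants_vcf = variants_vcf, variants_tsv = variants_tsv,
                 genes_bed = genes_bed, sets_gmt = sets_gmt,
                 blacklist_tsv = blacklist_tsv, cnvs_tsv = cnvs_tsv,
                 roh = roh, tiers = tiers, n_perm = n_perm,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

#' Render a report table in one of the survey styles
#'
#' * `table1`: per-patient ROH survey (run count, median/max/total length,
#'   genes within ROHs) from [summarize_rohs()] output.
#' * `table2`: per-patient tier counts with an "All" distinct-count row, as
#'   "n (genes)" strings, from [summarize_tiers()] output.
#' * `table3`: best-candidate variants, one row each, from an
#'   [annotated_variants()] table joined with [tier_variants()] output.
#'
#' @param x stage output appropriate for the style.
#' @param style `"table1"`, `"table2"` or `"table3"`.
#' @param assignments for `table3`: the [tier_variants()] output.
#' @return A `data.frame` ready to write as TSV.
#' @export
render_table <- function(x, style = c("table1", "table2", "table3"),
                         assignments = NULL) {
  style <- match.arg(style)
  if (style == "table1") {
    return(data.frame(
      Patient = x$sample,
      `Number of ROHs >1Mb` = x$n_rohs,
      `Median dimension (bp)` = x$median_length,
      `Max dimension (bp)` = x$max_length,
      `Amount of the genome within ROHs (bp)` = x$total_length,
      `Number of genes within ROHs` = x$n_genes,
      check.names = FALSE, stringsAsFactors = FALSE))
  }
  if (style == "table2") {
    fmt <- function(n, g) ifelse(n > 0, sprintf("%d (%d)", n, g), "0")
    return(data.frame(
      Patient = x$sample,
      Variants = x$n_variants,
      `LFF variants` = fmt(x$n_lff, x$n_lff_genes),
      `LFF variants in genes expressed in brain` = fmt(x$n_brain, x$n_brain_genes),
      `LFF-D variants` = fmt(x$n_lffd, x$n_lffd_genes),
      `Best candidate variants` = ifelse(x$n_best > 0, as.character(x$n_best), ""),
      check.names = FALSE, stringsAsFactors = FALSE))
  }
  # table3
  empty <- data.frame(
    Patient = character(), Variant = character(), `Gene name` = character(),
    `Gene ID` = character(), `cDNA change` = character(),
    `AA change` = character(), `SIFT (Pred.)` = character(),
    `PP2_HDIV (Pred.)` = character(), `MT (Pred.)` = character(),
    PP100V = numeric(), Frequency = character(), `ROH size` = character(),
    check.names = FALSE, stringsAsFactors = FALSE)
  if (is.null(assignments)) .stopf("table3 needs the tier `assignments`")
  best <- assignments[assignments$is_best, , drop = FALSE]
  if (nrow(best) == 0L) return(empty)
  v <- as.data.frame(x)
  v$key <- .variant_key(v$chrom, v$pos, v$ref, v$alt)
  j <- match(paste(best$sample, best$key), paste(v$sample, v$key))
  v <- v[j, , drop = FALSE]
  pred <- function(score, call) ifelse(is.na(score), "", sprintf("%.2f (%s)", score, call))
  max_af <- apply(cbind(v$af_db1, v$af_db2, v$af_db3), 1L,
                  function(a) if (all(is.na(a))) NA_real_ else max(a, na.rm = TRUE))
  out <- data.frame(
    Patient = v$sample,
    Variant = sprintf("%s:%d%s>%s", v$chrom, v$pos + 1L, v$ref, v$alt),
    `Gene name` = v$gene_id,
    `Gene ID` = ifelse(is.na(v$transcript), "", v$transcript),
    `cDNA change` = if (!is.null(v$cdna_change)) v$cdna_change else "",
    `AA change` = if (!is.null(v$aa_change)) v$aa_change else "",
    `SIFT (Pred.)` = pred(v$sift_score, v$sift_call),
    `PP2_HDIV (Pred.)` = pred(v$pp2_score, v$pp2_call),
    `MT (Pred.)` = pred(v$mt_score, v$mt_call),
    PP100V = v$phylop,
    Frequency = ifelse(is.na(max_af), "Novel", format(max_af, digits = 3)),
    `ROH size` = sprintf("%.1f Mb", v$roh_length / 1e6),
    check.names = FALSE, stringsAsFactors = FALSE)
  out[order(out$Patient), , drop = FALSE]
}

#' Run the full pipeline
#'
#' simulate (or load) -> detect ROHs -> select ROH-individuals -> assign ROH
#' context -> tier variants -> summarize -> gene-set enrichment, writing
#' `table1.tsv`, `table2.tsv`, `table3.tsv`, `enrichment.tsv`, `rohs.bed` and
#' `manifest.json` into `out_dir`.  Identical config + seed reproduce the
#' artifacts byte for byte.  Any stage error aborts the run, removes partial
#' outputs, and names the failing stage.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with the in-memory stage results
#'   (`genotypes, truth, segments, summaries, selected, variants,
#'   assignments, tier_table, enrichment, paths`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(config$out_dir,
                     c("table1.tsv", "table2.tsv", "table3.tsv",
                       "enrichment.tsv", "rohs.bed", "manifest.json"))
  names(paths) <- c("table1", "table2", "table3", "enrichment", "rohs", "manifest")
  stage <- "setup"
  on_fail <- function(e) {
    unlink(paths)
    .stopf("pipeline failed at stage '%s': %s", stage, conditionMessage(e))
  }
  tryCatch({
    stage <- "inputs"
    truth <- NULL
    if (!is.null(config$sim)) {
      sim <- config$sim
      map <- simulate_marker_map(sim)
      genes <- simulate_gene_intervals(sim)
      cohort <- simulate_cohort(sim, map)
      gm <- cohort$genotypes
      truth <- cohort$truth
      ex <- simulate_exome_variants(truth, genes, sim)
      variants <- ex$variants
      truth$variants <- ex$truth_variants
      blacklist <- NULL; cnvs <- NULL
      sets <- NULL   # built after the LFF list exists (below)
    } else {
      gm <- read_genotypes(config$genotypes_path, config$genotypes_format)
      genes <- read_gene_intervals(config$genes_bed)
      variants <- read_variant_annotations(config$variants_vcf, config$variants_tsv)
      sets <- read_gene_sets(config$sets_gmt)
      blacklist <- if (!is.null(config$blacklist_tsv)) {
        bl <- as.data.frame(data.table::fread(config$blacklist_tsv,
                                              colClasses = list(character = "chrom")))
        bl$pos <- bl$pos - 1L   # TSV is 1-based
        bl
      }
      cnvs <- if (!is.null(config$cnvs_tsv)) read_cnvs(config$cnvs_tsv)
    }

    stage <- "roh_mapping"
    segments <- detect_rohs(gm, config$roh)
    summaries <- summarize_rohs(segments, genes, config$roh,
                                sample_ids = gm$sample_ids)
    selected <- select_roh_individuals(summaries, config$roh)

    stage <- "variant_prioritization"
    sel_variants <- variants[variants$sample %in% selected, , drop = FALSE]
    sel_segments <- segments[segments$sample %in% selected, , drop = FALSE]
    sel_variants <- apply_blacklist_and_cnv(sel_variants, blacklist, cnvs)
    sel_variants <- assign_roh_context(sel_variants, sel_segments)
    assignments <- tier_variants(sel_variants, config$tiers)
    tier_table <- summarize_tiers(assignments)

    stage <- "set_enrichment"
    lff_genes <- unique(assignments$gene_id[assignments$is_lff])
    roh_gene_ov <- GenomicRanges::findOverlaps(
      .gr0(sel_segments$chrom, sel_segments$start, sel_segments$end),
      .gr0(genes$chrom, genes$start, genes$end))
    roh_genes <- unique(genes$gene_id[S4Vectors::subjectHits(roh_gene_ov)])
    background <- unique(c(roh_genes, lff_genes))
    if (is.null(sets)) {
      sets <- list(disease_set = simulate_gene_sets(
        universe = genes$gene_id, set_size = max(1L, round(0.1 * nrow(genes))),
        enrichment = 0, seed = .stage_seed(config$seed, "sets"),
        name = "disease_set"))
    }
    enr <- list()
    if (length(lff_genes) > 0L) {
      for (s in sets) {
        r <- permutation_overlap_test(lff_genes, s, background,
                                      n_perm = config$n_perm,
                                      seed = .stage_seed(config$seed, paste0("enr_", s$name)),
                                      match_to_roh_background = TRUE)
        enr[[s$name]] <- data.frame(
          query = "LFF_genes", target = s$name, n_query = r$n_query,
          n_overlap = r$n_overlap, overlap_fraction = r$overlap_fraction,
          n_perm = r$n_perm, n_as_extreme = r$n_as_extreme,
          empirical_p = r$empirical_p, method = r$method,
          background = r$background_name, stringsAsFactors = FALSE)
      }
    }
    enrichment <- if (length(enr) > 0L) do.call(rbind, enr) else
      data.frame(query = character(), target = character())
    rownames(enrichment) <- NULL

    stage <- "report"
    t1 <- render_table(summaries[summaries$sample %in% selected, , drop = FALSE],
                       "table1")
    t2 <- render_table(tier_table, "table2")
    t3 <- render_table(sel_variants, "table3", assignments = assignments)
    for (tb in list(list(t1, paths["table1"]), list(t2, paths["table2"]),
                    list(t3, paths["table3"]), list(enrichment, paths["enrichment"])))
      utils::write.table(tb[[1]], tb[[2]], sep = "\t", quote = FALSE,
                         row.names = FALSE)
    write_bed(sel_segments, paths["rohs"])
    manifest <- list(
      package = "autozyg",
      version = as.character(utils::packageVersion("autozyg")),
      seed = config$seed,
      n_perm = config$n_perm,
      simulated = !is.null(config$sim),
      sim = if (!is.null(config$sim)) {
        s <- unclass(config$sim)
        # named numeric vectors must serialize as JSON objects, not arrays
        s$chrom_lengths <- as.list(s$chrom_lengths)
        s$tier_probs <- as.list(s$tier_probs)
        s
      },
      inputs = Filter(Negate(is.null),
                      config[c("genotypes_path", "variants_vcf", "variants_tsv",
                               "genes_bed", "sets_gmt", "blacklist_tsv",
                               "cnvs_tsv")]),
      roh_params = unclass(config$roh),
      tier_params = unclass(config$tiers),
      selected = selected,
      outputs = as.list(paths))
    jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)

    invisible(list(genotypes = gm, genes = genes, truth = truth,
                   segments = segments, summaries = summaries,
                   selected = selected, variants = sel_variants,
                   assignments = assignments, tier_table = tier_table,
                   enrichment = enrichment, paths = paths))
  }, error = on_fail)
}
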