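# roh_mapping: run-of-homozygosity detection (PLINK-style scanning window),
# per-sample summaries, and the two-step selection of ROH-individuals.

#' ROH detection parameters
#'
#' Defaults reflect the usual array-based ROH calling conventions: runs of at
#' least 1 Mb and 50 SNPs, a 50-marker scanning window allowing one
#' heterozygous and five missing calls, runs split at inter-marker gaps above
#' 100 kb, at most 50 kb per marker, and a 4 Mb threshold above which a run is
#' counted as "long" (indicative of recent inbreeding).
#'
#' @param min_length minimum run length in bp.
#' @param min_snps minimum number of markers in a run.
#' @param max_het_in_run heterozygous calls tolerated per scanning window.
#' @param max_missing_in_run missing calls tolerated per scanning window.
#' @param max_gap maximum gap (bp) between consecutive markers inside a run.
#' @param min_density maximum bp per marker inside a run.
#' @param long_threshold bp above which a run counts as a long ROH.
#' @param window_snps scanning-window size in markers.
#' @param window_threshold minimum fraction of homozygous windows covering a
#'   marker for the marker to join a run.
#' @param end_refine trim run ends so each run starts and ends on a
#'   homozygous call with no heterozygote inside the terminal half-window
#'   (prevents runs from bleeding across flanking heterozygotes).
#' @return list of class `roh_params`.
#' @export
roh_params <- function(min_length = 1e6, min_snps = 50, max_het_in_run = 1,
                       max_missing_in_run = 5, max_gap = 1e5,
                       min_density = 5e4, long_threshold = 4e6,
                       window_snps = 50, window_threshold = 0.05,
                       end_refine = TRUE) {
  for (nm in c("min_length", "min_snps", "max_gap", "min_density",
               "long_threshold", "window_snps"))
    .check_pos(get(nm), nm)
  .check_pos(max_het_in_run, "max_het_in_run", strict = FALSE)
  .check_pos(max_missing_in_run, "max_missing_in_run", strict = FALSE)
  .check_prob(window_threshold, "window_threshold")
  structure(list(min_length = min_length, min_snps = min_snps,
                 max_het_in_run = max_het_in_run,
                 max_missing_in_run = max_missing_in_run, max_gap = max_gap,
                 min_density = min_density, long_threshold = long_threshold,
                 window_snps = window_snps, window_threshold = window_threshold,
                 end_refine = end_refine),
            class = "roh_params")
}

#' @noRd
#' Scan one gap-free block of one sample.  `g` genotype codes, `pos` 0-based
#' positions, both length n >= 1.  Returns a data.frame of runs (block-local
#' indices resolved to coordinates) or NULL.
.scan_block <- function(g, pos, params) {
  n <- length(g)
  w <- min(params$window_snps, n)
  het <- g == 1L
  mis <- g == -9L

  nw <- n - w + 1L
  chet <- c(0L, cumsum(het))
  cmis <- c(0L, cumsum(mis))
  s <- seq_len(nw)
  win_ok <- (chet[s + w] - chet[s]) <= params$max_het_in_run &
            (cmis[s + w] - cmis[s]) <= params$max_missing_in_run
  cok <- c(0L, cumsum(win_ok))

  i <- seq_len(n)
  lo <- pmax(1L, i - w + 1L)
  hi <- pmin(i, nw)
  n_cov <- hi - lo + 1L
  n_hom <- cok[hi + 1L] - cok[lo]
  flagged <- n_hom / n_cov > params$window_threshold

  if (!any(flagged)) return(NULL)
  r <- rle(flagged)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])

  hw <- as.integer(ceiling(w / 2))
  out <- vector("list", nrow(runs))
  for (k in seq_len(nrow(runs))) {
    a <- runs[k, 1L]; b <- runs[k, 2L]
    if (params$end_refine) {
      # fixpoint trim: the final left end is the smallest index whose call is
      # homozygous with no heterozygote inside its terminal half-window;
      # mirrored on the right (right windows clip at the trimmed left end)
      b0 <- b
      repeat {
        if (a > b) break
        h <- which(het[a:min(a + hw - 1L, b0)])
        if (length(h) > 0L) { a <- a + h[length(h)]; next }
        if (g[a] %in% c(1L, -9L)) { a <- a + 1L; next }
        break
      }
      repeat {
        if (b < a) break
        base <- max(b - hw + 1L, a)
        h <- which(het[base:b])
        if (length(h) > 0L) { b <- base + h[1L] - 2L; next }
        if (g[b] %in% c(1L, -9L)) { b <- b - 1L; next }
        break
      }
      if (a > b) next
    }
    n_snps <- b - a + 1L
    len <- pos[b] + 1L - pos[a]
    if (n_snps < params$min_snps) next
    if (len < params$min_length) next
    if (len / n_snps > params$min_density) next
    out[[k]] <- data.frame(start = pos[a], end = pos[b] + 1L, length = len,
                           n_snps = n_snps, n_het = sum(het[a:b]),
                           n_missing = sum(mis[a:b]))
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) NULL else do.call(rbind, out)
}

#' Detect runs of homozygosity
#'
#' Scanning-window algorithm: a `window_snps`-marker window is "homozygous"
#' when it holds at most `max_het_in_run` heterozygous and
#' `max_missing_in_run` missing calls; a marker joins a run when the fraction
#' of homozygous windows covering it exceeds `window_threshold`.  Maximal
#' flagged stretches are end-refined, split at inter-marker gaps above
#' `max_gap`, and kept when they pass `min_snps`, `min_length` and the
#' `min_density` (bp/marker) filters.
#'
#' @param gm a [genotype_matrix()].
#' @param params a [roh_params()].
#' @return `data.frame` with one row per run: `sample, chrom, start, end,
#'   length, n_snps, n_het, n_missing` (0-based half-open; `end` is one past
#'   the last marker of the run).  Per-sample runs are sorted and disjoint.
#' @export
detect_rohs <- function(gm, params = roh_params()) {
  if (!inherits(gm, "genotype_matrix")) .stopf("`gm` must be a genotype_matrix")
  if (!inherits(params, "roh_params")) .stopf("`params` must be roh_params()")
  map <- gm$map
  if (nrow(map) == 0L || nrow(gm$calls) == 0L) return(.empty_rohs())
  if (is.unsorted(.genomic_order(map$chrom, map$pos)))
    .stopf("marker map is not sorted; readers sort on load, this signals internal misuse")

  # split chromosomes into gap-free blocks once, shared across samples
  blocks <- list()
  for (chr in unique(map$chrom)) {
    idx <- which(map$chrom == chr)
    p <- map$pos[idx]
    brk <- which(diff(p) > params$max_gap)
    bs <- c(1L, brk + 1L)
    be <- c(brk, length(idx))
    for (k in seq_along(bs))
      blocks[[length(blocks) + 1L]] <- list(chrom = chr, idx = idx[bs[k]:be[k]])
  }

  res <- list()
  for (si in seq_along(gm$sample_ids)) {
    s <- gm$sample_ids[si]
    for (bl in blocks) {
      runs <- .scan_block(gm$calls[si, bl$idx], map$pos[bl$idx], params)
      if (!is.null(runs)) {
        runs$sample <- s
        runs$chrom <- bl$chrom
        res[[length(res) + 1L]] <- runs
      }
    }
  }
  if (length(res) == 0L) return(.empty_rohs())
  out <- do.call(rbind, res)
  out <- out[order(out$sample, out$chrom, out$start),
             c("sample", "chrom", "start", "end", "length", "n_snps",
               "n_het", "n_missing")]
  rownames(out) <- NULL
  out
}

.empty_rohs <- function() {
  data.frame(sample = character(), chrom = character(), start = integer(),
             end = integer(), length = integer(), n_snps = integer(),
             n_het = integer(), n_missing = integer(), stringsAsFactors = FALSE)
}

#' Summarize ROHs per sample
#'
#' Reports, per sample, the run count, the median/max/total run length, the
#' number of distinct genes overlapping any run by at least 1 bp, and the
#' count of runs longer than `long_threshold` — the per-patient quantities of
#' an ROH survey table.  The median is the interpolated (lower) median: the
#' mean of the two middle lengths for an even run count.
#'
#' @param segments output of [detect_rohs()].
#' @param genes gene intervals (from [read_gene_intervals()]); may be `NULL`,
#'   in which case `n_genes` is `NA`.
#' @param params a [roh_params()] (supplies `long_threshold`).
#' @param sample_ids samples to report (default: those present in `segments`);
#'   samples without runs get zero rows.
#' @param genome_length optional total genome length in bp; adds an `froh`
#'   column (`total_length / genome_length`) as a convenience.
#' @return `data.frame` with one row per sample.
#' @export
summarize_rohs <- function(segments, genes = NULL, params = roh_params(),
                           sample_ids = NULL, genome_length = NULL) {
  sample_ids <- sample_ids %||% sort(unique(segments$sample))
  out <- data.frame(sample = sample_ids, n_rohs = 0L, median_length = 0,
                    max_length = 0, total_length = 0, n_genes = NA_integer_,
                    n_long_rohs = 0L, stringsAsFactors = FALSE)
  if (!is.null(genes) && nrow(segments) > 0L) {
    ov <- GenomicRanges::findOverlaps(
      .gr0(segments$chrom, segments$start, segments$end),
      .gr0(genes$chrom, genes$start, genes$end))
  }
  for (k in seq_along(sample_ids)) {
    rows <- which(segments$sample == sample_ids[k])
    if (length(rows) == 0L) {
      if (!is.null(genes)) out$n_genes[k] <- 0L
      next
    }
    len <- segments$length[rows]
    out$n_rohs[k] <- length(rows)
    out$median_length[k] <- stats::median(len)
    out$max_length[k] <- max(len)
    out$total_length[k] <- sum(len)
    out$n_long_rohs[k] <- sum(len > params$long_threshold)
    if (!is.null(genes)) {
      hit <- S4Vectors::queryHits(ov) %in% rows
      out$n_genes[k] <- length(unique(genes$gene_id[S4Vectors::subjectHits(ov)[hit]]))
    }
  }
  if (!is.null(genome_length)) out$froh <- out$total_length / genome_length
  out
}

#' Select ROH-individuals by the two-step long-ROH rule
#'
#' Step 1 keeps samples with at least one run longer than `long_threshold`;
#' step 2 keeps those whose long-run count strictly exceeds the third quartile
#' (linear-interpolation, type-7 quantile) of the step-1 survivors.  The
#' strict inequality means threshold ties are excluded as a block: when all
#' survivors share one count, nobody is selected.
#'
#' @param summaries output of [summarize_rohs()].
#' @param params a [roh_params()].
#' @return Character vector of selected sample ids (may be empty).
#' @export
select_roh_individuals <- function(summaries, params = roh_params()) {
  if (nrow(summaries) == 0L) .stopf("`summaries` is empty")
  step1 <- summaries[summaries$n_long_rohs >= 1L, , drop = FALSE]
  if (nrow(step1) == 0L) {
    .warnf("no sample has a ROH longer than %g bp; selection is empty",
           params$long_threshold)
    return(character())
  }
  q3 <- stats::quantile(step1$n_long_rohs, probs = 0.75, type = 7, names = FALSE)
  step1$sample[step1$n_long_rohs > q3]
}
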