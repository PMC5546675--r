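# set_enrichment: permutation overlap test for gene lists, interval-relocation
# (INRICH-style) test for genomic regions, and hypergeometric
# over-representation with Benjamini-Hochberg correction.

.norm_genes <- function(x) unique(toupper(as.character(x)))

#' Overlap of a query gene list with a gene set
#'
#' Gene identifiers are matched case-insensitively (uppercased symbols), with
#' no alias resolution.
#'
#' @param query character vector of gene ids (non-empty).
#' @param target a [gene_set()] or character vector.
#' @return list with `n_overlap` and `fraction` (`n_overlap / length(query)`).
#' @export
overlap_fraction <- function(query, target) {
  query <- .norm_genes(query)
  if (length(query) == 0L) .stopf("`query` is empty")
  members <- .norm_genes(if (inherits(target, "gene_set")) target$members else target)
  n <- sum(query %in% members)
  list(n_overlap = n, fraction = n / length(query))
}

#' Permutation test for gene-set overlap
#'
#' Tests whether `query` overlaps `target` more than random draws of the same
#' size from `background`.  Draws are uniform without replacement; when the
#' number of distinct draws `choose(|background|, |query|)` is at most
#' `exhaustive_limit`, all draws are enumerated and the p-value is exact;
#' otherwise `n_perm` Monte-Carlo draws are used with the add-one correction
#' `p = (#{overlap >= observed} + 1) / (n_perm + 1)`, which never reports 0.
#'
#' The appropriate background is a modelling choice: to show an enrichment is
#' not explained by gene density inside ROHs, use the genes within the
#' cohort's ROH regions as background (`match_to_roh_background = TRUE`
#' records this choice in the result).
#'
#' @param query character vector of gene ids, a subset of `background`.
#' @param target a [gene_set()] or character vector.
#' @param background character vector of gene ids defining the sampling universe.
#' @param n_perm number of Monte-Carlo permutations.
#' @param seed RNG seed.
#' @param match_to_roh_background flag recorded in the result: `TRUE` when
#'   `background` is the ROH gene universe.
#' @param exhaustive_limit enumerate exhaustively when the draw count is at
#'   most this.
#' @return list of class `enrichment_result`: `target_name, n_query,
#'   n_overlap, overlap_fraction, n_perm, n_as_extreme, empirical_p, method,
#'   background_name, seed`.
#' @export
permutation_overlap_test <- function(query, target, background, n_perm = 9999,
                                     seed = 1L, match_to_roh_background = FALSE,
                                     exhaustive_limit = 1e4) {
  query <- .norm_genes(query)
  background <- .norm_genes(background)
  members <- .norm_genes(if (inherits(target, "gene_set")) target$members else target)
  if (length(query) == 0L) .stopf("`query` is empty")
  if (n_perm < 1L) .stopf("`n_perm` must be at least 1")
  off <- setdiff(query, background)
  if (length(off) > 0L)
    .stopf("query gene(s) not in background: %s%s",
           paste(head(off, 5L), collapse = ", "),
           if (length(off) > 5L) sprintf(" (and %d more)", length(off) - 5L) else "")
  if (length(intersect(members, background)) == 0L)
    .stopf("target set shares no gene with the background")

  ind <- background %in% members
  k <- length(query)
  observed <- sum(query %in% members)

  n_comb <- suppressWarnings(choose(length(background), k))
  if (is.finite(n_comb) && n_comb <= exhaustive_limit) {
    combos <- utils::combn(length(background), k)
    perm <- colSums(matrix(ind[combos], nrow = k))
    n_extreme <- sum(perm >= observed)
    p <- n_extreme / ncol(combos)
    n_used <- ncol(combos)
    method <- "exhaustive"
  } else {
    set.seed(as.integer(seed))
    perm <- integer(n_perm)
    N <- length(background)
    for (i in seq_len(n_perm)) perm[i] <- sum(ind[sample.int(N, k)])
    n_extreme <- sum(perm >= observed)
    p <- (n_extreme + 1) / (n_perm + 1)
    n_used <- n_perm
    method <- "sampled"
  }
  structure(list(
    target_name = if (inherits(target, "gene_set")) target$name else "target",
    n_query = k, n_overlap = observed, overlap_fraction = observed / k,
    n_perm = n_used, n_as_extreme = n_extreme, empirical_p = p,
    method = method,
    background_name = if (match_to_roh_background) "roh_genes" else "all_genes",
    match_to_roh_background = match_to_roh_background,
    seed = seed), class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "enrichment vs '%s': overlap %d/%d (%.1f%%), empirical p = %.4g (%s, %d draws, background %s)\n",
    x$target_name, x$n_overlap, x$n_query, 100 * x$overlap_fraction,
    x$empirical_p, x$method, x$n_perm, x$background_name))
  invisible(x)
}

#' Interval-relocation enrichment test (INRICH-style)
#'
#' The statistic is the number of query intervals (e.g. ROH segments)
#' overlapping at least one target-set gene.  The null relocates each
#' interval uniformly at random within its chromosome, preserving its length
#' and matching its gene content: placements are resampled until the
#' relocated interval covers a total gene count within `match_tol` (default
#' +/-20%) of the original, so the null respects local gene density.
#'
#' @param intervals data.frame with `chrom, start, end` (0-based half-open).
#' @param target a [gene_set()] or character vector of gene ids.
#' @param genes gene interval table ([gene_intervals()]).
#' @param n_perm permutations.
#' @param seed RNG seed.
#' @param chrom_lengths named vector; defaults to the per-chromosome maximum
#'   coordinate seen in `genes`/`intervals` (with a warning).
#' @param match_tol relative tolerance on the relocated gene count.
#' @param max_resample placement attempts per interval per permutation before
#'   accepting the closest match seen.
#' @return list of class `interval_enrichment_result` with `n_intervals`,
#'   `statistic`, `n_perm`, `n_as_extreme`, `empirical_p`, `relocation`.
#' @export
interval_enrichment_test <- function(intervals, target, genes, n_perm = 999,
                                     seed = 1L, chrom_lengths = NULL,
                                     match_tol = 0.2, max_resample = 200) {
  if (n_perm < 1L) .stopf("`n_perm` must be at least 1")
  members <- .norm_genes(if (inherits(target, "gene_set")) target$members else target)
  is_target <- toupper(genes$gene_id) %in% members
  if (is.null(chrom_lengths)) {
    .warnf("`chrom_lengths` not given; using max coordinate per chromosome")
    chrom_lengths <- tapply(c(genes$end, intervals$end),
                            c(genes$chrom, intervals$chrom), max)
  }
  too_long <- intervals$end - intervals$start >
    chrom_lengths[as.character(intervals$chrom)]
  if (any(is.na(too_long)) || any(too_long))
    .stopf("interval longer than its chromosome (or on an unknown chromosome)")

  # per-chromosome sorted gene boundaries for O(log n) overlap counting
  by_chr <- split(seq_len(nrow(genes)), genes$chrom)
  idx <- lapply(by_chr, function(ix) list(
    starts = sort(genes$start[ix]), ends = sort(genes$end[ix]),
    t_starts = sort(genes$start[ix][is_target[ix]]),
    t_ends = sort(genes$end[ix][is_target[ix]])))
  count_ov <- function(ch, s, e, tgt = FALSE) {
    d <- idx[[ch]]
    if (is.null(d)) return(0L)
    if (tgt) sum(d$t_starts < e) - sum(d$t_ends <= s)
    else sum(d$starts < e) - sum(d$ends <= s)
  }

  n_int <- nrow(intervals)
  obs_genes <- integer(n_int)
  obs_hit <- logical(n_int)
  for (i in seq_len(n_int)) {
    ch <- as.character(intervals$chrom[i])
    obs_genes[i] <- count_ov(ch, intervals$start[i], intervals$end[i])
    obs_hit[i] <- count_ov(ch, intervals$start[i], intervals$end[i], tgt = TRUE) > 0L
  }
  statistic <- sum(obs_hit)

  set.seed(as.integer(seed))
  lens <- intervals$end - intervals$start
  chs <- as.character(intervals$chrom)
  # integer counts within +/- match_tol of the original (for 1 gene the band
  # is exactly {1}; for 0 genes exactly {0})
  lo <- ceiling((1 - match_tol) * obs_genes)
  hi <- floor((1 + match_tol) * obs_genes)
  perm_stat <- integer(n_perm)
  for (p in seq_len(n_perm)) {
    hits <- 0L
    for (i in seq_len(n_int)) {
      L <- chrom_lengths[[chs[i]]]
      best_s <- NA_real_; best_d <- Inf
      for (tr in seq_len(max_resample)) {
        s <- floor(stats::runif(1, 0, L - lens[i] + 1))
        g <- count_ov(chs[i], s, s + lens[i])
        if (g >= lo[i] && g <= hi[i]) { best_s <- s; break }
        d <- abs(g - obs_genes[i])
        if (d < best_d) { best_d <- d; best_s <- s }
      }
      if (count_ov(chs[i], best_s, best_s + lens[i], tgt = TRUE) > 0L)
        hits <- hits + 1L
    }
    perm_stat[p] <- hits
  }
  n_extreme <- sum(perm_stat >= statistic)
  structure(list(
    target_name = if (inherits(target, "gene_set")) target$name else "target",
    n_intervals = n_int, statistic = statistic, n_perm = n_perm,
    n_as_extreme = n_extreme, empirical_p = (n_extreme + 1) / (n_perm + 1),
    relocation = "length-preserving, gene-density-matched", seed = seed),
    class = "interval_enrichment_result")
}

#' Hypergeometric over-representation analysis with BH correction
#'
#' For each set, the upper-tail hypergeometric p-value of the query/set
#' overlap within the background, Benjamini-Hochberg q-values across sets,
#' and a flag for sets with fewer than two query overlaps (conventionally not
#' reported).  Sets with no background member are skipped with a warning.
#'
#' @param query character vector of gene ids (subset of `background`).
#' @param sets list of [gene_set()] objects (e.g. from [read_gene_sets()]).
#' @param background character vector of gene ids.
#' @return `data.frame`: `set, n_set, n_overlap, fold, p, q, at_least_two`.
#' @export
hypergeometric_ora <- function(query, sets, background) {
  query <- .norm_genes(query)
  background <- .norm_genes(background)
  off <- setdiff(query, background)
  if (length(off) > 0L)
    .stopf("query gene(s) not in background: %s", paste(head(off, 5L), collapse = ", "))
  if (inherits(sets, "gene_set")) sets <- list(sets)
  N <- length(background); k <- length(query)
  rows <- list()
  for (s in sets) {
    members <- intersect(.norm_genes(s$members), background)
    if (length(members) == 0L) {
      .warnf("set '%s' has no background member; skipped", s$name)
      next
    }
    K <- length(members)
    x <- sum(query %in% members)
    p <- stats::phyper(x - 1, K, N - K, k, lower.tail = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      set = s$name, n_set = K, n_overlap = x,
      fold = (x / k) / (K / N), p = p, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(set = character(), n_set = integer(), n_overlap = integer(),
                      fold = numeric(), p = numeric(), q = numeric(),
                      at_least_two = logical(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$at_least_two <- out$n_overlap >= 2L
  out
}
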