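# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

.check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    .stopf("`%s` must be a single probability in [0, 1], got %s", name,
           paste(format(x), collapse = ","))
  invisible(x)
}

.check_pos <- function(x, name, strict = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) && (if (strict) x > 0 else x >= 0)
  if (!ok) .stopf("`%s` must be a single %s number", name,
                  if (strict) "positive" else "non-negative")
  invisible(x)
}

#' @noRd
#' Convert 0-based half-open intervals to a GRanges (1-based closed) for
#' overlap computations.  `chrom` is recycled against start/end.
.gr0 <- function(chrom, start0, end0) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = start0 + 1L, end = end0))
}

#' @noRd
#' Deterministic per-stage seed derived from a master seed and a stage label.
#' Keeps sub-streams independent when stages are run standalone.
.stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

#' @noRd
#' Sorted order of genomic rows: chromosome (natural string order of first
#' appearance is NOT used -- plain lexicographic keeps runs stable), then pos.
.genomic_order <- function(chrom, pos) order(chrom, pos, method = "radix")

#' @noRd
#' Canonical variant key used for blacklists, dedup and truth matching.
.variant_key <- function(chrom, pos0, ref, alt) {
  paste(chrom, pos0, ref, alt, sep = ":")
}
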