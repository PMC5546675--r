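# io_formats: containers and readers/writers for the standard formats the
# pipeline touches (PLINK PED/MAP, VCF, BED, GMT, TSV), with strict validation.
#
# Internal convention: ALL coordinates are 0-based half-open.  VCF and MAP
# positions (1-based) are converted on read and write; BED is already 0-based
# half-open and passes through unchanged.

GENO_CODES <- c(hom_ref = 0L, het = 1L, hom_alt = 2L, missing = -9L)

#' Marker map of a genotype panel
#'
#' One row per SNP marker, sorted by (chrom, pos).  Positions are stored
#' 0-based; `freq` is the population frequency of allele `a2` (the allele
#' counted by genotype code 2).
#'
#' @param chrom character chromosome names.
#' @param pos integer 0-based marker positions.
#' @param id marker identifiers (generated when `NULL`).
#' @param a1,a2 the two alleles at each marker.
#' @param freq frequency of `a2` in `[0, 1]`; may be `NA` when unknown.
#' @return A `data.frame` of class `marker_map` with columns
#'   `chrom, pos, id, a1, a2, freq`.
#' @export
marker_map <- function(chrom, pos, id = NULL, a1 = "A", a2 = "G", freq = NA_real_) {
  n <- length(pos)
  df <- data.frame(
    chrom = as.character(rep_len(chrom, n)),
    pos   = as.integer(pos),
    id    = as.character(id %||% paste0("snp_", seq_len(n))),
    a1    = as.character(rep_len(a1, n)),
    a2    = as.character(rep_len(a2, n)),
    freq  = as.numeric(rep_len(freq, n)),
    stringsAsFactors = FALSE
  )
  o <- .genomic_order(df$chrom, df$pos)
  if (is.unsorted(o)) {
    .warnf("marker map was not sorted by (chrom, pos); sorting")
    df <- df[o, , drop = FALSE]
    rownames(df) <- NULL
  }
  dup <- duplicated(df[, c("chrom", "pos")])
  if (any(dup)) {
    i <- which(dup)[1L]
    .stopf("duplicate marker position %s:%d (marker '%s')",
           df$chrom[i], df$pos[i], df$id[i])
  }
  bad <- !is.na(df$freq) & (df$freq < 0 | df$freq > 1)
  if (any(bad)) .stopf("marker allele frequencies outside [0, 1] (first: '%s')",
                       df$id[which(bad)[1L]])
  class(df) <- c("marker_map", "data.frame")
  df
}

#' Genotype matrix
#'
#' Samples x markers call matrix with codes 0 = hom-ref, 1 = het,
#' 2 = hom-alt, -9 = missing, tied to its [marker_map()].
#'
#' @param calls integer matrix, samples in rows, markers in columns.
#' @param map a [marker_map()] with one row per column of `calls`.
#' @param sample_ids sample identifiers (default: rownames of `calls`).
#' @return A list of class `genotype_matrix` with elements
#'   `sample_ids`, `calls`, `map`.
#' @export
genotype_matrix <- function(calls, map, sample_ids = rownames(calls)) {
  if (!inherits(map, "marker_map")) .stopf("`map` must be a marker_map")
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (ncol(calls) != nrow(map))
    .stopf("calls has %d marker columns but map has %d rows", ncol(calls), nrow(map))
  if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_len(nrow(calls)))
  if (length(sample_ids) != nrow(calls))
    .stopf("sample_ids length %d != %d samples", length(sample_ids), nrow(calls))
  bad <- !(calls %in% GENO_CODES)
  if (any(bad)) {
    i <- which(bad)[1L]
    .stopf("invalid genotype code %s at sample %s, marker %s",
           calls[i], sample_ids[(i - 1L) %% nrow(calls) + 1L],
           map$id[(i - 1L) %/% nrow(calls) + 1L])
  }
  dimnames(calls) <- list(as.character(sample_ids), map$id)
  structure(list(sample_ids = as.character(sample_ids), calls = calls, map = map),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d markers on %d chromosome(s)\n",
              nrow(x$calls), ncol(x$calls), length(unique(x$map$chrom))))
  invisible(x)
}

## ---- PLINK PED/MAP ---------------------------------------------------------

#' Write a genotype panel as PLINK PED/MAP
#'
#' The MAP file is written with six columns (chrom, id, cM, 1-based pos,
#' A1, A2) so allele definitions survive a round trip; standard 4-column MAP
#' files are accepted on read.
#'
#' @param gm a [genotype_matrix()].
#' @param prefix output path prefix; writes `<prefix>.ped` and `<prefix>.map`.
#' @return Invisibly, the two file paths.
#' @export
write_plink <- function(gm, prefix) {
  map <- gm$map
  map_out <- data.table::data.table(
    chrom = map$chrom, id = map$id, cm = 0, pos = map$pos + 1L,
    a1 = map$a1, a2 = map$a2
  )
  data.table::fwrite(map_out, paste0(prefix, ".map"), sep = "\t", col.names = FALSE)

  n <- nrow(gm$calls)
  allele_strings <- function(j) {
    g <- gm$calls[, j]
    a1 <- map$a1[j]; a2 <- map$a2[j]
    out <- character(n)
    out[g == 0L]  <- paste(a1, a1)
    out[g == 1L]  <- paste(a1, a2)
    out[g == 2L]  <- paste(a2, a2)
    out[g == -9L] <- "0 0"
    out
  }
  geno <- vapply(seq_len(ncol(gm$calls)), allele_strings, character(n))
  if (is.null(dim(geno))) geno <- matrix(geno, nrow = n)
  lines <- paste(gm$sample_ids, gm$sample_ids, 0, 0, 0, -9,
                 apply(geno, 1L, paste, collapse = " "))
  writeLines(lines, paste0(prefix, ".ped"))
  invisible(c(ped = paste0(prefix, ".ped"), map = paste0(prefix, ".map")))
}

.read_map_file <- function(path) {
  mp <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = 1))
  if (!ncol(mp) %in% c(4L, 6L))
    .stopf("MAP file '%s' must have 4 or 6 columns, found %d", path, ncol(mp))
  has_alleles <- ncol(mp) == 6L
  list(chrom = as.character(mp[[1]]), id = as.character(mp[[2]]),
       pos = as.integer(mp[[4]]) - 1L,
       a1 = if (has_alleles) as.character(mp[[5]]) else NULL,
       a2 = if (has_alleles) as.character(mp[[6]]) else NULL)
}

.read_plink <- function(prefix) {
  ped_path <- if (grepl("\\.ped$", prefix)) prefix else paste0(prefix, ".ped")
  map_path <- sub("\\.ped$", ".map", ped_path)
  if (!file.exists(ped_path)) .stopf("PED file '%s' not found", ped_path)
  if (!file.exists(map_path)) .stopf("MAP file '%s' not found", map_path)
  mp <- .read_map_file(map_path)
  m <- length(mp$pos)

  fields <- strsplit(trimws(readLines(ped_path)), "[ \t]+")
  fields <- fields[lengths(fields) > 0L]
  n <- length(fields)
  ids <- vapply(fields, `[[`, character(1), 2L)
  calls <- matrix(-9L, nrow = n, ncol = m)
  infer <- is.null(mp$a1)
  a1 <- mp$a1 %||% rep(NA_character_, m)
  a2 <- mp$a2 %||% rep(NA_character_, m)

  for (s in seq_len(n)) {
    f <- fields[[s]]
    if (length(f) != 6L + 2L * m)
      .stopf("PED sample '%s' has %d genotype fields, expected %d",
             ids[s], length(f) - 6L, 2L * m)
    g1 <- f[seq(7L, by = 2L, length.out = m)]
    g2 <- f[seq(8L, by = 2L, length.out = m)]
    for (j in seq_len(m)) {
      x <- g1[j]; y <- g2[j]
      if (x == "0" || y == "0") { calls[s, j] <- -9L; next }
      if (infer) {
        for (al in unique(c(x, y))) {
          if (is.na(a1[j])) a1[j] <- al
          else if (is.na(a2[j]) && al != a1[j]) a2[j] <- al
        }
      }
      known <- c(a1[j], a2[j])
      if (!(x %in% known) || !(y %in% known))
        .stopf("PED allele mismatch: sample '%s', marker '%s' carries %s/%s but map defines %s/%s",
               ids[s], mp$id[j], x, y, a1[j], a2[j] %||% "?")
      calls[s, j] <- sum(c(x, y) == a2[j], na.rm = TRUE)
    }
  }
  # monomorphic inferred markers: a2 never observed
  a2[is.na(a2)] <- "N"
  map <- marker_map(mp$chrom, mp$pos, mp$id, a1 = a1, a2 = a2)
  # marker_map() may have re-sorted; apply the same order to the calls
  calls <- calls[, match(map$id, mp$id), drop = FALSE]
  genotype_matrix(calls, map, sample_ids = ids)
}

## ---- VCF (genotype panel) --------------------------------------------------

#' Write a genotype panel as a minimal multi-sample VCF
#'
#' Sites carry the marker alleles as REF/ALT, the `a2` frequency in
#' `INFO/AF`, and per-sample GT fields.
#'
#' @param gm a [genotype_matrix()].
#' @param path output `.vcf` path (plain text).
#' @return Invisibly, `path`.
#' @export
write_genotypes_vcf <- function(gm, path) {
  map <- gm$map
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1", `-9` = "./.")
  gt <- matrix(gt_code[as.character(t(gm$calls))], nrow = nrow(map))
  info <- ifelse(is.na(map$freq), ".", sprintf("AF=%.6g", map$freq))
  body <- paste(map$chrom, map$pos + 1L, map$id, map$a1, map$a2, ".", "PASS",
                info, "GT", apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=autozyg",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Allele frequency of ALT\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$sample_ids), collapse = "\t")
  )
  writeLines(c(header, body), path)
  invisible(path)
}

.gt_to_code <- function(gt) {
  gt <- sub(":.*$", "", gt)
  gt <- gsub("\\|", "/", gt)
  out <- rep(-9L, length(gt))
  out[gt %in% c("0/0")] <- 0L
  out[gt %in% c("0/1", "1/0")] <- 1L
  out[gt %in% c("1/1")] <- 2L
  out
}

.read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(as.matrix(fix))   # single-record VCF
  gt <- vcfR::extract.gt(v)
  info <- vcfR::extract.info(v, element = "AF", as.numeric = TRUE)
  map <- marker_map(chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]) - 1L,
                    id = fix[, "ID"], a1 = fix[, "REF"], a2 = fix[, "ALT"],
                    freq = suppressWarnings(as.numeric(info)))
  calls <- t(apply(gt, 2L, .gt_to_code))
  if (nrow(map) == 1L) calls <- matrix(calls, ncol = 1L, dimnames = list(colnames(gt), NULL))
  # order columns as the (possibly re-sorted) map
  key_vcf <- paste(fix[, "CHROM"], fix[, "POS"])
  key_map <- paste(map$chrom, map$pos + 1L)
  calls <- calls[, match(key_map, key_vcf), drop = FALSE]
  genotype_matrix(calls, map, sample_ids = colnames(gt))
}

#' Read a genotype panel (PLINK PED/MAP or VCF)
#'
#' @param path for `format = "ped"`, the file prefix or the `.ped` path (the
#'   matching `.map` must sit beside it); for `format = "vcf"`, a plain-text
#'   VCF path.
#' @param format `"ped"` or `"vcf"`.
#' @return A [genotype_matrix()]; markers are sorted by (chrom, pos), with a
#'   warning if the input was unsorted.
#' @export
read_genotypes <- function(path, format = c("ped", "vcf")) {
  format <- match.arg(format)
  switch(format, ped = .read_plink(path), vcf = .read_genotypes_vcf(path))
}

## ---- BED gene intervals ----------------------------------------------------

#' Read gene intervals from a BED file
#'
#' BED is 0-based half-open, which matches the internal convention, so
#' coordinates pass through unchanged.
#'
#' @param path BED file with at least 4 columns (chrom, start, end, name).
#' @return `data.frame` with columns `gene_id, chrom, start, end`, sorted by
#'   (chrom, start).
#' @export
read_gene_intervals <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  if (is.null(gr$name) || anyNA(gr$name))
    .stopf("BED file '%s' must carry gene names in column 4", path)
  gene_intervals(gene_id = gr$name,
                 chrom = as.character(GenomicRanges::seqnames(gr)),
                 start = GenomicRanges::start(gr) - 1L,
                 end = GenomicRanges::end(gr))
}

#' Construct/validate a gene interval table (0-based half-open)
#'
#' @param gene_id,chrom,start,end vectors of equal length.
#' @return Sorted, validated `data.frame`.
#' @export
gene_intervals <- function(gene_id, chrom, start, end) {
  df <- data.frame(gene_id = as.character(gene_id), chrom = as.character(chrom),
                   start = as.integer(start), end = as.integer(end),
                   stringsAsFactors = FALSE)
  if (any(df$start >= df$end))
    .stopf("gene interval with start >= end (first: '%s')",
           df$gene_id[which(df$start >= df$end)[1L]])
  df <- df[.genomic_order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write gene intervals (or ROH segments) as BED
#'
#' @param df data.frame with `chrom`, `start`, `end` and a name column
#'   (`gene_id` or `sample`).
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(df, path) {
  name <- df$gene_id %||% df$sample %||% rep(".", nrow(df))
  lines <- paste(df$chrom, df$start, df$end, name, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

## ---- GMT gene sets ---------------------------------------------------------

#' Construct a gene set
#' @param name set name.
#' @param members character vector of gene ids (deduplicated, must be non-empty).
#' @param description free-text description.
#' @return list of class `gene_set`.
#' @export
gene_set <- function(name, members, description = "") {
  members <- unique(as.character(members))
  members <- members[nzchar(members)]
  if (length(members) == 0L) .stopf("gene set '%s' has no members", name)
  structure(list(name = as.character(name), description = as.character(description),
                 members = members), class = "gene_set")
}

#' Read gene sets from a GMT file
#'
#' Each line: `name<TAB>description<TAB>gene1<TAB>gene2...`.  Lines with fewer
#' than three fields are an error reported with their line number.
#'
#' @param path GMT file.
#' @return Named list of [gene_set()] objects.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short) > 0L)
    .stopf("malformed GMT line %d in '%s': fewer than 3 tab-separated fields",
           short[1L], path)
  sets <- lapply(fields, function(f) gene_set(f[1L], f[-(1:2)], description = f[2L]))
  stats::setNames(sets, vapply(sets, `[[`, character(1), "name"))
}

#' Write gene sets to a GMT file
#' @param sets list of [gene_set()] objects.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_gene_sets <- function(sets, path) {
  if (inherits(sets, "gene_set")) sets <- list(sets)
  lines <- vapply(sets, function(s)
    paste(c(s$name, if (nzchar(s$description)) s$description else "na", s$members),
          collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

## ---- CNV intervals ---------------------------------------------------------

#' Read per-sample CNV calls from a BED-like TSV
#'
#' Expected columns: `sample, chrom, start, end, copy_number`
#' (0-based half-open, header required).
#'
#' @param path TSV path.
#' @return Validated, sorted `data.frame`.
#' @export
read_cnvs <- function(path) {
  df <- as.data.frame(data.table::fread(path, colClasses = list(character = "chrom")))
  need <- c("sample", "chrom", "start", "end", "copy_number")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    .stopf("CNV file '%s' is missing column(s): %s", path, paste(miss, collapse = ", "))
  if (any(df$start >= df$end)) .stopf("CNV interval with start >= end in '%s'", path)
  if (any(df$copy_number < 0)) .stopf("negative copy_number in '%s'", path)
  df <- df[order(df$sample, df$chrom, df$start), need, drop = FALSE]
  rownames(df) <- NULL
  df
}

## ---- Annotated variants (VCF + sidecar annotation TSV) ---------------------

ANN_TSV_COLS <- c("chrom", "pos", "ref", "alt", "gene", "transcript",
                  "consequence", "SIFT", "PP2_HDIV", "MT", "phyloP100way",
                  "AF_db1", "AF_db2", "AF_db3", "nHom_db1", "nHom_db2",
                  "nHom_db3", "FPKM_brain")

CONSEQUENCES <- c("missense", "stop_gain", "stop_loss", "start_loss",
                  "splice_site", "frameshift", "inframe_indel", "synonymous",
                  "other")
FUNCTIONAL_CONSEQUENCES <- c("missense", "stop_gain", "stop_loss", "start_loss",
                             "splice_site", "frameshift", "inframe_indel")

# Published predictor conventions: SIFT deleterious below 0.05, PolyPhen-2
# HDIV probably-damaging at/above 0.957, MutationTaster disease-causing
# probability at/above 0.5.
SIFT_D_BELOW <- 0.05
PP2_D_AT_LEAST <- 0.957
MT_D_AT_LEAST <- 0.5

.pred_call <- function(score, type) {
  ifelse(is.na(score), NA_character_,
         switch(type,
                sift = ifelse(score < SIFT_D_BELOW, "D", "T"),
                pp2  = ifelse(score >= PP2_D_AT_LEAST, "D", "T"),
                mt   = ifelse(score >= MT_D_AT_LEAST, "D", "T")))
}

#' Construct/validate an annotated variant table
#'
#' Fills defaults for optional columns, derives predictor D/T calls from
#' scores, and checks invariants.  Absent database frequencies/homozygote
#' counts are `NA` ("not reported"), which is distinct from 0: a variant absent
#' from all three databases is "novel".
#'
#' @param df data.frame with at least `sample, chrom, pos, ref, alt, zygosity,
#'   gene_id, consequence`.  `pos` is 0-based.
#' @return `data.frame` of class `annotated_variants`.
#' @export
annotated_variants <- function(df) {
  need <- c("sample", "chrom", "pos", "ref", "alt", "zygosity", "gene_id",
            "consequence")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    .stopf("annotated variant table missing column(s): %s", paste(miss, collapse = ", "))
  n <- nrow(df)
  defaults <- list(
    transcript = NA_character_, sift_score = NA_real_, pp2_score = NA_real_,
    mt_score = NA_real_, phylop = NA_real_, af_db1 = NA_real_, af_db2 = NA_real_,
    af_db3 = NA_real_, nhom_db1 = NA_integer_, nhom_db2 = NA_integer_,
    nhom_db3 = NA_integer_, fpkm_brain = NA_real_, roh_length = NA_real_,
    in_blacklist = FALSE, in_cnv = FALSE
  )
  for (nm in names(defaults)) if (is.null(df[[nm]])) df[[nm]] <- rep(defaults[[nm]], n)
  bad_z <- !df$zygosity %in% c("hom_alt", "het", "hom_ref", "missing")
  if (any(bad_z)) .stopf("invalid zygosity value '%s'", df$zygosity[which(bad_z)[1L]])
  bad_c <- !df$consequence %in% c(CONSEQUENCES, "intergenic")
  if (any(bad_c)) .stopf("invalid consequence '%s'", df$consequence[which(bad_c)[1L]])
  df$sift_call <- .pred_call(df$sift_score, "sift")
  df$pp2_call  <- .pred_call(df$pp2_score, "pp2")
  df$mt_call   <- .pred_call(df$mt_score, "mt")
  for (col in c("af_db1", "af_db2", "af_db3")) {
    bad <- !is.na(df[[col]]) & (df[[col]] < 0 | df[[col]] > 1)
    if (any(bad)) .stopf("database AF outside [0, 1] in column %s", col)
  }
  df$pos <- as.integer(df$pos)
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  rownames(df) <- NULL
  class(df) <- c("annotated_variants", "data.frame")
  df
}

#' Write annotated variants as VCF + annotation TSV
#'
#' The VCF carries per-sample genotypes at each distinct site; the TSV carries
#' one annotation row per distinct (chrom, pos, ref, alt) with 1-based
#' positions, mirroring the usual exome report layout.
#'
#' @param variants an [annotated_variants()] table.
#' @param vcf_path,tsv_path output paths.
#' @return Invisibly, the two paths.
#' @export
write_variants <- function(variants, vcf_path, tsv_path) {
  v <- as.data.frame(variants)
  v$key <- .variant_key(v$chrom, v$pos, v$ref, v$alt)
  sites <- v[!duplicated(v$key), , drop = FALSE]
  sites <- sites[.genomic_order(sites$chrom, sites$pos), , drop = FALSE]
  samples <- sort(unique(v$sample))

  zyg_to_gt <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1", missing = "./.")
  gt <- matrix("0/0", nrow = nrow(sites), ncol = length(samples),
               dimnames = list(sites$key, samples))
  gt[cbind(match(v$key, sites$key), match(v$sample, samples))] <- zyg_to_gt[v$zygosity]

  header <- c(
    "##fileformat=VCFv4.2",
    "##source=autozyg",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- paste(sites$chrom, sites$pos + 1L, ".", sites$ref, sites$alt, ".",
                "PASS", ".", "GT", apply(gt, 1L, paste, collapse = "\t"),
                sep = "\t")
  writeLines(c(header, body), vcf_path)

  tsv <- data.table::data.table(
    chrom = sites$chrom, pos = sites$pos + 1L, ref = sites$ref, alt = sites$alt,
    gene = sites$gene_id, transcript = sites$transcript,
    consequence = sites$consequence,
    SIFT = sites$sift_score, PP2_HDIV = sites$pp2_score, MT = sites$mt_score,
    phyloP100way = sites$phylop,
    AF_db1 = sites$af_db1, AF_db2 = sites$af_db2, AF_db3 = sites$af_db3,
    nHom_db1 = sites$nhom_db1, nHom_db2 = sites$nhom_db2, nHom_db3 = sites$nhom_db3,
    FPKM_brain = sites$fpkm_brain
  )
  data.table::fwrite(tsv, tsv_path, sep = "\t", na = ".", quote = FALSE)
  invisible(c(vcf = vcf_path, tsv = tsv_path))
}

#' Read annotated variants from a VCF plus sidecar annotation TSV
#'
#' Per-sample genotype rows are taken from the VCF (hom-ref and fully missing
#' genotypes are dropped); annotations are joined by (chrom, pos, ref, alt).
#' Every annotation row must match a VCF site.
#'
#' @param vcf_path multi-sample VCF (plain text).
#' @param tsv_path annotation TSV with columns
#'   `chrom pos ref alt gene transcript consequence SIFT PP2_HDIV MT
#'   phyloP100way AF_db1..3 nHom_db1..3 FPKM_brain` (`pos` 1-based, `.` = absent).
#' @return An [annotated_variants()] table, one row per (sample, variant).
#' @export
read_variant_annotations <- function(vcf_path, tsv_path) {
  ann <- as.data.frame(data.table::fread(tsv_path, na.strings = c(".", "NA", ""),
                                         colClasses = list(character = "chrom")))
  miss <- setdiff(ANN_TSV_COLS, names(ann))
  if (length(miss) > 0L)
    .stopf("annotation TSV '%s' missing column(s): %s", tsv_path,
           paste(miss, collapse = ", "))
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- t(as.matrix(fix))   # single-record VCF
  gt <- vcfR::extract.gt(vcf)
  site_key <- .variant_key(fix[, "CHROM"], as.integer(fix[, "POS"]) - 1L,
                           fix[, "REF"], fix[, "ALT"])
  ann_key <- .variant_key(ann$chrom, ann$pos - 1L, ann$ref, ann$alt)
  unmatched <- !(ann_key %in% site_key)
  if (any(unmatched))
    .stopf("%d annotation row(s) have no matching VCF record (first: %s)",
           sum(unmatched), ann_key[which(unmatched)[1L]])

  zyg_of <- c(`0` = "hom_ref", `1` = "het", `2` = "hom_alt", `-9` = "missing")
  rows <- list()
  samples <- colnames(gt)
  for (s in samples) {
    code <- .gt_to_code(gt[, s])
    keep <- code %in% c(1L, 2L)   # carry het and hom-alt calls per sample
    if (!any(keep)) next
    i <- which(keep)
    j <- match(site_key[i], ann_key)
    rows[[s]] <- data.frame(
      sample = s, chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]) - 1L,
      ref = fix[i, "REF"], alt = fix[i, "ALT"],
      zygosity = unname(zyg_of[as.character(code[keep])]),
      gene_id = ann$gene[j], transcript = ann$transcript[j],
      consequence = ann$consequence[j],
      sift_score = ann$SIFT[j], pp2_score = ann$PP2_HDIV[j], mt_score = ann$MT[j],
      phylop = ann$phyloP100way[j],
      af_db1 = ann$AF_db1[j], af_db2 = ann$AF_db2[j], af_db3 = ann$AF_db3[j],
      nhom_db1 = ann$nHom_db1[j], nhom_db2 = ann$nHom_db2[j],
      nhom_db3 = ann$nHom_db3[j], fpkm_brain = ann$FPKM_brain[j],
      stringsAsFactors = FALSE
    )
  }
  out <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(sample = character(), chrom = character(), pos = integer(),
               ref = character(), alt = character(), zygosity = character(),
               gene_id = character(), consequence = character(),
               stringsAsFactors = FALSE)
  out$gene_id[is.na(out$gene_id)] <- "intergenic"
  annotated_variants(out)
}
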