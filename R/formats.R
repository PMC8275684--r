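# Readers and writers for the on-disk formats used throughout the pipeline.
# All coordinates on disk are 0-based half-open (BED convention).

#' Read a BED file of genomic intervals
#'
#' Honours the first six BED columns (chrom, start, end, name, score, strand)
#' and preserves any additional columns verbatim in an `extra` column, so
#' MACS2 narrowPeak files round-trip without interpreting summit columns.
#' Lines starting with `track`, `browser` or `#` are skipped. Output is
#' sorted by (chrom, start, end).
#'
#' @param path path to a tab-separated BED file.
#' @return data.frame with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand` and (when present in the file) `extra`. Coordinates are 0-based
#'   half-open integers; `score` is kept as character to preserve the file
#'   contents exactly.
#' @seealso [write_bed()]
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(lines)
  idx <- which(keep)
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  n <- length(fields)
  if (n == 0L)
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), score = character(),
                      strand = character(), stringsAsFactors = FALSE))
  nf <- lengths(fields)
  if (any(nf < 3L))
    stopf("BED parse error at line %d: fewer than 3 fields", idx[which(nf < 3L)[1L]])
  get_col <- function(i, default) {
    vapply(fields, function(f) if (length(f) >= i) f[i] else default, character(1))
  }
  chrom <- get_col(1L, NA_character_)
  start <- suppressWarnings(as.integer(get_col(2L, NA_character_)))
  end <- suppressWarnings(as.integer(get_col(3L, NA_character_)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stopf("BED parse error at line %d: non-integer coordinate", idx[bad[1L]])
  bad <- which(!(start >= 0L & start < end))
  if (length(bad))
    stopf("BED parse error at line %d: start >= end", idx[bad[1L]])
  out <- data.frame(chrom = chrom, start = start, end = end,
                    name = get_col(4L, "."), score = get_col(5L, "."),
                    strand = get_col(6L, "."), stringsAsFactors = FALSE)
  if (any(nf > 6L)) {
    out$extra <- vapply(fields, function(f) {
      if (length(f) > 6L) paste(f[-(1:6)], collapse = "\t") else ""
    }, character(1))
  }
  out[order(out$chrom, out$start, out$end), , drop = FALSE]
}

#' Write genomic intervals to a BED file
#'
#' Writes the columns present in `x` (at least chrom/start/end; name, score,
#' strand and extra columns when available), sorted by (chrom, start, end).
#' `read_bed()` followed by `write_bed()` reproduces a sorted input file.
#'
#' @param x data.frame of intervals as returned by [read_bed()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_bed <- function(x, path) {
  check_intervals(x, "BED intervals")
  x <- x[order(x$chrom, x$start, x$end), , drop = FALSE]
  cols <- list(x$chrom, x$start, x$end)
  for (cn in c("name", "score", "strand")) {
    if (cn %in% names(x)) cols[[length(cols) + 1L]] <- as.character(x[[cn]])
  }
  line <- do.call(paste, c(cols, sep = "\t"))
  if ("extra" %in% names(x)) {
    has_extra <- nzchar(x$extra)
    line[has_extra] <- paste(line[has_extra], x$extra[has_extra], sep = "\t")
  }
  writeLines(line, path)
  invisible(path)
}

read_tsv_table <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             check.names = FALSE, quote = "", comment.char = "")
}

write_tsv_table <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

require_columns <- function(x, cols, what) {
  missing <- base::setdiff(cols, names(x))
  if (length(missing))
    stopf("%s: missing required column(s): %s", what, paste(missing, collapse = ", "))
  invisible(x)
}

#' Read a per-cytosine site count table
#'
#' The table holds converted (`NT`) and unconverted (`NC`) read counts per
#' cytosine and sample. Required columns: `chrom`, `pos` (0-based position of
#' the cytosine on its own strand), `strand`, `context`, `sample`, `NT`, `NC`.
#' Negative counts and duplicate (chrom, pos, strand, sample) keys are
#' rejected. An empty file with a header yields an empty table.
#'
#' @param path path to the TSV file.
#' @return typed data.frame of site counts.
#' @export
read_site_counts <- function(path) {
  x <- read_tsv_table(path)
  require_columns(x, c("chrom", "pos", "strand", "context", "sample", "NT", "NC"),
                  "site count table")
  x$pos <- as.integer(x$pos); x$NT <- as.integer(x$NT); x$NC <- as.integer(x$NC)
  if (nrow(x)) {
    if (any(is.na(x$NT) | is.na(x$NC) | x$NT < 0 | x$NC < 0))
      stopf("site count table: NT/NC must be non-negative integers")
    if (any(is.na(x$pos) | x$pos < 0))
      stopf("site count table: pos must be a non-negative integer")
    key <- paste(x$chrom, x$pos, x$strand, x$sample)
    if (anyDuplicated(key))
      stopf("site count table: duplicate (chrom, pos, strand, sample) row: %s",
            key[duplicated(key)][1L])
  }
  x
}

#' @rdname read_site_counts
#' @param x site count data.frame.
#' @export
write_site_counts <- function(x, path) write_tsv_table(x, path)

#' Read a TPM expression matrix
#'
#' Expects a TSV with a `gene` column followed by one numeric column per
#' tissue. Values must be non-negative; duplicate gene ids are rejected.
#'
#' @param path path to the TSV file.
#' @return numeric matrix, genes in rows (rownames), tissues in columns.
#' @export
read_tpm <- function(path) {
  x <- read_tsv_table(path)
  require_columns(x, "gene", "TPM table")
  if (anyDuplicated(x$gene)) stopf("TPM table: duplicate gene id '%s'",
                                   x$gene[duplicated(x$gene)][1L])
  m <- as.matrix(x[, base::setdiff(names(x), "gene"), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- x$gene
  if (length(m) && any(is.na(m) | m < 0)) stopf("TPM table: negative or missing value")
  m
}

#' @rdname read_tpm
#' @param x gene-by-tissue numeric matrix with rownames.
#' @export
write_tpm <- function(x, path) {
  write_tsv_table(data.frame(gene = rownames(x), x, check.names = FALSE), path)
}

#' Read a SNP catalog
#'
#' Required columns: `chrom`, `pos` (0-based), `rsid`, `phenotype`.
#' Duplicate (chrom, pos, phenotype) keys are rejected; the same position may
#' appear under several phenotypes.
#'
#' @param path path to the TSV file.
#' @return data.frame of SNPs.
#' @export
read_snps <- function(path) {
  x <- read_tsv_table(path)
  require_columns(x, c("chrom", "pos", "rsid", "phenotype"), "SNP catalog")
  x$pos <- as.integer(x$pos)
  if (nrow(x)) {
    if (any(is.na(x$pos) | x$pos < 0)) stopf("SNP catalog: pos must be >= 0")
    key <- paste(x$chrom, x$pos, x$phenotype)
    if (anyDuplicated(key))
      stopf("SNP catalog: duplicate (chrom, pos, phenotype) row: %s",
            key[duplicated(key)][1L])
  }
  x
}

#' @rdname read_snps
#' @param x SNP data.frame.
#' @export
write_snps <- function(x, path) write_tsv_table(x, path)

#' Read a minimal gene-model table
#'
#' The canonical gene-model format is a TSV with columns `gene_id`, `chrom`,
#' `strand`, `start`, `end`, `tss`, `biotype`, `exon_starts`, `exon_ends`
#' (comma-separated 0-based half-open exon coordinates). The TSS must equal
#' `start` on the + strand and `end - 1` on the - strand.
#'
#' @param path path to the TSV file.
#' @return data.frame of gene models.
#' @export
read_gene_models <- function(path) {
  x <- read_tsv_table(path)
  require_columns(x, c("gene_id", "chrom", "strand", "start", "end", "tss",
                       "biotype", "exon_starts", "exon_ends"), "gene models")
  x$start <- as.integer(x$start); x$end <- as.integer(x$end); x$tss <- as.integer(x$tss)
  if (nrow(x)) {
    check_intervals(x, "gene models")
    expected <- ifelse(x$strand == "+", x$start, x$end - 1L)
    bad <- which(x$tss != expected)
    if (length(bad))
      stopf("gene models: TSS inconsistent with strand for gene '%s'", x$gene_id[bad[1L]])
  }
  x
}

#' @rdname read_gene_models
#' @param x gene-model data.frame.
#' @export
write_gene_models <- function(x, path) write_tsv_table(x, path)

#' Read a region-by-sample count matrix
#'
#' TSV with a `region` column followed by one numeric column per sample.
#'
#' @param path path to the TSV file.
#' @return numeric matrix, regions in rows, samples in columns.
#' @export
read_count_matrix <- function(path) {
  x <- read_tsv_table(path)
  require_columns(x, "region", "count matrix")
  m <- as.matrix(x[, base::setdiff(names(x), "region"), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- x$region
  if (length(m) && any(is.na(m) | m < 0)) stopf("count matrix: negative or missing value")
  m
}

#' @rdname read_count_matrix
#' @param x region-by-sample matrix with rownames.
#' @export
write_count_matrix <- function(x, path) {
  write_tsv_table(data.frame(region = rownames(x), x, check.names = FALSE), path)
}

#' Read a sample sheet mapping samples to tissues
#'
#' Required columns: `sample`, `tissue`; an optional `replicate` column is
#' preserved.
#'
#' @param path path to the TSV file.
#' @return data.frame with one row per sample.
#' @export
read_sample_sheet <- function(path) {
  x <- read_tsv_table(path)
  require_columns(x, c("sample", "tissue"), "sample sheet")
  if (anyDuplicated(x$sample)) stopf("sample sheet: duplicate sample id")
  x
}

#' Read and write FASTA genomes
#'
#' Thin wrappers over Biostrings. `read_fasta()` returns a `DNAStringSet`;
#' `chrom_lengths()` extracts the named vector of sequence lengths used by
#' coordinate-validation code throughout the package.
#'
#' @param path FASTA file path.
#' @return `read_fasta()`: a `Biostrings::DNAStringSet`.
#' @export
read_fasta <- function(path) Biostrings::readDNAStringSet(path)

#' @rdname read_fasta
#' @param x named character vector or `DNAStringSet` of chromosome sequences.
#' @export
write_fasta <- function(x, path) {
  if (!methods::is(x, "DNAStringSet")) x <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname read_fasta
#' @param genome a `DNAStringSet` or named character vector.
#' @export
chrom_lengths <- function(genome) {
  if (methods::is(genome, "DNAStringSet"))
    setNames(Biostrings::width(genome), names(genome))
  else
    setNames(nchar(genome), names(genome))
}
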