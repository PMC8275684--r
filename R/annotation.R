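# Genomic feature annotation: promoter/exon/intron/intergenic classes and
# observed-vs-expected enrichment.

#' Build a genomic feature catalog from gene models
#'
#' Promoters are `TSS +/- promoter_halfwidth` (clipped to chromosome ends
#' with a warning). Exons and introns are derived from the gene bodies, and
#' intergenic space is the complement. Classes are flattened by the fixed
#' precedence promoter > exon > intron > intergenic, so the four classes
#' partition the genome exactly.
#'
#' @param gene_models gene-model data.frame (see [read_gene_models()]).
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param promoter_halfwidth promoter half-width around the TSS (bp, default
#'   2000: "2 kb around the TSS").
#' @return object of class `feature_catalog`: a list of disjoint `GRanges`
#'   (`promoter`, `exon`, `intron`, `intergenic`) plus `chrom_lengths`.
#' @export
build_features <- function(gene_models, chrom_lengths, promoter_halfwidth = 2000) {
  genome_gr <- GenomicRanges::GRanges(names(chrom_lengths),
                                      IRanges::IRanges(1L, as.integer(chrom_lengths)))
  empty <- GenomicRanges::GRanges()
  if (is.null(gene_models) || !nrow(gene_models)) {
    cat_list <- list(promoter = empty, exon = empty, intron = empty,
                     intergenic = genome_gr)
  } else {
    check_intervals(gene_models, "gene models")
    if (any(gene_models$end > chrom_lengths[gene_models$chrom]))
      stopf("gene model outside chromosome bounds")
    L <- chrom_lengths[gene_models$chrom]
    p_start <- gene_models$tss - promoter_halfwidth
    p_end <- gene_models$tss + promoter_halfwidth
    if (any(p_start < 0 | p_end > L)) {
      warnf("promoter window clipped at chromosome end for %d gene(s)",
            sum(p_start < 0 | p_end > L))
      p_start <- pmax(0, p_start)
      p_end <- pmin(L, p_end)
    }
    prom <- GenomicRanges::reduce(GenomicRanges::GRanges(
      gene_models$chrom, IRanges::IRanges(p_start + 1L, p_end)))
    bodies <- GenomicRanges::reduce(as_granges0(
      gene_models[, c("chrom", "start", "end")]))
    ex_chrom <- rep(gene_models$chrom,
                    lengths(strsplit(gene_models$exon_starts, ",")))
    ex_start <- as.integer(unlist(strsplit(gene_models$exon_starts, ",")))
    ex_end <- as.integer(unlist(strsplit(gene_models$exon_ends, ",")))
    exome <- GenomicRanges::reduce(GenomicRanges::GRanges(
      ex_chrom, IRanges::IRanges(ex_start + 1L, ex_end)))
    cat_list <- list(
      promoter = prom,
      exon = GenomicRanges::setdiff(exome, prom),
      intron = GenomicRanges::setdiff(GenomicRanges::setdiff(bodies, exome), prom),
      intergenic = GenomicRanges::setdiff(
        genome_gr, GenomicRanges::union(prom, bodies)))
  }
  structure(c(cat_list, list(chrom_lengths = chrom_lengths,
                             promoter_halfwidth = promoter_halfwidth)),
            class = "feature_catalog")
}

feature_classes <- c("promoter", "exon", "intron", "intergenic")

#' Assign queries to genomic feature classes
#'
#' Point queries are classified by their own position; interval queries by
#' their midpoint. Because the catalog classes are disjoint by construction,
#' each query maps to exactly one class (the precedence
#' promoter > exon > intron > intergenic is already baked into the catalog).
#'
#' @param query data.frame with either `chrom`/`pos` (0-based points) or
#'   `chrom`/`start`/`end` (0-based half-open intervals).
#' @param catalog a [build_features()] catalog.
#' @return character vector of class labels.
#' @export
assign_class <- function(query, catalog) {
  stopifnot(inherits(catalog, "feature_catalog"))
  if (all(c("start", "end") %in% names(query))) {
    check_intervals(query, "query intervals")
    pos <- (query$start + query$end) %/% 2L
  } else {
    require_columns(query, c("chrom", "pos"), "query points")
    pos <- query$pos
  }
  L <- catalog$chrom_lengths[as.character(query$chrom)]
  if (anyNA(L) || any(pos < 0 | pos >= L)) stopf("query position off the genome")
  gr <- points_granges0(query$chrom, pos)
  cls <- rep(NA_character_, length(gr))
  for (cl in feature_classes) {
    hit <- countOverlaps(gr, catalog[[cl]]) > 0L
    cls[is.na(cls) & hit] <- cl
  }
  if (anyNA(cls)) stopf("internal error: catalog does not cover the genome")
  cls
}

#' Observed-vs-expected enrichment of feature classes
#'
#' Compares the fraction of queries assigned to each class with the fraction
#' of the genome the class covers, as `log2(observed / expected)`. Classes
#' with zero observations are reported as `-Inf`.
#'
#' @param assignments character vector of class labels from [assign_class()].
#' @param catalog a [build_features()] catalog.
#' @return data.frame with columns `class`, `n_obs`, `obs_fraction`,
#'   `exp_fraction`, `log2_ratio`.
#' @export
class_enrichment <- function(assignments, catalog) {
  stopifnot(inherits(catalog, "feature_catalog"))
  if (!length(assignments)) stopf("at least one assignment is required")
  n <- length(assignments)
  obs_n <- vapply(feature_classes, function(cl) sum(assignments == cl), numeric(1))
  obs <- obs_n / n
  genome_bp <- sum(catalog$chrom_lengths)
  exp_frac <- vapply(feature_classes,
                     function(cl) sum(width(catalog[[cl]])) / genome_bp,
                     numeric(1))
  if (any(exp_frac == 0 & obs > 0))
    stopf("class with zero genomic coverage has observations: inconsistent catalog")
  data.frame(class = feature_classes, n_obs = obs_n, obs_fraction = obs,
             exp_fraction = exp_frac,
             log2_ratio = ifelse(obs == 0, -Inf, log2(obs / exp_frac)),
             stringsAsFactors = FALSE, row.names = NULL)
}
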