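# Tissue-specific expression, gene-body signal and tsDhMR-to-gene linkage.

#' Identify genes with tissue-specific expression
#'
#' Genes with mean TPM below `min_mean_tpm` are dropped as lowly expressed
#' everywhere. For each tissue, the fold change of each remaining gene is
#' its TPM over the mean of the other tissues; genes are ranked by
#' descending fold change, the top `top_n` are taken, and among those, genes
#' with fold change below `min_fc` are dropped (rank-then-filter order), so
#' lists may be shorter than `top_n`.
#'
#' @param tpm gene-by-tissue TPM matrix.
#' @param top_n genes retained per tissue before the fold-change filter
#'   (default 300).
#' @param min_mean_tpm mean-expression floor (default 1).
#' @param min_fc fold-change floor (default 2).
#' @return named list (one element per tissue) of gene-id character vectors.
#' @export
tissue_specific_genes <- function(tpm, top_n = 300L, min_mean_tpm = 1,
                                  min_fc = 2) {
  tpm <- as.matrix(tpm)
  if (ncol(tpm) < 2L) stopf("at least two tissues are required")
  keep <- rowMeans(tpm) >= min_mean_tpm
  tpm <- tpm[keep, , drop = FALSE]
  out <- lapply(seq_len(ncol(tpm)), function(t) {
    other <- rowMeans(tpm[, -t, drop = FALSE])
    fc <- ifelse(other > 0, tpm[, t] / other, ifelse(tpm[, t] > 0, Inf, 0))
    top <- head(order(fc, decreasing = TRUE), top_n)
    rownames(tpm)[top][fc[top] >= min_fc]
  })
  setNames(out, colnames(tpm))
}

#' Aggregate site counts over gene bodies
#'
#' Sums the converted-read counts (`NT`) of all sites falling inside each
#' gene body, per sample: a simple proxy for read density over the gene.
#'
#' @param sites site count data.frame (see [read_site_counts()]).
#' @param gene_models gene-model data.frame.
#' @return gene-by-sample numeric matrix of summed counts.
#' @export
gene_site_counts <- function(sites, gene_models) {
  check_intervals(gene_models, "gene models")
  samples <- unique(sites$sample)
  out <- matrix(0, nrow(gene_models), length(samples),
                dimnames = list(gene_models$gene_id, samples))
  gr_sites <- points_granges0(sites$chrom, sites$pos)
  gr_genes <- as_granges0(gene_models)
  hits <- GenomicRanges::findOverlaps(gr_sites, gr_genes, ignore.strand = TRUE)
  if (length(hits)) {
    df <- data.frame(gene = gene_models$gene_id[S4Vectors::subjectHits(hits)],
                     sample = sites$sample[S4Vectors::queryHits(hits)],
                     nt = sites$NT[S4Vectors::queryHits(hits)])
    agg <- tapply(df$nt, list(df$gene, df$sample), sum)
    out[rownames(agg), colnames(agg)] <- ifelse(is.na(agg), 0, agg)
  }
  out
}

#' Gene-body signal density (RPKM-like)
#'
#' `count / (gene length in kb x library size in millions)`: a density
#' invariant to jointly scaling all counts and the library size.
#'
#' @param counts gene-by-sample matrix of counts in gene bodies (for
#'   instance from [gene_site_counts()]).
#' @param gene_models gene-model data.frame; rows are matched to `counts`
#'   rownames by `gene_id`.
#' @param library_sizes per-sample total read counts (named vector matched
#'   to `counts` columns; default: column sums).
#' @return gene-by-sample matrix of densities.
#' @export
gene_body_signal <- function(counts, gene_models, library_sizes = colSums(counts)) {
  counts <- as.matrix(counts)
  len <- gene_models$end - gene_models$start
  names(len) <- gene_models$gene_id
  len <- len[rownames(counts)]
  if (anyNA(len)) stopf("gene in counts missing from gene models")
  if (any(len <= 0)) stopf("zero-length gene body")
  if (!is.null(names(library_sizes)))
    library_sizes <- library_sizes[colnames(counts)]
  if (any(library_sizes <= 0)) stopf("library sizes must be positive")
  sweep(counts / (len / 1000), 2L, library_sizes / 1e6, "/")
}

#' Correlate gene-body signal with expression
#'
#' Spearman (default, rank-based with average ranks on ties) or Pearson
#' correlation between matched signal and TPM, computed per gene across
#' tissues (default) or per tissue across genes. Constant series give `NA`.
#'
#' @param signal gene-by-tissue signal matrix (e.g. [gene_body_signal()]).
#' @param tpm gene-by-tissue TPM matrix; genes and tissues are matched by
#'   name.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param by `"gene"` (across tissues, default) or `"tissue"` (across genes).
#' @return named numeric vector of correlations.
#' @export
expression_correlation <- function(signal, tpm,
                                   method = c("spearman", "pearson"),
                                   by = c("gene", "tissue")) {
  method <- match.arg(method)
  by <- match.arg(by)
  genes <- intersect(rownames(signal), rownames(tpm))
  tissues <- intersect(colnames(signal), colnames(tpm))
  if (length(tissues) < 3L) stopf("at least three matched tissues are required")
  s <- signal[genes, tissues, drop = FALSE]
  e <- tpm[genes, tissues, drop = FALSE]
  cor_safe <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    cor(x, y, method = method)
  }
  if (by == "gene")
    vapply(genes, function(g) cor_safe(s[g, ], e[g, ]), numeric(1))
  else
    vapply(tissues, function(t) cor_safe(s[, t], e[, t]), numeric(1))
}

#' Link tsDhMRs to putative target genes by windowed correlation
#'
#' Candidate pairs are (region, gene) with the gene's TSS within `window` bp
#' of the region interval (closed bound; distance 0 inside the region). For
#' each pair, the Pearson correlation across tissues between the region's
#' normalized 5hmC signal and the gene's TPM is tested with the two-sided
#' t-statistic `t = r sqrt(n-2) / sqrt(1-r^2)` on `n - 2` degrees of
#' freedom. A link is confident when `r > min_r` and `p < alpha`. Degenerate
#' (constant) series are skipped with a warning; p-values are floored at
#' 1e-300 so a perfect fit stays confident.
#'
#' @param tsdhmrs output of [call_tsdhmrs()] (only rows with
#'   `is_tsdhmr = TRUE` are used), or a character vector of region names.
#' @param regions region intervals data.frame with a `name` column matching
#'   the tsDhMR region ids.
#' @param gene_models gene-model data.frame.
#' @param region_signal region-by-tissue matrix of replicate-merged
#'   normalized counts (the same matrix that fed [call_tsdhmrs()]).
#' @param tpm gene-by-tissue TPM matrix (tissues matched by name).
#' @param window TSS search window in bp (default 500000, inclusive).
#' @param min_r Pearson correlation threshold for a confident link
#'   (default 0.8).
#' @param alpha p-value threshold (default 0.05).
#' @return data.frame with one row per candidate pair: `region`, `gene`,
#'   `distance`, `pearson_r`, `p_value`, `confident`.
#' @export
link_tsdhmrs <- function(tsdhmrs, regions, gene_models, region_signal, tpm,
                         window = 500000, min_r = 0.8, alpha = 0.05) {
  region_ids <- if (is.character(tsdhmrs)) unique(tsdhmrs)
                else unique(tsdhmrs$region[tsdhmrs$is_tsdhmr])
  regions <- regions[match(region_ids, regions$name), , drop = FALSE]
  if (anyNA(regions$chrom)) stopf("tsDhMR region missing from region table")
  tissues <- intersect(colnames(region_signal), colnames(tpm))
  if (length(tissues) < 4L)
    stopf("at least four matched tissues are required for the correlation test")

  reg_gr <- as_granges0(regions)
  tss_gr <- points_granges0(gene_models$chrom, gene_models$tss)
  hits <- GenomicRanges::findOverlaps(reg_gr, tss_gr, maxgap = window + 1L,
                                      ignore.strand = TRUE)
  ri <- S4Vectors::queryHits(hits)
  gi <- S4Vectors::subjectHits(hits)
  d <- point_interval_distance(gene_models$tss[gi], regions$start[ri],
                               regions$end[ri])
  keep <- d <= window
  ri <- ri[keep]; gi <- gi[keep]; d <- d[keep]
  n_skipped <- 0L
  rows <- vector("list", length(ri))
  for (k in seq_along(ri)) {
    x <- region_signal[regions$name[ri[k]], tissues]
    y <- tpm[gene_models$gene_id[gi[k]], tissues]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      n_skipped <- n_skipped + 1L
      next
    }
    ct <- suppressWarnings(cor.test(x, y, method = "pearson"))
    rows[[k]] <- data.frame(
      region = regions$name[ri[k]], gene = gene_models$gene_id[gi[k]],
      distance = d[k], pearson_r = unname(ct$estimate),
      p_value = max(ct$p.value, 1e-300), stringsAsFactors = FALSE)
  }
  if (n_skipped)
    warnf("skipped %d candidate pair(s) with constant signal or expression",
          n_skipped)
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(region = character(), gene = character(),
                      distance = integer(), pearson_r = numeric(),
                      p_value = numeric(), stringsAsFactors = FALSE)
  out$confident <- out$pearson_r > min_r & out$p_value < alpha
  rownames(out) <- NULL
  out
}
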