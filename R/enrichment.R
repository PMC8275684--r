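# SNP-catalog enrichment in tsDhMRs: one-sided Fisher's exact tests.

#' Flag SNPs overlapping a set of regions
#'
#' Point-in-interval membership with the half-open convention: a SNP at a
#' region's start coordinate is inside; one at the end coordinate is
#' outside. SNPs on chromosomes absent from the region set are counted as
#' outside (with a warning).
#'
#' @param snps data.frame with `chrom` and `pos` (0-based points).
#' @param regions data.frame of intervals (chrom, start, end).
#' @param quiet suppress the off-chromosome warning.
#' @return logical vector, `TRUE` where the SNP lies inside some region.
#' @export
overlap_snps <- function(snps, regions, quiet = FALSE) {
  require_columns(snps, c("chrom", "pos"), "SNPs")
  if (!nrow(regions)) return(rep(FALSE, nrow(snps)))
  check_intervals(regions, "regions")
  off <- !(snps$chrom %in% unique(regions$chrom))
  if (any(off) && !quiet)
    warnf("%d SNP(s) on chromosomes absent from the region set; counted as outside",
          sum(off))
  countOverlaps(points_granges0(snps$chrom, snps$pos), as_granges0(regions)) > 0L
}

#' Per-phenotype Fisher enrichment of SNPs in regions
#'
#' For each phenotype, builds the 2x2 table (a = phenotype SNPs inside the
#' regions, b = phenotype SNPs outside, c = other SNPs inside, d = other
#' SNPs outside) over the universe of all SNPs in the catalog, and computes
#' the one-sided (greater) Fisher exact p-value together with the sample
#' odds ratio `(a d) / (b c)` (`Inf` when `b c = 0`). Benjamini-Hochberg
#' adjusted p-values across phenotypes are reported as an extra column; the
#' raw p-value is primary.
#'
#' @param in_region logical vector from [overlap_snps()].
#' @param phenotype character vector of phenotype labels, parallel to
#'   `in_region`.
#' @return data.frame sorted by p-value with columns `phenotype`, `a`, `b`,
#'   `c`, `d`, `odds_ratio`, `p_value`, `p_adjusted`.
#' @export
fisher_enrichment <- function(in_region, phenotype) {
  stopifnot(length(in_region) == length(phenotype))
  if (!length(in_region)) stopf("empty SNP universe")
  phenos <- unique(phenotype)
  rows <- lapply(phenos, function(ph) {
    is_ph <- phenotype == ph
    a <- sum(is_ph & in_region)
    b <- sum(is_ph & !in_region)
    c_ <- sum(!is_ph & in_region)
    d <- sum(!is_ph & !in_region)
    p <- fisher.test(matrix(c(a, b, c_, d), 2L, byrow = TRUE),
                     alternative = "greater")$p.value
    or <- if (b * c_ == 0) {
      if (a * d == 0) NaN else Inf
    } else (a / b) * (d / c_)
    data.frame(phenotype = ph, a = a, b = b, c = c_, d = d, odds_ratio = or,
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$phenotype), , drop = FALSE]
  rownames(out) <- NULL
  out
}
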