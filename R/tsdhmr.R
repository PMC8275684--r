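# Merged-peak count matrices and tissue-specific differentially
# hydroxymethylated region (tsDhMR) calling.

#' Merge peak intervals from multiple samples
#'
#' Computes the union of overlapping-or-touching intervals per chromosome
#' (bedtools-merge semantics). Idempotent; output is sorted by
#' (chrom, start) and named `merged_00001`, ...
#'
#' @param peaks a data.frame of intervals, or a list of such data.frames
#'   (one per sample) that are concatenated first.
#' @return data.frame of merged regions (chrom, start, end, name).
#' @export
merge_peaks <- function(peaks) {
  if (is.data.frame(peaks)) peaks <- list(peaks)
  all <- do.call(rbind, lapply(peaks, function(p) {
    check_intervals(p, "peaks")
    p[, c("chrom", "start", "end")]
  }))
  if (!nrow(all))
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), stringsAsFactors = FALSE))
  gr <- GenomicRanges::reduce(as_granges0(all))
  gr <- GenomicRanges::sort(gr)
  out <- data.frame(chrom = as.character(seqnames(gr)), start = start(gr) - 1L,
                    end = end(gr), stringsAsFactors = FALSE)
  out$name <- sprintf("merged_%05d", seq_len(nrow(out)))
  out
}

#' Median-of-ratios size factors
#'
#' For each region the reference is the geometric mean of its counts over
#' samples (regions containing any zero are excluded from the reference);
#' each sample's size factor is the median over regions of the ratio of its
#' count to the reference. Dividing counts by these factors normalizes
#' sequencing depth.
#'
#' @param counts region-by-sample numeric matrix of raw counts.
#' @param pseudocount optional value added to all counts before estimation,
#'   for matrices with no all-positive region.
#' @return named positive numeric vector, one size factor per sample.
#' @export
size_factors <- function(counts, pseudocount = 0) {
  counts <- as.matrix(counts) + pseudocount
  if (any(counts < 0)) stopf("counts must be non-negative")
  log_geo <- rowMeans(log(counts))
  if (!any(is.finite(log_geo)))
    stopf(paste0("no region has all-positive counts; ",
                 "set pseudocount > 0 to estimate size factors"))
  apply(counts, 2L, function(cc) {
    exp(median((log(cc) - log_geo)[is.finite(log_geo) & cc > 0]))
  })
}

#' Divide a count matrix by per-sample size factors
#'
#' @param counts region-by-sample matrix.
#' @param sf per-sample size factors (default: estimated by [size_factors()]).
#' @return normalized matrix `counts[, j] / sf[j]`.
#' @export
normalize_counts <- function(counts, sf = size_factors(counts)) {
  if (any(sf <= 0)) stopf("size factors must be positive")
  sweep(as.matrix(counts), 2L, sf, "/")
}

#' Merge biological replicates into tissue-level signal
#'
#' Aggregates the normalized columns of each tissue by mean (default) or
#' sum. Mean aggregation is invariant to replicate order and count.
#'
#' @param mat region-by-sample matrix (normalized counts).
#' @param sample_tissues sample sheet data.frame (`sample`, `tissue`) or a
#'   named character vector mapping sample to tissue.
#' @param mode `"mean"` (default) or `"sum"`.
#' @return region-by-tissue matrix.
#' @export
merge_replicates <- function(mat, sample_tissues, mode = c("mean", "sum")) {
  mode <- match.arg(mode)
  mat <- as.matrix(mat)
  if (is.data.frame(sample_tissues)) {
    require_columns(sample_tissues, c("sample", "tissue"), "sample sheet")
    map <- setNames(sample_tissues$tissue, sample_tissues$sample)
  } else map <- sample_tissues
  tissue <- map[colnames(mat)]
  if (anyNA(tissue))
    stopf("unknown tissue label for sample(s): %s",
          paste(colnames(mat)[is.na(tissue)], collapse = ", "))
  agg <- if (mode == "mean") rowMeans else rowSums
  vapply(unique(unname(tissue)), function(t) {
    agg(mat[, tissue == t, drop = FALSE])
  }, numeric(nrow(mat)))
}

#' Exact Poisson upper-tail p-value
#'
#' `P(X >= count)` for `X ~ Poisson(lambda)`. Non-integer counts (which
#' arise from normalized, replicate-merged signal) are floored before the
#' exact tail is evaluated, a conservative choice. `lambda` below
#' `lambda_min` is raised to `lambda_min` to avoid zero-rate artifacts.
#'
#' @param count observed count(s), `>= 0`.
#' @param lambda Poisson rate(s), `>= 0`.
#' @param lambda_min pseudocount floor for the rate (default 0.5).
#' @return numeric vector of upper-tail p-values (`count = 0` gives 1).
#' @export
poisson_upper_pvalue <- function(count, lambda, lambda_min = 0.5) {
  if (any(count < 0) || any(lambda < 0)) stopf("count and lambda must be >= 0")
  count <- floor(count)
  lambda <- pmax(lambda, lambda_min)
  ppois(count - 1, lambda, lower.tail = FALSE)
}

#' Call tissue-specific differentially hydroxymethylated regions
#'
#' For each (region, tissue) pair the null rate `lambda` is the mean of the
#' other tissues' merged normalized counts; the one-tailed Poisson p-value
#' of the tissue's count is Bonferroni-adjusted (family = regions x tissues
#' by default). A pair is a tsDhMR when the adjusted p-value is below
#' `alpha` *and* the fold change over `lambda` exceeds `min_fc`. A region
#' may be specific to more than one tissue.
#'
#' @param tissue_mat region-by-tissue matrix of replicate-merged normalized
#'   counts (from [merge_replicates()]).
#' @param alpha adjusted-p threshold (default 0.05).
#' @param min_fc fold-change threshold (default 2).
#' @param family Bonferroni family: `"global"` (regions x tissues, default)
#'   or `"per_tissue"` (regions only).
#' @param lambda_min rate floor passed to [poisson_upper_pvalue()].
#' @return data.frame with one row per (region, tissue): `region`, `tissue`,
#'   `tissue_count`, `lambda_other`, `fold_change`, `p_value`,
#'   `p_bonferroni`, `is_tsdhmr`.
#' @export
call_tsdhmrs <- function(tissue_mat, alpha = 0.05, min_fc = 2,
                         family = c("global", "per_tissue"), lambda_min = 0.5) {
  family <- match.arg(family)
  tissue_mat <- as.matrix(tissue_mat)
  n_t <- ncol(tissue_mat)
  if (n_t < 2L) stopf("at least two tissues are required")
  n_r <- nrow(tissue_mat)
  if (is.null(rownames(tissue_mat)))
    rownames(tissue_mat) <- sprintf("region_%05d", seq_len(n_r))
  m <- if (family == "global") n_r * n_t else n_r
  res <- lapply(seq_len(n_t), function(t) {
    lam <- rowMeans(tissue_mat[, -t, drop = FALSE])
    cnt <- tissue_mat[, t]
    fc <- ifelse(lam > 0, cnt / lam, ifelse(cnt > 0, Inf, 0))
    p <- poisson_upper_pvalue(cnt, lam, lambda_min)
    data.frame(region = rownames(tissue_mat), tissue = colnames(tissue_mat)[t],
               tissue_count = cnt, lambda_other = lam, fold_change = fc,
               p_value = p, p_bonferroni = bonferroni_adjust(p, m),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, res)
  out$is_tsdhmr <- out$p_bonferroni < alpha & out$fold_change > min_fc
  out
}
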