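# Spike-in calibration, read filtering and single-base 5hmC site calling.

#' Estimate conversion rates from spike-in controls
#'
#' The conversion rate of each class is the pooled ratio
#' `sum(NT) / sum(NT + NC)` over its spike-in cytosines: `p_true` over fully
#' hydroxymethylated sites and `p_bg` (the background, "normal cytosine"
#' conversion rate used as the binomial null) over unmodified sites.
#'
#' @param spikeins data.frame with columns `state` (`"5hmC"` or
#'   `"unmodified"`), `NT` and `NC`.
#' @return list with elements `p_true` and `p_bg` (`0 <= p_bg < p_true <= 1`).
#' @export
estimate_conversion <- function(spikeins) {
  require_columns(spikeins, c("state", "NT", "NC"), "spike-in counts")
  if (any(spikeins$NT < 0 | spikeins$NC < 0))
    stopf("spike-in counts must be non-negative")
  pooled <- function(cls) {
    x <- spikeins[spikeins$state == cls, , drop = FALSE]
    depth <- sum(x$NT) + sum(x$NC)
    if (nrow(x) == 0L || depth == 0)
      stopf("no %s spike-in coverage: cannot estimate conversion rate", cls)
    sum(x$NT) / depth
  }
  p_true <- pooled("5hmC")
  p_bg <- pooled("unmodified")
  if (p_bg >= p_true)
    stopf(paste0("background conversion (%.4f) >= 5hmC conversion (%.4f); ",
                 "conversion chemistry failed"), p_bg, p_true)
  list(p_true = p_true, p_bg = p_bg)
}

#' Filter read pairs by C-to-T conversion evidence
#'
#' Keeps read pairs whose conversion count is at least `min_conversions`
#' (default 1: at least one C-to-T conversion signal). `min_conversions = 0`
#' is the identity filter.
#'
#' @param read_conversions named non-negative integer vector, one entry per
#'   read pair.
#' @param min_conversions minimum conversions required to keep a read pair.
#' @return character vector of kept read-pair ids.
#' @export
filter_reads <- function(read_conversions, min_conversions = 1L) {
  if (any(!is.finite(read_conversions)) || any(read_conversions < 0))
    stopf("read conversion counts must be non-negative")
  names(read_conversions)[read_conversions >= min_conversions]
}

#' Exact binomial upper-tail p-value for a converted-count observation
#'
#' `P(X >= NT)` for `X ~ Binomial(N, p_bg)`: the probability of observing at
#' least `NT` converted reads by background conversion alone. Vectorized;
#' computed via the regularized incomplete beta function (`pbinom` upper
#' tail), accurate in the extreme tails used at stringent alpha.
#'
#' @param nt observed converted reads (`0 <= nt <= n`).
#' @param n sequencing depth `NT + NC`.
#' @param p_bg background conversion rate in (0, 1).
#' @return numeric vector of upper-tail p-values (`nt = 0` gives 1).
#' @export
binom_site_pvalue <- function(nt, n, p_bg) {
  if (any(p_bg <= 0 | p_bg >= 1)) stopf("p_bg must be in (0, 1)")
  if (any(nt < 0) || any(n < 0)) stopf("nt and n must be non-negative")
  if (any(nt > n)) stopf("nt must not exceed n")
  pbinom(nt - 1, n, p_bg, lower.tail = FALSE)
}

#' Holm step-down and Bonferroni adjustment
#'
#' `holm_adjust()` applies the Holm step-down adjustment
#' (`adj(i) = min(1, max_{j<=i} (m - j + 1) p_(j))` over the ascending order,
#' restored to input order); `bonferroni_adjust()` multiplies by the family
#' size and caps at 1. Both accept a family size `m` larger than the number
#' of p-values actually computed, for families in which some members were
#' never tested (their p-values are by construction the largest).
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @param m family size (defaults to `length(p)`).
#' @return adjusted p-values, elementwise `>=` the input.
#' @export
holm_adjust <- function(p, m = length(p)) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) stopf("p-values must be in [0, 1]")
  if (m < length(p)) stopf("family size m must be >= length(p)")
  p.adjust(p, method = "holm", n = m)
}

#' @rdname holm_adjust
#' @export
bonferroni_adjust <- function(p, m = length(p)) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) stopf("p-values must be in [0, 1]")
  if (m < length(p)) stopf("family size m must be >= length(p)")
  pmin(1, p * m)
}

#' Call single-base 5hmC sites
#'
#' For every site passing the depth filter (`NT + NC >= min_depth`), tests
#' the converted count against the background conversion rate with
#' [binom_site_pvalue()] and applies Holm step-down FWER control. Sites with
#' fewer than `min_nt` converted reads are discarded from calling (never
#' tested, `p = NA`), but still count toward the Holm family size: the
#' family is defined by the ancillary depth filter alone, which preserves
#' family-wise error control under the null. A site is called when its
#' Holm-adjusted p-value is below `alpha` *and* it lies within a 5hmC
#' enriched peak of its tissue.
#'
#' @param sites site count data.frame (see [read_site_counts()]).
#' @param rates conversion rates from [estimate_conversion()] (list with
#'   `p_bg`; `p_true` is not used by the test).
#' @param peaks peak intervals: a data.frame with columns chrom/start/end and
#'   optionally `tissue` (peaks without a tissue column gate all tissues), or
#'   a named list of such data.frames keyed by tissue.
#' @param sample_tissues optional sample sheet data.frame (`sample`,
#'   `tissue`); by default each sample is its own tissue.
#' @param alpha FWER level (default 0.001).
#' @param min_depth minimum `NT + NC` to enter the tested family (default 5).
#' @param min_nt minimum converted reads for a site to be testable (default 3).
#' @param family scope of the Holm family: `"per_sample"` (default) or
#'   `"per_tissue"` (all samples of a tissue pooled into one family).
#' @return the input data.frame with added columns `n`, `tissue`, `tested`,
#'   `p_value`, `p_holm`, `in_peak` and `called`.
#' @export
call_sites <- function(sites, rates, peaks, sample_tissues = NULL,
                       alpha = 0.001, min_depth = 5L, min_nt = 3L,
                       family = c("per_sample", "per_tissue")) {
  family <- match.arg(family)
  require_columns(sites, c("chrom", "pos", "strand", "sample", "NT", "NC"),
                  "site count table")
  if (is.null(rates) || is.null(rates$p_bg))
    stopf("conversion rates are required (see estimate_conversion())")
  out <- sites
  out$n <- out$NT + out$NC
  if (is.null(sample_tissues)) {
    out$tissue <- out$sample
  } else {
    require_columns(sample_tissues, c("sample", "tissue"), "sample sheet")
    out$tissue <- sample_tissues$tissue[match(out$sample, sample_tissues$sample)]
    if (anyNA(out$tissue)) stopf("sample missing from sample sheet")
  }

  if (is.data.frame(peaks)) {
    peak_list <- if ("tissue" %in% names(peaks)) split(peaks, peaks$tissue)
                 else list(peaks)
  } else peak_list <- peaks
  out$in_peak <- FALSE
  site_gr <- points_granges0(out$chrom, out$pos)
  if (length(peak_list) == 1L && is.null(names(peak_list))) {
    out$in_peak <- countOverlaps(site_gr, as_granges0(peak_list[[1L]])) > 0L
  } else {
    for (t in unique(out$tissue)) {
      rows <- which(out$tissue == t)
      pk <- peak_list[[t]]
      if (is.null(pk) || !nrow(pk)) next
      out$in_peak[rows] <- countOverlaps(site_gr[rows], as_granges0(pk)) > 0L
    }
  }

  depth_pass <- out$n >= min_depth
  out$tested <- depth_pass & out$NT >= min_nt
  out$p_value <- NA_real_
  out$p_value[out$tested] <- binom_site_pvalue(out$NT[out$tested],
                                               out$n[out$tested], rates$p_bg)
  out$p_holm <- NA_real_
  group <- if (family == "per_sample") out$sample else out$tissue
  for (g in unique(group)) {
    in_g <- group == g
    tested_g <- which(in_g & out$tested)
    m <- sum(in_g & depth_pass)
    if (length(tested_g))
      out$p_holm[tested_g] <- holm_adjust(out$p_value[tested_g], m = m)
  }
  out$called <- out$tested & !is.na(out$p_holm) & out$p_holm < alpha & out$in_peak
  out
}

#' Classify the sequence context of a cytosine
#'
#' Returns the CG/CHG/CHH context (H is A, C or T) and the immediate 3' base
#' of each cytosine, on its own strand: minus-strand contexts are read off
#' the reverse complement. Positions that are not a cytosine on the stated
#' strand are an error, as are contexts that run off the chromosome end.
#'
#' @param genome `DNAStringSet` or named character vector of chromosome
#'   sequences.
#' @param chrom,pos,strand vectors describing the cytosines (0-based `pos`).
#' @return data.frame with columns `context` and `next_base`.
#' @export
classify_context <- function(genome, chrom, pos, strand) {
  seqs <- if (methods::is(genome, "DNAStringSet")) as.character(genome) else genome
  n <- length(pos)
  chrom <- rep_len(chrom, n)
  strand <- rep_len(strand, n)
  b0 <- b1 <- b2 <- character(n)
  for (ch in unique(chrom)) {
    if (!ch %in% names(seqs)) stopf("chromosome '%s' not in genome", ch)
    s <- seqs[[ch]]
    L <- nchar(s)
    i <- which(chrom == ch)
    p <- pos[i]
    if (any(p < 0 | p >= L)) stopf("position off chromosome '%s'", ch)
    plus <- strand[i] == "+"
    at <- function(q) {
      r <- rep(NA_character_, length(q))
      ok <- which(q >= 0 & q < L)
      if (length(ok)) r[ok] <- substring(s, q[ok] + 1L, q[ok] + 1L)
      r
    }
    b0[i] <- at(p)
    b1[i][plus] <- at(p[plus] + 1L)
    b2[i][plus] <- at(p[plus] + 2L)
    b1[i][!plus] <- comp_base(at(p[!plus] - 1L))
    b2[i][!plus] <- comp_base(at(p[!plus] - 2L))
  }
  is_c <- ifelse(strand == "+", b0 == "C", b0 == "G")
  if (any(!is_c))
    stopf("position %s:%d is not a cytosine on the %s strand",
          chrom[!is_c][1L], pos[!is_c][1L], strand[!is_c][1L])
  if (anyNA(b1))
    stopf("context runs off the chromosome end (truncated context)")
  context <- ifelse(b1 == "G", "CG",
                    ifelse(is.na(b2), NA_character_,
                           ifelse(b2 == "G", "CHG", "CHH")))
  if (anyNA(context))
    stopf("context runs off the chromosome end (truncated context)")
  data.frame(context = context, next_base = b1, stringsAsFactors = FALSE)
}

#' Fraction of symmetrically modified CpG dyads
#'
#' A CpG dyad pairs a plus-strand cytosine at position x with the
#' minus-strand cytosine at x + 1. Among dyads with at least one called
#' CG-context site, returns the fraction called on both strands.
#'
#' @param sites data.frame with columns `chrom`, `pos`, `strand`, `context`
#'   and (optionally) `called`; rows with `called = FALSE` are ignored.
#' @return a fraction in \[0, 1\], or `NA` if no called CG site exists.
#' @export
symmetry_fraction <- function(sites) {
  if ("called" %in% names(sites)) sites <- sites[sites$called, , drop = FALSE]
  cg <- sites[sites$context == "CG", , drop = FALSE]
  if (!nrow(cg)) return(NA_real_)
  dyad_pos <- ifelse(cg$strand == "+", cg$pos, cg$pos - 1L)
  key <- paste(cg$chrom, dyad_pos)
  both <- tapply(cg$strand, key, function(s) all(c("+", "-") %in% s))
  mean(both)
}

#' Fraction of called sites in non-CG (CH) context
#'
#' @param sites data.frame with columns `context`, optionally `called` and
#'   `sample`.
#' @param by `NULL` for a pooled fraction, or `"sample"` for a per-sample
#'   named vector.
#' @return fraction(s) of called sites with CHG or CHH context; `NA` where no
#'   site is called.
#' @export
ch_fraction <- function(sites, by = NULL) {
  if ("called" %in% names(sites)) sites <- sites[sites$called, , drop = FALSE]
  if (!nrow(sites)) {
    message("no called sites: CH fraction undefined")
    return(NA_real_)
  }
  is_ch <- sites$context %in% c("CHG", "CHH")
  if (is.null(by)) return(mean(is_ch))
  if (by != "sample") stopf("'by' must be NULL or \"sample\"")
  vapply(split(is_ch, sites$sample), mean, numeric(1))
}
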