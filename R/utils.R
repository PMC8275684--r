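# Internal helpers shared across modules.

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count_scalar <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == floor(x)
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stopf("'%s' must be a single value in [0, 1], got %s", name, format(x))
  invisible(x)
}

# Interval data.frames use BED-style 0-based half-open coordinates.
check_intervals <- function(x, what = "intervals") {
  if (!is.data.frame(x) || !all(c("chrom", "start", "end") %in% names(x)))
    stopf("%s must be a data.frame with columns chrom, start, end", what)
  bad <- which(!(x$start >= 0 & x$start < x$end))
  if (length(bad))
    stopf("%s: invalid interval (start >= end or start < 0) at row %d",
          what, bad[1L])
  invisible(x)
}

# 0-based half-open intervals -> GRanges (1-based closed).
as_granges0 <- function(x, strand = NULL) {
  check_intervals(x)
  s <- if (!is.null(strand)) strand
       else if ("strand" %in% names(x)) ifelse(x$strand %in% c("+", "-"), x$strand, "*")
       else "*"
  GenomicRanges::GRanges(as.character(x$chrom),
                         IRanges::IRanges(x$start + 1L, x$end),
                         strand = s)
}

# 0-based point positions -> width-1 GRanges.
points_granges0 <- function(chrom, pos) {
  GenomicRanges::GRanges(as.character(chrom), IRanges::IRanges(pos + 1L, pos + 1L))
}

# Distance (bp) from 0-based point to a 0-based half-open interval; 0 inside.
point_interval_distance <- function(pos, start, end) {
  ifelse(pos < start, start - pos, ifelse(pos >= end, pos - (end - 1L), 0L))
}

# Poisson truncated to >= 1, by inverse CDF.
rtpois <- function(n, lambda) {
  u <- runif(n, dpois(0, lambda), 1)
  pmax(1L, qpois(u, lambda))
}

comp_base <- function(b) {
  chartr("ACGTacgt", "TGCAtgca", b)
}
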