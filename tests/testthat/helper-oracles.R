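# Independent brute-force oracles used to validate the exact-tail and
# multiplicity routines. These deliberately avoid pbinom/ppois/phyper/
# p.adjust: tails are term-by-term log-space summations (smallest terms
# first), adjustments are literal evaluations of their definitions.

oracle_binom_upper <- function(nt, n, p) {
  if (nt <= 0) return(1)
  k <- nt:n
  terms <- exp(lchoose(n, k) + k * log(p) + (n - k) * log1p(-p))
  sum(sort(terms))
}

oracle_pois_upper <- function(count, lambda) {
  if (count <= 0) return(1)
  kmax <- max(ceiling(2 * lambda), count) + 400
  k <- count:kmax
  terms <- exp(k * log(lambda) - lambda - lgamma(k + 1))
  sum(sort(terms))
}

oracle_holm <- function(p, m = length(p)) {
  o <- order(p)
  adj <- numeric(length(p))
  running <- 0
  for (i in seq_along(o)) {
    running <- max(running, (m - i + 1) * p[o[i]])
    adj[o[i]] <- min(1, running)
  }
  adj
}

oracle_bonferroni <- function(p, m = length(p)) {
  vapply(p, function(pp) min(1, pp * m), numeric(1))
}

# One-sided (greater) Fisher p for table (a, b // c, d): hypergeometric sum
# over all tables at least as extreme in the a cell.
oracle_fisher_greater <- function(a, b, c, d) {
  N <- a + b + c + d
  K <- a + c          # in-region total
  n1 <- a + b         # phenotype total
  x <- a:min(n1, K)
  terms <- exp(lchoose(K, x) + lchoose(N - K, n1 - x) - lchoose(N, n1))
  sum(sort(terms))
}

# Small toy genome used by context-classification tests. 0-based positions;
# labels derived by hand from the sequence ACGACAGCTACCGTAGCATG.
toy_context_genome <- function() c(chr1 = "ACGACAGCTACCGTAGCATG")

toy_context_cases <- function() {
  data.frame(
    pos = c(1L, 4L, 7L, 10L, 11L, 16L, 2L, 6L, 12L, 15L, 19L),
    strand = rep(c("+", "-"), c(6L, 5L)),
    context = c("CG", "CHG", "CHH", "CHG", "CG", "CHH",
                "CG", "CHG", "CG", "CHH", "CHH"),
    next_base = c("G", "A", "T", "C", "G", "A",
                  "G", "T", "G", "T", "A"),
    stringsAsFactors = FALSE)
}
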