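# Independent brute-force oracles used to validate the fast implementations.

# EHH by direct enumeration of homozygous carrier pairs: probability two
# random carriers are identical at every site between the core and `site`.
bruteEHH <- function(m, core, allele, site) {
  carriers <- which(m[, core] == allele)
  n <- length(carriers)
  span <- if (site >= core) core:site else site:core
  same <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (all(m[carriers[i], span] == m[carriers[j], span]))
      same <- same + 1
  }
  same / (n * (n - 1) / 2)
}

# S* by exhaustive enumeration over every ordered subset of >= 2 SNVs.
bruteSStar <- function(genotypes, pos, bonus = 5000, mismatch = -10000,
                       minDist = 10) {
  n <- length(genotypes)
  if (n < 2) return(0)
  o <- order(pos)
  genotypes <- genotypes[o]; pos <- pos[o]
  sc <- function(i, j) {
    d <- pos[j] - pos[i]
    if (d < minDist) return(-Inf)
    if (genotypes[i] == genotypes[j]) bonus + d else mismatch
  }
  best <- -Inf
  for (mask in 1:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(idx) < 2) next
    tot <- 0
    for (k in seq_len(length(idx) - 1)) {
      s <- sc(idx[k], idx[k + 1])
      tot <- tot + s
    }
    if (is.finite(tot) && tot > best) best <- tot
  }
  if (is.finite(best)) best else 0
}

# HWE exact p by enumeration over heterozygote configurations, computed
# through binomial coefficients (a different route than the package's
# log-factorial implementation).
bruteHWE <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  if (nA == 0 || nA == 2 * n) return(1)
  rare <- min(nA, 2 * n - nA)
  hets <- seq(rare %% 2, rare, by = 2)
  w <- vapply(hets, function(h) {
    hAA <- (nA - h) / 2
    choose(n, hAA) * choose(n - hAA, h) * 2^h
  }, numeric(1))
  p <- w / sum(w)
  pObs <- p[hets == nAa]
  sum(p[p <= pObs * (1 + 1e-9)])
}

# Weir-Cockerham (1984) theta written out step by step, independently of
# the package implementation.
oracleWC <- function(g1, g2) {
  n_i <- c(length(g1), length(g2))
  p_i <- c(sum(g1) / (2 * n_i[1]), sum(g2) / (2 * n_i[2]))
  h_i <- c(mean(g1 == 1), mean(g2 == 1))
  r <- 2
  n_bar <- mean(n_i)
  n_c <- (r * n_bar - sum(n_i^2) / (r * n_bar)) / (r - 1)
  p_bar <- sum(n_i * p_i) / sum(n_i)
  s2 <- sum(n_i * (p_i - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- sum(n_i * h_i) / sum(n_i)
  a <- (n_bar / n_c) * (s2 - (p_bar * (1 - p_bar) -
                                (r - 1) * s2 / r - h_bar / 4) / (n_bar - 1))
  b <- (n_bar / (n_bar - 1)) * (p_bar * (1 - p_bar) -
                                  (r - 1) * s2 / r -
                                  (2 * n_bar - 1) * h_bar / (4 * n_bar))
  cc <- h_bar / 2
  a / (a + b + cc)
}

# D by site-pattern (ABBA/BABA) counting on single binary haplotypes.
bruteD <- function(h1, h2, h3, h4) {
  abba <- sum(h1 == 0 & h2 == 1 & h3 == 1 & h4 == 0)
  baba <- sum(h1 == 1 & h2 == 0 & h3 == 1 & h4 == 0)
  (abba - baba) / (abba + baba)
}

# small deterministic HaplotypeMatrix from a plain matrix
hapFixture <- function(m, positions = NULL, pop = "pop1") {
  m <- as.matrix(m)
  if (is.null(positions)) positions <- seq_len(ncol(m)) * 1000
  HaplotypeMatrix(m, positions, populations = pop)
}
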