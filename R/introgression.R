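# Archaic-introgression statistics: Patterson's D (ABBA-BABA), the
# window-wise f_d estimator, and an S*-like linkage score maximized by
# dynamic programming.

#' Patterson's D statistic from derived-allele frequencies
#'
#' D = sum[(1-p1) p2 p3 (1-p4) - p1 (1-p2) p3 (1-p4)] /
#'     sum[(1-p1) p2 p3 (1-p4) + p1 (1-p2) p3 (1-p4)]
#' over sites; p1 = sister population, p2 = test (recipient) population,
#' p3 = archaic, p4 = outgroup (defines ancestral polarity).  On binary
#' haplotype data this reduces to (ABBA - BABA) / (ABBA + BABA).
#'
#' @param p1,p2,p3,p4 per-site derived-allele frequencies (equal lengths)
#' @return list(d, num, den, n_informative); d is NA when the denominator
#'   is zero
#' @export
dStatistic <- function(p1, p2, p3, p4) {
  stopifnot(length(p1) == length(p2), length(p2) == length(p3),
            length(p3) == length(p4))
  abba <- (1 - p1) * p2 * p3 * (1 - p4)
  baba <- p1 * (1 - p2) * p3 * (1 - p4)
  num <- sum(abba - baba)
  den <- sum(abba + baba)
  list(d = if (den == 0) NA_real_ else num / den, num = num, den = den,
       n_informative = sum(abba + baba > 0))
}

#' f_d statistic for a window
#'
#' f_d = S(P1, P2, P3, O) / S(P1, P_D, P_D, O), where S is the D numerator
#' and P_D per site is whichever of P2/P3 has the higher derived-allele
#' frequency.  Bounds the local admixture fraction; reported as NA
#' (undefined) where the D numerator is negative.
#'
#' @inheritParams dStatistic
#' @return list(fd, num, den); fd = 0 when the numerator is 0, NA when the
#'   numerator is negative or the denominator is 0
#' @export
fdStatistic <- function(p1, p2, p3, p4) {
  stopifnot(length(p1) == length(p2), length(p2) == length(p3),
            length(p3) == length(p4))
  s <- function(a, b, c, d) sum((1 - a) * b * c * (1 - d) -
                                  a * (1 - b) * c * (1 - d))
  pd <- pmax(p2, p3)
  num <- s(p1, p2, p3, p4)
  den <- s(p1, pd, pd, p4)
  fd <- if (num < 0) NA_real_
  else if (num == 0) 0
  else if (den == 0) NA_real_
  else num / den
  list(fd = fd, num = num, den = den)
}

#' S*-like linkage score for one individual in a window
#'
#' Candidate SNVs are those whose derived allele is absent from the
#' outgroup panel.  For an ordered chain of candidate SNVs, consecutive
#' pairs score \code{bonus} + bp-distance when the individual's genotypes
#' at the two SNVs match (and the distance is at least \code{minDist} bp),
#' \code{mismatch} when they differ, and -Inf below \code{minDist}.  S* is
#' the maximum total score over all ordered subsets, found by dynamic
#' programming; the maximizing chain is returned.
#'
#' @param genotypes individual's genotypes (0/1/2 dosages) at the window's
#'   candidate SNVs, in position order
#' @param pos physical positions (bp) of those SNVs
#' @param bonus score bonus for a congruent pair (default 5000)
#' @param mismatch penalty for a genotype mismatch (default -10000)
#' @param minDist minimum pair distance in bp (default 10)
#' @return list(score, chain); score 0 and empty chain with < 2 SNVs
#' @export
sStar <- function(genotypes, pos, bonus = 5000, mismatch = -10000,
                  minDist = 10) {
  n <- length(genotypes)
  stopifnot(length(pos) == n)
  if (n < 2) return(list(score = 0, chain = integer()))
  o <- order(pos)
  genotypes <- genotypes[o]; pos <- pos[o]
  pairScore <- function(i, j) {
    d <- pos[j] - pos[i]
    if (d < minDist) return(-Inf)
    if (genotypes[i] == genotypes[j]) bonus + d else mismatch
  }
  best <- rep(-Inf, n)     # best chain score ending at j (chain length >= 2)
  prev <- rep(NA_integer_, n)
  fresh <- rep(TRUE, n)    # TRUE: the best chain at j starts at prev[j]
  for (j in 2:n) {
    for (i in 1:(j - 1)) {
      s <- pairScore(i, j)
      if (!is.finite(s)) next
      base <- max(best[i], 0)           # extend chain at i, or start fresh
      if (s + base > best[j]) {
        best[j] <- s + base
        prev[j] <- i
        fresh[j] <- !(is.finite(best[i]) && best[i] >= 0)
      }
    }
  }
  if (!any(is.finite(best))) return(list(score = 0, chain = integer()))
  jBest <- which.max(best)
  score <- best[jBest]
  chain <- jBest
  j <- jBest
  while (!is.na(prev[j])) {
    chain <- c(prev[j], chain)
    if (fresh[j]) break
    j <- prev[j]
  }
  list(score = score, chain = o[chain])
}
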