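# Quality control of short-read SV genotypes: missing-rate / recall flags,
# Hardy-Weinberg exact testing, cross-dataset concordance, and read-depth
# copy-number profiles.

#' Missing-rate and recall flags per locus
#'
#' pass-MR: the genotyping missing rate is below \code{mrThreshold}
#' (default 5%, i.e. genotyped in at least 95% of samples); recalled:
#' pass-MR and the genotyped alternate-allele frequency is positive
#' (loci with genotyped AF = 0 were discovered but never recalled).
#'
#' @param gm a \linkS4class{GenotypeMatrix}
#' @param mrThreshold missing-rate threshold in (0, 1]
#' @return data.frame(locus_id, mr, af, pass_mr, recalled)
#' @export
qcMissingAndRecall <- function(gm, mrThreshold = 0.05) {
  stopifnot(mrThreshold > 0, mrThreshold <= 1)
  mr <- missingRate(gm)
  af <- genotypedAF(gm)
  passMr <- mr < mrThreshold
  data.frame(locus_id = mcols(gm@loci)$locus_id, mr = mr, af = af,
             pass_mr = passMr,
             recalled = passMr & !is.nan(af) & af > 0)
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact conditional test of the heterozygote count given the allele
#' counts: the probability of each possible heterozygote configuration is
#' computed from the hypergeometric-style HWE distribution and the
#' two-sided p-value sums the probabilities of all configurations no more
#' likely than the observed one.  Monomorphic loci return p = 1.
#'
#' @param nAA,nAa,naa genotype counts (non-negative, total >= 1)
#' @return exact p-value in (0, 1]
#' @examples
#' hweExactTest(0, 1, 0)    # 1
#' hweExactTest(50, 0, 50)  # extreme heterozygote deficit
#' @export
hweExactTest <- function(nAA, nAa, naa) {
  stopifnot(nAA >= 0, nAa >= 0, naa >= 0, nAA + nAa + naa >= 1)
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  na <- 2 * naa + nAa
  if (nA == 0 || na == 0) return(1)
  rare <- min(nA, na)
  hets <- seq(rare %% 2, rare, by = 2)
  # log P(het = h | n, nA) = log [ n! / (nAA! h! naa!) * 2^h * nA! na! / (2n)! ]
  logP <- vapply(hets, function(h) {
    hAA <- (nA - h) / 2
    haa <- (na - h) / 2
    lfactorial(n) - lfactorial(hAA) - lfactorial(h) - lfactorial(haa) +
      h * log(2) + lfactorial(nA) + lfactorial(na) - lfactorial(2 * n)
  }, numeric(1))
  p <- exp(logP - max(logP))
  p <- p / sum(p)
  pObs <- p[hets == nAa]
  min(1, sum(p[p <= pObs * (1 + 1e-9)]))
}

#' Per-population HWE filter
#'
#' Applies [hweExactTest()] within each population and flags a locus as a
#' violation when it fails in any of them.
#'
#' @param gm a \linkS4class{GenotypeMatrix}
#' @param alpha significance threshold
#' @param populations populations to test (default: all in the panel)
#' @return data.frame(locus_id, one p-value column per population,
#'   violates)
#' @export
hweFilter <- function(gm, alpha = 1e-3, populations = NULL) {
  panel <- samplePanel(gm)
  if (is.null(populations)) populations <- sort(unique(panel$population))
  g <- genotypes(gm)
  res <- data.frame(locus_id = mcols(gm@loci)$locus_id)
  for (pop in populations) {
    cols <- which(panel$population == pop)
    pv <- apply(g[, cols, drop = FALSE], 1, function(row) {
      row <- row[!is.na(row)]
      if (!length(row)) return(NA_real_)
      hweExactTest(sum(row == 0), sum(row == 1), sum(row == 2))
    })
    res[[paste0("p_", pop)]] <- pv
  }
  pcols <- grep("^p_", names(res))
  res$violates <- apply(res[, pcols, drop = FALSE], 1, function(p)
    any(!is.na(p) & p < alpha))
  res
}

#' Cross-dataset genotype-concordance filter
#'
#' For every pair of source datasets sharing a population, allele counts
#' within the shared population are compared by Fisher's exact test of
#' homogeneity on the 2x2 ref/alt table.  A pair fails when p < alpha; a
#' locus fails overall when it fails in more than \code{maxFailures}
#' comparisons.
#'
#' @param gm a \linkS4class{GenotypeMatrix} with >= 2 datasets in its panel
#' @param alpha per-comparison significance level in (0, 1)
#' @param maxFailures failures tolerated before the locus is removed
#'   (default 1 = "failed in more than one comparison")
#' @return data.frame(locus_id, n_comparisons, n_failures, pass)
#' @export
datasetConcordanceFilter <- function(gm, alpha = 1e-3, maxFailures = 1) {
  stopifnot(alpha > 0, alpha < 1)
  panel <- samplePanel(gm)
  datasets <- sort(unique(panel$dataset))
  if (length(datasets) < 2) stop("need >= 2 source datasets")
  g <- genotypes(gm)
  pairs <- utils::combn(datasets, 2, simplify = FALSE)
  nl <- nrow(g)
  fails <- integer(nl)
  comps <- integer(nl)
  for (pr in pairs) {
    shared <- intersect(panel$population[panel$dataset == pr[1]],
                        panel$population[panel$dataset == pr[2]])
    if (!length(shared)) next   # no shared population: comparison skipped
    for (pop in shared) {
      c1 <- which(panel$dataset == pr[1] & panel$population == pop)
      c2 <- which(panel$dataset == pr[2] & panel$population == pop)
      for (i in seq_len(nl)) {
        g1 <- g[i, c1]; g1 <- g1[!is.na(g1)]
        g2 <- g[i, c2]; g2 <- g2[!is.na(g2)]
        if (!length(g1) || !length(g2)) next
        tab <- matrix(c(sum(g1), 2 * length(g1) - sum(g1),
                        sum(g2), 2 * length(g2) - sum(g2)), 2)
        comps[i] <- comps[i] + 1L
        if (stats::fisher.test(tab)$p.value < alpha)
          fails[i] <- fails[i] + 1L
      }
    }
  }
  data.frame(locus_id = mcols(gm@loci)$locus_id, n_comparisons = comps,
             n_failures = fails, pass = fails <= maxFailures)
}

#' Integer copy-number profile from per-base read depth
#'
#' Sliding windows of \code{window} bp advanced by \code{step} bp;
#' CN(w) = round(2 * mean depth in window / genome median depth).  A
#' trailing partial window is kept when it is at least \code{step} bp long.
#'
#' @param depth numeric vector of per-base depth
#' @param medianDepth genome-wide median depth (> 0)
#' @param window window size in bp (>= step)
#' @param step step size in bp (>= 1)
#' @return data.frame(start, end, cn)
#' @export
copyNumberProfile <- function(depth, medianDepth, window = 100, step = 50) {
  stopifnot(window >= step, step >= 1, medianDepth > 0)
  n <- length(depth)
  if (n == 0) stop("zero-length depth array")
  starts <- seq(1, max(1, n), by = step)
  starts <- starts[starts <= n]
  ends <- pmin(starts + window - 1, n)
  keep <- ends - starts + 1 >= step | starts == 1
  starts <- starts[keep]; ends <- ends[keep]
  cs <- cumsum(c(0, depth))
  mu <- (cs[ends + 1] - cs[starts]) / (ends - starts + 1)
  data.frame(start = starts, end = ends,
             cn = as.integer(round(2 * mu / medianDepth)))
}
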