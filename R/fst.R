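# Allele frequencies, F_ST (Weir-Cockerham 1984 and Hudson), stratified-SV
# calling and LD tagging.

#' Per-population allele frequencies and diploid counts
#'
#' @param gm a \linkS4class{GenotypeMatrix}
#' @param populations populations to report (default: all in the panel)
#' @return data.frame with locus_id, then af_<pop> and n_<pop> (non-missing
#'   diploid counts) per population; AF is NaN where all genotypes are
#'   missing.
#' @export
alleleFrequencies <- function(gm, populations = NULL) {
  panel <- samplePanel(gm)
  if (is.null(populations)) populations <- sort(unique(panel$population))
  if (!all(populations %in% panel$population))
    stop("population absent from panel: ",
         paste(setdiff(populations, panel$population), collapse = ", "))
  g <- genotypes(gm)
  out <- data.frame(locus_id = mcols(gm@loci)$locus_id)
  for (pop in populations) {
    cols <- which(panel$population == pop)
    sub <- g[, cols, drop = FALSE]
    nObs <- rowSums(!is.na(sub))
    af <- ifelse(nObs > 0, rowSums(sub, na.rm = TRUE) / (2 * nObs), NaN)
    out[[paste0("af_", pop)]] <- af
    out[[paste0("n_", pop)]] <- nObs
  }
  out
}

#' Weir-Cockerham (1984) F_ST from two-population genotype counts
#'
#' Computes the 1984 variance components a (among populations), b (among
#' individuals within populations) and c (within individuals) from sample
#' sizes, allele frequencies and observed heterozygote frequencies, and
#' theta = a / (a + b + c).  Windows aggregate as ratio-of-sums:
#' sum(a) / sum(a + b + c) over member sites.
#'
#' @param counts1,counts2 numeric length-3 vectors c(nAA, nAa, naa) of
#'   genotype counts in each population (>= 2 non-missing diploids each).
#' @return list(a, b, c, fst, p1, p2, n1, n2); \code{fst} is NA (undefined)
#'   when both populations are monomorphic for the same allele.
#' @export
wcFst <- function(counts1, counts2) {
  n1 <- sum(counts1); n2 <- sum(counts2)
  stopifnot(n1 >= 2, n2 >= 2)
  p1 <- (2 * counts1[1] + counts1[2]) / (2 * n1)
  p2 <- (2 * counts2[1] + counts2[2]) / (2 * n2)
  h1 <- counts1[2] / n1
  h2 <- counts2[2] / n2
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc *
    (s2 - 1 / (nbar - 1) *
       (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) /
       (4 * nbar) * hbar)
  cc <- hbar / 2
  denom <- a + b + cc
  fst <- if (denom == 0) NA_real_ else a / denom
  list(a = unname(a), b = unname(b), c = unname(cc), fst = unname(fst),
       p1 = unname(p1), p2 = unname(p2), n1 = n1, n2 = n2)
}

#' Hudson F_ST from allele frequencies and allele counts
#'
#' Sample-size-corrected frequency-only estimator:
#' numerator = (p1 - p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1),
#' denominator = p1(1-p2) + p2(1-p1); value = numerator / denominator.
#' Windows aggregate as ratio-of-sums.
#'
#' @param p1,p2 alternate-allele frequencies in each population
#' @param n1,n2 allele (not diploid) counts, >= 2 each
#' @return list(num, den, fst); fst is NA when the denominator is 0 (both
#'   populations fixed for the same allele)
#' @examples
#' hudsonFst(0.58, 156, 0.02, 348)$fst  # ~0.54
#' @export
hudsonFst <- function(p1, n1, p2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, p1 >= 0, p1 <= 1, p2 >= 0, p2 <= 1)
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  list(num = num, den = den,
       fst = if (den == 0) NA_real_ else num / den)
}

#' Per-locus two-population F_ST across a GenotypeMatrix
#'
#' @param gm a \linkS4class{GenotypeMatrix}
#' @param pop1,pop2 population labels (pop1 is the focal population)
#' @param estimator "wc" (Weir-Cockerham) or "hudson"
#' @return data.frame(locus_id, p1, p2, n1, n2, num, den, fst) with n in
#'   diploids; loci with < 2 genotyped diploids in either population get NA
#' @export
fstScan <- function(gm, pop1, pop2, estimator = c("wc", "hudson")) {
  estimator <- match.arg(estimator)
  panel <- samplePanel(gm)
  g <- genotypes(gm)
  c1 <- which(panel$population == pop1)
  c2 <- which(panel$population == pop2)
  if (!length(c1) || !length(c2)) stop("population absent from panel")
  n <- nrow(g)
  out <- data.frame(locus_id = mcols(gm@loci)$locus_id,
                    p1 = NA_real_, p2 = NA_real_,
                    n1 = NA_integer_, n2 = NA_integer_,
                    num = NA_real_, den = NA_real_, fst = NA_real_)
  for (i in seq_len(n)) {
    g1 <- g[i, c1]; g1 <- g1[!is.na(g1)]
    g2 <- g[i, c2]; g2 <- g2[!is.na(g2)]
    if (length(g1) < 2 || length(g2) < 2) next
    out$n1[i] <- length(g1); out$n2[i] <- length(g2)
    if (estimator == "wc") {
      r <- wcFst(c(sum(g1 == 0), sum(g1 == 1), sum(g1 == 2)),
                 c(sum(g2 == 0), sum(g2 == 1), sum(g2 == 2)))
      # store alt-allele frequencies for readability
      out$p1[i] <- 1 - r$p1; out$p2[i] <- 1 - r$p2
      out$num[i] <- r$a; out$den[i] <- r$a + r$b + r$c
      out$fst[i] <- r$fst
    } else {
      p1 <- sum(g1) / (2 * length(g1))
      p2 <- sum(g2) / (2 * length(g2))
      r <- hudsonFst(p1, 2 * length(g1), p2, 2 * length(g2))
      out$p1[i] <- p1; out$p2[i] <- p2
      out$num[i] <- r$num; out$den[i] <- r$den; out$fst[i] <- r$fst
    }
  }
  out
}

#' Aggregate per-site F_ST components over windows (ratio of sums)
#' @param fst data.frame from [fstScan()] with num/den columns
#' @param windowId vector assigning each row to a window
#' @return data.frame(window, fst)
#' @export
fstWindows <- function(fst, windowId) {
  num <- tapply(fst$num, windowId, sum, na.rm = TRUE)
  den <- tapply(fst$den, windowId, sum, na.rm = TRUE)
  data.frame(window = names(num),
             fst = as.numeric(num) / as.numeric(den))
}

#' Population-stratified SVs: loci with F_ST above a threshold
#'
#' Strict inequality, sorted descending by F_ST.
#'
#' @param fst data.frame with columns locus_id and fst
#' @param threshold stratification threshold (default 0.1)
#' @return the subset with fst > threshold, ordered by decreasing fst
#' @export
stratifySVs <- function(fst, threshold = 0.1) {
  stopifnot(threshold >= 0)
  hit <- !is.na(fst$fst) & fst$fst > threshold
  out <- fst[hit, , drop = FALSE]
  out[order(-out$fst), , drop = FALSE]
}

#' Squared correlation (r2) between two biallelic variants
#'
#' Haplotype-based when both inputs are phased 0/1 haplotype vectors;
#' genotype dosages (0/1/2) give the genotype-correlation version.
#'
#' @param a,b numeric vectors of equal length (0/1 haplotypes or 0/1/2
#'   dosages); pairs with missing values are dropped
#' @return r^2 in [0, 1]; NA when either variant is monomorphic
#' @export
ldR2 <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  if (length(unique(a)) < 2 || length(unique(b)) < 2) return(NA_real_)
  stats::cor(a, b)^2
}

#' Tag SNVs linked to an SV at one or more r2 cutoffs
#'
#' @param sv vector of SV alleles/dosages (one entry per haplotype or
#'   sample, matching the SNV matrix columns... rows are haplotypes)
#' @param snvs matrix of SNV alleles with one column per SNV
#' @param cutoffs r2 cutoffs to report
#' @return list(r2 = per-SNV r2, linked = list per cutoff of SNV column
#'   indices with r2 > cutoff, no_tag = logical per cutoff)
#' @export
tagLinkedSNVs <- function(sv, snvs, cutoffs = c(0.8, 0.9)) {
  r2 <- apply(snvs, 2, function(col) ldR2(sv, col))
  linked <- lapply(cutoffs, function(ct) which(!is.na(r2) & r2 > ct))
  names(linked) <- as.character(cutoffs)
  list(r2 = r2, linked = linked,
       no_tag = vapply(linked, function(x) length(x) == 0, logical(1)))
}
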