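# Haplotype-homozygosity statistics: EHH curves, integrated haplotype
# homozygosity (iHH), iHS and XP-EHH.
#
# EHH(d) is the probability that two randomly drawn carrier haplotypes are
# identical at every site from the core out to distance d.  Integration is
# over genetic distance (uniform map when none is supplied), truncated when
# EHH falls below a cutoff (linear interpolation to the crossing point) or
# when the next inter-site gap exceeds maxGap bp.

#' EHH decay curve around a core site
#'
#' @param haps a \linkS4class{HaplotypeMatrix}
#' @param coreSite column index of the core site
#' @param coreAllele 0 (ancestral) or 1 (derived) core allele
#' @param cutoff computation stops once EHH drops below this value
#' @return data.frame(site, position, gen_pos, direction, ehh) including
#'   the core itself at distance 0 with EHH = 1
#' @export
ehhCurve <- function(haps, coreSite, coreAllele = 1, cutoff = 0.05) {
  m <- hapMatrix(haps)
  carriers <- which(m[, coreSite] == coreAllele)
  if (length(carriers) < 2)
    stop("fewer than 2 haplotypes carry the core allele")
  pos <- positions(haps)
  gp <- genPositions(haps)
  pieces <- list(data.frame(site = coreSite, position = pos[coreSite],
                            gen_pos = gp[coreSite], direction = 0L,
                            ehh = 1))
  for (dir in c(-1L, 1L)) {
    v <- .ehhDecayCpp(m, coreSite, carriers, dir, cutoff)
    if (length(v)) {
      idx <- coreSite + dir * seq_along(v)
      pieces[[length(pieces) + 1L]] <-
        data.frame(site = idx, position = pos[idx], gen_pos = gp[idx],
                   direction = dir, ehh = v)
    }
  }
  out <- do.call(rbind, pieces)
  out[order(out$position), , drop = FALSE]
}

# integrate one direction's EHH decay over genetic distance.
# ehh: decay values at successive sites; gpos: their genetic positions (cM);
# gp0: core genetic position; bp: physical positions; bp0: core position.
.ihhOneSide <- function(ehh, gpos, gp0, bp, bp0, cutoff, maxGap) {
  K <- length(ehh)
  if (!K) return(0)
  prevE <- c(1, ehh[-K])
  d <- abs(gpos - c(gp0, gpos[-K]))
  gap <- abs(bp - c(bp0, bp[-K])) > maxGap
  firstGap <- which(gap)[1]                 # stop before a map gap
  firstBelow <- which(ehh < cutoff)[1]      # partial trapezoid at crossing
  lim <- min(K, firstGap - 1L, na.rm = TRUE)
  nFull <- min(lim, firstBelow - 1L, na.rm = TRUE)
  ihh <- if (nFull > 0)
    sum(d[seq_len(nFull)] * (prevE[seq_len(nFull)] +
                               ehh[seq_len(nFull)]) / 2) else 0
  if (!is.na(firstBelow) && firstBelow <= lim &&
      prevE[firstBelow] > cutoff) {
    frac <- (prevE[firstBelow] - cutoff) / (prevE[firstBelow] -
                                              ehh[firstBelow])
    ihh <- ihh + d[firstBelow] * frac * (prevE[firstBelow] + cutoff) / 2
  }
  ihh
}

# iHH for a given carrier set, both directions
.ihh <- function(haps, coreSite, carriers, cutoff, maxGap,
                 maxSteps = NULL) {
  m <- hapMatrix(haps)
  pos <- positions(haps)
  gp <- genPositions(haps)
  tot <- 0
  for (dir in c(-1L, 1L)) {
    v <- .ehhDecayCpp(m, coreSite, carriers, dir, cutoff)
    if (!is.null(maxSteps)) v <- v[seq_len(min(length(v), maxSteps[[as.character(dir)]]))]
    idx <- coreSite + dir * seq_along(v)
    tot <- tot + .ihhOneSide(v, gp[idx], gp[coreSite], pos[idx],
                             pos[coreSite], cutoff, maxGap)
  }
  tot
}

#' Unstandardized iHS at a core site
#'
#' iHS = ln(iHH_ancestral / iHH_derived), where iHH is the trapezoidal
#' integral of the allele-specific EHH curve over genetic distance down to
#' \code{cutoff}.
#'
#' @inheritParams ehhCurve
#' @param mafMin minimum derived-allele frequency (sites outside
#'   [mafMin, 1 - mafMin] are refused)
#' @param maxGap maximum inter-site gap (bp) beyond which integration stops
#' @return list(uihs, ihh_a, ihh_d, daf); uihs is NA (flagged) when either
#'   integral is zero
#' @export
ihs <- function(haps, coreSite, mafMin = 0.05, cutoff = 0.05,
                maxGap = 2e5) {
  m <- hapMatrix(haps)
  col <- m[, coreSite]
  daf <- mean(col)
  if (daf < mafMin || daf > 1 - mafMin)
    stop("derived allele frequency outside [mafMin, 1 - mafMin]")
  anc <- which(col == 0L)
  der <- which(col == 1L)
  ihhA <- if (length(anc) >= 2)
    .ihh(haps, coreSite, anc, cutoff, maxGap) else 0
  ihhD <- if (length(der) >= 2)
    .ihh(haps, coreSite, der, cutoff, maxGap) else 0
  uihs <- if (ihhA > 0 && ihhD > 0) log(ihhA / ihhD) else NA_real_
  list(uihs = uihs, ihh_a = ihhA, ihh_d = ihhD, daf = daf)
}

#' Unstandardized iHS across all eligible sites
#'
#' @inheritParams ihs
#' @return data.frame(site, position, daf, uihs)
#' @export
ihsScan <- function(haps, mafMin = 0.05, cutoff = 0.05, maxGap = 2e5) {
  daf <- derivedFreq(haps)
  sites <- which(daf >= mafMin & daf <= 1 - mafMin)
  uihs <- vapply(sites, function(s) {
    r <- ihs(haps, s, mafMin, cutoff, maxGap)
    if (is.na(r$uihs)) NA_real_ else r$uihs
  }, numeric(1))
  data.frame(site = sites, position = positions(haps)[sites],
             daf = daf[sites], uihs = uihs)
}

#' Bin parameters for iHS standardization
#'
#' Mean and standard deviation of unstandardized iHS per derived-allele-
#' frequency bin, typically computed on a genome-wide or simulated neutral
#' reference set and then applied to a scanned region.
#'
#' @param uihs unstandardized iHS values
#' @param daf derived-allele frequencies, same length
#' @param nBins number of equal-width frequency bins (default 50)
#' @return data.frame(bin, mean, sd, n)
#' @export
ihsBinParams <- function(uihs, daf, nBins = 50) {
  bin <- pmin(nBins, pmax(1, ceiling(daf * nBins)))
  ok <- !is.na(uihs)
  out <- data.frame(bin = sort(unique(bin[ok])))
  out$mean <- vapply(out$bin, function(b)
    mean(uihs[ok & bin == b]), numeric(1))
  out$sd <- vapply(out$bin, function(b)
    stats::sd(uihs[ok & bin == b]), numeric(1))
  out$n <- vapply(out$bin, function(b) sum(ok & bin == b), numeric(1))
  out
}

#' Standardize iHS within derived-allele-frequency bins
#'
#' Subtracts the bin mean and divides by the bin standard deviation so that
#' standardized values have mean 0, sd 1 within each DAF bin.  When
#' \code{params} (from [ihsBinParams()] on a reference set, e.g. pooled
#' neutral simulations or the genome-wide scan) is supplied, its bin means
#' and sds are used instead of the input's own — required when the scanned
#' region is small or potentially swept, since self-standardization absorbs
#' the signal.
#'
#' @inheritParams ihsBinParams
#' @param params optional reference bin parameters from [ihsBinParams()]
#' @return numeric vector of standardized iHS (NA preserved; bins absent
#'   from the reference, or with < 2 usable values, return NA)
#' @export
standardizeIHS <- function(uihs, daf, nBins = 50, params = NULL) {
  bin <- pmin(nBins, pmax(1, ceiling(daf * nBins)))
  if (is.null(params)) params <- ihsBinParams(uihs, daf, nBins)
  out <- rep(NA_real_, length(uihs))
  idx <- match(bin, params$bin)
  ok <- !is.na(uihs) & !is.na(idx)
  usable <- ok & params$n[idx] >= 2 & !is.na(params$sd[idx]) &
    params$sd[idx] > 0
  out[usable] <- (uihs[usable] - params$mean[idx[usable]]) /
    params$sd[idx[usable]]
  out
}

#' Unstandardized XP-EHH between two populations at a core site
#'
#' ln(iHH_A / iHH_B) where each population's EHH (over all its haplotypes,
#' regardless of core allele) is integrated over the region where the
#' pooled two-population EHH stays at or above \code{cutoff}.  Positive
#' values mean longer haplotypes (less decay) in population A.
#'
#' @param hapsA,hapsB \linkS4class{HaplotypeMatrix} objects over identical
#'   sites for the two populations
#' @param coreSite core column index (must segregate in the pooled sample)
#' @param cutoff pooled-EHH integration cutoff
#' @param maxGap maximum inter-site gap in bp
#' @return list(uxpehh, ihh_a, ihh_b)
#' @export
xpehh <- function(hapsA, hapsB, coreSite, cutoff = 0.05, maxGap = 2e5) {
  if (!identical(positions(hapsA), positions(hapsB)))
    stop("populations must share the same site set")
  mA <- hapMatrix(hapsA); mB <- hapMatrix(hapsB)
  pooled <- rbind(mA, mB)
  col <- pooled[, coreSite]
  if (min(col) == max(col))
    stop("core site not segregating in the pooled sample")
  .xpehhCore(mA, mB, pooled, positions(hapsA), genPositions(hapsA),
             coreSite, cutoff, maxGap)
}

.xpehhCore <- function(mA, mB, pooled, pos, gp, coreSite, cutoff,
                       maxGap) {
  ihhA <- 0; ihhB <- 0
  for (dir in c(-1L, 1L)) {
    vP <- .ehhDecayCpp(pooled, coreSite, seq_len(nrow(pooled)), dir, cutoff)
    K <- length(vP)            # pooled EHH < cutoff at step K: common bound
    if (!K) next
    vA <- .ehhDecayCpp(mA, coreSite, seq_len(nrow(mA)), dir, 0, K)
    vB <- .ehhDecayCpp(mB, coreSite, seq_len(nrow(mB)), dir, 0, K)
    pad <- function(v) c(v, rep(0, max(0, K - length(v))))[seq_len(K)]
    idx <- coreSite + dir * seq_len(K)
    ihhA <- ihhA + .ihhOneSide(pad(vA), gp[idx], gp[coreSite], pos[idx],
                               pos[coreSite], 0, maxGap)
    ihhB <- ihhB + .ihhOneSide(pad(vB), gp[idx], gp[coreSite], pos[idx],
                               pos[coreSite], 0, maxGap)
  }
  ux <- if (ihhA > 0 && ihhB > 0) log(ihhA / ihhB) else NA_real_
  list(uxpehh = ux, ihh_a = ihhA, ihh_b = ihhB)
}

#' XP-EHH across all shared segregating sites, with standardization
#'
#' @inheritParams xpehh
#' @param standardize z-score the unstandardized values (mean 0, sd 1)
#' @param params optional reference c(mean, sd) for standardization,
#'   e.g. from pooled neutral simulations; the scan's own moments are used
#'   when absent
#' @return data.frame(site, position, uxpehh, xpehh)
#' @export
xpehhScan <- function(hapsA, hapsB, cutoff = 0.05, maxGap = 2e5,
                      standardize = TRUE, params = NULL) {
  mA <- hapMatrix(hapsA); mB <- hapMatrix(hapsB)
  pooled <- rbind(mA, mB)
  pooledFreq <- colMeans(pooled)
  sites <- which(pooledFreq > 0 & pooledFreq < 1)
  pos <- positions(hapsA); gp <- genPositions(hapsA)
  ux <- vapply(sites, function(s)
    .xpehhCore(mA, mB, pooled, pos, gp, s, cutoff, maxGap)$uxpehh,
    numeric(1))
  if (is.null(params)) {
    params <- c(mean(ux, na.rm = TRUE), stats::sd(ux, na.rm = TRUE))
  }
  z <- if (standardize && sum(!is.na(ux)) >= 1 && !is.na(params[2]) &&
           params[2] > 0)
    (ux - params[1]) / params[2]
  else rep(NA_real_, length(ux))
  data.frame(site = sites, position = positions(hapsA)[sites],
             uxpehh = ux, xpehh = z)
}
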