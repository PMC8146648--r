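# Window-level selection/introgression scan, empirical p-values against a
# simulated neutral null, and the final per-SV adaptive/introgressed
# classification.

#' Candidate archaic SNVs for S* in one individual
#'
#' Sites whose derived allele is absent from the outgroup panel and carried
#' (dosage >= 1) by the individual.
#'
#' @param haps a \linkS4class{HaplotypeMatrix}
#' @param sampleId individual to score
#' @param outgroupPop population label of the outgroup panel
#' @param sites optional site indices restricting the window
#' @return list(sites, genotypes, pos)
#' @export
sStarCandidates <- function(haps, sampleId, outgroupPop, sites = NULL) {
  m <- hapMatrix(haps)
  if (is.null(sites)) sites <- seq_len(ncol(m))
  outRows <- which(popLabels(haps) == outgroupPop)
  indRows <- which(sampleIds(haps) == sampleId)
  if (length(indRows) != 2) stop("sample not found (need 2 haplotypes)")
  outCount <- colSums(m[outRows, sites, drop = FALSE])
  dosage <- colSums(m[indRows, sites, drop = FALSE])
  keep <- outCount == 0 & dosage >= 1
  list(sites = sites[keep], genotypes = dosage[keep],
       pos = positions(haps)[sites[keep]])
}

#' Maximum S* over target individuals in a window
#' @inheritParams sStarCandidates
#' @param targetPop population whose individuals are scored
#' @param ... passed to [sStar()]
#' @return maximum S* score (0 when no individual has >= 2 candidates)
#' @export
sStarWindow <- function(haps, targetPop, outgroupPop, sites = NULL, ...) {
  ids <- unique(sampleIds(haps)[popLabels(haps) == targetPop])
  scores <- vapply(ids, function(id) {
    cand <- sStarCandidates(haps, id, outgroupPop, sites)
    sStar(cand$genotypes, cand$pos, ...)$score
  }, numeric(1))
  if (!length(scores)) 0 else max(scores, 0)
}

#' Per-window selection and introgression statistics
#'
#' Tiles [1, sequenceLength] with non-overlapping windows and reports, per
#' window: the maximum |standardized iHS| in the target population, the
#' maximum standardized XP-EHH (target vs sister), the D and f_d statistics
#' (P1 = sister, P2 = target, P3 = archaic, P4 = outgroup) and the maximum
#' S* over target individuals.  iHS and XP-EHH are standardized over the
#' whole scanned region.
#'
#' @param haps a \linkS4class{HaplotypeMatrix} containing all populations
#' @param targetPop,sisterPop,archaicPop,outgroupPop population labels
#' @param sequenceLength scanned length in bp
#' @param windowSize window size in bp (default 50 kb)
#' @param mafMin,cutoff,maxGap haplotype-statistic settings (see [ihs()])
#' @param sStarArgs list of arguments forwarded to [sStar()]
#' @param ihsParams optional [ihsBinParams()] reference for iHS
#'   standardization (e.g. from pooled neutral simulations)
#' @param xpehhParams optional c(mean, sd) reference for XP-EHH
#'   standardization
#' @param detail attach the per-site iHS and XP-EHH scans as attribute
#'   \code{"sites"} (used by [restandardizeWindows()])
#' @return data.frame(start, end, n_snps, max_abs_ihs, max_xpehh, d, fd,
#'   s_star)
#' @export
scanWindows <- function(haps, targetPop, sisterPop, archaicPop,
                        outgroupPop, sequenceLength, windowSize = 50000,
                        mafMin = 0.05, cutoff = 0.05, maxGap = 2e5,
                        sStarArgs = list(), ihsParams = NULL,
                        xpehhParams = NULL, detail = FALSE) {
  tgt <- subsetByPop(haps, targetPop)
  sis <- subsetByPop(haps, sisterPop)
  arc <- subsetByPop(haps, archaicPop)
  out <- subsetByPop(haps, outgroupPop)
  pos <- positions(haps)
  ihsDf <- ihsScan(tgt, mafMin, cutoff, maxGap)
  ihsDf$std <- standardizeIHS(ihsDf$uihs, ihsDf$daf, params = ihsParams)
  xpDf <- xpehhScan(tgt, sis, cutoff, maxGap, params = xpehhParams)
  p1 <- colMeans(hapMatrix(sis))
  p2 <- colMeans(hapMatrix(tgt))
  p3 <- colMeans(hapMatrix(arc))
  p4 <- colMeans(hapMatrix(out))
  starts <- seq(1, sequenceLength, by = windowSize)
  res <- lapply(starts, function(s) {
    e <- min(s + windowSize - 1, sequenceLength)
    inWin <- which(pos >= s & pos <= e)
    iW <- ihsDf$std[ihsDf$position >= s & ihsDf$position <= e]
    xW <- xpDf$xpehh[xpDf$position >= s & xpDf$position <= e]
    d <- dStatistic(p1[inWin], p2[inWin], p3[inWin], p4[inWin])$d
    fd <- fdStatistic(p1[inWin], p2[inWin], p3[inWin], p4[inWin])$fd
    ss <- do.call(sStarWindow,
                  c(list(haps, targetPop, outgroupPop, sites = inWin),
                    sStarArgs))
    data.frame(start = s, end = e, n_snps = length(inWin),
               max_abs_ihs = if (any(!is.na(iW)))
                 max(abs(iW), na.rm = TRUE) else NA_real_,
               max_xpehh = if (any(!is.na(xW)))
                 max(xW, na.rm = TRUE) else NA_real_,
               d = d, fd = fd, s_star = ss)
  })
  out <- do.call(rbind, res)
  if (detail) attr(out, "sites") <- list(ihs = ihsDf, xpehh = xpDf)
  out
}

#' Re-standardize scanned windows against reference parameters
#'
#' Recomputes the per-window |iHS| and XP-EHH maxima of a
#' [scanWindows()] result (run with \code{detail = TRUE}) using reference
#' standardization parameters, without re-running the haplotype scans.
#' Used to standardize observed and null windows against one common
#' (e.g. pooled-neutral) reference.
#'
#' @param windows result of \code{scanWindows(..., detail = TRUE)}
#' @param ihsParams reference bin parameters from [ihsBinParams()]
#' @param xpehhParams reference c(mean, sd) for XP-EHH
#' @return the windows data.frame with updated max_abs_ihs / max_xpehh
#' @export
restandardizeWindows <- function(windows, ihsParams = NULL,
                                 xpehhParams = NULL) {
  sites <- attr(windows, "sites")
  if (is.null(sites))
    stop("windows must come from scanWindows(..., detail = TRUE)")
  ihsDf <- sites$ihs
  xpDf <- sites$xpehh
  if (!is.null(ihsParams))
    ihsDf$std <- standardizeIHS(ihsDf$uihs, ihsDf$daf, params = ihsParams)
  if (!is.null(xpehhParams))
    xpDf$xpehh <- (xpDf$uxpehh - xpehhParams[1]) / xpehhParams[2]
  for (k in seq_len(nrow(windows))) {
    iW <- ihsDf$std[ihsDf$position >= windows$start[k] &
                      ihsDf$position <= windows$end[k]]
    xW <- xpDf$xpehh[xpDf$position >= windows$start[k] &
                       xpDf$position <= windows$end[k]]
    windows$max_abs_ihs[k] <- if (any(!is.na(iW)))
      max(abs(iW), na.rm = TRUE) else NA_real_
    windows$max_xpehh[k] <- if (any(!is.na(xW)))
      max(xW, na.rm = TRUE) else NA_real_
  }
  attr(windows, "sites") <- list(ihs = ihsDf, xpehh = xpDf)
  windows
}

#' Empirical p-values against a simulated null
#'
#' p = (1 + number of null values as or more extreme) / (1 + N).
#' Upper-tailed: extreme means null >= observed.  Two-sided: |null| >=
#' |observed|.
#'
#' @param observed numeric vector of observed statistics
#' @param null numeric vector of null statistics (>= 100 advised)
#' @param side "upper" or "two.sided"
#' @return numeric vector of p-values in (0, 1]; NA observations give NA
#' @export
empiricalPValues <- function(observed, null,
                             side = c("upper", "two.sided")) {
  side <- match.arg(side)
  null <- null[!is.na(null)]
  if (!length(null)) stop("empty null set")
  if (side == "two.sided") {
    null <- abs(null)
    observed <- abs(observed)
  }
  ns <- sort(null)
  vapply(observed, function(x) {
    if (is.na(x)) return(NA_real_)
    nGE <- length(ns) - findInterval(x - 1e-12, ns)
    .empP(nGE, length(ns))
  }, numeric(1))
}

#' Attach per-statistic empirical p-values to scanned windows
#'
#' iHS is two-sided (via the upper tail of the windowed |iHS| maximum);
#' XP-EHH (target direction), D, f_d and S* are upper-tailed.
#'
#' @param obs data.frame from [scanWindows()]
#' @param null data.frame from [scanWindows()] on neutral simulations
#' @return \code{obs} with columns p_ihs, p_xpehh, p_d, p_fd, p_sstar
#' @export
windowPValues <- function(obs, null) {
  obs$p_ihs <- empiricalPValues(obs$max_abs_ihs, null$max_abs_ihs)
  obs$p_xpehh <- empiricalPValues(obs$max_xpehh, null$max_xpehh)
  obs$p_d <- empiricalPValues(obs$d, null$d)
  obs$p_fd <- empiricalPValues(obs$fd, null$fd)
  obs$p_sstar <- empiricalPValues(obs$s_star, null$s_star)
  obs
}

#' Classify stratified SVs as selected, introgressed, both, or neither
#'
#' An SV is a selection candidate when any scanned window within
#' \code{radius} bp has iHS p < alpha; an introgression candidate when any
#' window within the radius is simultaneously significant for D, f_d and
#' S* under the same archaic reference; adaptive-introgressed when both
#' hold.  The reported p-value per statistic comes from the most
#' significant, then closest, window.
#'
#' @param svs data.frame with columns locus_id, pos (bp) and optionally
#'   chrom and fst
#' @param windows data.frame from [windowPValues()], optionally with
#'   columns chrom and archaic_ref
#' @param radius search radius in bp (default 500 kb)
#' @param alpha significance level (default 0.05)
#' @return data.frame(locus_id, fst, p_sel, p_d, p_fd, p_sstar, class)
#' @export
classifyAdaptation <- function(svs, windows, radius = 5e5, alpha = 0.05) {
  stopifnot(radius > 0, alpha > 0, alpha < 1)
  if (!"archaic_ref" %in% names(windows)) windows$archaic_ref <- "archaic"
  if (!"chrom" %in% names(windows)) windows$chrom <- "chr1"
  if (!"chrom" %in% names(svs)) svs$chrom <- "chr1"
  res <- lapply(seq_len(nrow(svs)), function(i) {
    sv <- svs[i, ]
    w <- windows[windows$chrom == sv$chrom, , drop = FALSE]
    out <- data.frame(locus_id = sv$locus_id,
                      fst = if ("fst" %in% names(sv)) sv$fst else NA_real_,
                      p_sel = NA_real_, p_d = NA_real_, p_fd = NA_real_,
                      p_sstar = NA_real_, class = "none")
    if (!nrow(w)) {
      warning("no scanned windows on ", sv$chrom, " for ", sv$locus_id)
      return(out)
    }
    dist <- pmax(0, w$start - sv$pos, sv$pos - w$end)
    near <- w[dist <= radius, , drop = FALSE]
    nearDist <- dist[dist <= radius]
    if (!nrow(near)) return(out)
    pick <- function(p) {
      ok <- !is.na(p)
      if (!any(ok)) return(NA_real_)
      o <- order(p, nearDist)[1]
      p[o]
    }
    out$p_sel <- pick(near$p_ihs)
    sel <- !is.na(out$p_sel) && out$p_sel < alpha
    intro <- FALSE
    for (ref in unique(near$archaic_ref)) {
      nr <- near[near$archaic_ref == ref, , drop = FALSE]
      hit <- !is.na(nr$p_d) & nr$p_d < alpha &
        !is.na(nr$p_fd) & nr$p_fd < alpha &
        !is.na(nr$p_sstar) & nr$p_sstar < alpha
      if (any(hit)) intro <- TRUE
    }
    out$p_d <- pick(near$p_d)
    out$p_fd <- pick(near$p_fd)
    out$p_sstar <- pick(near$p_sstar)
    out$class <- if (sel && intro) "adaptive-introgressed"
    else if (sel) "selection-only"
    else if (intro) "introgression-only"
    else "none"
    out
  })
  do.call(rbind, res)
}
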