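# Catalog construction: merge per-sample SV calls into non-redundant loci,
# assign discovery categories, filter unreliable genotypes, and compute
# catalog-level statistics.

.svtypes <- c("DEL", "INS", "DUP", "INV", "TRA")

.checkCalls <- function(calls) {
  need <- c("sample", "chrom", "start", "end", "svtype", "length")
  if (!all(need %in% names(calls)))
    stop("calls need columns ", paste(need, collapse = ", "))
  if (!all(calls$svtype %in% .svtypes))
    stop("svtype must be one of ", paste(.svtypes, collapse = ", "))
  nonTra <- calls$svtype != "TRA"
  if (any(abs(calls$length[nonTra]) < 50))
    stop("non-TRA SVs must be >= 50 bp")
  if (!"support" %in% names(calls)) calls$support <- 1
  if (!"qual" %in% names(calls)) calls$qual <- 60
  if (!"genotype" %in% names(calls)) calls$genotype <- "0/1"
  calls
}

# single-linkage clustering of one (chrom, svtype) stratum, calls sorted by
# start; returns integer cluster labels
.clusterStratum <- function(start, second, len, maxDist, sizeSim, useLen) {
  n <- length(start)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (i in seq_len(n)) {
    j <- i + 1L
    while (j <= n && start[j] - start[i] <= maxDist) {
      ok <- abs(second[j] - second[i]) <= maxDist
      if (ok && useLen) {
        r <- min(len[i], len[j]) / max(len[i], len[j])
        ok <- r >= sizeSim
      }
      if (ok) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
      j <- j + 1L
    }
  }
  vapply(seq_len(n), find, integer(1))
}

#' Merge per-sample SV calls into a non-redundant catalog
#'
#' Calls of the same type on the same chromosome are clustered by single
#' linkage: two calls are linked when their start positions and their end
#' positions (insertions: start and length; translocations: both breakends,
#' no length test) lie within \code{maxDist} bp and their lengths agree
#' within \code{sizeSim} (min/max ratio).  Each cluster becomes one locus
#' whose representative is the member with the highest read support, ties
#' broken by smallest start.  Merging a merged catalog again is a no-op.
#'
#' @param callsets named list of per-sample call data.frames (columns
#'   sample, chrom, start, end, svtype, length, and optionally genotype,
#'   support, qual), or a single combined data.frame.
#' @param maxDist maximum breakpoint distance in bp (default 1000).
#' @param sizeSim minimum length-ratio similarity in (0, 1] (default 0.7).
#' @return an \linkS4class{SVCatalog}
#' @export
mergeCalls <- function(callsets, maxDist = 1000, sizeSim = 0.7) {
  stopifnot(maxDist > 0, sizeSim > 0, sizeSim <= 1)
  if (is.data.frame(callsets)) {
    nSamples <- length(unique(callsets$sample))
    calls <- callsets
  } else {
    if (!length(callsets)) stop("empty callsets")
    nSamples <- length(callsets)
    calls <- do.call(rbind, c(callsets, list(make.row.names = FALSE)))
  }
  calls <- .checkCalls(calls)
  pref <- startsWith(as.character(calls$chrom), "chr")
  if (length(unique(pref)) > 1)
    stop("mixed reference contig naming between samples")
  calls <- calls[order(calls$chrom, calls$svtype, calls$start,
                       calls$end, calls$sample), , drop = FALSE]
  rownames(calls) <- NULL
  strata <- interaction(calls$chrom, calls$svtype, drop = TRUE)
  calls$cluster <- NA_integer_
  offset <- 0L
  for (st in levels(strata)) {
    idx <- which(strata == st)
    sub <- calls[idx, ]
    useLen <- sub$svtype[1] != "TRA"
    second <- if (sub$svtype[1] == "INS") sub$length else sub$end
    cl <- .clusterStratum(sub$start, second, abs(sub$length),
                          maxDist, sizeSim, useLen)
    calls$cluster[idx] <- offset + as.integer(factor(cl))
    offset <- offset + length(unique(cl))
  }
  # representative per cluster: max support, then smallest start
  o <- order(calls$cluster, -calls$support, calls$start, calls$sample)
  firsts <- o[!duplicated(calls$cluster[o])]
  rep <- calls[firsts, ]
  carriers <- tapply(calls$sample, calls$cluster,
                     function(s) length(unique(s)))
  rep$n_carriers <- as.integer(carriers[as.character(rep$cluster)])
  o2 <- order(rep$chrom, rep$start, rep$end)
  rep <- rep[o2, ]
  rep$locus_id <- sprintf("SV%05d", seq_len(nrow(rep)))
  idMap <- setNames(rep$locus_id, rep$cluster)
  calls$locus_id <- idMap[as.character(calls$cluster)]
  calls$cluster <- NULL
  loci <- GRanges(rep$chrom, IRanges(rep$start, pmax(rep$start, rep$end)),
                  locus_id = rep$locus_id, svtype = rep$svtype,
                  svlen = rep$length, support = rep$support,
                  n_carriers = rep$n_carriers)
  new("SVCatalog", loci = loci, calls = calls,
      nSamples = as.integer(nSamples))
}

#' Assign discovery categories to catalog loci
#'
#' shared = identified in all samples; major = in at least half the samples
#' (and not shared); singleton = in exactly one; polymorphic = the rest.
#'
#' @param catalog an \linkS4class{SVCatalog}
#' @param nSamples cohort size (default: the catalog's own)
#' @return the catalog with a \code{category} mcol on its loci
#' @export
categorizeDiscovery <- function(catalog, nSamples = cohortSize(catalog)) {
  carriers <- mcols(catalog@loci)$n_carriers
  if (any(carriers > nSamples))
    stop("carrier count exceeds cohort size")
  category <- ifelse(carriers == nSamples, "shared",
              ifelse(carriers >= ceiling(nSamples / 2), "major",
              ifelse(carriers == 1, "singleton", "polymorphic")))
  mcols(catalog@loci)$category <- category
  catalog@nSamples <- as.integer(nSamples)
  catalog
}

#' Filter unreliable member genotypes by hard support/quality thresholds
#'
#' Member calls below the thresholds are removed (each removal logged with
#' its reason); loci left without any member are dropped and representative
#' statistics are recomputed from the surviving members.
#'
#' @param catalog an \linkS4class{SVCatalog}
#' @param minSupport minimum read support (calls with less are removed).
#' @param minQual minimum quality score.
#' @return list(catalog = filtered \linkS4class{SVCatalog},
#'   removed = data.frame(locus_id, sample, support, qual, reason))
#' @export
filterUnreliableGenotypes <- function(catalog, minSupport = 0,
                                      minQual = 0) {
  stopifnot(minSupport >= 0, minQual >= 0)
  calls <- catalog@calls
  lowS <- calls$support < minSupport
  lowQ <- calls$qual < minQual
  bad <- lowS | lowQ
  removed <- data.frame(
    locus_id = calls$locus_id[bad], sample = calls$sample[bad],
    support = calls$support[bad], qual = calls$qual[bad],
    reason = ifelse(lowS[bad] & lowQ[bad], "support+qual",
                    ifelse(lowS[bad], "support", "qual")))
  keep <- calls[!bad, , drop = FALSE]
  if (!nrow(keep)) {
    empty <- new("SVCatalog", loci = catalog@loci[0], calls = keep,
                 nSamples = catalog@nSamples)
    return(list(catalog = empty, removed = removed))
  }
  # recompute per-locus representative and carriers from survivors
  o <- order(keep$locus_id, -keep$support, keep$start, keep$sample)
  firsts <- o[!duplicated(keep$locus_id[o])]
  rep <- keep[firsts, ]
  carriers <- tapply(keep$sample, keep$locus_id,
                     function(s) length(unique(s)))
  rep$n_carriers <- as.integer(carriers[rep$locus_id])
  o2 <- order(rep$chrom, rep$start, rep$end)
  rep <- rep[o2, ]
  loci <- GRanges(rep$chrom, IRanges(rep$start, pmax(rep$start, rep$end)),
                  locus_id = rep$locus_id, svtype = rep$svtype,
                  svlen = rep$length, support = rep$support,
                  n_carriers = rep$n_carriers)
  oldMc <- mcols(catalog@loci)
  if ("category" %in% names(oldMc)) {
    cat0 <- setNames(oldMc$category, oldMc$locus_id)
    mcols(loci)$category <- cat0[mcols(loci)$locus_id]
  }
  list(catalog = new("SVCatalog", loci = loci, calls = keep,
                     nSamples = catalog@nSamples),
       removed = removed)
}

#' Proportion of loci with concordant member breakpoints
#'
#' A locus is concordant when the spans of its members' start positions and
#' end positions both fit within \code{interval} bp.  Monotone
#' non-decreasing in \code{interval}; single-call loci always count.
#'
#' @param catalog an \linkS4class{SVCatalog}
#' @param interval concordance interval in bp (> 0)
#' @return proportion in [0, 1]
#' @export
breakpointConcordance <- function(catalog, interval = 100) {
  stopifnot(interval > 0)
  calls <- catalog@calls
  if (!nrow(calls)) return(NA_real_)
  spanS <- tapply(calls$start, calls$locus_id,
                  function(x) max(x) - min(x))
  spanE <- tapply(calls$end, calls$locus_id,
                  function(x) max(x) - min(x))
  mean(spanS <= interval & spanE <= interval)
}

#' Compare a catalog against external callsets: novelty and maximum AF
#'
#' Match rule: same svtype and, for DEL/DUP/INV, at least 50% reciprocal
#' overlap; for INS (and TRA), breakpoint within \code{insDist} bp and, for
#' INS, lengths within 50% of each other.  A locus with no match in any
#' external set is novel; otherwise the maximum external allele frequency
#' over its matches is reported.
#'
#' @param catalog an \linkS4class{SVCatalog}
#' @param external a data.frame (chrom, start, end, svtype, length, af) or a
#'   list of such data.frames.
#' @param recipOverlap minimum reciprocal overlap for DEL/DUP/INV.
#' @param insDist breakpoint distance for INS/TRA matching, bp.
#' @param lenSim minimum INS length-ratio similarity.
#' @return data.frame(locus_id, novel, max_external_af); the number of
#'   malformed external records skipped is attached as attribute
#'   \code{"skipped"} (with a warning when non-zero).
#' @export
compareCallsets <- function(catalog, external, recipOverlap = 0.5,
                            insDist = 1000, lenSim = 0.5) {
  if (is.data.frame(external)) external <- list(external)
  ext <- if (length(external))
    do.call(rbind, c(external, list(make.row.names = FALSE)))
    else data.frame(chrom = character(), start = numeric(),
                    end = numeric(), svtype = character(),
                    length = numeric(), af = numeric())
  if (!"af" %in% names(ext)) ext$af <- NA_real_
  malformed <- is.na(ext$chrom) | is.na(ext$start) | is.na(ext$svtype) |
    (!is.na(ext$end) & ext$end < ext$start & ext$svtype != "INS")
  if (any(malformed))
    warning(sum(malformed), " malformed external records skipped")
  ext <- ext[!malformed, , drop = FALSE]
  loci <- catalog@loci
  mc <- mcols(loci)
  maxAF <- rep(NA_real_, length(loci))
  novel <- rep(TRUE, length(loci))
  if (nrow(ext) && length(loci)) {
    extGR <- GRanges(ext$chrom, IRanges(ext$start, pmax(ext$start, ext$end)))
    hits <- GenomicRanges::findOverlaps(loci, extGR, maxgap = insDist)
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    sameType <- as.character(mc$svtype[qi]) == ext$svtype[si]
    ovl <- pmax(0, pmin(end(loci)[qi], end(extGR)[si]) -
                  pmax(start(loci)[qi], start(extGR)[si]) + 1)
    wQ <- GenomicRanges::width(loci)[qi]
    wS <- GenomicRanges::width(extGR)[si]
    isIns <- as.character(mc$svtype[qi]) %in% c("INS", "TRA")
    recip <- ovl >= recipOverlap * wQ & ovl >= recipOverlap * wS
    bpClose <- abs(GenomicRanges::start(loci)[qi] - ext$start[si]) <= insDist
    lenOK <- ifelse(as.character(mc$svtype[qi]) == "INS",
                    pmin(abs(mc$svlen[qi]), abs(ext$length[si])) /
                      pmax(abs(mc$svlen[qi]), abs(ext$length[si])) >= lenSim,
                    TRUE)
    match <- sameType & ifelse(isIns, bpClose & lenOK, recip)
    if (any(match)) {
      qm <- qi[match]
      novel[unique(qm)] <- FALSE
      afs <- tapply(ext$af[si[match]], qm, function(a)
        if (all(is.na(a))) NA_real_ else max(a, na.rm = TRUE))
      maxAF[as.integer(names(afs))] <- as.numeric(afs)
    }
  }
  out <- data.frame(locus_id = mc$locus_id, novel = novel,
                    max_external_af = maxAF)
  attr(out, "skipped") <- sum(malformed)
  out
}

#' SV density fold-change in chromosome-arm tails, with permutation p
#'
#' Compares SV density (loci per bp, by start position) in the terminal
#' \code{tail} bp of each chromosome arm against the rest of the arms
#' (centromeres excluded), against a null of uniform repositioning of loci
#' within their chromosomes.
#'
#' @param catalog an \linkS4class{SVCatalog}
#' @param chromInfo data.frame(chrom, length, cen_start, cen_end); rows with
#'   missing centromere coordinates are excluded with a warning.
#' @param tail arm-tail size in bp (default 5 Mb).
#' @param nPerm number of permutations (>= 100).
#' @param seed integer seed.
#' @return list(fc = observed fold change, p = permutation p-value,
#'   perm = permuted fold changes)
#' @export
armTailDensity <- function(catalog, chromInfo, tail = 5e6, nPerm = 1000,
                           seed = 1) {
  stopifnot(nPerm >= 100, tail > 0)
  miss <- is.na(chromInfo$cen_start) | is.na(chromInfo$cen_end)
  if (any(miss)) {
    warning("excluding chromosome(s) without centromere: ",
            paste(chromInfo$chrom[miss], collapse = ", "))
    chromInfo <- chromInfo[!miss, , drop = FALSE]
  }
  loci <- catalog@loci
  keep <- as.character(seqnames(loci)) %in% chromInfo$chrom
  pos <- start(loci)[keep]
  chr <- as.character(seqnames(loci))[keep]
  info <- chromInfo
  # per chromosome: tail regions are the distal `tail` bp of each arm
  inTail <- function(p, ci) {
    pTail <- pmin(tail, ci$cen_start - 1)
    qTail <- pmin(tail, ci$length - ci$cen_end)
    (p <= pTail) | (p > ci$length - qTail & p <= ci$length)
  }
  armBp <- sum(info$cen_start - 1) + sum(info$length - info$cen_end)
  tailBp <- sum(pmin(tail, info$cen_start - 1)) +
    sum(pmin(tail, info$length - info$cen_end))
  fcOf <- function(p, chr) {
    nt <- 0L; tot <- 0L
    for (i in seq_len(nrow(info))) {
      ci <- info[i, ]
      pp <- p[chr == ci$chrom]
      inArm <- pp < ci$cen_start | pp > ci$cen_end
      pp <- pp[inArm]
      nt <- nt + sum(inTail(pp, ci))
      tot <- tot + length(pp)
    }
    dTail <- nt / tailBp
    dRest <- (tot - nt) / (armBp - tailBp)
    if (dRest == 0) Inf else dTail / dRest
  }
  obs <- fcOf(pos, chr)
  lenOf <- setNames(info$length, info$chrom)
  perm <- .withSeed(seed, vapply(seq_len(nPerm), function(b) {
    p2 <- floor(stats::runif(length(pos), 1, lenOf[chr] + 1))
    fcOf(p2, chr)
  }, numeric(1)))
  list(fc = obs, p = .empP(sum(perm >= obs), nPerm), perm = perm)
}
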