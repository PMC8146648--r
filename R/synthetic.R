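# Synthetic-data generators beyond the coalescent backend: sweep
# implantation, per-sample SV callsets with realistic call noise, and
# annotation tracks with SINE-like (~300 bp) and LINE-like (~6 kb) length
# classes.

#' Implant a partial selective sweep into a haplotype matrix
#'
#' A cheap, deterministic stand-in for a selective sweep used to give the
#' haplotype statistics something to detect: a fraction of the haplotypes
#' carrying the derived allele at \code{focalSite} are replaced by
#' recombined copies of one template carrier.  Per copied haplotype, the
#' copied segment extends from the focal site outward to an exponentially
#' distributed breakpoint on each side (mean \code{decayScale} bp), so break
#' probability increases with distance, mimicking haplotype decay.
#'
#' @param haps a \linkS4class{HaplotypeMatrix}.
#' @param focalSite column index of the (segregating) core site.
#' @param carrierFraction fraction of derived-allele carriers to overwrite,
#'   in (0, 1].
#' @param decayScale mean copied-segment length per side, bp (Inf = copy
#'   whole haplotypes).
#' @param seed integer seed.
#' @return list(haps = modified HaplotypeMatrix, truth = TruthSet whose
#'   \code{sweep} records the focal site, template and overwritten rows).
#' @export
implantSweep <- function(haps, focalSite, carrierFraction, decayScale,
                         seed) {
  stopifnot(carrierFraction > 0, carrierFraction <= 1, decayScale >= 0)
  m <- hapMatrix(haps)
  if (focalSite < 1 || focalSite > ncol(m)) stop("focal site out of range")
  col <- m[, focalSite]
  if (min(col) == max(col)) stop("focal site is monomorphic")
  carriers <- which(col == 1L)
  pos <- positions(haps)
  .withSeed(seed, {
    template <- carriers[sample.int(length(carriers), 1L)]
    others <- setdiff(carriers, template)
    nCopy <- round(carrierFraction * length(carriers))
    copyRows <- if (nCopy >= length(carriers)) others
      else if (nCopy <= 1) integer()
      else others[sample.int(length(others), nCopy - 1L)]
    for (r in copyRows) {
      dl <- if (is.finite(decayScale) && decayScale > 0)
        stats::rexp(1, 1 / decayScale) else if (decayScale == 0) 0 else Inf
      dr <- if (is.finite(decayScale) && decayScale > 0)
        stats::rexp(1, 1 / decayScale) else if (decayScale == 0) 0 else Inf
      seg <- which(pos >= pos[focalSite] - dl & pos <= pos[focalSite] + dr)
      m[r, seg] <- m[template, seg]
    }
    out <- HaplotypeMatrix(m, pos, genPos = genPositions(haps),
                           samples = sampleIds(haps),
                           populations = popLabels(haps))
    truth <- TruthSet(
      sweep = list(focalSite = focalSite, focalPos = pos[focalSite],
                   carrierFraction = carrierFraction,
                   decayScale = decayScale, template = template,
                   copied = copyRows),
      seed = seed)
    list(haps = out, truth = truth)
  })
}

#' Generate a set of true SV loci to plant in a synthetic genome
#'
#' Lengths follow the characteristic bimodal SV length spectrum: an Alu-like
#' mode near 300 bp, an L1-like mode near 6 kb, and a broad log-uniform
#' background, truncated below at 50 bp.  Loci are spaced at least
#' \code{minGap} apart so that merging fidelity can be scored against truth.
#'
#' @param n number of loci.
#' @param genomeLength genome length in bp.
#' @param seed integer seed.
#' @param chrom chromosome name.
#' @param typeProbs named probabilities over c(DEL, INS, DUP, INV).
#' @param minGap minimum start-to-start spacing between loci, bp.
#' @return data.frame(chrom, start, end, svtype, length, af)
#' @export
generateTruthSVs <- function(n, genomeLength, seed, chrom = "chr1",
                             typeProbs = c(DEL = 0.5, INS = 0.42,
                                           DUP = 0.05, INV = 0.03),
                             minGap = 5000) {
  .withSeed(seed, {
    mode <- sample(c("alu", "line", "bg"), n, replace = TRUE,
                   prob = c(0.35, 0.12, 0.53))
    len <- numeric(n)
    len[mode == "alu"] <- round(stats::rnorm(sum(mode == "alu"), 300, 30))
    len[mode == "line"] <- round(stats::rnorm(sum(mode == "line"), 6000, 600))
    nbg <- sum(mode == "bg")
    len[mode == "bg"] <- round(exp(stats::runif(nbg, log(50), log(8000))))
    len <- pmax(len, 50)
    svtype <- sample(names(typeProbs), n, replace = TRUE, prob = typeProbs)
    # sequential placement with random slack keeps loci >= minGap apart
    slack <- genomeLength - sum(len) - n * minGap
    if (slack <= 0)
      stop("genome too short for ", n, " loci at minGap ", minGap)
    extra <- stats::runif(n + 1)
    extra <- floor(extra / sum(extra) * slack)
    start <- cumsum(c(1, len[-n] + minGap)) + cumsum(extra[-(n + 1)])
    end <- ifelse(svtype == "INS", start, start + len - 1)
    af <- round(stats::rbeta(n, 0.8, 1.6), 3)
    af <- pmin(pmax(af, 0.05), 0.95)
    data.frame(chrom = chrom, start = start, end = end, svtype = svtype,
               length = len, af = af)
  })
}

#' Generate per-sample SV callsets from truth loci
#'
#' Emulates long-read discovery noise: per-locus carriers are drawn from the
#' truth allele frequency (diploid carrier probability 1-(1-af)^2, at least
#' one carrier forced), each call's breakpoints are truth plus a Gaussian
#' positional shift common to both ends (rounded, clipped at 1; insertions
#' additionally get Gaussian length jitter), dropout silently removes calls
#' from carriers, and genotype error flips carrier status in either
#' direction.
#'
#' @param truthSVs data.frame as returned by [generateTruthSVs()].
#' @param nSamples cohort size.
#' @param jitterSd Gaussian breakpoint jitter sd, bp (>= 0).
#' @param genotypeError probability of flipping a sample's carrier status.
#' @param dropout probability a true carrier's call is dropped.
#' @param seed integer seed.
#' @param meanSupport mean read support of emitted calls (Poisson).
#' @return list(callsets = named list of per-sample call data.frames,
#'   truth = \linkS4class{TruthSet} carrying the truth loci and the realised
#'   carrier matrix)
#' @export
generateSVCallsets <- function(truthSVs, nSamples, jitterSd = 20,
                               genotypeError = 0, dropout = 0, seed = 1,
                               meanSupport = 10) {
  stopifnot(jitterSd >= 0, genotypeError >= 0, genotypeError <= 1,
            dropout >= 0, dropout <= 1)
  nl <- nrow(truthSVs)
  .withSeed(seed, {
    pCarrier <- 1 - (1 - truthSVs$af)^2
    carrier <- matrix(stats::runif(nl * nSamples) <
                        rep(pCarrier, nSamples), nl, nSamples)
    none <- rowSums(carrier) == 0
    carrier[none, 1] <- TRUE          # every truth locus has >= 1 carrier
    called <- carrier
    if (genotypeError > 0) {
      flip <- matrix(stats::runif(nl * nSamples) < genotypeError,
                     nl, nSamples)
      called <- xor(called, flip)
    }
    if (dropout > 0) {
      drop <- matrix(stats::runif(nl * nSamples) < dropout, nl, nSamples)
      called <- called & !drop
    }
    sampleIds <- sprintf("sample%02d", seq_len(nSamples))
    callsets <- lapply(seq_len(nSamples), function(s) {
      idx <- which(called[, s])
      if (!length(idx))
        return(data.frame(sample = character(), chrom = character(),
                          start = numeric(), end = numeric(),
                          svtype = character(), length = numeric(),
                          genotype = character(), support = numeric(),
                          qual = numeric()))
      ns <- length(idx)
      # per-call positional shift moves both breakpoints together (the
      # dominant long-read error mode: events slide in repeats while the
      # called length stays consistent); insertions get length jitter too
      shift <- round(stats::rnorm(ns, 0, jitterSd))
      start <- pmax(1, truthSVs$start[idx] + shift)
      ins <- truthSVs$svtype[idx] == "INS"
      lenJit <- round(stats::rnorm(ns, 0, jitterSd))
      len <- pmax(50, truthSVs$length[idx] + ifelse(ins, lenJit, 0))
      end <- ifelse(ins, start, start + len - 1)
      data.frame(sample = sampleIds[s], chrom = truthSVs$chrom[idx],
                 start = start, end = end, svtype = truthSVs$svtype[idx],
                 length = len, genotype = "0/1",
                 support = stats::rpois(ns, meanSupport) + 1L,
                 qual = round(stats::runif(ns, 20, 60)))
    })
    names(callsets) <- sampleIds
    truth <- TruthSet(svLoci = cbind(truthSVs,
                                     n_carriers = rowSums(carrier)),
                      seed = seed)
    list(callsets = callsets, truth = truth, carrier = carrier)
  })
}

.drawIntervals <- function(nElem, genomeLength, meanLen, sdLen, minLen = 30) {
  if (nElem == 0)
    return(data.frame(start = numeric(), end = numeric()))
  len <- pmax(minLen, round(stats::rnorm(nElem, meanLen, sdLen)))
  if (genomeLength < max(len))
    stop("genome length shorter than largest element (", max(len), " bp)")
  start <- floor(stats::runif(nElem, 1, genomeLength - len + 1))
  data.frame(start = start, end = start + len - 1)
}

#' Generate synthetic annotation tracks
#'
#' Produces the interval tracks the annotation stage consumes: interspersed
#' repeats with SINE-like (~300 bp), LINE-like (~6 kb), LTR and DNA classes,
#' tandem repeats, segmental duplications, gene models (TSS/exons/introns),
#' a 15-state chromatin tiling, CTCF clusters, TAD boundaries and intra-
#' chromosomal loop-anchor pairs.  All intervals are 1-based inclusive on a
#' single synthetic chromosome.
#'
#' @param genomeLength genome length in bp.
#' @param seed integer seed.
#' @param densities named per-Mb element counts; any subset of SINE, LINE,
#'   LTR, DNA, TR, SEGDUP, GENE, CTCF, TAD, LOOP can be overridden.
#' @param chrom chromosome name.
#' @return list with elements \code{repeats} (GRanges, mcols \code{class}),
#'   \code{tandem} (GRanges), \code{segdup} (GRanges), \code{genes} (list of
#'   GRanges: genes, exons, introns, tss), \code{chromatin} (GRanges, mcols
#'   \code{state}), \code{ctcf} (GRanges), \code{tad} (GRanges),
#'   \code{loops} (data.frame chrom, start1, end1, start2, end2)
#' @export
generateTracks <- function(genomeLength, seed,
                           densities = c(SINE = 400, LINE = 60, LTR = 50,
                                         DNA = 30, TR = 100, SEGDUP = 5,
                                         GENE = 10, CTCF = 50, TAD = 2,
                                         LOOP = 10),
                           chrom = "chr1") {
  defaults <- c(SINE = 400, LINE = 60, LTR = 50, DNA = 30, TR = 100,
                SEGDUP = 5, GENE = 10, CTCF = 50, TAD = 2, LOOP = 10)
  defaults[names(densities)] <- densities
  densities <- defaults
  if (any(densities < 0)) stop("densities must be non-negative")
  mb <- genomeLength / 1e6
  cnt <- function(key) stats::rpois(1, densities[[key]] * mb)
  gr <- function(df, ...) {
    if (!nrow(df)) return(GRanges())
    GRanges(chrom, IRanges(df$start, df$end), ...)
  }
  .withSeed(seed, {
    repSpec <- list(SINE = c(300, 50), LINE = c(6000, 1500),
                    LTR = c(1500, 500), DNA = c(800, 300))
    repList <- lapply(names(repSpec), function(cl) {
      d <- .drawIntervals(cnt(cl), genomeLength, repSpec[[cl]][1],
                          repSpec[[cl]][2])
      if (nrow(d)) d$class <- cl
      d
    })
    repDf <- do.call(rbind, repList[vapply(repList, nrow, 1L) > 0])
    repeats <- if (!is.null(repDf) && nrow(repDf)) {
      o <- order(repDf$start)
      GRanges(chrom, IRanges(repDf$start[o], repDf$end[o]),
              class = repDf$class[o])
    } else GRanges()
    tandem <- gr(.drawIntervals(cnt("TR"), genomeLength, 500, 300, 50))
    segdup <- gr(.drawIntervals(cnt("SEGDUP"), genomeLength, 20000, 5000,
                                1000))
    # gene models: non-overlapping gene bodies with exon/intron structure
    nGene <- cnt("GENE")
    geneLen <- pmax(2000, round(stats::rnorm(nGene, 20000, 8000)))
    slot <- genomeLength / max(nGene, 1)
    geneStart <- round((seq_len(nGene) - 1) * slot +
                         stats::runif(nGene, 1, pmax(2, slot - geneLen)))
    geneEnd <- pmin(geneStart + geneLen - 1, genomeLength)
    exons <- NULL
    if (nGene) {
      exList <- lapply(seq_len(nGene), function(g) {
        nEx <- sample(3:8, 1)
        bnd <- sort(stats::runif(nEx - 1, geneStart[g], geneEnd[g]))
        exStart <- round(c(geneStart[g], bnd))
        exEnd <- pmin(exStart + pmax(80, round(stats::rnorm(nEx, 150, 40))),
                      geneEnd[g])
        ok <- exStart <= exEnd
        data.frame(start = exStart[ok], end = exEnd[ok],
                   gene = sprintf("gene%03d", g))
      })
      exons <- do.call(rbind, exList)
    }
    genesGR <- if (nGene)
      GRanges(chrom, IRanges(geneStart, geneEnd),
              gene = sprintf("gene%03d", seq_len(nGene))) else GRanges()
    exonsGR <- if (!is.null(exons) && nrow(exons))
      GRanges(chrom, IRanges(exons$start, exons$end), gene = exons$gene)
      else GRanges()
    intronsGR <- if (length(genesGR))
      GenomicRanges::setdiff(genesGR, exonsGR) else GRanges()
    tssGR <- if (nGene)
      GRanges(chrom, IRanges(geneStart, geneStart),
              gene = sprintf("gene%03d", seq_len(nGene))) else GRanges()
    # chromatin: contiguous tiling with 15 states
    nTile <- max(1, round(genomeLength / 2000))
    bnd <- sort(sample.int(genomeLength - 1, min(nTile, genomeLength - 1)))
    tileStart <- c(1, bnd + 1)
    tileEnd <- c(bnd, genomeLength)
    states <- paste0("E", sample.int(15, length(tileStart), replace = TRUE))
    chromatin <- GRanges(chrom, IRanges(tileStart, tileEnd), state = states)
    ctcf <- gr(.drawIntervals(cnt("CTCF"), genomeLength, 200, 50, 50))
    tad <- gr(.drawIntervals(cnt("TAD"), genomeLength, 10000, 2000, 1000))
    nLoop <- cnt("LOOP")
    loops <- if (nLoop) {
      a1 <- .drawIntervals(nLoop, genomeLength - 60000, 5000, 1000, 1000)
      gap <- round(stats::runif(nLoop, 50000, 500000))
      s2 <- pmin(a1$end + gap, genomeLength - 6000)
      data.frame(chrom = chrom, start1 = a1$start, end1 = a1$end,
                 start2 = s2, end2 = pmin(s2 + 5000, genomeLength))
    } else data.frame(chrom = character(), start1 = numeric(),
                      end1 = numeric(), start2 = numeric(),
                      end2 = numeric())
    list(repeats = repeats, tandem = tandem, segdup = segdup,
         genes = list(genes = genesGR, exons = exonsGR,
                      introns = intronsGR, tss = tssGR),
         chromatin = chromatin, ctcf = ctcf, tad = tad, loops = loops)
  })
}

#' Generate a population-structured SV genotype matrix
#'
#' Emulates short-read graph genotyping of the truth SV loci across a
#' multi-population panel: per-locus population allele frequencies start at
#' the truth AF, a chosen subset of loci gets a population-stratified shift
#' in the focal population, genotypes are drawn under Hardy-Weinberg
#' proportions within each population, and genotypes are masked at random
#' to emulate the genotyping missing rate.
#'
#' @param truthSVs data.frame from [generateTruthSVs()].
#' @param nPerPop named vector of diploid sample counts per population.
#' @param seed integer seed.
#' @param missRate per-genotype missing probability.
#' @param stratified integer indices of loci made population-stratified.
#' @param deltaAF allele-frequency shift applied to stratified loci in
#'   \code{focalPop}.
#' @param focalPop population receiving the shift (default first of
#'   \code{nPerPop}).
#' @param datasets number of source datasets the samples are spread over.
#' @return a \linkS4class{GenotypeMatrix}
#' @export
generateGenotypeMatrix <- function(truthSVs, nPerPop, seed,
                                   missRate = 0.02,
                                   stratified = integer(),
                                   deltaAF = 0.4,
                                   focalPop = names(nPerPop)[1],
                                   datasets = 2) {
  nl <- nrow(truthSVs)
  pops <- names(nPerPop)
  .withSeed(seed, {
    panel <- data.frame(
      sample = sprintf("%s_%03d", rep(pops, nPerPop),
                       unlist(lapply(nPerPop, seq_len))),
      population = rep(pops, nPerPop),
      dataset = paste0("ds", 1 +
                         (unlist(lapply(nPerPop, seq_len)) %% datasets)))
    af <- matrix(rep(truthSVs$af, length(pops)), nl, length(pops),
                 dimnames = list(NULL, pops))
    if (length(stratified)) {
      shifted <- pmin(0.98, af[stratified, focalPop] + deltaAF)
      af[stratified, focalPop] <- shifted
    }
    g <- matrix(NA_integer_, nl, nrow(panel))
    for (pop in pops) {
      cols <- which(panel$population == pop)
      g[, cols] <- stats::rbinom(nl * length(cols), 2, rep(af[, pop],
                                                           length(cols)))
    }
    mask <- matrix(stats::runif(length(g)) < missRate, nl, ncol(g))
    g[mask] <- NA_integer_
    loci <- GRanges(truthSVs$chrom,
                    IRanges(truthSVs$start,
                            pmax(truthSVs$start, truthSVs$end)),
                    locus_id = sprintf("SV%05d", seq_len(nl)),
                    svtype = truthSVs$svtype, svlen = truthSVs$length)
    GenotypeMatrix(g, loci, panel)
  })
}
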