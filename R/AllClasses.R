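#' @import methods
#' @importFrom GenomicRanges GRanges seqnames start end width mcols mcols<-
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors DataFrame
NULL

#' DemographicModel: a population tree with sizes, splits and migration
#'
#' Describes the demographic history used by the coalescent simulator: a set
#' of populations (extant and ancestral) with diploid effective sizes, a
#' sequence of pairwise splits (in generations before present), a single
#' symmetric migration rate among extant modern populations, per-generation
#' mutation and recombination rates, and an optional archaic branch
#' delivering a single admixture pulse into a named recipient.
#'
#' @slot populations data.frame with columns \code{name}, \code{size}
#'   (diploid Ne) and \code{extant} (logical; sampled populations).
#' @slot splits data.frame with columns \code{time} (generations),
#'   \code{derived1}, \code{derived2}, \code{ancestral}; each row merges two
#'   lineages into an ancestral population, ordered by time.
#' @slot migration symmetric per-generation migration rate among extant
#'   modern (non-archaic) populations.
#' @slot mutationRate per-bp per-generation mutation rate.
#' @slot recombinationRate per-bp per-generation recombination rate.
#' @slot generationTime years per generation (used only to convert the
#'   years quoted in the literature into generations).
#' @slot archaic either \code{NULL} or a list with elements \code{name}
#'   (population carrying the archaic lineage), \code{pulseTime}
#'   (generations), \code{pulseFrac} (admixture proportion in [0,1]) and
#'   \code{recipient} (extant population receiving the pulse).
#'
#' @seealso [tibHanAfrModel()], [tibHanNorthSouthModel()], [simulateNeutral()]
#' @export
setClass("DemographicModel", representation(
  populations = "data.frame",
  splits = "data.frame",
  migration = "numeric",
  mutationRate = "numeric",
  recombinationRate = "numeric",
  generationTime = "numeric",
  archaic = "ANY"
))

setValidity("DemographicModel", function(object) {
  msg <- character()
  p <- object@populations
  s <- object@splits
  if (!all(c("name", "size", "extant") %in% names(p)))
    msg <- c(msg, "populations must have columns name, size, extant")
  else {
    if (any(p$size <= 0)) msg <- c(msg, "all population sizes must be > 0")
    if (anyDuplicated(p$name)) msg <- c(msg, "population names must be unique")
  }
  if (nrow(s)) {
    if (!all(c("time", "derived1", "derived2", "ancestral") %in% names(s)))
      msg <- c(msg, "splits must have columns time, derived1, derived2, ancestral")
    else {
      if (is.unsorted(s$time, strictly = TRUE))
        msg <- c(msg, "split times must be strictly increasing")
      known <- p$name
      refs <- c(s$derived1, s$derived2, s$ancestral)
      if (!all(refs %in% known))
        msg <- c(msg, "split refers to unknown population")
      # each lineage may be merged away at most once
      merged <- c(s$derived1, s$derived2)
      if (anyDuplicated(merged))
        msg <- c(msg, "a population is merged away more than once")
    }
  }
  a <- object@archaic
  if (!is.null(a)) {
    need <- c("name", "pulseTime", "pulseFrac", "recipient")
    if (!all(need %in% names(a)))
      msg <- c(msg, "archaic must have name, pulseTime, pulseFrac, recipient")
    else {
      if (a$pulseFrac < 0 || a$pulseFrac > 1)
        msg <- c(msg, "pulse fraction must lie in [0, 1]")
      div <- archaicDivergence(object)
      if (!is.na(div) && a$pulseTime >= div)
        msg <- c(msg, "pulse time must precede the archaic divergence time")
    }
  }
  if (length(object@migration) != 1 || object@migration < 0)
    msg <- c(msg, "migration must be a single non-negative rate")
  if (object@mutationRate < 0 || object@recombinationRate < 0)
    msg <- c(msg, "rates must be non-negative")
  if (object@generationTime <= 0)
    msg <- c(msg, "generation time must be positive")
  if (length(msg)) msg else TRUE
})

#' HaplotypeMatrix: phased binary SNV haplotypes
#'
#' Phased, biallelic SNV haplotypes with ancestral/derived polarity: rows are
#' haplotypes (two per diploid sample), columns are segregating sites coded 0
#' (ancestral) / 1 (derived).  Physical positions are 1-based bp, genetic
#' positions are cM.
#'
#' @slot haps integer matrix of 0/1 alleles, haplotypes x sites.
#' @slot positions numeric, strictly increasing physical positions (bp).
#' @slot genPos numeric genetic positions (cM), same length as positions.
#' @slot samples character, sample id per haplotype (each id appears twice).
#' @slot populations character, population label per haplotype.
#'
#' @export
setClass("HaplotypeMatrix", representation(
  haps = "matrix",
  positions = "numeric",
  genPos = "numeric",
  samples = "character",
  populations = "character"
))

setValidity("HaplotypeMatrix", function(object) {
  msg <- character()
  h <- object@haps
  if (ncol(h) != length(object@positions))
    msg <- c(msg, "ncol(haps) must equal length(positions)")
  if (length(object@genPos) != length(object@positions))
    msg <- c(msg, "genPos and positions lengths differ")
  if (nrow(h) != length(object@samples) ||
      nrow(h) != length(object@populations))
    msg <- c(msg, "one sample id and population label per haplotype required")
  if (ncol(h) > 1 && is.unsorted(object@positions, strictly = TRUE))
    msg <- c(msg, "positions must be strictly increasing")
  if (length(h) && !all(h %in% c(0L, 1L)))
    msg <- c(msg, "alleles must be 0 (ancestral) or 1 (derived)")
  if (nrow(h)) {
    tab <- table(object@samples)
    if (!all(tab == 2L))
      msg <- c(msg, "each diploid sample must contribute exactly 2 haplotypes")
  }
  if (length(msg)) msg else TRUE
})

#' TruthSet: ground truth emitted by the synthetic-data generators
#'
#' Records what the generator actually planted so downstream recovery can be
#' scored: true SV loci, introgressed tract intervals per haplotype, the
#' sweep focal site (if any), and the seed used.
#'
#' @slot svLoci data.frame of true SV loci (chrom, start, end, svtype,
#'   length, af) or a 0-row data.frame.
#' @slot tracts data.frame of introgressed tracts (hap, start, end),
#'   1-based inclusive bp, or 0-row.
#' @slot sweep list describing an implanted sweep (focalSite, focalPos,
#'   carrierFraction, decayScale) or empty list.
#' @slot seed integer seed used by the generator.
#' @export
setClass("TruthSet", representation(
  svLoci = "data.frame",
  tracts = "data.frame",
  sweep = "list",
  seed = "integer"
))

setValidity("TruthSet", function(object) {
  msg <- character()
  tr <- object@tracts
  if (nrow(tr) && !all(c("hap", "start", "end") %in% names(tr)))
    msg <- c(msg, "tracts must have columns hap, start, end")
  if (nrow(tr) && any(tr$end < tr$start))
    msg <- c(msg, "tract end must be >= start")
  if (length(msg)) msg else TRUE
})

#' GenotypeMatrix: SV-by-sample diploid genotypes
#'
#' Diploid genotypes for SV loci genotyped from short reads: 0, 1, 2 copies
#' of the alternate allele or NA (missing), with a sample panel mapping each
#' sample to a population and a source dataset.
#'
#' @slot geno integer matrix loci x samples with values 0/1/2/NA.
#' @slot loci GRanges of the loci, mcols carrying at least \code{locus_id}
#'   and \code{svtype}.
#' @slot panel data.frame with columns \code{sample}, \code{population},
#'   \code{dataset}; rownames irrelevant, one row per sample (column order
#'   of \code{geno}).
#' @export
setClass("GenotypeMatrix", representation(
  geno = "matrix",
  loci = "GRanges",
  panel = "data.frame"
))

setValidity("GenotypeMatrix", function(object) {
  msg <- character()
  g <- object@geno
  if (nrow(g) != length(object@loci))
    msg <- c(msg, "nrow(geno) must equal length(loci)")
  if (ncol(g) != nrow(object@panel))
    msg <- c(msg, "ncol(geno) must equal nrow(panel)")
  if (!all(c("sample", "population", "dataset") %in% names(object@panel)))
    msg <- c(msg, "panel needs columns sample, population, dataset")
  vals <- g[!is.na(g)]
  if (length(vals) && !all(vals %in% 0:2))
    msg <- c(msg, "genotypes must be 0, 1, 2 or NA")
  if (length(msg)) msg else TRUE
})

#' SVCatalog: a non-redundant catalog of SV loci with member calls
#'
#' The merged catalog: one representative interval per locus plus the member
#' calls it was built from, the carrier samples, and a discovery category.
#'
#' @slot loci GRanges of representative intervals; mcols: \code{locus_id},
#'   \code{svtype}, \code{svlen}, \code{support}, \code{n_carriers} and
#'   (after [categorizeDiscovery()]) \code{category}.
#' @slot calls data.frame of member calls with a \code{locus_id} column
#'   linking each call to its locus.
#' @slot nSamples integer, cohort size the catalog was discovered in.
#' @export
setClass("SVCatalog", representation(
  loci = "GRanges",
  calls = "data.frame",
  nSamples = "integer"
))

setValidity("SVCatalog", function(object) {
  msg <- character()
  mc <- mcols(object@loci)
  need <- c("locus_id", "svtype", "svlen", "support", "n_carriers")
  if (!all(need %in% names(mc)))
    msg <- c(msg, paste("loci mcols must contain",
                        paste(need, collapse = ", ")))
  if (nrow(object@calls) &&
      !all(c("locus_id", "sample", "svtype") %in% names(object@calls)))
    msg <- c(msg, "calls must have locus_id, sample, svtype columns")
  if (nrow(object@calls) && all(c("locus_id", "svtype") %in% names(object@calls)) &&
      "locus_id" %in% names(mc)) {
    type_of <- setNames(as.character(mc$svtype), mc$locus_id)
    bad <- object@calls$svtype != type_of[as.character(object@calls$locus_id)]
    if (any(bad, na.rm = TRUE))
      msg <- c(msg, "member call svtype differs from its locus svtype")
  }
  if (length(msg)) msg else TRUE
})
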