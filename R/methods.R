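# Accessors, show methods, constructors for the core classes.

#' Construct a HaplotypeMatrix
#'
#' @param haps 0/1 matrix, haplotypes in rows, sites in columns.
#' @param positions physical positions in bp (1-based, strictly increasing).
#' @param genPos genetic positions in cM; defaults to a uniform map derived
#'   from \code{rate} (cM = bp * rate * 100).
#' @param samples sample id per haplotype; defaults to pairing consecutive
#'   rows ("S1", "S1", "S2", ...).
#' @param populations population label per haplotype (recycled if length 1).
#' @param rate recombination rate per bp per generation used for the default
#'   uniform genetic map.
#' @return a \linkS4class{HaplotypeMatrix}
#' @export
HaplotypeMatrix <- function(haps, positions, genPos = NULL, samples = NULL,
                            populations = "pop1", rate = 1e-8) {
  haps <- as.matrix(haps)
  storage.mode(haps) <- "integer"
  if (is.null(genPos)) genPos <- (positions - 1) * rate * 100
  if (is.null(samples)) {
    if (nrow(haps) %% 2L != 0L)
      stop("odd number of haplotypes; supply explicit sample ids")
    samples <- paste0("S", rep(seq_len(nrow(haps) / 2L), each = 2L))
  }
  if (length(populations) == 1L) populations <- rep(populations, nrow(haps))
  new("HaplotypeMatrix", haps = haps, positions = as.numeric(positions),
      genPos = as.numeric(genPos), samples = as.character(samples),
      populations = as.character(populations))
}

#' @rdname HaplotypeMatrix-class
#' @export
setMethod("nHap", "HaplotypeMatrix", function(x) nrow(x@haps))

#' @rdname HaplotypeMatrix-class
#' @export
setMethod("nSites", "HaplotypeMatrix", function(x) ncol(x@haps))

#' @rdname HaplotypeMatrix-class
#' @export
setMethod("hapMatrix", "HaplotypeMatrix", function(x) x@haps)

#' @rdname HaplotypeMatrix-class
#' @export
setMethod("positions", "HaplotypeMatrix", function(x) x@positions)

#' @rdname HaplotypeMatrix-class
#' @export
setMethod("genPositions", "HaplotypeMatrix", function(x) x@genPos)

#' @rdname HaplotypeMatrix-class
#' @export
setMethod("sampleIds", "HaplotypeMatrix", function(x) x@samples)

#' @rdname HaplotypeMatrix-class
#' @export
setMethod("popLabels", "HaplotypeMatrix", function(x) x@populations)

#' @rdname HaplotypeMatrix-class
#' @export
setMethod("derivedFreq", "HaplotypeMatrix",
          function(x) colMeans(x@haps))

#' @rdname HaplotypeMatrix-class
#' @export
setMethod("subsetByPop", "HaplotypeMatrix", function(x, pop) {
  keep <- x@populations %in% pop
  if (!any(keep)) stop("no haplotypes in population(s) ",
                       paste(pop, collapse = ", "))
  new("HaplotypeMatrix", haps = x@haps[keep, , drop = FALSE],
      positions = x@positions, genPos = x@genPos,
      samples = x@samples[keep], populations = x@populations[keep])
})

#' Subset a HaplotypeMatrix by haplotype rows and/or site columns
#' @param x a HaplotypeMatrix
#' @param i haplotype index
#' @param j site index
#' @param ... ignored
#' @param drop ignored (always FALSE)
#' @export
setMethod("[", "HaplotypeMatrix", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@haps))
  if (missing(j)) j <- seq_len(ncol(x@haps))
  new("HaplotypeMatrix", haps = x@haps[i, j, drop = FALSE],
      positions = x@positions[j], genPos = x@genPos[j],
      samples = x@samples[i], populations = x@populations[i])
})

setMethod("show", "HaplotypeMatrix", function(object) {
  cat("HaplotypeMatrix:", nrow(object@haps), "haplotypes x",
      ncol(object@haps), "sites\n")
  if (ncol(object@haps))
    cat("  positions:", min(object@positions), "-", max(object@positions),
        "bp\n")
  tab <- table(object@populations)
  cat("  populations:",
      paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
})

#' Construct a TruthSet
#' @param svLoci data.frame of true SV loci (may be empty).
#' @param tracts data.frame of introgressed tracts (hap, start, end).
#' @param sweep list describing an implanted sweep.
#' @param seed integer seed.
#' @return a \linkS4class{TruthSet}
#' @export
TruthSet <- function(svLoci = data.frame(), tracts = data.frame(),
                     sweep = list(), seed = NA_integer_) {
  new("TruthSet", svLoci = svLoci, tracts = tracts, sweep = sweep,
      seed = as.integer(seed))
}

#' @rdname TruthSet-class
#' @export
setMethod("truthSVs", "TruthSet", function(x) x@svLoci)

#' @rdname TruthSet-class
#' @export
setMethod("truthTracts", "TruthSet", function(x) x@tracts)

setMethod("show", "TruthSet", function(object) {
  cat("TruthSet: ", nrow(object@svLoci), " SV loci, ",
      nrow(object@tracts), " introgressed tracts, sweep: ",
      if (length(object@sweep)) "yes" else "no",
      ", seed ", object@seed, "\n", sep = "")
})

#' Construct a GenotypeMatrix
#' @param geno loci x samples matrix of 0/1/2/NA alternate-allele dosages.
#' @param loci GRanges of loci with mcols locus_id and svtype.
#' @param panel data.frame with columns sample, population, dataset.
#' @return a \linkS4class{GenotypeMatrix}
#' @export
GenotypeMatrix <- function(geno, loci, panel) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (!"dataset" %in% names(panel)) panel$dataset <- "ds1"
  new("GenotypeMatrix", geno = geno, loci = loci, panel = panel)
}

#' @rdname GenotypeMatrix-class
#' @export
setMethod("genotypes", "GenotypeMatrix", function(x) x@geno)

#' @rdname GenotypeMatrix-class
#' @export
setMethod("samplePanel", "GenotypeMatrix", function(x) x@panel)

#' @rdname GenotypeMatrix-class
#' @export
setMethod("missingRate", "GenotypeMatrix",
          function(x) rowMeans(is.na(x@geno)))

#' Genotyped alternate-allele frequency per locus
#'
#' Alternate alleles over non-missing alleles; NaN when every genotype at a
#' locus is missing.
#' @rdname GenotypeMatrix-class
#' @export
setMethod("genotypedAF", "GenotypeMatrix", function(x) {
  alt <- rowSums(x@geno, na.rm = TRUE)
  tot <- 2 * rowSums(!is.na(x@geno))
  ifelse(tot > 0, alt / tot, NaN)
})

setMethod("show", "GenotypeMatrix", function(object) {
  cat("GenotypeMatrix:", nrow(object@geno), "loci x", ncol(object@geno),
      "samples\n")
  tab <- table(object@panel$population)
  cat("  populations:",
      paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  cat("  median missing rate:",
      signif(stats::median(missingRate(object)), 3), "\n")
})

#' @rdname SVCatalog-class
#' @export
setMethod("svLoci", "SVCatalog", function(x) x@loci)

#' @rdname SVCatalog-class
#' @export
setMethod("memberCalls", "SVCatalog", function(x) x@calls)

#' @rdname SVCatalog-class
#' @export
setMethod("cohortSize", "SVCatalog", function(x) x@nSamples)

#' @rdname SVCatalog-class
#' @export
setMethod("length", "SVCatalog", function(x) length(x@loci))

setMethod("show", "SVCatalog", function(object) {
  cat("SVCatalog:", length(object@loci), "loci from",
      nrow(object@calls), "calls in", object@nSamples, "samples\n")
  if (length(object@loci)) {
    tab <- table(mcols(object@loci)$svtype)
    cat("  types:",
        paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
    if ("category" %in% names(mcols(object@loci))) {
      tab <- table(mcols(object@loci)$category)
      cat("  categories:",
          paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
    }
  }
})

setMethod("show", "DemographicModel", function(object) {
  ext <- object@populations$name[object@populations$extant]
  cat("DemographicModel:", nrow(object@populations), "populations (extant:",
      paste(ext, collapse = ", "), ")\n")
  if (nrow(object@splits))
    cat("  splits (gen):",
        paste(sprintf("%s+%s->%s @%g", object@splits$derived1,
                      object@splits$derived2, object@splits$ancestral,
                      object@splits$time), collapse = "; "), "\n")
  cat("  migration:", object@migration, " mu:", object@mutationRate,
      " r:", object@recombinationRate, "\n")
  if (!is.null(object@archaic))
    cat("  archaic pulse:", object@archaic$pulseFrac, "into",
        object@archaic$recipient, "at", object@archaic$pulseTime,
        "generations\n")
})
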