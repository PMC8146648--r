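#' @rdname HaplotypeMatrix-class
#' @param x a \linkS4class{HaplotypeMatrix}
#' @export
setGeneric("nHap", function(x) standardGeneric("nHap"))

#' @rdname HaplotypeMatrix-class
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))

#' @rdname HaplotypeMatrix-class
#' @export
setGeneric("hapMatrix", function(x) standardGeneric("hapMatrix"))

#' @rdname HaplotypeMatrix-class
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))

#' @rdname HaplotypeMatrix-class
#' @export
setGeneric("genPositions", function(x) standardGeneric("genPositions"))

#' @rdname HaplotypeMatrix-class
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname HaplotypeMatrix-class
#' @export
setGeneric("popLabels", function(x) standardGeneric("popLabels"))

#' @rdname HaplotypeMatrix-class
#' @param pop population label(s) to keep
#' @export
setGeneric("subsetByPop", function(x, pop) standardGeneric("subsetByPop"))

#' @rdname HaplotypeMatrix-class
#' @export
setGeneric("derivedFreq", function(x) standardGeneric("derivedFreq"))

#' @rdname GenotypeMatrix-class
#' @param x a \linkS4class{GenotypeMatrix}
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("samplePanel", function(x) standardGeneric("samplePanel"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("missingRate", function(x) standardGeneric("missingRate"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("genotypedAF", function(x) standardGeneric("genotypedAF"))

#' @rdname SVCatalog-class
#' @param x a \linkS4class{SVCatalog}
#' @export
setGeneric("svLoci", function(x) standardGeneric("svLoci"))

#' @rdname SVCatalog-class
#' @export
setGeneric("memberCalls", function(x) standardGeneric("memberCalls"))

#' @rdname SVCatalog-class
#' @export
setGeneric("cohortSize", function(x) standardGeneric("cohortSize"))

#' @rdname TruthSet-class
#' @param x a \linkS4class{TruthSet}
#' @export
setGeneric("truthSVs", function(x) standardGeneric("truthSVs"))

#' @rdname TruthSet-class
#' @export
setGeneric("truthTracts", function(x) standardGeneric("truthTracts"))
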