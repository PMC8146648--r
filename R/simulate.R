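# Coalescent simulation of phased haplotypes under a DemographicModel.
#
# The heavy lifting is done by msprime through the bundled helper
# inst/python/coalsim.py; this file builds the model description, runs the
# helper, and parses its plain-text output back into HaplotypeMatrix +
# TruthSet objects.  Ancestral alleles are 0 by construction (binary
# mutation model), positions are 1-based bp.

.pythonBin <- function() {
  bin <- getOption("svadapt.python", "")
  if (!nzchar(bin)) bin <- Sys.which("python")
  if (!nzchar(bin)) bin <- Sys.which("python3")
  if (!nzchar(bin))
    stop("no python interpreter found; set options(svadapt.python=...)")
  bin
}

.modelToSpec <- function(model, samplesPerPop, sequenceLength, seed,
                         replicates) {
  p <- model@populations
  pops <- lapply(seq_len(nrow(p)), function(i)
    list(name = p$name[i], size = p$size[i], extant = p$extant[i]))
  s <- model@splits
  splits <- lapply(seq_len(nrow(s)), function(i)
    list(time = s$time[i], derived = list(s$derived1[i], s$derived2[i]),
         ancestral = s$ancestral[i]))
  arc <- NULL
  if (!is.null(model@archaic))
    arc <- list(name = model@archaic$name,
                pulse_time = model@archaic$pulseTime,
                pulse_frac = model@archaic$pulseFrac,
                recipient = model@archaic$recipient)
  samples <- as.list(samplesPerPop)
  list(populations = pops, splits = splits,
       migration = model@migration, archaic = arc,
       mutation_rate = model@mutationRate,
       recombination_rate = model@recombinationRate,
       length = sequenceLength, samples = samples,
       seed = as.integer(seed), replicates = as.integer(replicates))
}

.parseCoalsimOutput <- function(path, model, seed, recipient = NULL) {
  lines <- readLines(path)
  repStarts <- grep("^>REP", lines)
  ends <- c(repStarts[-1] - 1L, length(lines))
  out <- vector("list", length(repStarts))
  for (k in seq_along(repStarts)) {
    block <- lines[repStarts[k]:ends[k]]
    pops <- strsplit(sub("^POPS ?", "", block[startsWith(block, "POPS")]),
                     " ")[[1]]
    posLine <- sub("^POS ?", "", block[startsWith(block, "POS")])
    positions <- if (nzchar(posLine))
      as.numeric(strsplit(posLine, " ")[[1]]) else numeric()
    hapLines <- sub("^HAP ", "", block[startsWith(block, "HAP")])
    n <- length(hapLines)
    if (length(positions)) {
      haps <- matrix(0L, n, length(positions))
      for (i in seq_len(n))
        haps[i, ] <- as.integer(strsplit(hapLines[i], "")[[1]])
    } else haps <- matrix(0L, n, 0L)
    # individuals are consecutive haplotype pairs within each population
    ind <- integer(n)
    counter <- new.env(parent = emptyenv())
    for (i in seq(1L, n, by = 2L)) {
      p <- pops[i]
      k2 <- (if (is.null(counter[[p]])) 0L else counter[[p]]) + 1L
      counter[[p]] <- k2
      ind[c(i, i + 1L)] <- k2
    }
    samples <- sprintf("%s_%03d", pops, ind)
    tractLines <- block[startsWith(block, "TRACT")]
    tracts <- if (length(tractLines)) {
      m <- do.call(rbind, strsplit(sub("^TRACT ", "", tractLines), " "))
      data.frame(hap = as.integer(m[, 1]), start = as.numeric(m[, 2]),
                 end = as.numeric(m[, 3]))
    } else data.frame(hap = integer(), start = numeric(), end = numeric())
    if (!is.null(recipient) && nrow(tracts))
      tracts <- tracts[pops[tracts$hap] == recipient, , drop = FALSE]
    rownames(tracts) <- NULL
    hm <- HaplotypeMatrix(haps, positions, samples = samples,
                          populations = pops,
                          rate = model@recombinationRate)
    out[[k]] <- list(haps = hm,
                     truth = TruthSet(tracts = tracts, seed = seed))
  }
  out
}

.runCoalsim <- function(model, samplesPerPop, sequenceLength, seed,
                        replicates, recipient = NULL) {
  script <- system.file("python", "coalsim.py", package = "svadapt",
                        mustWork = TRUE)
  specFile <- tempfile(fileext = ".json")
  outFile <- tempfile(fileext = ".txt")
  on.exit(unlink(c(specFile, outFile)))
  spec <- .modelToSpec(model, samplesPerPop, sequenceLength, seed,
                       replicates)
  jsonlite::write_json(spec, specFile, auto_unbox = TRUE, digits = NA)
  status <- system2(.pythonBin(), c(script, specFile, outFile),
                    stdout = FALSE, stderr = "")
  if (status != 0)
    stop("coalescent simulation failed (python exit status ", status, ")")
  .parseCoalsimOutput(outFile, model, seed, recipient)
}

.checkSampleCounts <- function(model, samplesPerPop) {
  extant <- model@populations$name[model@populations$extant]
  if (is.null(names(samplesPerPop)) ||
      !all(names(samplesPerPop) %in% model@populations$name))
    stop("samplesPerPop must be named with the model's population labels")
  modern <- setdiff(names(samplesPerPop),
                    if (is.null(model@archaic)) character()
                    else model@archaic$name)
  if (any(samplesPerPop[modern] < 1))
    stop("at least one diploid sample (2 haplotypes) per sampled population")
  invisible(TRUE)
}

#' Simulate neutral phased haplotypes under a demographic model
#'
#' Runs a coalescent simulation (msprime backend) of the supplied model and
#' returns phased biallelic 0/1 haplotypes, ancestral allele = 0 by
#' construction.  Identical (model, samplesPerPop, seed) give identical
#' output.
#'
#' @param model a \linkS4class{DemographicModel} (no archaic pulse needed).
#' @param samplesPerPop named integer vector of diploid sample counts per
#'   extant population.
#' @param sequenceLength simulated sequence length in bp (>= 10 kb advised).
#' @param seed integer random seed.
#' @param replicates number of independent replicates.
#' @return for \code{replicates = 1} a list with elements \code{haps}
#'   (\linkS4class{HaplotypeMatrix}) and \code{truth}
#'   (\linkS4class{TruthSet}); otherwise an unnamed list of such lists.
#' @examples
#' \dontrun{
#' sim <- simulateNeutral(panmicticModel(), c(POP = 10), 1e5, seed = 1)
#' sim$haps
#' }
#' @export
simulateNeutral <- function(model, samplesPerPop, sequenceLength, seed,
                            replicates = 1) {
  stopifnot(sequenceLength >= 1000)
  .checkSampleCounts(model, samplesPerPop)
  res <- .runCoalsim(model, samplesPerPop, sequenceLength, seed, replicates)
  if (replicates == 1) res[[1]] else res
}

#' Simulate haplotypes with an archaic admixture pulse
#'
#' As [simulateNeutral()] but requires the model to carry an archaic branch;
#' the returned TruthSet records, per recipient haplotype, the intervals that
#' truly descend from the archaic population (recovered from census nodes at
#' the pulse time).
#'
#' @inheritParams simulateNeutral
#' @return as [simulateNeutral()]; \code{truth} carries the introgressed
#'   tracts of recipient haplotypes.
#' @export
simulateArchaicIntrogression <- function(model, samplesPerPop,
                                         sequenceLength, seed,
                                         replicates = 1) {
  if (is.null(model@archaic))
    stop("model has no archaic branch configured")
  if (model@archaic$pulseFrac < 0 || model@archaic$pulseFrac > 1)
    stop("pulse fraction must lie in [0, 1]")
  arcName <- model@archaic$name
  if (!arcName %in% names(samplesPerPop) || samplesPerPop[arcName] < 1)
    stop("at least one archaic sample must be drawn (add '", arcName,
         "' to samplesPerPop)")
  .checkSampleCounts(model, samplesPerPop)
  res <- .runCoalsim(model, samplesPerPop, sequenceLength, seed, replicates,
                     recipient = model@archaic$recipient)
  if (replicates == 1) res[[1]] else res
}

#' Fraction of a haplotype's sequence covered by introgressed tracts
#' @param truth a \linkS4class{TruthSet} with tracts
#' @param sequenceLength total sequence length in bp
#' @param haps optional haplotype indices to average over (default: all
#'   haplotypes appearing in the tract table's population)
#' @return named numeric vector of per-haplotype introgressed fractions
#' @export
introgressedFraction <- function(truth, sequenceLength, haps = NULL) {
  tr <- truthTracts(truth)
  if (is.null(haps)) haps <- sort(unique(tr$hap))
  out <- vapply(haps, function(h) {
    sub <- tr[tr$hap == h, , drop = FALSE]
    sum(sub$end - sub$start + 1) / sequenceLength
  }, numeric(1))
  names(out) <- haps
  out
}
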