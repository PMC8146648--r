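# Demographic model constructors.
#
# Split-time point estimates follow the fitted values quoted for the two
# population models (TIB-HANN-HANS: TIB vs HAN split ~17,000 y, HANN vs HANS
# ~770 y; YRI-TIB-HAN: TIB vs HAN ~22,000 y, AFR vs CHN ~88,000 y).  Effective
# sizes are configurable placeholders; the archaic branch (divergence 600 ky,
# pulse 50 ky, 5% into the Tibetan lineage by default) is a package choice
# documented in the methods vignette.

#' Construct a DemographicModel
#'
#' @param populations data.frame with columns \code{name}, \code{size}
#'   (diploid Ne), \code{extant}.
#' @param splits data.frame with columns \code{time} (generations),
#'   \code{derived1}, \code{derived2}, \code{ancestral}.
#' @param migration symmetric migration rate per generation among extant
#'   modern populations.
#' @param mutationRate per-bp per-generation mutation rate.
#' @param recombinationRate per-bp per-generation recombination rate.
#' @param generationTime years per generation.
#' @param archaic NULL or list(name, pulseTime, pulseFrac, recipient).
#' @return a \linkS4class{DemographicModel}
#' @export
DemographicModel <- function(populations, splits,
                             migration = 1e-4,
                             mutationRate = 1.25e-8,
                             recombinationRate = 1e-8,
                             generationTime = 25,
                             archaic = NULL) {
  splits <- splits[order(splits$time), , drop = FALSE]
  rownames(splits) <- NULL
  new("DemographicModel", populations = populations, splits = splits,
      migration = migration, mutationRate = mutationRate,
      recombinationRate = recombinationRate,
      generationTime = generationTime, archaic = archaic)
}

#' Convert years before present to generations under a model's clock
#' @param years years before present
#' @param generationTime years per generation
#' @export
yearsToGenerations <- function(years, generationTime = 25) {
  years / generationTime
}

# Time (generations) at which the archaic lineage splits off, NA if no
# archaic branch is configured.
archaicDivergence <- function(model) {
  a <- model@archaic
  if (is.null(a)) return(NA_real_)
  s <- model@splits
  hit <- s$derived1 == a$name | s$derived2 == a$name
  if (!any(hit)) return(NA_real_)
  min(s$time[hit])
}

#' Three-population Tibetan/Han/African model with an optional archaic branch
#'
#' A YRI-TIB-HAN-style tree: Tibetans and Hans diverge ~22,000 years ago,
#' their common ancestor diverges from Africans ~88,000 years ago, with
#' symmetric low-level migration among the extant modern populations.  When
#' \code{pulseFrac > 0} an archaic lineage (divergence \code{archaicSplitYears})
#' delivers a single pulse into \code{recipient} at \code{pulseYears}.
#'
#' @param neTib,neHan,neAfr,neAnc,neArc diploid effective sizes.
#' @param tibHanYears,afrChnYears,archaicSplitYears split times in years.
#' @param pulseYears,pulseFrac archaic pulse time (years) and fraction.
#' @param recipient population receiving the pulse.
#' @param migration symmetric migration rate per generation.
#' @param mutationRate,recombinationRate per-bp per-generation rates.
#' @param generationTime years per generation.
#' @return a \linkS4class{DemographicModel}
#' @export
tibHanAfrModel <- function(neTib = 5000, neHan = 20000, neAfr = 15000,
                           neAnc = 10000, neArc = 5000,
                           tibHanYears = 22000, afrChnYears = 88000,
                           archaicSplitYears = 600000,
                           pulseYears = 15000, pulseFrac = 0,
                           recipient = "TIB",
                           migration = 1e-4, mutationRate = 1.25e-8,
                           recombinationRate = 1e-8, generationTime = 25) {
  g <- function(y) yearsToGenerations(y, generationTime)
  pops <- data.frame(
    name = c("TIB", "HAN", "AFR", "ARC", "ANC_CHN", "ANC_MOD", "ANC_ROOT"),
    size = c(neTib, neHan, neAfr, neArc, neAnc, neAnc, neAnc),
    extant = c(TRUE, TRUE, TRUE, pulseFrac > 0, FALSE, FALSE, FALSE))
  splits <- data.frame(
    time = c(g(tibHanYears), g(afrChnYears), g(archaicSplitYears)),
    derived1 = c("TIB", "ANC_CHN", "ANC_MOD"),
    derived2 = c("HAN", "AFR", "ARC"),
    ancestral = c("ANC_CHN", "ANC_MOD", "ANC_ROOT"))
  archaic <- NULL
  if (pulseFrac > 0)
    archaic <- list(name = "ARC", pulseTime = g(pulseYears),
                    pulseFrac = pulseFrac, recipient = recipient)
  DemographicModel(pops, splits, migration = migration,
                   mutationRate = mutationRate,
                   recombinationRate = recombinationRate,
                   generationTime = generationTime, archaic = archaic)
}

#' Tibetan / northern-Han / southern-Han model
#'
#' The TIB-HANN-HANS tree: HANN and HANS diverge very recently (~770 years
#' ago) while their common ancestor split from Tibetans ~17,000 years ago.
#'
#' @param neTib,neHan,neAnc diploid effective sizes.
#' @param hannHansYears,tibHanYears split times in years.
#' @inheritParams tibHanAfrModel
#' @return a \linkS4class{DemographicModel}
#' @export
tibHanNorthSouthModel <- function(neTib = 5000, neHan = 20000, neAnc = 10000,
                                  hannHansYears = 770, tibHanYears = 17000,
                                  migration = 1e-4, mutationRate = 1.25e-8,
                                  recombinationRate = 1e-8,
                                  generationTime = 25) {
  g <- function(y) yearsToGenerations(y, generationTime)
  pops <- data.frame(
    name = c("TIB", "HANN", "HANS", "ANC_HAN", "ANC_CHN"),
    size = c(neTib, neHan, neHan, neHan, neAnc),
    extant = c(TRUE, TRUE, TRUE, FALSE, FALSE))
  splits <- data.frame(
    time = c(g(hannHansYears), g(tibHanYears)),
    derived1 = c("HANN", "ANC_HAN"),
    derived2 = c("HANS", "TIB"),
    ancestral = c("ANC_HAN", "ANC_CHN"))
  DemographicModel(pops, splits, migration = migration,
                   mutationRate = mutationRate,
                   recombinationRate = recombinationRate,
                   generationTime = generationTime, archaic = NULL)
}

#' Single panmictic population (calibration baseline)
#' @param ne diploid effective size
#' @inheritParams tibHanAfrModel
#' @return a \linkS4class{DemographicModel}
#' @export
panmicticModel <- function(ne = 10000, mutationRate = 1.25e-8,
                           recombinationRate = 1e-8, generationTime = 25) {
  pops <- data.frame(name = "POP", size = ne, extant = TRUE)
  splits <- data.frame(time = numeric(), derived1 = character(),
                       derived2 = character(), ancestral = character())
  DemographicModel(pops, splits, migration = 0,
                   mutationRate = mutationRate,
                   recombinationRate = recombinationRate,
                   generationTime = generationTime, archaic = NULL)
}
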