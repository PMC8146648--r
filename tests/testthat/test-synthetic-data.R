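# Synthetic-data generators: determinism, calibration against coalescent
# expectations, and the noise model of the SV callset emulator.

test_that("neutral simulation is deterministic and honours the seed", {
  model <- panmicticModel(ne = 5000)
  a <- simulateNeutral(model, c(POP = 5), 5e4, seed = 42)
  b <- simulateNeutral(model, c(POP = 5), 5e4, seed = 42)
  d <- simulateNeutral(model, c(POP = 5), 5e4, seed = 43)
  expect_identical(hapMatrix(a$haps), hapMatrix(b$haps))
  expect_identical(positions(a$haps), positions(b$haps))
  expect_false(identical(hapMatrix(a$haps), hapMatrix(d$haps)))
  expect_true(all(hapMatrix(a$haps) %in% 0:1))
  expect_true(!is.unsorted(positions(a$haps), strictly = TRUE))
})

test_that("zero mutation rate yields zero segregating sites", {
  model <- panmicticModel(ne = 5000, mutationRate = 0)
  sim <- simulateNeutral(model, c(POP = 5), 5e4, seed = 1)
  expect_equal(nSites(sim$haps), 0)
})

test_that("neutral diversity matches the 4*Ne*mu expectation", {
  ne <- 10000; mu <- 1.25e-8; L <- 1e6
  reps <- simulateNeutral(panmicticModel(ne = ne, mutationRate = mu),
                          c(POP = 50), L, seed = 99, replicates = 50)
  piPerRep <- vapply(reps, function(r) {
    p <- derivedFreq(r$haps)
    n <- nHap(r$haps)
    sum(2 * p * (1 - p) * n / (n - 1)) / L   # mean pairwise diversity
  }, numeric(1))
  theta <- 4 * ne * mu
  se <- stats::sd(piPerRep) / sqrt(length(piPerRep))
  expect_lt(abs(mean(piPerRep) - theta), 3 * se)
  # Watterson's estimator agrees too
  thetaW <- vapply(reps, function(r)
    nSites(r$haps) / sum(1 / seq_len(nHap(r$haps) - 1)) / L, numeric(1))
  seW <- stats::sd(thetaW) / sqrt(length(thetaW))
  expect_lt(abs(mean(thetaW) - theta), 3 * seW)
})

test_that("archaic pulse produces recipient tracts near the pulse fraction", {
  model <- tibHanAfrModel(pulseFrac = 0.05)
  reps <- simulateArchaicIntrogression(
    model, c(TIB = 10, HAN = 10, AFR = 5, ARC = 1), 2e6, seed = 7,
    replicates = 6)
  fr <- vapply(reps, function(r) {
    tibHaps <- which(popLabels(r$haps) == "TIB")
    mean(introgressedFraction(r$truth, 2e6, haps = tibHaps))
  }, numeric(1))
  expect_gt(mean(fr), 0.02)
  expect_lt(mean(fr), 0.08)
  # truth tracts stay inside the simulated sequence
  tr <- truthTracts(reps[[1]]$truth)
  expect_true(all(tr$start >= 1 & tr$end <= 2e6))
})

test_that("archaic simulation refuses a model without the archaic branch", {
  expect_error(simulateArchaicIntrogression(
    tibHanAfrModel(), c(TIB = 5, HAN = 5, AFR = 5), 5e4, seed = 1),
    "archaic")
})

test_that("sweep implantation homogenises carriers as specified", {
  sim <- simulateNeutral(panmicticModel(ne = 8000), c(POP = 25), 2e5,
                         seed = 5)
  daf <- derivedFreq(sim$haps)
  focal <- which(daf > 0.3 & daf < 0.7)[1]
  m0 <- hapMatrix(sim$haps)

  # decayScale = Inf, full carrier fraction: all carriers identical
  swInf <- implantSweep(sim$haps, focal, 1, Inf, seed = 2)
  mi <- hapMatrix(swInf$haps)
  carriers <- which(mi[, focal] == 1)
  expect_true(all(apply(mi[carriers, , drop = FALSE], 2,
                        function(x) length(unique(x)) == 1)))
  curve <- ehhCurve(swInf$haps, focal, coreAllele = 1, cutoff = 0)
  expect_true(all(curve$ehh == 1))

  # decayScale = 0: nothing changes
  sw0 <- implantSweep(sim$haps, focal, 0.8, 0, seed = 3)
  expect_identical(hapMatrix(sw0$haps), m0)

  # homozygosity around the focal site increases
  sw <- implantSweep(sim$haps, focal, 0.9, 2e5, seed = 4)
  ehhBefore <- ehhCurve(sim$haps, focal, cutoff = 0)
  ehhAfter <- ehhCurve(sw$haps, focal, cutoff = 0)
  shared <- intersect(ehhBefore$site, ehhAfter$site)
  eb <- ehhBefore$ehh[match(shared, ehhBefore$site)]
  ea <- ehhAfter$ehh[match(shared, ehhAfter$site)]
  expect_true(all(ea >= eb - 1e-12))
  expect_gt(mean(ea), mean(eb))

  expect_error(implantSweep(sim$haps, focal, 0, 1e5, seed = 1))
})

test_that("SV callsets reproduce truth exactly without noise", {
  truth <- generateTruthSVs(30, 5e5, seed = 11)
  res <- generateSVCallsets(truth, 10, jitterSd = 0, genotypeError = 0,
                            dropout = 0, seed = 12)
  allCalls <- do.call(rbind, res$callsets)
  expect_true(all(allCalls$start == truth$start[
    match(allCalls$start, truth$start)]))
  # every call's breakpoints equal some truth locus exactly
  expect_true(all(allCalls$start %in% truth$start))
  expect_true(all(allCalls$end %in% truth$end))
  # carrier counts in truth match emitted calls
  expect_equal(nrow(allCalls), sum(res$carrier))
})

test_that("full dropout empties the callsets", {
  truth <- generateTruthSVs(10, 2e5, seed = 3)
  res <- generateSVCallsets(truth, 5, dropout = 1, seed = 4)
  expect_true(all(vapply(res$callsets, nrow, integer(1)) == 0))
})

test_that("breakpoint jitter keeps calls of a locus within 100 bp", {
  truth <- generateTruthSVs(60, 1e6, seed = 21)
  res <- generateSVCallsets(truth, 25, jitterSd = 20, seed = 22)
  allCalls <- do.call(rbind, res$callsets)
  # group calls by their truth locus (loci are >= 5 kb apart)
  span <- vapply(seq_len(nrow(truth)), function(i) {
    sub <- allCalls[abs(allCalls$start - truth$start[i]) < 2500, ]
    if (nrow(sub) < 2) 0 else max(sub$start) - min(sub$start)
  }, numeric(1))
  expect_gte(mean(span <= 100), 0.95)
})

test_that("track generator honours densities and length classes", {
  tk <- generateTracks(5e5, seed = 31)
  sine <- tk$repeats[GenomicRanges::mcols(tk$repeats)$class == "SINE"]
  expect_gt(length(sine), 0)
  med <- stats::median(GenomicRanges::width(sine))
  expect_gte(med, 250)
  expect_lte(med, 350)
  line <- tk$repeats[GenomicRanges::mcols(tk$repeats)$class == "LINE"]
  expect_gt(stats::median(GenomicRanges::width(line)), 4000)
  allIv <- c(tk$repeats, tk$tandem, tk$ctcf)
  expect_true(all(GenomicRanges::start(allIv) >= 1))
  expect_true(all(GenomicRanges::end(allIv) <= 5e5))
  expect_true(all(GenomicRanges::start(allIv) <=
                    GenomicRanges::end(allIv)))
  # zero density empties a class
  tk0 <- generateTracks(5e5, seed = 31, densities = c(LTR = 0))
  expect_equal(sum(GenomicRanges::mcols(tk0$repeats)$class == "LTR"), 0)
  # chromatin states tile the genome contiguously
  expect_equal(sum(GenomicRanges::width(tk0$chromatin)), 5e5)
})

test_that("truth sets are conserved by value semantics", {
  truth <- generateTruthSVs(5, 1e5, seed = 1)
  res <- generateSVCallsets(truth, 3, seed = 2)
  snapshot <- truthSVs(res$truth)
  invisible(mergeCalls(res$callsets))
  expect_identical(truthSVs(res$truth), snapshot)
})
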