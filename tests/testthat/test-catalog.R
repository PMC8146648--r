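# Catalog construction: merging, discovery categories, genotype filtering,
# concordance, novelty comparison and arm-tail density.

makeCall <- function(sample, start, end, svtype = "DEL",
                     len = end - start + 1, support = 10, qual = 50) {
  data.frame(sample = sample, chrom = "chr1", start = start, end = end,
             svtype = svtype, length = len, genotype = "0/1",
             support = support, qual = qual)
}

test_that("identical calls merge into one locus; distant calls stay apart", {
  cs <- list(s1 = makeCall("s1", 10000, 10499),
             s2 = makeCall("s2", 10000, 10499))
  cat1 <- mergeCalls(cs)
  expect_equal(length(cat1), 1)
  expect_equal(GenomicRanges::mcols(svLoci(cat1))$n_carriers, 2L)

  cs2 <- list(s1 = rbind(makeCall("s1", 10000, 10499),
                         makeCall("s1", 12000, 12499)))
  cat2 <- mergeCalls(cs2, maxDist = 1000)
  expect_equal(length(cat2), 2)
})

test_that("calls of different types or dissimilar lengths never merge", {
  cs <- list(s1 = makeCall("s1", 10000, 10499, "DEL"),
             s2 = makeCall("s2", 10000, 10499, "DUP"))
  expect_equal(length(mergeCalls(cs)), 2)
  # same start, very different length: fails the size-similarity test
  cs2 <- list(s1 = makeCall("s1", 10000, 10099),
              s2 = makeCall("s2", 10000, 10999))
  expect_equal(length(mergeCalls(cs2)), 2)
})

test_that("merging is idempotent and invariant to sample order", {
  truth <- generateTruthSVs(40, 6e5, seed = 51)
  res <- generateSVCallsets(truth, 15, jitterSd = 20, seed = 52)
  cat1 <- mergeCalls(res$callsets)
  cat2 <- mergeCalls(rev(res$callsets))
  expect_equal(GenomicRanges::start(svLoci(cat1)),
               GenomicRanges::start(svLoci(cat2)))
  expect_equal(GenomicRanges::mcols(svLoci(cat1))$n_carriers,
               GenomicRanges::mcols(svLoci(cat2))$n_carriers)
  # re-merging the representatives is a no-op
  reps <- memberCalls(cat1)
  reps <- reps[!duplicated(reps$locus_id), ]
  reps$sample <- "rep"
  cat3 <- mergeCalls(list(rep = reps[, setdiff(names(reps), "locus_id")]))
  expect_equal(length(cat3), length(cat1))
})

test_that("jittered callsets recover the truth locus count", {
  truth <- generateTruthSVs(100, 2e6, seed = 61)
  res <- generateSVCallsets(truth, 25, jitterSd = 20, seed = 62)
  catg <- mergeCalls(res$callsets, maxDist = 1000, sizeSim = 0.7)
  # >= 99% of truth loci are recovered by a merged locus within 100 bp
  starts <- GenomicRanges::start(svLoci(catg))
  recovered <- vapply(truth$start, function(s)
    any(abs(starts - s) <= 100), logical(1))
  expect_gte(mean(recovered), 0.99)
  # no runaway over- or under-merging (very short loci may split on the
  # size-similarity rule under breakpoint jitter)
  expect_lte(abs(length(catg) - nrow(truth)), ceiling(0.05 * nrow(truth)))
})

test_that("discovery categories partition the catalog", {
  cs <- list(
    a = rbind(makeCall("a", 1000, 1999), makeCall("a", 5000, 5999),
              makeCall("a", 9000, 9999)),
    b = rbind(makeCall("b", 1000, 1999), makeCall("b", 5000, 5999)),
    c = rbind(makeCall("c", 1000, 1999)),
    d = rbind(makeCall("d", 1000, 1999), makeCall("d", 20000, 20999)))
  catg <- categorizeDiscovery(mergeCalls(cs))
  mc <- GenomicRanges::mcols(svLoci(catg))
  cats <- setNames(mc$category, GenomicRanges::start(svLoci(catg)))
  expect_equal(unname(cats["1000"]), "shared")      # 4/4 samples
  expect_equal(unname(cats["5000"]), "major")       # 2/4 samples
  expect_equal(unname(cats["9000"]), "singleton")
  expect_equal(unname(cats["20000"]), "singleton")
  expect_equal(sum(table(mc$category)), length(catg))
  # definitional thresholds at a 25-sample cohort
  carriers <- c(25, 13, 2, 1)
  category <- ifelse(carriers == 25, "shared",
              ifelse(carriers >= 13, "major",
              ifelse(carriers == 1, "singleton", "polymorphic")))
  expect_equal(category, c("shared", "major", "polymorphic", "singleton"))
})

test_that("genotype filtering removes low-support calls and logs them", {
  truth <- generateTruthSVs(30, 5e5, seed = 71)
  res <- generateSVCallsets(truth, 10, seed = 72)
  catg <- mergeCalls(res$callsets)
  # zero thresholds: identity
  f0 <- filterUnreliableGenotypes(catg, 0, 0)
  expect_equal(length(f0$catalog), length(catg))
  expect_equal(nrow(f0$removed), 0)
  # impossible thresholds: everything removed, fully logged
  fAll <- filterUnreliableGenotypes(catg, minSupport = 1e6)
  expect_equal(length(fAll$catalog), 0)
  expect_equal(nrow(fAll$removed), nrow(memberCalls(catg)))
  # Poisson support, threshold 3: removal fraction tracks the CDF at 2
  calls <- memberCalls(catg)
  set.seed(73)
  calls$support <- stats::rpois(nrow(calls), 10)
  cat2 <- new("SVCatalog", loci = svLoci(catg), calls = calls,
              nSamples = cohortSize(catg))
  f <- filterUnreliableGenotypes(cat2, minSupport = 3)
  frac <- nrow(f$removed) / nrow(calls)
  expected <- stats::ppois(2, 10)
  tol <- 3 * sqrt(expected * (1 - expected) / nrow(calls))
  expect_lt(abs(frac - expected), tol + 1e-9)
})

test_that("breakpoint concordance is monotone and saturates", {
  truth <- generateTruthSVs(40, 8e5, seed = 81)
  res <- generateSVCallsets(truth, 20, jitterSd = 20, seed = 82)
  catg <- mergeCalls(res$callsets)
  c50 <- breakpointConcordance(catg, 50)
  c100 <- breakpointConcordance(catg, 100)
  c1e9 <- breakpointConcordance(catg, 1e9)
  expect_lte(c50, c100)
  expect_equal(c1e9, 1)
  # single-call loci are always concordant
  single <- mergeCalls(list(s1 = makeCall("s1", 1000, 1999)))
  expect_equal(breakpointConcordance(single, 1), 1)
})

test_that("novelty comparison identifies planted matches", {
  truth <- generateTruthSVs(10, 3e5, seed = 91)
  res <- generateSVCallsets(truth, 5, jitterSd = 0, seed = 92)
  catg <- mergeCalls(res$callsets)
  expect_equal(length(catg), 10)
  # empty external set: all novel
  allNovel <- compareCallsets(catg, data.frame(
    chrom = character(), start = numeric(), end = numeric(),
    svtype = character(), length = numeric(), af = numeric()))
  expect_true(all(allNovel$novel))
  # the catalog itself as external: nothing novel
  self <- data.frame(chrom = "chr1",
                     start = GenomicRanges::start(svLoci(catg)),
                     end = GenomicRanges::end(svLoci(catg)),
                     svtype = GenomicRanges::mcols(svLoci(catg))$svtype,
                     length = GenomicRanges::mcols(svLoci(catg))$svlen,
                     af = 0.5)
  none <- compareCallsets(catg, self)
  expect_false(any(none$novel))
  expect_true(all(none$max_external_af == 0.5))
  # plant matches for 4 loci only: exactly 6 novel
  planted <- self[1:4, ]
  some <- compareCallsets(catg, planted)
  expect_equal(sum(some$novel), 6)
})

test_that("arm-tail density has calibrated permutation behaviour", {
  info <- data.frame(chrom = "chr1", length = 5e7, cen_start = 2.4e7,
                     cen_end = 2.6e7)
  mkCat <- function(pos) {
    calls <- do.call(rbind, lapply(seq_along(pos), function(i)
      makeCall(paste0("s", i %% 3), pos[i], pos[i] + 499)))
    mergeCalls(list(calls))
  }
  # all SVs in the distal 5 Mb: minimal possible p
  set.seed(101)
  tails <- c(stats::runif(50, 1, 5e6), stats::runif(50, 4.5e7, 5e7 - 500))
  res <- armTailDensity(mkCat(tails), info, tail = 5e6, nPerm = 199,
                        seed = 5)
  expect_equal(res$p, 1 / 200)
  expect_gt(res$fc, 1)
  # uniform SVs: fold change sits inside the permutation interval
  unif <- sort(stats::runif(150, 1, 5e7 - 500))
  res2 <- armTailDensity(mkCat(unif), info, tail = 5e6, nPerm = 199,
                         seed = 6)
  expect_gte(res2$fc, stats::quantile(res2$perm, 0.025))
  expect_lte(res2$fc, stats::quantile(res2$perm, 0.975))
  expect_gt(res2$p, 0.025)
  # missing centromere excludes the chromosome with a warning
  info2 <- rbind(info, data.frame(chrom = "chr2", length = 1e7,
                                  cen_start = NA, cen_end = NA))
  expect_warning(armTailDensity(mkCat(unif), info2, nPerm = 100,
                                seed = 7), "centromere")
})
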