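# Allele frequencies, Weir-Cockerham and Hudson F_ST, stratification and LD.

library(GenomicRanges)

test_that("allele frequencies match hand-computed values", {
  g <- rbind(c(1, 1, 1, 0, 2, 2),     # TIB: 3 hets; HAN: 0/0, 1/1, 1/1
             c(NA, NA, NA, 0, 0, 1))
  panel <- data.frame(sample = paste0("s", 1:6),
                      population = rep(c("TIB", "HAN"), each = 3),
                      dataset = "ds1")
  loci <- GRanges("chr1", IRanges(c(100, 200), width = 50),
                  locus_id = c("SV1", "SV2"), svtype = "DEL", svlen = 50)
  gm <- GenotypeMatrix(g, loci, panel)
  af <- alleleFrequencies(gm)
  expect_equal(af$af_TIB, c(0.5, NaN))
  expect_equal(af$af_HAN, c(4 / 6, 1 / 6))
  expect_equal(af$n_TIB, c(3, 0))
  expect_error(alleleFrequencies(gm, "YRI"), "absent")
})

test_that("Weir-Cockerham theta behaves at the boundary cases", {
  # fixed difference, no heterozygotes, equal n: theta = 1
  r <- wcFst(c(20, 0, 0), c(0, 0, 20))
  expect_equal(r$fst, 1)
  # identical genotype arrays: theta <= 0
  r2 <- wcFst(c(5, 10, 5), c(5, 10, 5))
  expect_lte(r2$fst, 0)
  # both monomorphic for the same allele: undefined
  expect_true(is.na(wcFst(c(20, 0, 0), c(10, 0, 0))$fst))
})

test_that("Weir-Cockerham matches the independent 1984 oracle", {
  set.seed(23)
  for (i in 1:40) {
    n1 <- sample(5:80, 1); n2 <- sample(5:80, 1)
    g1 <- stats::rbinom(n1, 2, stats::runif(1, 0.1, 0.9))
    g2 <- stats::rbinom(g2n <- n2, 2, stats::runif(1, 0.1, 0.9))
    if (length(unique(c(g1, g2))) == 1) next
    ours <- wcFst(c(sum(g1 == 0), sum(g1 == 1), sum(g1 == 2)),
                  c(sum(g2 == 0), sum(g2 == 1), sum(g2 == 2)))$fst
    # oracle works on reference-allele frequencies; theta is label-free
    expect_equal(ours, oracleWC(2 - g1, 2 - g2), tolerance = 1e-12)
  }
})

test_that("Hudson estimator has the documented analytic behaviour", {
  # equal frequencies: the sample-size corrections push the value <= 0
  expect_lte(hudsonFst(0.4, 100, 0.4, 100)$fst, 0)
  # both fixed for the same allele: undefined
  expect_true(is.na(hudsonFst(0, 100, 0, 100)$fst))
  # ratio-of-sums windows equal the per-site value for single sites
  h <- hudsonFst(0.7, 200, 0.2, 100)
  expect_equal(h$num / h$den, h$fst)
})

test_that("Weir-Cockerham and Hudson agree on balanced HWE data", {
  set.seed(29)
  diffs <- replicate(60, {
    p1 <- stats::runif(1, 0.1, 0.9); p2 <- stats::runif(1, 0.1, 0.9)
    g1 <- stats::rbinom(200, 2, p1); g2 <- stats::rbinom(200, 2, p2)
    wc <- wcFst(c(sum(g1 == 0), sum(g1 == 1), sum(g1 == 2)),
                c(sum(g2 == 0), sum(g2 == 1), sum(g2 == 2)))$fst
    hu <- hudsonFst(mean(g1) / 2, 400, mean(g2) / 2, 400)$fst
    wc - hu
  })
  expect_lt(stats::median(abs(diffs), na.rm = TRUE), 0.02)
})

test_that("stratification is a strict-threshold ordered subset", {
  fst <- data.frame(locus_id = c("a", "b", "c", "d"),
                    fst = c(0.54, 0.1, 0.19, NA))
  out <- stratifySVs(fst, 0.1)
  expect_equal(out$locus_id, c("a", "c"))      # 0.1 exactly is excluded
  expect_equal(out$fst, sort(out$fst, decreasing = TRUE))
  expect_equal(nrow(stratifySVs(fst[0, ], 0.1)), 0)
})

test_that("LD r2 is exact for perfect coupling and repulsion", {
  a <- c(0, 0, 1, 1, 0, 1)
  expect_equal(ldR2(a, a), 1)
  expect_equal(ldR2(a, 1 - a), 1)
  expect_true(is.na(ldR2(a, rep(0, 6))))
  # independent sites: E[r2] ~ 1/n
  set.seed(31)
  r2s <- replicate(2000, ldR2(stats::rbinom(200, 1, 0.5),
                              stats::rbinom(200, 1, 0.5)))
  expect_lt(abs(mean(r2s) - 1 / 200), 3 * stats::sd(r2s) / sqrt(2000))
  # tagging report
  snvs <- cbind(a, 1 - a, c(0, 1, 0, 1, 0, 1))
  tag <- tagLinkedSNVs(a, snvs, cutoffs = c(0.8, 0.9))
  expect_equal(unname(tag$linked[["0.9"]]), c(1L, 2L))
  expect_false(tag$no_tag[["0.8"]])
})

test_that("fstScan produces stratified loci where planted", {
  truth <- generateTruthSVs(40, 6e5, seed = 41)
  gm <- generateGenotypeMatrix(truth, c(TIB = 78, HAN = 174, AFR = 24),
                               seed = 42, stratified = 1:6, deltaAF = 0.5)
  fst <- fstScan(gm, "TIB", "HAN")
  strat <- stratifySVs(fst, 0.1)
  expect_gte(sum(strat$locus_id %in% sprintf("SV%05d", 1:6)), 5)
  hud <- fstScan(gm, "TIB", "HAN", estimator = "hudson")
  expect_lt(stats::median(abs(fst$fst - hud$fst), na.rm = TRUE), 0.03)
  # window aggregation reduces to the per-site value for single sites
  w <- fstWindows(fst[1:3, ], c("w1", "w2", "w3"))
  expect_equal(w$fst, fst$fst[1:3], tolerance = 1e-12)
})
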