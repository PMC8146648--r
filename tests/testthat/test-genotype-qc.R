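# Genotype QC: missing-rate/recall flags, the Hardy-Weinberg exact test
# against full enumeration, dataset concordance and copy-number profiles.

library(GenomicRanges)

mkGM <- function(geno, pops, datasets = NULL) {
  geno <- as.matrix(geno)
  n <- ncol(geno)
  panel <- data.frame(sample = paste0("s", seq_len(n)), population = pops,
                      dataset = datasets %||% "ds1")
  loci <- GRanges("chr1", IRanges(seq_len(nrow(geno)) * 1000, width = 100),
                  locus_id = sprintf("SV%03d", seq_len(nrow(geno))),
                  svtype = "DEL", svlen = 100)
  GenotypeMatrix(geno, loci, panel)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("missing-rate and recall flags follow their definitions", {
  g <- rbind(c(0, 1, 0, 0),            # complete, one het: recalled
             c(0, 0, 0, 0),            # complete, AF 0: not recalled
             c(NA, NA, 0, 1))          # MR 0.5: fails MR
  gm <- mkGM(g, rep("TIB", 4))
  qc <- qcMissingAndRecall(gm, mrThreshold = 0.05)
  expect_equal(qc$pass_mr, c(TRUE, TRUE, FALSE))
  expect_equal(qc$recalled, c(TRUE, FALSE, FALSE))
  expect_equal(qc$mr[3], 0.5)
  gm2 <- mkGM(rbind(c(0, 1, NA, 0, 0, 0, 0, 0, 0, 0)), rep("TIB", 10))
  expect_false(qcMissingAndRecall(gm2, 0.05)$pass_mr)  # MR 0.10 > 0.05
})

test_that("HWE exact test matches enumeration and handles edge cases", {
  expect_equal(hweExactTest(0, 1, 0), 1)
  expect_lt(hweExactTest(50, 0, 50), 1e-6)
  expect_equal(hweExactTest(10, 0, 0), 1)   # monomorphic
  # oracle equivalence over random genotype-count configurations, n <= 200
  set.seed(7)
  for (i in 1:60) {
    n <- sample(1:200, 1)
    nAA <- sample(0:n, 1)
    nAa <- sample(0:(n - nAA), 1)
    naa <- n - nAA - nAa
    expect_equal(hweExactTest(nAA, nAa, naa), bruteHWE(nAA, nAa, naa),
                 tolerance = 1e-10)
  }
})

test_that("HWE violation rate is calibrated under true equilibrium", {
  set.seed(11)
  nl <- 1000; n <- 120
  af <- stats::runif(nl, 0.1, 0.9)
  g <- matrix(stats::rbinom(nl * n, 2, rep(af, n)), nl, n)
  gm <- mkGM(g, rep("TIB", n))
  res <- hweFilter(gm, alpha = 0.05)
  frac <- mean(res$violates)
  # exact-test conservatism keeps the rate at or below alpha
  expect_lte(frac, 0.05 + 3 * sqrt(0.05 * 0.95 / nl))
  expect_gt(frac, 0.001)
})

test_that("dataset concordance flags only truly discordant loci", {
  # identical frequencies: no failures
  set.seed(13)
  g <- matrix(stats::rbinom(50 * 60, 2, 0.4), 50, 60)
  gm <- mkGM(g, rep("TIB", 60), rep(c("ds1", "ds2"), each = 30))
  res <- datasetConcordanceFilter(gm, alpha = 1e-3)
  expect_true(all(res$pass))
  expect_true(all(res$n_comparisons == 1))
  # fixed 0/0 vs fixed 1/1, n = 50 each: certain failure at alpha 1e-3
  g2 <- rbind(c(rep(0, 50), rep(2, 50)))
  gm2 <- mkGM(g2, rep("TIB", 100), rep(c("ds1", "ds2"), each = 50))
  res2 <- datasetConcordanceFilter(gm2, alpha = 1e-3, maxFailures = 0)
  expect_false(res2$pass)
  # a pair with no shared population is skipped
  gm3 <- mkGM(g2, rep(c("TIB", "HAN"), each = 50),
              rep(c("ds1", "ds2"), each = 50))
  res3 <- datasetConcordanceFilter(gm3, alpha = 1e-3)
  expect_equal(res3$n_comparisons, 0L)
})

test_that("per-pair concordance failure rate is near alpha under the null", {
  set.seed(17)
  nl <- 400; alpha <- 0.05
  af <- stats::runif(nl, 0.2, 0.8)
  g <- matrix(stats::rbinom(nl * 80, 2, rep(af, 80)), nl, 80)
  gm <- mkGM(g, rep("TIB", 80), rep(c("ds1", "ds2"), each = 40))
  res <- datasetConcordanceFilter(gm, alpha = alpha, maxFailures = 0)
  frac <- mean(!res$pass)
  # Fisher's exact test is conservative: failure rate <= alpha + noise
  expect_lte(frac, alpha + 3 * sqrt(alpha * (1 - alpha) / nl))
})

test_that("copy-number profiles round depth into integer CN", {
  depth <- rep(30, 1000)
  cn <- copyNumberProfile(depth, medianDepth = 30, window = 100, step = 50)
  expect_true(all(cn$cn == 2))
  expect_equal(cn$start[2] - cn$start[1], 50)
  # a 335 bp heterozygous deletion halves the depth
  depth2 <- depth
  depth2[401:735] <- 15
  cn2 <- copyNumberProfile(depth2, 30, 100, 50)
  contained <- cn2$start >= 401 & cn2$end <= 735
  expect_true(all(cn2$cn[contained] == 1))
  # homozygous loss gives CN 0
  depth3 <- depth; depth3[101:500] <- 0
  cn3 <- copyNumberProfile(depth3, 30, 100, 50)
  expect_true(all(cn3$cn[cn3$start >= 101 & cn3$end <= 500] == 0))
  expect_error(copyNumberProfile(numeric(), 30), "zero-length")
})
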