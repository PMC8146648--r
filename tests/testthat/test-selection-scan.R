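# Haplotype statistics (EHH, iHS, XP-EHH), introgression statistics
# (D, f_d, S*), empirical p-values and the per-SV classification.

test_that("EHH equals brute-force homozygous-pair counting", {
  set.seed(3)
  for (rep in 1:5) {
    m <- matrix(stats::rbinom(20 * 15, 1, 0.5), 20, 15)
    core <- 8
    if (sum(m[, core] == 1) < 2 || sum(m[, core] == 0) < 2) next
    haps <- hapFixture(m)
    curve <- ehhCurve(haps, core, coreAllele = 1, cutoff = 0)
    for (k in seq_len(nrow(curve))) {
      expect_equal(curve$ehh[k], bruteEHH(m, core, 1, curve$site[k]),
                   tolerance = 1e-12)
    }
  }
})

test_that("EHH is 1 for identical carriers and decays monotonically", {
  set.seed(4)
  m <- rbind(matrix(0L, 4, 9),                       # identical carriers
             matrix(stats::rbinom(6 * 9, 1, 0.5), 6, 9))
  m[1:4, 5] <- 1L
  m[5:10, 5] <- 0L      # only the identical rows carry the core allele
  haps <- hapFixture(m)
  curve <- ehhCurve(haps, 5, coreAllele = 1, cutoff = 0)
  expect_true(all(curve$ehh == 1))
  # monotone non-increasing away from any core
  set.seed(5)
  m2 <- matrix(stats::rbinom(30 * 40, 1, 0.4), 30, 40)
  h2 <- hapFixture(m2)
  for (core in c(10, 20, 30)) {
    if (sum(m2[, core] == 1) < 2) next
    cv <- ehhCurve(h2, core, 1, cutoff = 0)
    left <- cv$ehh[cv$direction == -1]
    right <- cv$ehh[cv$direction == 1]
    expect_true(all(diff(left) >= -1e-12))   # stored outward->inward? no:
    expect_true(all(diff(rev(right)) >= -1e-12))
  }
})

test_that("iHS is antisymmetric and zero for mirror-symmetric data", {
  set.seed(7)
  half <- matrix(stats::rbinom(10 * 21, 1, 0.5), 10, 21)
  m <- rbind(half, half)
  m[1:10, 11] <- 0L
  m[11:20, 11] <- 1L   # ancestral and derived sets are identical mirrors
  haps <- hapFixture(m)
  r <- ihs(haps, 11)
  expect_equal(r$uihs, 0, tolerance = 1e-12)
  # swapping allele labels at the core flips the sign
  m2 <- m
  m2[, 11] <- 1L - m2[, 11]
  r2 <- ihs(hapFixture(m2), 11)
  expect_equal(r2$uihs, -r$uihs, tolerance = 1e-12)
  # standardization: mean 0, sd 1 within bins
  set.seed(11)
  u <- stats::rnorm(500); daf <- stats::runif(500, 0.05, 0.95)
  z <- standardizeIHS(u, daf, nBins = 10)
  bins <- ceiling(daf * 10)
  for (b in unique(bins)) {
    idx <- which(bins == b & !is.na(z))
    expect_equal(mean(z[idx]), 0, tolerance = 1e-10)
    expect_equal(stats::sd(z[idx]), 1, tolerance = 1e-10)
  }
  expect_error(ihs(haps, 11, mafMin = 0.6), "frequency")
})

test_that("XP-EHH is zero for identical populations, antisymmetric on swap", {
  set.seed(13)
  m <- matrix(stats::rbinom(16 * 31, 1, 0.4), 16, 31)
  a <- hapFixture(m, pop = "A")
  b <- hapFixture(m, pop = "B")
  expect_equal(xpehh(a, b, 16)$uxpehh, 0, tolerance = 1e-12)
  sim <- simulateNeutral(panmicticModel(ne = 5000), c(POP = 20), 1e5,
                         seed = 3)
  h <- sim$haps
  a2 <- h[1:20, ]; b2 <- h[21:40, ]
  core <- which(derivedFreq(h) > 0.2 & derivedFreq(h) < 0.8)[5]
  ab <- xpehh(a2, b2, core)$uxpehh
  ba <- xpehh(b2, a2, core)$uxpehh
  expect_equal(ab, -ba, tolerance = 1e-12)
})

test_that("D statistic equals ABBA/BABA counting on binary fixtures", {
  # explicit pattern counts: ABBA 30, BABA 10 -> D = 0.5
  p1 <- c(rep(0, 30), rep(1, 10))
  p2 <- c(rep(1, 30), rep(0, 10))
  p3 <- rep(1, 40)
  p4 <- rep(0, 40)
  expect_equal(dStatistic(p1, p2, p3, p4)$d, 0.5)
  # equal counts cancel
  expect_equal(dStatistic(c(0, 1), c(1, 0), c(1, 1), c(0, 0))$d, 0)
  # random binary haplotypes: frequency formula = site-pattern counting
  set.seed(17)
  for (i in 1:10) {
    h <- matrix(stats::rbinom(4 * 60, 1, 0.5), 4, 60)
    keep <- h[3, ] == 1 & h[4, ] == 0 & (h[1, ] != h[2, ])
    if (!any(keep)) next
    expect_equal(dStatistic(h[1, ], h[2, ], h[3, ], h[4, ])$d,
                 bruteD(h[1, ], h[2, ], h[3, ], h[4, ]),
                 tolerance = 1e-12)
  }
  expect_true(is.na(dStatistic(0, 0, 0, 0)$d))
})

test_that("f_d follows its defining identities", {
  set.seed(19)
  p1 <- stats::runif(20, 0, 0.3)
  p23 <- stats::runif(20, 0.4, 1)
  # P2 = P3 at every site: numerator equals denominator
  expect_equal(fdStatistic(p1, p23, p23, rep(0, 20))$fd, 1)
  # zero numerator
  expect_equal(fdStatistic(c(0.5), c(0.5), c(0.5), c(0.5))$fd, 0)
  # negative numerator: undefined
  expect_true(is.na(fdStatistic(c(1), c(0), c(1), c(0))$fd))
})

test_that("S* dynamic programming matches exhaustive enumeration", {
  # arithmetic example: 3 congruent SNVs 20 kb apart
  expect_equal(sStar(c(1, 1, 1), c(0, 20000, 40000))$score,
               2 * (5000 + 20000))
  expect_equal(sStar(c(1), c(100))$score, 0)
  # chains below the minimum spacing are forbidden
  expect_equal(sStar(c(1, 1), c(100, 105))$score, 0)
  # randomized equivalence against brute force, windows of <= 12 SNVs
  set.seed(23)
  for (i in 1:25) {
    k <- sample(2:12, 1)
    pos <- sort(sample(1:50000, k))
    gt <- sample(0:2, k, replace = TRUE)
    expect_equal(sStar(gt, pos)$score, bruteSStar(gt, pos))
  }
})

test_that("empirical p-values honour sidedness and extremes", {
  null <- 1:100
  expect_equal(empiricalPValues(1000, null), 1 / 101)     # above all
  expect_equal(empiricalPValues(0, null), 1)              # below all
  expect_equal(empiricalPValues(100, null), 2 / 101)      # ties counted
  expect_equal(empiricalPValues(-50, c(-1, 1), side = "two.sided"),
               1 / 3)
  expect_error(empiricalPValues(1, numeric()), "empty null")
  # held-out calibration: p-values of null draws are uniform
  set.seed(29)
  null2 <- stats::rnorm(400)
  held <- stats::rnorm(400)
  p <- empiricalPValues(held, null2)
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("classification combines selection and introgression correctly", {
  win <- data.frame(start = c(1, 50001), end = c(50000, 100000),
                    p_ihs = c(0.01, 0.5), p_xpehh = c(0.2, 0.9),
                    p_d = c(0.03, 0.6), p_fd = c(0.04, 0.7),
                    p_sstar = c(0.02, 0.8))
  svs <- data.frame(locus_id = c("sv1", "sv2"), pos = c(25000, 99000))
  res <- classifyAdaptation(svs, win, radius = 10000, alpha = 0.05)
  expect_equal(res$class, c("adaptive-introgressed", "none"))
  # selection-only when introgression stats are not jointly significant
  win2 <- win; win2$p_fd[1] <- 0.5
  res2 <- classifyAdaptation(svs[1, ], win2, radius = 10000)
  expect_equal(res2$class, "selection-only")
  # introgression-only
  win3 <- win; win3$p_ihs[1] <- 0.9
  res3 <- classifyAdaptation(svs[1, ], win3, radius = 10000)
  expect_equal(res3$class, "introgression-only")
  # all three introgression statistics must be significant together
  win4 <- win; win4$p_ihs[1] <- 0.9; win4$p_sstar[1] <- 0.9
  expect_equal(classifyAdaptation(svs[1, ], win4,
                                  radius = 10000)$class, "none")
  # an SV on an unscanned chromosome warns and returns none
  svs2 <- data.frame(locus_id = "sv3", pos = 100, chrom = "chr9")
  expect_warning(res4 <- classifyAdaptation(svs2, win, radius = 1e4),
                 "no scanned windows")
  expect_equal(res4$class, "none")
})

test_that("sStarCandidates restricts to archaic-like variants", {
  m <- rbind(c(1, 0, 1, 0),   # target sample (2 haplotypes)
             c(1, 0, 0, 0),
             c(0, 0, 0, 1),   # outgroup carries the derived allele at 4
             c(0, 0, 0, 0))
  haps <- HaplotypeMatrix(m, c(100, 5000, 20000, 40000),
                          samples = c("t1", "t1", "o1", "o1"),
                          populations = c("TIB", "TIB", "AFR", "AFR"))
  cand <- sStarCandidates(haps, "t1", "AFR")
  # site 2 not carried by the individual, site 4 present in the outgroup
  expect_equal(cand$sites, c(1L, 3L))
  expect_equal(cand$genotypes, c(2, 1))
})
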