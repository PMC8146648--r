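# Annotation: junction intersection, permutation enrichment, mechanism
# classification, functional consequence, and loop-anchor rules.

library(GenomicRanges)

mkLoci <- function(start, end, svtype, len = end - start + 1) {
  GRanges("chr1", IRanges(start, pmax(start, end)),
          locus_id = sprintf("SV%03d", seq_along(start)),
          svtype = svtype, svlen = len)
}

test_that("junction intersection recovers planted overlaps exactly", {
  track <- GRanges("chr1", IRanges(c(1000, 8000, 20000),
                                   c(1500, 8400, 26000)),
                   class = c("SINE", "SINE", "LINE"))
  loci <- mkLoci(c(1200, 8350, 50000), c(5000, 8360, 50000),
                 c("DEL", "DEL", "INS"))
  labs <- intersectTracks(loci, track, junctionWindow = 50)
  expect_equal(labs[["SV001"]], "SINE")   # start junction inside SINE
  expect_equal(labs[["SV002"]], "SINE")   # both junctions inside one SINE
  expect_equal(labs[["SV003"]], character())
  # empty track: nothing
  expect_true(all(lengths(intersectTracks(loci, GRanges())) == 0))
  # window widens the reach: DEL end 5000 is 3000 away from nothing;
  # a junction 40 bp outside an interval is caught at window 50
  loci2 <- mkLoci(1540, 2000, "DEL")
  expect_equal(intersectTracks(loci2, track, 50)[[1]], "SINE")
  expect_equal(length(intersectTracks(loci2, track, 10)[[1]]), 0)
})

test_that("enrichment is extreme for planted loci and null for none", {
  set.seed(42)
  track <- GRanges("chr1", IRanges(seq(1000, 99000, by = 2000), width = 500),
                   class = "SINE")
  # loci planted only inside SINE intervals
  inSine <- mkLoci(start(track)[1:20] + 100, start(track)[1:20] + 200,
                   rep("DEL", 20))
  enr <- permutationEnrichment(inSine, track, c(chr1 = 1e5), nPerm = 199,
                               seed = 1, junctionWindow = 10)
  expect_equal(enr$p[enr$label == "SINE"], 1 / 200)
  expect_gt(enr$fc[enr$label == "SINE"], 1)
  expect_equal(enr$lfc, log2(enr$fc))
  expect_equal(enr$p_adj, pmin(1, enr$p * nrow(enr)))
})

test_that("mechanism classification follows the stated precedence", {
  repeats <- GRanges("chr1",
                     IRanges(c(990, 2000, 5000, 5900, 7000),
                             c(1100, 2200, 5120, 6050, 7300)),
                     class = c("SINE", "LINE", "SINE", "SINE", "LINE"))
  tandem <- GRanges("chr1", IRanges(3000, 4000))
  loci <- mkLoci(c(1050, 3100, 5050, 9000, 9500),
                 c(2100, 3800, 6000, 9000, 9700),
                 c("DEL", "DEL", "DEL", "INS", "DEL"))
  insLabels <- c(SV004 = "LINE")
  mech <- classifyMechanism(loci, repeats, tandem, insLabels,
                            junctionWindow = 50)
  expect_equal(mech$mechanism,
               c("unclassified",  # SINE / LINE flanks: different classes
                 "VNTR",          # contained in the tandem repeat
                 "NAHR",          # SINE at both junctions
                 "TE",            # inserted sequence labelled LINE
                 "unclassified")) # no repeat context
  # VNTR outranks NAHR: deletion inside a tandem repeat that also has
  # matching flanking repeats stays VNTR
  tandem2 <- GRanges("chr1", IRanges(4900, 6100))
  mech2 <- classifyMechanism(loci[3], repeats, tandem2)
  expect_equal(mech2$mechanism, "VNTR")
  # every DEL/INS gets exactly one class
  expect_true(all(table(mech$locus_id) == 1))
  # INS without an inserted-sequence label: TE test skipped, noted
  mech3 <- classifyMechanism(loci[4], repeats, tandem)
  expect_equal(mech3$mechanism, "unclassified")
  expect_match(mech3$evidence, "skipped")
})

test_that("functional consequence distinguishes planted classes", {
  genes <- list(
    genes = GRanges("chr1", IRanges(10000, 30000), gene = "gene001"),
    exons = GRanges("chr1", IRanges(c(10000, 20000), c(10500, 20500)),
                    gene = "gene001"),
    introns = GRanges("chr1", IRanges(10501, 19999)),
    tss = GRanges("chr1", IRanges(10000, 10000), gene = "gene001"))
  loci <- mkLoci(c(10200, 12000, 50000, 20100),
                 c(10800, 13000, 50400, 20100),
                 c("DEL", "DEL", "DEL", "INS"))
  fc <- functionalConsequence(loci, genes,
                              lofIntolerant = "gene001")
  expect_equal(fc$consequence,
               c("LoF", "intronic", "intergenic", "LoF"))
  expect_equal(fc$tss_distance[1], 200)
  expect_true(all(fc$intolerant))
  # DUP over an exon is coding-other, not LoF
  dup <- mkLoci(9000, 11000, "DUP")
  expect_equal(functionalConsequence(dup, genes)$consequence,
               "coding-other")
})

test_that("loop-anchor rules match hand-derived truth", {
  loops <- data.frame(chrom = "chr1",
                      start1 = c(10000, 40000, 70000),
                      end1 = c(15000, 45000, 75000),
                      start2 = c(100000, 140000, 170000),
                      end2 = c(105000, 145000, 175000))
  tss <- GRanges("chr1", IRanges(c(101000, 141000, 50000), width = 1),
                 gene = c("geneA", "geneB", "geneC"))
  svs <- mkLoci(c(12000, 46000, 200000),
                c(13000, 46000, 201000),
                c("DEL", "INS", "DEL"))
  res <- apply3DRules(svs, loops, tss, anchorProximity = 10000)
  # DEL over anchor 1 of loop1 removes it; geneA TSS is in the partner
  expect_equal(res$effect[1], "removed")
  expect_equal(res$interactions[1], "loop001")
  expect_equal(res$genes[1], "geneA")
  # INS 1 kb from loop2's anchor duplicates it; geneB affected
  expect_equal(res$effect[2], "created")
  expect_equal(res$genes[2], "geneB")
  # distant DEL: no effect
  expect_equal(res$effect[3], "none")
  # inter-chromosomal anchors are rejected
  badLoops <- data.frame(chrom1 = "chr1", chrom2 = "chr2",
                         start1 = 1, end1 = 10, start2 = 1, end2 = 10)
  expect_error(apply3DRules(svs, badLoops, tss), "chromosom")
})
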