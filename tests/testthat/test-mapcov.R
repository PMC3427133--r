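mkAln <- function(aligned, matches, readLength, gaps = 0L, strand = "+",
                  contig = "c1", read = "r1", tStart = 1L) {
  blockAlignments(read, contig, strand, qStart = 1L, tStart = tStart,
                  blockLen = aligned, matches = matches,
                  gaps = gaps, readLength = readLength)
}

test_that("the 40%/96% validity rule is inclusive and matches the worked case", {
  # 88-bp read with 35 aligned, 34 matching: 35/88 < 0.40 -> invalid
  expect_false(isValidAlignment(mkAln(35, 34, 88)))
  # exactly at both boundaries -> valid
  expect_true(isValidAlignment(mkAln(40, 39, 100)))
  expect_true(all(isValidAlignment(mkAln(40, 40, 100))))
  # full-length but 95% identity -> invalid
  expect_false(isValidAlignment(mkAln(100, 95, 100)))
  # exactly 96% identity passes
  expect_true(isValidAlignment(mkAln(100, 96, 100)))
})

test_that("the validity filter is monotone in both thresholds", {
  set.seed(51)
  for (i in 1:50) {
    ab <- sample(20:100, 1)
    a <- mkAln(ab, sample(ceiling(0.9 * ab):ab, 1), 100)
    base <- isValidAlignment(a, 0.40, 0.96)
    expect_true(!isValidAlignment(a, 0.50, 0.96) || base)
    expect_true(!isValidAlignment(a, 0.40, 0.98) || base)
  }
})

test_that("pileups add depth per covered base, complementing minus strands", {
  set.seed(52)
  ctg <- setNames(randomDnaStr(120), "c1")
  r1 <- setNames(substr(ctg, 11, 60), "r1")
  r2 <- setNames(substr(ctg, 41, 90), "r2")
  aln <- alignReads(c(r1, r2), ctg)
  pu <- buildPileup(aln, c(r1, r2), ctg)
  d <- pileupDepth(pu, "c1")
  expect_equal(d[1:10], rep(0L, 10))
  expect_equal(d[11:40], rep(1L, 30))
  expect_equal(d[41:60], rep(2L, 20))
  expect_equal(d[61:90], rep(1L, 30))
  # a minus-strand read contributes its reverse complement in contig space
  r3 <- setNames(revComp(substr(ctg, 11, 60)), "r3")
  aln3 <- alignReads(r3, ctg)
  expect_equal(alnTable(aln3)$strand, "-")
  pu3 <- buildPileup(aln3, r3, ctg)
  bc <- baseCounts(pu3, "c1")
  ref <- strsplit(unname(ctg), "")[[1]]
  hit <- vapply(11:60, function(p)
    bc[match(ref[p], c("A", "C", "G", "T")), p], integer(1))
  expect_true(all(hit == 1L))
  expect_error(buildPileup(aln, c(r1, r2), setNames(unname(ctg), "other")),
               "unknown contig")
})

test_that("pileup depth equals a per-read interval-stabbing oracle", {
  sim <- simulateDiploidTranscriptome(nContigs = 4, seed = 53)
  gr <- simulateGenomicReads(sim$haplotypes, coverage = 8, readLength = 60,
                             errorRate = 0, seed = 54)
  aln <- filterValidAlignments(truthAlignments(gr, sim))
  pu <- buildPileup(aln, gr$reads, sim$reference)
  for (ct in names(sim$reference)[1:2]) {
    expect_equal(pileupDepth(pu, ct),
                 depthOracle(aln, width(sim$reference)[match(ct, names(sim$reference))], ct))
  }
})

test_that("mean coverage follows the top-hit rule and excludes gapped hits", {
  ctg <- c(c1 = strrep("A", 1000), c2 = strrep("C", 500))
  aln <- blockAlignments(
    readId = c(sprintf("r%02d", 1:10), "r11", "r11", "r12"),
    contigId = c(rep("c1", 10), "c1", "c2", "c2"),
    strand = "+",
    qStart = as.list(rep(1L, 13)),
    tStart = as.list(rep(1L, 13)),
    blockLen = as.list(rep(100L, 13)),
    matches = c(rep(100L, 10), 100L, 100L, 90L),
    readLength = rep(100L, 13))
  cov <- contigMeanCoverage(aln, ctg)
  # r11 maps to both with equal score: first listed (c1) wins
  expect_equal(unname(cov["c1"]), 1100 / 1000)
  expect_equal(unname(cov["c2"]), 100 / 500)
  # gapped alignments are excluded from coverage
  g <- blockAlignments("r13", "c2", "+", qStart = list(c(1L, 51L)),
                       tStart = list(c(1L, 61L)), blockLen = list(c(50L, 50L)),
                       matches = 100L, readLength = 100L)
  tb <- rbind(alnTable(aln), alnTable(g))
  cov2 <- contigMeanCoverage(new("BlockAlignments", table = tb), ctg)
  expect_equal(cov2, cov)
  # no mapped reads -> zero coverage
  expect_equal(unname(contigMeanCoverage(alignReads(
    setNames(randomDnaStr(50), "rx"), ctg), ctg)["c2"]), 0)
})

test_that("modal coverage rounds, excludes zeros and breaks ties low", {
  expect_equal(modalCoverage(c(23.6, 24.2, 24.4, 7.1)), 24L)
  expect_equal(modalCoverage(c(10, 20)), 10L)
  expect_equal(modalCoverage(c(0, 0, 12, 12.4, 3)), 12L)
  expect_error(modalCoverage(c(0, 0)), "positive coverage")
})

test_that("genome size is total bases over modal coverage, scale-equivariant", {
  expect_equal(estimateGenomeSize(10100, 24), 10100 / 24)
  expect_equal(round(estimateGenomeSize(10100, 24)), 421)
  expect_equal(estimateGenomeSize(24, 24), 1)
  expect_error(estimateGenomeSize(100, 0), "modal coverage")
  # doubling read counts doubles total bases and modal coverage alike
  means <- c(11.8, 12.2, 12.1, 6.3)
  est1 <- estimateGenomeSize(1e6, modalCoverage(means))
  est2 <- estimateGenomeSize(2e6, modalCoverage(2 * means))
  expect_equal(est2, est1)
})

test_that("simulated uniform coverage recovers its own depth as the mode", {
  sim <- simulateDiploidTranscriptome(nContigs = 60, snvRate = 0,
                                      indelRate = 0, seed = 55)
  gr <- simulateGenomicReads(sim$haplotypes["A"], coverage = 24,
                             readLength = 100, errorRate = 0, pad = 0,
                             seed = 56)
  aln <- filterValidAlignments(alignReads(gr$reads, sim$reference))
  cov <- contigMeanCoverage(aln, sim$reference)
  expect_equal(modalCoverage(cov), 24L)
})
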