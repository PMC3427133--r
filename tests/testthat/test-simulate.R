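test_that("zero SNV rate yields identical haplotypes and an empty truth", {
  sim <- simulateDiploidTranscriptome(nContigs = 10, snvRate = 0,
                                      indelRate = 0, seed = 3)
  expect_identical(as.character(sim$haplotypes$A),
                   as.character(sim$haplotypes$B))
  expect_length(truthVariants(sim$truth), 0L)
})

test_that("planted SNV count matches the binomial expectation at 1 Mb", {
  sim <- simulateDiploidTranscriptome(totalBp = 1e6, indelRate = 0, seed = 8)
  L <- sum(width(sim$reference))
  nSnv <- sum(truthVariants(sim$truth)$type == "snv")
  expected <- L / 808
  sdev <- sqrt(L * (1 / 808) * (1 - 1 / 808))
  expect_lt(abs(nSnv - expected), 3 * sdev)
})

test_that("extreme Ts/Tv ratio plants only transitions", {
  sim <- simulateDiploidTranscriptome(nContigs = 30, tstvRatio = 1e9,
                                      indelRate = 0, seed = 4)
  v <- truthVariants(sim$truth)
  expect_true(all(v$class == "transition"))
  expect_true(all(paste0(v$ref, v$alt) %in% c("AG", "GA", "CT", "TC")))
})

test_that("planted transition fraction converges to tstv/(1+tstv)", {
  sim <- simulateDiploidTranscriptome(totalBp = 1e6, indelRate = 0, seed = 15)
  v <- truthVariants(sim$truth)
  p <- 1.6 / 2.6
  frac <- mean(v$class == "transition")
  sdev <- sqrt(p * (1 - p) / length(v))
  expect_lt(abs(frac - p), 3 * sdev)
})

test_that("indel sizes follow the weights and avoid contig ends", {
  sim <- simulateDiploidTranscriptome(totalBp = 5e5, indelRate = 1 / 800,
                                      seed = 5)
  v <- truthVariants(sim$truth)
  ind <- v[v$class == "indel"]
  expect_gt(length(ind), 100)
  expect_true(all(ind$len >= 1 & ind$len <= 8))
  # monotone frequency: size 1 strictly dominates sizes >= 4
  tab <- tabulate(ind$len, 8)
  expect_true(all(tab[1] > tab[4:8]))
  lens <- setNames(width(sim$reference),
                   names(sim$reference))[as.character(seqnames(ind))]
  expect_true(all(start(ind) >= 100 & start(ind) <= lens - 100))
})

test_that("simulated reads cover the haplotypes at the requested depth", {
  sim <- simulateDiploidTranscriptome(nContigs = 20, seed = 6)
  gr <- simulateGenomicReads(sim$haplotypes, coverage = 12, readLength = 80,
                             errorRate = 0, pad = 0, seed = 7)
  L <- sum(width(sim$haplotypes$A)) + sum(width(sim$haplotypes$B))
  totalBases <- sum(width(gr$reads))
  expect_lt(abs(totalBases - 12 * L) / (12 * L), 0.02)
})

test_that("error-free reads are exact substrings of their padded haplotype", {
  sim <- simulateDiploidTranscriptome(nContigs = 5, seed = 9)
  gr <- simulateGenomicReads(sim$haplotypes, coverage = 3, readLength = 60,
                             errorRate = 0, seed = 10)
  prov <- gr$provenance
  idx <- sample(nrow(prov), 50)
  for (i in idx) {
    hap <- gr$paddedHaplotypes[[prov$hap[i]]][[prov$contig[i]]]
    expected <- substr(hap, prov$start[i], prov$start[i] + prov$readLength[i] - 1L)
    got <- as.character(gr$reads[[prov$readId[i]]])
    if (prov$strand[i] == "-") got <- revComp(got)
    expect_identical(got, expected)
  }
})

test_that("read simulation is byte-identical under a fixed seed", {
  sim <- simulateDiploidTranscriptome(nContigs = 5, seed = 2)
  a <- simulateGenomicReads(sim$haplotypes, coverage = 4, seed = 42)
  b <- simulateGenomicReads(sim$haplotypes, coverage = 4, seed = 42)
  fa <- withr::local_tempfile(fileext = ".fq")
  fb <- withr::local_tempfile(fileext = ".fq")
  writeReads(a$reads, fa); writeReads(b$reads, fb)
  expect_identical(readLines(fa), readLines(fb))
})

test_that("read length exceeding every padded sequence is a config error", {
  sim <- simulateDiploidTranscriptome(nContigs = 3, seed = 2)
  expect_error(simulateGenomicReads(sim$haplotypes, coverage = 1,
                                    readLength = 10000L, pad = 0),
               "shortest")
})

test_that("Sanger pairs come from opposite ends of one contig, reproducibly", {
  set.seed(1)
  ctg <- DNAStringSet(c(big1 = randomDnaStr(2000), big2 = randomDnaStr(2500)))
  sp <- simulateSangerPairs(ctg, nPairs = 20, insertMean = 1900,
                            insertSd = 50, readLength = 400, seed = 31)
  for (i in seq_len(5)) {
    src <- as.character(ctg[[sp$truth$contig[i]]])
    fwd <- as.character(sp$reads[[sp$pairs$fwd[i]]])
    rev <- as.character(sp$reads[[sp$pairs$rev[i]]])
    expect_true(grepl(fwd, src, fixed = TRUE))       # plus strand, 5' end
    expect_true(grepl(revComp(rev), src, fixed = TRUE))  # minus strand, 3' end
  }
  sp2 <- simulateSangerPairs(ctg, nPairs = 20, insertMean = 1900,
                             insertSd = 50, readLength = 400, seed = 31)
  expect_identical(as.character(sp$reads), as.character(sp2$reads))
  expect_error(simulateSangerPairs(ctg[width(ctg) < 100], nPairs = 5),
               "long enough")
})

test_that("hairpin injection appends the reverse complement of the tail arm", {
  hp <- injectHairpin("ACGTACGT", 8)
  expect_equal(hp$contig, paste0("ACGTACGT", revComp("ACGTACGT")))
  expect_equal(hp$apex, 8L)
  expect_equal(nchar(hp$contig), 16L)
  hp0 <- injectHairpin("ACGTACGT", 0)
  expect_equal(hp0$contig, "ACGTACGT")
  expect_true(is.na(hp0$apex))
})

test_that("truth tables round-trip through TSV", {
  sim <- simulateDiploidTranscriptome(nContigs = 20, seed = 12)
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeTruthTable(sim$truth, tf)
  back <- readTruthTable(tf)
  v <- truthVariants(sim$truth)
  expect_equal(length(back), length(v))
  expect_equal(start(back), start(v))
  expect_equal(back$alt, v$alt)
})
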