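# build a pileup for one short contig directly from synthetic reads
pileFromReads <- function(ctg, reads, tStarts) {
  aln <- blockAlignments(names(reads), "c1", "+",
                         qStart = as.list(rep(1L, length(reads))),
                         tStart = as.list(as.integer(tStarts)),
                         blockLen = as.list(nchar(reads)),
                         matches = nchar(reads),
                         readLength = nchar(reads))
  buildPileup(aln, reads, ctg)
}

test_that("SNV calls respect the 10x depth and 35% fraction floors inclusively", {
  ctg <- c(c1 = strrep("A", 30))
  mk <- function(nRef, nAlt) {
    reads <- setNames(c(rep(strrep("A", 10), nRef), rep(strrep("G", 10), nAlt)),
                      sprintf("r%02d", seq_len(nRef + nAlt)))
    pileFromReads(ctg, reads, rep(11L, nRef + nAlt))
  }
  # depth 10, alt 4/10 = 0.40 -> called
  calls <- callVariants(mk(6, 4), ctg)
  expect_equal(length(calls), 10L)  # every covered position is an A/G site
  expect_true(all(calls$alt == "G" & calls$depth == 10L))
  # depth 9 at 0.44 -> no call
  expect_length(callVariants(mk(5, 4), ctg), 0L)
  # exactly 35%: 7/20 -> called; just below: 6/20 off by one -> not
  expect_length(callVariants(mk(13, 7), ctg), 10L)
  expect_length(callVariants(mk(14, 6), ctg), 0L)
})

test_that("ties between alternative bases break alphabetically", {
  ctg <- c(c1 = strrep("A", 12))
  reads <- setNames(c(rep(strrep("A", 12), 3), rep(strrep("T", 12), 4),
                      rep(strrep("G", 12), 4)),
                    sprintf("r%02d", 1:11))
  calls <- callVariants(pileFromReads(ctg, reads, rep(1L, 11)), ctg)
  expect_true(all(calls$alt == "G"))   # G before T
  expect_true(all(calls$refMinority))  # reference at 3/11 is itself a minority
})

test_that("substitution classes enumerate 4 transitions and 8 transversions", {
  bases <- c("A", "C", "G", "T")
  pairs <- expand.grid(ref = bases, alt = bases, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ref != pairs$alt, ]
  cls <- classifySubstitution(pairs$ref, pairs$alt)
  expect_equal(sum(cls == "transition"), 4L)
  expect_equal(sum(cls == "transversion"), 8L)
  expect_equal(classifySubstitution("A", "G"), "transition")
  expect_equal(classifySubstitution("G", "C"), "transversion")
  expect_error(classifySubstitution("A", "A"), "differ")
  expect_error(classifySubstitution("A", "N"), "bases")
})

test_that("error-free haploid data yields no variant calls", {
  sim <- simulateDiploidTranscriptome(nContigs = 10, snvRate = 0,
                                      indelRate = 0, seed = 61)
  gr <- simulateGenomicReads(sim$haplotypes, coverage = 15, errorRate = 0,
                             seed = 62)
  aln <- filterValidAlignments(truthAlignments(gr, sim))
  calls <- callVariants(buildPileup(aln, gr$reads, sim$reference),
                        sim$reference)
  expect_length(calls, 0L)
})

test_that("calls never violate the floors and shrink as thresholds rise", {
  run <- smallVariantRun(totalBp = 1.5e5, coverage = 12, errorRate = 0.005,
                         seed = 63)
  pu <- buildPileup(filterValidAlignments(truthAlignments(run$reads, run$sim)),
                    run$reads$reads, run$sim$reference)
  calls <- callVariants(pu, run$sim$reference)
  expect_true(all(calls$depth >= 10L))
  expect_true(all(calls$altFraction >= 0.35))
  stricter <- callVariants(pu, run$sim$reference, minFrac = 0.45)
  expect_lte(length(stricter), length(calls))
  key <- function(x) paste(seqnames(x), start(x), x$alt)
  expect_true(all(key(stricter) %in% key(calls)))
})

test_that("planted SNVs are recovered on clean simulated data", {
  run <- smallVariantRun(totalBp = 3e5, coverage = 20, errorRate = 0,
                         seed = 64)
  sc <- scoreSnvCalls(run$calls, truthVariants(run$sim$truth))
  expect_gte(sc$recall, 0.95)
  expect_gte(sc$precision, 0.99)
  ind <- truthVariants(run$sim$truth)
  ind <- ind[ind$class == "indel"]
  indC <- run$calls[run$calls$class == "indel"]
  hit <- findOverlaps(indC, ind)
  expect_gte(length(unique(subjectHits(hit))), 0.9 * length(ind))
})

test_that("variant summaries tabulate classes, density and indel sizes", {
  expect_equal(snvDensity(44.7e6, 55300), 808)
  expect_equal(snvDensity(1000, 1), 1000)
  expect_true(is.na(snvDensity(1000, 0)))
  gr <- GRanges(rep("c1", 8), IRanges(1:8, width = 1),
                type = c(rep("SNV", 3), rep("insertion", 3), rep("deletion", 2)),
                ref = c("A", "C", "G", rep("A", 5)),
                alt = c("G", "T", "C", "+A", "+AA", "+AT", "-AC", "-ACGTACGTA"),
                class = c("transition", "transition", "transversion",
                          rep("indel", 5)),
                depth = 20L, altCount = 10L, altFraction = 0.5,
                len = c(1L, 1L, 1L, 1L, 2L, 2L, 8L, 9L),
                refMinority = FALSE)
  vs <- summarizeVariants(gr, 3000)
  expect_equal(unname(snvClassCounts(vs)[c("A/G", "C/T", "G/C")]),
               c(1L, 1L, 1L))
  expect_equal(sum(snvClassCounts(vs)), 3L)
  expect_equal(unname(indelSizeHist(vs)[c("1", "2", "8", ">8")]),
               c(1L, 2L, 1L, 1L))
  expect_equal(sum(indelSizeHist(vs)), 5L)
  expect_equal(bpPerSnv(vs), 1000)
})

test_that("VCF output is left-anchored, 1-based, and read back intact", {
  skip_if_not_installed("VariantAnnotation")
  ctg <- c(c1 = paste0(strrep("A", 99), "C", strrep("G", 20)))
  calls <- GRanges(rep("c1", 3), IRanges(c(10L, 100L, 110L), width = 1),
                   type = c("deletion", "SNV", "insertion"),
                   ref = c("A", "C", "G"),
                   alt = c("-AA", "T", "+TT"),
                   class = c("indel", "transversion", "indel"),
                   depth = c(20L, 30L, 25L), altCount = c(9L, 15L, 10L),
                   altFraction = c(0.45, 0.5, 0.4),
                   len = c(2L, 1L, 2L), refMinority = FALSE)
  tf <- withr::local_tempfile(fileext = ".vcf")
  writeVariantVcf(calls, ctg, tf)
  v <- VariantAnnotation::readVcf(tf)
  rr <- SummarizedExperiment::rowRanges(v)
  expect_equal(BiocGenerics::start(rr), c(10L, 100L, 110L))
  expect_equal(as.character(rr$REF), c("AAA", "C", "G"))
  expect_equal(as.character(unlist(rr$ALT)), c("A", "T", "GTT"))
  expect_equal(VariantAnnotation::info(v)$DP, c(20L, 30L, 25L))
  expect_error(writeVariantVcf(rev(calls), ctg, tf), "sorted")
})
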