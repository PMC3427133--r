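# Shared fixture builders and independent oracles. Everything is generated
# in code; no data files.

suppressPackageStartupMessages({
  library(Biostrings)
  library(GenomicRanges)
})

randomDnaStr <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

qreads <- function(seqs, quals = NULL) {
  if (is.null(quals)) quals <- strrep("I", nchar(seqs))
  if (is.numeric(quals[[1]]) || is.list(quals))
    quals <- vapply(quals, function(q) rawToChar(as.raw(q + 33L)), character(1))
  if (is.null(names(seqs))) names(seqs) <- sprintf("r%03d", seq_along(seqs))
  QualityScaledDNAStringSet(DNAStringSet(seqs),
                            PhredQuality(BStringSet(quals)))
}

# brute-force local alignment score by dynamic programming
# (match +1, mismatch -1, gap open/extend -2); the independent oracle for
# the seed-and-extend mapper on small instances
swScore <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  H <- matrix(0, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (x[i] == y[j]) match else mismatch
      H[i + 1, j + 1] <- max(0, H[i, j] + s, H[i, j + 1] + gap,
                             H[i + 1, j] + gap)
      best <- max(best, H[i + 1, j + 1])
    }
  }
  best
}

# per-position depth by direct interval stabbing over alignment blocks
depthOracle <- function(aln, contigLen, contig) {
  tb <- alnTable(aln)
  d <- integer(contigLen)
  for (i in seq_len(nrow(tb))) {
    if (tb$contigId[i] != contig) next
    ts <- tb$tStart[[i]]; bl <- tb$blockLen[[i]]
    for (j in seq_along(ts)) {
      idx <- ts[j]:(ts[j] + bl[j] - 1L)
      d[idx] <- d[idx] + 1L
    }
  }
  d
}

# score SNV calls against a planted truth table
scoreSnvCalls <- function(calls, truth) {
  snvT <- truth[truth$type == "snv"]
  snvC <- calls[calls$type == "SNV"]
  hit <- findOverlaps(snvC, snvT)
  ok <- snvC$alt[queryHits(hit)] == snvT$alt[subjectHits(hit)]
  tp <- length(unique(subjectHits(hit)[ok]))
  list(planted = length(snvT), called = length(snvC), tp = tp,
       recall = tp / max(length(snvT), 1L),
       precision = sum(ok) / max(length(snvC), 1L))
}

# run the read-cleaning + variant-calling pipeline on a small simulation
smallVariantRun <- function(totalBp, coverage, errorRate, seed) {
  sim <- simulateDiploidTranscriptome(totalBp = totalBp, seed = seed)
  gr <- simulateGenomicReads(sim$haplotypes, coverage = coverage,
                             readLength = 100L, errorRate = errorRate,
                             seed = seed + 1L)
  aln <- filterValidAlignments(truthAlignments(gr, sim))
  pu <- buildPileup(aln, gr$reads, sim$reference)
  calls <- callVariants(pu, sim$reference)
  list(sim = sim, reads = gr, calls = calls,
       totalBp = sum(width(sim$reference)))
}
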