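# encode a protein as DNA using the first codon of the standard code
codonFor <- function(aa) {
  names(Biostrings::GENETIC_CODE)[match(aa, Biostrings::GENETIC_CODE)]
}
encodeProtein <- function(prot, stop = TRUE) {
  paste(c(vapply(strsplit(prot, "")[[1]], codonFor, character(1)),
          if (stop) "TAA"), collapse = "")
}

test_that("ORF finding translates all six frames, stop-to-stop", {
  orfs <- findOrfs("ATGAAATGA", minAa = 1)
  expect_true(any(orfs$protein == "MK" & orfs$frame == 1L &
                    orfs$start == 1L & orfs$end == 6L))
  # a coding contig and its reverse complement give the same protein set
  set.seed(81)
  nt <- encodeProtein("MLKTEEDRRGW")
  fwd <- findOrfs(nt, minAa = 5)
  rev <- findOrfs(revComp(nt), minAa = 5)
  expect_setequal(fwd$protein, rev$protein)
  expect_true("MLKTEEDRRGW" %in% fwd$protein)
})

test_that("six-frame output equals a brute-force translation oracle", {
  set.seed(82)
  for (rep in 1:5) {
    nt <- randomDnaStr(240)
    got <- findOrfs(nt, minAa = 8)
    # oracle: translate each frame, split on stops, keep segments >= 8 aa
    expected <- character(0)
    for (fr in 1:3) {
      for (s in c(nt, revComp(nt))) {
        usable <- nchar(s) - fr + 1
        usable <- usable - usable %% 3
        if (usable < 3) next
        aa <- as.character(Biostrings::translate(Biostrings::DNAString(
          substr(s, fr, fr + usable - 1)), if.fuzzy.codon = "X"))
        segs <- strsplit(aa, "*", fixed = TRUE)[[1]]
        expected <- c(expected, segs[nchar(segs) >= 8])
      }
    }
    expect_setequal(got$protein, expected)
  }
})

test_that("GLW motif grammar classifies by the following residues", {
  prot <- paste0("MSEKR", "AAGLWG", "KRSS", "AAGLWCG", "KRSS", "AAGLWCS",
                 "KRSS", "AAGLWT", "KR", strrep("S", 30))
  orfs <- S4Vectors::DataFrame(contig = "c", frame = 1L, start = 1L,
                               end = 3L * nchar(prot), protein = prot)
  hits <- scanGlwPrecursors(orfs, minMotifs = 4)
  expect_equal(nrow(hits), 1L)
  expect_equal(unlist(hits$motifClass[[1]]),
               c("amidated", "cys-amidated", "cys-unamidated", "other"))
  # motif positions index exact GLW occurrences
  mp <- unlist(hits$motifPos[[1]])
  expect_true(all(substring(prot, mp, mp + 2) == "GLW"))
  # below the motif floor there is no hit
  expect_equal(nrow(scanGlwPrecursors(orfs, minMotifs = 5)), 0L)
})

test_that("mature peptides follow the processing grammar, hand-traced", {
  # fragment APAPEQPGLWG: amide G consumed, two X-P dipeptides trimmed
  prot <- paste0("M", strrep("S", 20), "KRAPAPEQPGLWGKR", strrep("S", 20))
  orfs <- S4Vectors::DataFrame(contig = "c", frame = 1L, start = 1L,
                               end = 3L * nchar(prot), protein = prot)
  hits <- scanGlwPrecursors(orfs, minMotifs = 1)
  pep <- predictMaturePeptides(hits[1, ])
  expect_equal(pep$sequence, "EQPGLW")
  expect_true(pep$cTerminalAmide)
  expect_false(pep$nTerminalPyroglu)
  expect_equal(pep$display, "EQPGLW-NH2")

  # a leading glutamine becomes pyroglutamate and blocks X-P trimming
  prot2 <- paste0("M", strrep("S", 20), "KRQPIGLWGKR", strrep("S", 20))
  hits2 <- scanGlwPrecursors(S4Vectors::DataFrame(
    contig = "c", frame = 1L, start = 1L, end = 3L * nchar(prot2),
    protein = prot2), minMotifs = 1)
  pep2 <- predictMaturePeptides(hits2[1, ])
  expect_equal(pep2$sequence, "QPIGLW")
  expect_true(pep2$nTerminalPyroglu)
  expect_equal(pep2$display, "pEPIGLW-NH2")

  # cysteine-extended unamidated motif: no amide, peptide ends in GLWC
  prot3 <- paste0("M", strrep("S", 20), "KRTEGLWCKR", strrep("S", 20))
  hits3 <- scanGlwPrecursors(S4Vectors::DataFrame(
    contig = "c", frame = 1L, start = 1L, end = 3L * nchar(prot3),
    protein = prot3), minMotifs = 1)
  pep3 <- predictMaturePeptides(hits3[1, ])
  expect_equal(pep3$sequence, "TEGLWC")
  expect_false(pep3$cTerminalAmide)
  expect_equal(pep3$display, "TEGLWC")

  # no X-A/X-P prefix: trimming is a no-op
  prot4 <- paste0("M", strrep("S", 20), "KRTEDGLWGKR", strrep("S", 20))
  hits4 <- scanGlwPrecursors(S4Vectors::DataFrame(
    contig = "c", frame = 1L, start = 1L, end = 3L * nchar(prot4),
    protein = prot4), minMotifs = 1)
  expect_equal(predictMaturePeptides(hits4[1, ])$sequence, "TEDGLW")

  # missing flanking basic residue: motif skipped with a warning
  prot5 <- paste0("M", strrep("S", 20), "TEGLWGKR", strrep("S", 20))
  hits5 <- scanGlwPrecursors(S4Vectors::DataFrame(
    contig = "c", frame = 1L, start = 1L, end = 3L * nchar(prot5),
    protein = prot5), minMotifs = 1)
  expect_warning(out <- predictMaturePeptides(hits5[1, ]), "basic")
  expect_equal(nrow(out), 0L)
})

test_that("amidated peptides always end in W or C", {
  prot <- paste0("M", strrep("T", 15), "KRAQIGLWGKRSS", "KRNEGLWCGKR",
                 strrep("T", 15))
  hits <- scanGlwPrecursors(S4Vectors::DataFrame(
    contig = "c", frame = 1L, start = 1L, end = 3L * nchar(prot),
    protein = prot), minMotifs = 2)
  pep <- predictMaturePeptides(hits[1, ])
  amidated <- pep[pep$cTerminalAmide, ]
  expect_true(all(substring(amidated$sequence,
                            nchar(amidated$sequence),
                            nchar(amidated$sequence)) %in% c("W", "C")))
})

test_that("query parsing handles pyroglutamate and amide notation", {
  q <- parsePeptideQuery("pEPLPIGLW-NH_2_")   # Hym-248
  expect_equal(q$core, "QPLPIGLW")
  expect_true(q$amidated)
  expect_true(q$pyroglu)
  q2 <- parsePeptideQuery("pEQPGLW-NH2")      # Metamorphosin-A
  expect_equal(q2$core, "QQPGLW")
  plain <- parsePeptideQuery("AGLW")
  expect_false(plain$amidated)
  expect_error(parsePeptideQuery("pEP1GLW-NH2"), "unparseable")
})

test_that("matching separates exact hits from C-terminal suffix hits", {
  pep <- S4Vectors::DataFrame(
    motifIndex = 1:3,
    sequence = c("QPLPIGLW", "QPGLW", "AGLW"),
    nTerminalPyroglu = c(TRUE, TRUE, FALSE),
    cTerminalAmide = c(TRUE, TRUE, FALSE),
    display = c("pEPLPIGLW-NH2", "pEPGLW-NH2", "AGLW"))
  m <- matchQueryPeptide(pep, "pEPLPIGLW-NH_2_")
  expect_equal(as.logical(m$exact), c(TRUE, FALSE, FALSE))
  # Metamorphosin-A (QQPGLW) vs predicted QPGLW: suffix only
  m2 <- matchQueryPeptide(pep, "pEQPGLW-NH_2_")
  expect_equal(as.logical(m2$exact), c(FALSE, FALSE, FALSE))
  expect_equal(as.logical(m2$suffix), c(FALSE, TRUE, FALSE))
  # amidation state must agree even for identical cores
  m3 <- matchQueryPeptide(pep, "AGLW-NH2")
  expect_false(any(m3$exact))
})
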