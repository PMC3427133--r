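# Accessor generics and methods. Slots are never touched directly by user
# code; everything routes through these.

#' @rdname BlockAlignments-class
#' @param x,object an object of the documented class.
#' @export
setGeneric("alnTable", function(x) standardGeneric("alnTable"))

#' @rdname BlockAlignments-class
#' @export
setMethod("alnTable", "BlockAlignments", function(x) x@table)

#' @rdname BlockAlignments-class
#' @export
setMethod("length", "BlockAlignments", function(x) nrow(x@table))

#' Fraction of aligned bases that match, per alignment
#' @param x a \code{BlockAlignments} object.
#' @return numeric vector of per-alignment identities in [0, 1].
#' @export
setGeneric("alnIdentity", function(x) standardGeneric("alnIdentity"))

#' @rdname alnIdentity
#' @export
setMethod("alnIdentity", "BlockAlignments", function(x) {
  tb <- x@table
  ifelse(tb$alignedBases > 0L, tb$matches / tb$alignedBases, 0)
})

#' @rdname BlockAlignments-class
#' @param i row indices.
#' @export
setMethod("[", "BlockAlignments", function(x, i) {
  new("BlockAlignments", table = x@table[i, , drop = FALSE])
})

#' Base counts of a pileup for one contig
#' @param x a \code{Pileup}.
#' @param contig contig identifier.
#' @return 4 x L integer matrix with rows A, C, G, T.
#' @export
setGeneric("baseCounts", function(x, contig) standardGeneric("baseCounts"))

#' @rdname baseCounts
#' @export
setMethod("baseCounts", "Pileup", function(x, contig) {
  off <- x@offsets[[contig]]
  len <- x@contigLens[[contig]]
  x@counts[, (off + 1L):(off + len), drop = FALSE]
})

#' Read depth of a pileup
#' @param x a \code{Pileup}.
#' @param contig contig id, or NULL for the concatenated axis.
#' @return integer vector of per-position depths (sum of A,C,G,T counts).
#' @export
setGeneric("pileupDepth", function(x, contig = NULL)
  standardGeneric("pileupDepth"))

#' @rdname pileupDepth
#' @export
setMethod("pileupDepth", "Pileup", function(x, contig = NULL) {
  if (is.null(contig)) return(.colSums(x@counts, 4L, ncol(x@counts)))
  .colSums(baseCounts(x, contig), 4L, x@contigLens[[contig]])
})

#' @rdname Pileup-class
#' @param x a \code{Pileup}.
#' @export
setGeneric("indelEvents", function(x) standardGeneric("indelEvents"))

#' @rdname Pileup-class
#' @export
setMethod("indelEvents", "Pileup", function(x) x@indelEvents)

#' @rdname CoverageSummary-class
#' @param x a \code{CoverageSummary}.
#' @export
setGeneric("perContigCoverage", function(x)
  standardGeneric("perContigCoverage"))

#' @rdname CoverageSummary-class
#' @export
setMethod("perContigCoverage", "CoverageSummary", function(x) x@perContig)

#' @rdname CoverageSummary-class
#' @export
setGeneric("genomeSize", function(x) standardGeneric("genomeSize"))

#' @rdname CoverageSummary-class
#' @export
setMethod("genomeSize", "CoverageSummary", function(x) x@genomeSize)

#' @rdname CoverageSummary-class
#' @export
setGeneric("modalCov", function(x) standardGeneric("modalCov"))

#' @rdname CoverageSummary-class
#' @export
setMethod("modalCov", "CoverageSummary", function(x) x@modal)

#' @rdname VariantSummary-class
#' @param x the object.
#' @export
setGeneric("snvClassCounts", function(x) standardGeneric("snvClassCounts"))

#' @rdname VariantSummary-class
#' @export
setMethod("snvClassCounts", "VariantSummary", function(x) x@snvClassCounts)

#' @rdname VariantSummary-class
#' @export
setGeneric("indelSizeHist", function(x) standardGeneric("indelSizeHist"))

#' @rdname VariantSummary-class
#' @export
setMethod("indelSizeHist", "VariantSummary", function(x) x@indelSizeHist)

#' @rdname VariantSummary-class
#' @export
setGeneric("bpPerSnv", function(x) standardGeneric("bpPerSnv"))

#' @rdname VariantSummary-class
#' @export
setMethod("bpPerSnv", "VariantSummary", function(x) x@bpPerSnv)

#' Counts and percentages of a concordance report as a named list
#' @param x a \code{ConcordanceReport}.
#' @export
setGeneric("reportCounts", function(x) standardGeneric("reportCounts"))

#' @rdname reportCounts
#' @export
setMethod("reportCounts", "ConcordanceReport", function(x) {
  list(totalPairs = x@totalPairs, bothMapped = x@bothMapped,
       uniqueUnique = x@uniqueUnique, uniqueConcordant = x@uniqueConcordant,
       multiMap = x@multiMap, multiConcordant = x@multiConcordant,
       pctUnique = x@pctUnique, pctMulti = x@pctMulti)
})

#' @rdname AssemblyStats-class
#' @param x an \code{AssemblyStats}.
#' @export
setGeneric("n50", function(x) standardGeneric("n50"))

#' @rdname AssemblyStats-class
#' @export
setMethod("n50", "AssemblyStats", function(x) x@n50)

#' Assembly statistics as a named list
#' @param x an \code{AssemblyStats}.
#' @export
setGeneric("statsList", function(x) standardGeneric("statsList"))

#' @rdname statsList
#' @export
setMethod("statsList", "AssemblyStats", function(x) {
  list(n = x@n, totalBp = x@totalBp, minLen = x@minLen, maxLen = x@maxLen,
       meanLen = x@meanLen, medianLen = x@medianLen, n50 = x@n50,
       histBreaks = x@histBreaks, histCounts = x@histCounts)
})

#' Planted variants of a simulation truth table
#' @param x a \code{SimTruth}.
#' @return a \code{GRanges} of planted variants.
#' @export
setGeneric("truthVariants", function(x) standardGeneric("truthVariants"))

#' @rdname truthVariants
#' @export
setMethod("truthVariants", "SimTruth", function(x) x@variants)
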