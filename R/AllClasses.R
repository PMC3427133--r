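#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' Block alignments of reads to contigs
#'
#' A set of read-to-contig alignments, each an ordered list of co-linear
#' un-gapped blocks, in the style of a PSL record. Coordinates are 1-based
#' closed. For minus-strand alignments the read ("query") coordinates refer to
#' the reverse complement of the stored read, as in PSL.
#'
#' Columns of the underlying table: \code{readId}, \code{contigId},
#' \code{strand} (\code{"+"}/\code{"-"}), \code{qStart}, \code{tStart},
#' \code{blockLen} (parallel \code{IntegerList}s: read start, contig start and
#' length of each block), \code{matches}, \code{alignedBases}, \code{gaps}
#' (gap openings between blocks) and \code{readLength}.
#'
#' @slot table A \code{DataFrame} with the columns above.
#' @export
setClass("BlockAlignments", representation(table = "DataFrame"))

setValidity("BlockAlignments", function(object) {
  tb <- object@table
  need <- c("readId", "contigId", "strand", "qStart", "tStart", "blockLen",
            "matches", "alignedBases", "gaps", "readLength")
  if (!all(need %in% colnames(tb)))
    return(paste("missing columns:",
                 paste(setdiff(need, colnames(tb)), collapse = ", ")))
  if (nrow(tb) == 0L) return(TRUE)
  if (!all(tb$strand %in% c("+", "-"))) return("strand must be '+' or '-'")
  ab <- sum(tb$blockLen)
  if (!all(tb$alignedBases == ab))
    return("alignedBases must equal the sum of block lengths")
  if (any(tb$matches > tb$alignedBases) || any(tb$matches < 0L))
    return("matches must lie in [0, alignedBases]")
  TRUE
})

#' Per-position base and indel-opening counts over a contig set
#'
#' Counts are stored over one concatenated coordinate axis with per-contig
#' offsets, which keeps the object flat and the variant caller vectorised.
#'
#' @slot counts 4 x N integer matrix (rows A, C, G, T) of base observations.
#' @slot insOpen,delOpen integer vectors of length N counting reads that open
#'   an insertion/deletion immediately after each position.
#' @slot offsets 0-based start offset of each contig on the concatenated axis.
#' @slot contigLens named integer vector of contig lengths.
#' @slot indelEvents \code{DataFrame} of distinct indel events
#'   (\code{contig}, \code{pos}, \code{type}, \code{len}, \code{seq},
#'   \code{count}); \code{pos} is the left-flanking contig position.
#' @export
setClass("Pileup", representation(
  counts = "matrix", insOpen = "integer", delOpen = "integer",
  offsets = "integer", contigLens = "integer", indelEvents = "DataFrame"))

setValidity("Pileup", function(object) {
  if (nrow(object@counts) != 4L) return("counts must have 4 rows (A,C,G,T)")
  n <- ncol(object@counts)
  if (length(object@insOpen) != n || length(object@delOpen) != n)
    return("insOpen/delOpen length must match ncol(counts)")
  if (sum(object@contigLens) != n)
    return("contig lengths must sum to ncol(counts)")
  if (any(object@counts < 0L)) return("negative counts")
  TRUE
})

#' Coverage summary and genome-size estimate
#'
#' @slot perContig named numeric vector of per-contig mean coverages
#'   (aligned bases mapped to the contig divided by contig length).
#' @slot modal integer modal coverage over contigs with non-zero coverage.
#' @slot totalBases total genomic read bases sequenced (bp).
#' @slot genomeSize estimated genome size in bp (totalBases / modal).
#' @export
setClass("CoverageSummary", representation(
  perContig = "numeric", modal = "integer",
  totalBases = "numeric", genomeSize = "numeric"))

#' Variant spectrum summary
#'
#' Counts of called heterozygous SNVs by unordered base-pair class, indel
#' count with a 1..8/">8" size histogram, and the SNV density expressed as
#' base pairs of contig sequence per SNV.
#'
#' @slot snvClassCounts named integer vector over classes
#'   A/G, C/T, A/C, G/C, A/T, G/T.
#' @slot indelCount integer; \code{indelSizeHist} named integer histogram.
#' @slot totalSnvs integer; \code{totalBp} numeric; \code{bpPerSnv} numeric
#'   (NA when no SNVs were called).
#' @export
setClass("VariantSummary", representation(
  snvClassCounts = "integer", indelCount = "integer",
  indelSizeHist = "integer", totalSnvs = "integer",
  totalBp = "numeric", bpPerSnv = "numeric"))

setValidity("VariantSummary", function(object) {
  if (sum(object@snvClassCounts) != object@totalSnvs)
    return("SNV class counts must sum to totalSnvs")
  if (sum(object@indelSizeHist) != object@indelCount)
    return("indel size histogram must sum to indelCount")
  TRUE
})

#' Paired-end orientation concordance report
#'
#' Classifies read pairs mapped to an assembly into unique-unique pairs (each
#' read maps to exactly one contig), counted concordant when both reads hit
#' the same contig in opposite orientations, and multi-map pairs (at least one
#' read maps to several contigs), counted concordant when some contig is hit
#' by both reads in opposite orientations.
#'
#' @slot totalPairs,bothMapped,uniqueUnique,uniqueConcordant,multiMap,multiConcordant
#'   integer pair counts.
#' @slot pctUnique,pctMulti integer-rounded percentages of the two
#'   concordance ratios.
#' @export
setClass("ConcordanceReport", representation(
  totalPairs = "integer", bothMapped = "integer",
  uniqueUnique = "integer", uniqueConcordant = "integer",
  multiMap = "integer", multiConcordant = "integer",
  pctUnique = "numeric", pctMulti = "numeric"))

setValidity("ConcordanceReport", function(object) {
  if (object@uniqueConcordant > object@uniqueUnique)
    return("uniqueConcordant cannot exceed uniqueUnique")
  if (object@multiConcordant > object@multiMap)
    return("multiConcordant cannot exceed multiMap")
  if (object@uniqueUnique + object@multiMap > object@bothMapped)
    return("category counts cannot exceed mapped pairs")
  TRUE
})

#' Assembly summary statistics
#'
#' @slot n,totalBp,minLen,maxLen integer/numeric scalar summaries.
#' @slot meanLen,medianLen,n50 numeric scalar summaries.
#' @slot histBreaks,histCounts fixed 400-bp length histogram anchored at
#'   200 bp (counts; breaks are left edges).
#' @export
setClass("AssemblyStats", representation(
  n = "integer", totalBp = "numeric", minLen = "integer", maxLen = "integer",
  meanLen = "numeric", medianLen = "numeric", n50 = "integer",
  histBreaks = "numeric", histCounts = "integer"))

#' Truth table for a simulated diploid transcriptome
#'
#' @slot variants \code{GRanges} of planted variants (mcols: \code{type} =
#'   snv/ins/del, \code{ref}, \code{alt}, \code{class}, \code{len}); SNV
#'   positions are the variant site, indel positions the left-flanking base.
#' @slot hairpins \code{DataFrame} of planted hairpins (contig, apex).
#' @slot genomeSize numeric true genome size in bp (NA for transcriptome-only
#'   simulations).
#' @slot maps per-contig haplotype-to-reference segment maps used to project
#'   simulated reads back onto reference coordinates.
#' @export
setClass("SimTruth", representation(
  variants = "GRanges", hairpins = "DataFrame",
  genomeSize = "numeric", maps = "list"))

## ---- show methods -------------------------------------------------------

setMethod("show", "BlockAlignments", function(object) {
  tb <- object@table
  cat("BlockAlignments with", nrow(tb), "alignments on",
      length(unique(tb$contigId)), "contigs\n")
  if (nrow(tb) > 0) {
    id <- tb$matches / pmax(tb$alignedBases, 1L)
    cat(sprintf("  median identity %.3f, gapped alignments: %d\n",
                stats::median(id), sum(tb$gaps > 0L)))
  }
})

setMethod("show", "Pileup", function(object) {
  cat("Pileup over", length(object@contigLens), "contigs,",
      sum(object@contigLens), "positions;",
      sum(object@counts), "base observations,",
      nrow(object@indelEvents), "distinct indel events\n")
})

setMethod("show", "CoverageSummary", function(object) {
  cat(sprintf(paste0("CoverageSummary: %d contigs, modal coverage %dx, ",
                     "%.3g bases sequenced\n  genome size estimate: %.4g bp ",
                     "(%.1f Mb)\n"),
              length(object@perContig), object@modal, object@totalBases,
              object@genomeSize, object@genomeSize / 1e6))
})

setMethod("show", "VariantSummary", function(object) {
  cat("VariantSummary:", object@totalSnvs, "SNVs,",
      object@indelCount, "indels over", format(object@totalBp, big.mark = ","),
      "bp\n")
  print(object@snvClassCounts)
  if (is.na(object@bpPerSnv)) cat("  density: undefined (no SNVs)\n")
  else cat("  density: 1 SNV per", object@bpPerSnv, "bp\n")
})

setMethod("show", "ConcordanceReport", function(object) {
  cat("ConcordanceReport:", object@totalPairs, "pairs;",
      object@bothMapped, "with both reads mapped\n")
  cat(sprintf("  unique-unique: %d/%d concordant (%d%%)\n",
              object@uniqueConcordant, object@uniqueUnique, object@pctUnique))
  cat(sprintf("  multi-map:     %d/%d concordant (%d%%)\n",
              object@multiConcordant, object@multiMap, object@pctMulti))
})

setMethod("show", "AssemblyStats", function(object) {
  cat(sprintf(paste0("AssemblyStats: %d contigs, %.4g bp total\n",
                     "  range %d-%d bp, mean %.0f, median %.0f, N50 %d\n"),
              object@n, object@totalBp, object@minLen, object@maxLen,
              object@meanLen, object@medianLen, object@n50))
})

setMethod("show", "SimTruth", function(object) {
  v <- object@variants
  cat("SimTruth:", length(v), "planted variants (",
      sum(v$type == "snv"), "SNVs,", sum(v$type != "snv"), "indels ),",
      nrow(object@hairpins), "hairpins\n")
})
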