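#' Alignment validity filter
#'
#' An alignment is valid when at least \code{minFrac} of the read aligned and
#' the aligned portion agrees with the contig at \code{minIdent} or better;
#' both boundaries are inclusive. The denominator of the aligned fraction is
#' the (post-trimming) read length carried by the alignment record. The low
#' aligned-fraction floor tolerates reads that straddle exon-intron
#' boundaries while the identity floor keeps specificity.
#'
#' @param aln a \code{BlockAlignments} object.
#' @param minFrac minimum aligned fraction of the read (default 0.40).
#' @param minIdent minimum matches/alignedBases identity (default 0.96).
#' @return logical vector, one element per alignment.
#' @examples
#' a <- blockAlignments("r1", "c1", "+", 1, 1, 40, matches = 39,
#'                      readLength = 100)
#' isValidAlignment(a)           # 0.40 aligned, 0.975 identity -> TRUE
#' @export
isValidAlignment <- function(aln, minFrac = 0.40, minIdent = 0.96) {
  tb <- alnTable(aln)
  tb$alignedBases >= minFrac * tb$readLength &
    tb$matches >= minIdent * tb$alignedBases
}

#' @rdname isValidAlignment
#' @return \code{filterValidAlignments} returns the subset of valid
#'   alignments.
#' @export
filterValidAlignments <- function(aln, minFrac = 0.40, minIdent = 0.96) {
  aln[which(isValidAlignment(aln, minFrac, minIdent))]
}

#' Build a per-position pileup from valid alignments
#'
#' Each read base of each aligned block increments the count of its base at
#' the corresponding contig position; minus-strand reads contribute through
#' their reverse complement (i.e. in contig orientation). Gap openings
#' between consecutive blocks are tallied as insertion/deletion openings at
#' the left-flanking contig position, together with the implied indel length
#' and sequence. Read Ns contribute to no base count.
#'
#' @param aln a \code{BlockAlignments} object (pre-filtered for validity).
#' @param reads the reads, named consistently with the alignments' readId
#'   (\code{DNAStringSet}, \code{QualityScaledDNAStringSet} or named
#'   character).
#' @param contigs named \code{DNAStringSet} or character vector.
#' @param chunkBases approximate bases processed per internal chunk.
#' @return a \code{\link{Pileup-class}} object.
#' @export
buildPileup <- function(aln, reads, contigs, chunkBases = 3e7) {
  tb <- alnTable(aln)
  cs <- .asSeqChar(contigs)
  if (is.null(names(cs))) stop("contigs must be named", call. = FALSE)
  if (nrow(tb) && !all(tb$contigId %in% names(cs)))
    stop("alignment references unknown contig", call. = FALSE)
  lens <- stats::setNames(nchar(cs), names(cs))
  offs <- stats::setNames(c(0, cumsum(as.numeric(lens)))[seq_along(lens)],
                          names(lens))
  N <- sum(lens)
  counts <- matrix(0L, nrow = 4L, ncol = N)
  insOpen <- integer(N); delOpen <- integer(N)
  evKeys <- list()

  if (nrow(tb)) {
    rseq <- .asSeqChar(reads)
    if (is.null(names(rseq))) stop("reads must be named", call. = FALSE)
    seqs <- rseq[tb$readId]
    minus <- tb$strand == "-"
    if (any(minus))
      seqs[minus] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(seqs[minus])))

    meanAb <- max(mean(tb$alignedBases), 1)
    csize <- max(1L, as.integer(chunkBases / meanAb))
    for (csr in seq(1L, nrow(tb), by = csize)) {
      ce <- min(csr + csize - 1L, nrow(tb))
      rows <- csr:ce
      nb <- lengths(tb$blockLen[rows])
      alnIdx <- rep(rows, nb)
      qs <- unlist(tb$qStart[rows], use.names = FALSE)
      ts <- unlist(tb$tStart[rows], use.names = FALSE)
      bl <- unlist(tb$blockLen[rows], use.names = FALSE)
      rw <- substring(seqs[alnIdx], qs, qs + bl - 1L)
      braw <- charToRaw(paste(rw, collapse = ""))
      g0 <- offs[tb$contigId[alnIdx]] + ts - 1L
      gpos <- rep(g0, bl) + sequence(bl)
      code <- .codeBases(braw)
      ok <- which(!is.na(code))
      idx4 <- (gpos[ok] - 1) * 4 + code[ok]
      add <- tabulate(idx4, nbins = 4 * N)
      counts <- counts + matrix(add, nrow = 4L)

      # indel openings at junctions between consecutive blocks (flat)
      nBl <- length(bl)
      if (nBl > 1L) {
        jn <- which(alnIdx[-1L] == alnIdx[-nBl])
        if (length(jn)) {
          tGap <- ts[jn + 1L] - (ts[jn] + bl[jn])
          qGap <- qs[jn + 1L] - (qs[jn] + bl[jn])
          flank <- ts[jn] + bl[jn] - 1L
          gj <- offs[tb$contigId[alnIdx[jn]]] + flank
          dj <- which(tGap > 0L)
          if (length(dj)) {
            delOpen <- delOpen + tabulate(gj[dj], nbins = N)
            sq <- substr(cs[tb$contigId[alnIdx[jn[dj]]]],
                         flank[dj] + 1L, flank[dj] + tGap[dj])
            evKeys[[length(evKeys) + 1L]] <-
              paste(tb$contigId[alnIdx[jn[dj]]], flank[dj], "del",
                    tGap[dj], sq, sep = "\t")
          }
          ij <- which(qGap > 0L)
          if (length(ij)) {
            insOpen <- insOpen + tabulate(gj[ij], nbins = N)
            sq <- substr(seqs[alnIdx[jn[ij]]], qs[jn[ij]] + bl[jn[ij]],
                         qs[jn[ij]] + bl[jn[ij]] + qGap[ij] - 1L)
            evKeys[[length(evKeys) + 1L]] <-
              paste(tb$contigId[alnIdx[jn[ij]]], flank[ij], "ins",
                    qGap[ij], sq, sep = "\t")
          }
        }
      }
    }
  }

  if (length(evKeys)) {
    tt <- table(unlist(evKeys, use.names = FALSE))
    parts <- strsplit(names(tt), "\t", fixed = TRUE)
    ev <- S4Vectors::DataFrame(
      contig = vapply(parts, `[[`, character(1), 1L),
      pos = as.integer(vapply(parts, `[[`, character(1), 2L)),
      type = vapply(parts, `[[`, character(1), 3L),
      len = as.integer(vapply(parts, `[[`, character(1), 4L)),
      seq = vapply(parts, `[[`, character(1), 5L),
      count = as.integer(tt))
  } else {
    ev <- S4Vectors::DataFrame(contig = character(0), pos = integer(0),
                               type = character(0), len = integer(0),
                               seq = character(0), count = integer(0))
  }
  methods::new("Pileup", counts = counts, insOpen = insOpen,
               delOpen = delOpen,
               offsets = stats::setNames(as.integer(offs), names(lens)),
               contigLens = stats::setNames(as.integer(lens), names(lens)),
               indelEvents = ev)
}

#' Mean read coverage per contig
#'
#' Sums the aligned bases of all reads whose best hit is the given contig and
#' divides by the contig length. Each read is assigned to a single top-
#' scoring hit (most matching bases; ties go to the first alignment listed),
#' and gapped alignments are excluded.
#'
#' @param aln a \code{BlockAlignments} object (typically validity-filtered).
#' @param contigs named \code{DNAStringSet} or character vector.
#' @return named numeric vector of mean coverages, one per contig (0 for
#'   contigs with no mapped reads).
#' @export
contigMeanCoverage <- function(aln, contigs) {
  cs <- .asSeqChar(contigs)
  lens <- stats::setNames(nchar(cs), names(cs))
  tb <- alnTable(aln)
  out <- stats::setNames(numeric(length(lens)), names(lens))
  if (nrow(tb) == 0L) return(out)
  ungapped <- which(tb$gaps == 0L)
  tb <- tb[ungapped, , drop = FALSE]
  if (nrow(tb) == 0L) return(out)
  o <- order(match(tb$readId, unique(tb$readId)), -tb$matches)
  tb <- tb[o, , drop = FALSE]
  best <- !duplicated(tb$readId)
  tb <- tb[best, , drop = FALSE]
  agg <- rowsum(as.numeric(tb$alignedBases), tb$contigId)
  out[rownames(agg)] <- agg[, 1] / lens[rownames(agg)]
  out
}

#' Modal coverage over a contig set
#'
#' The mode of the per-contig mean coverages after rounding each to the
#' nearest integer; contigs with zero coverage are excluded and ties break
#' toward the lower value.
#'
#' @param means numeric vector of per-contig mean coverages.
#' @return integer modal coverage.
#' @examples
#' modalCoverage(c(23.6, 24.2, 24.4, 7.1))  # 24
#' @export
modalCoverage <- function(means) {
  r <- round(means[!is.na(means) & means > 0])
  r <- r[r >= 1]
  if (!length(r)) stop("no contig with positive coverage", call. = FALSE)
  tt <- table(r)
  vals <- as.integer(names(tt))
  as.integer(vals[which.max(tt)])  # which.max takes the first (lowest) mode
}

#' Estimate genome size from sequencing depth
#'
#' The total amount of genomic read sequence divided by the estimated
#' sequencing depth (the modal per-contig coverage). Units follow the input:
#' bases in, bases out.
#'
#' @param totalBases total genomic read bases sequenced.
#' @param modalCov modal coverage (estimated sequencing depth), must be >= 1.
#' @return estimated genome size (same units as \code{totalBases}).
#' @examples
#' estimateGenomeSize(10100, 24)  # 420.8 Mb when totalBases is in Mb
#' @export
estimateGenomeSize <- function(totalBases, modalCov) {
  stopifnot(.isSingleNumber(totalBases), .isSingleNumber(modalCov))
  if (modalCov < 1) stop("modal coverage must be at least 1", call. = FALSE)
  totalBases / modalCov
}

#' Coverage summary with genome-size estimate
#'
#' Convenience wrapper chaining \code{\link{contigMeanCoverage}},
#' \code{\link{modalCoverage}} and \code{\link{estimateGenomeSize}}.
#'
#' @param aln validity-filtered \code{BlockAlignments}.
#' @param contigs named \code{DNAStringSet} or character vector.
#' @param totalBases total genomic read bases sequenced (bp), including
#'   unmapped reads.
#' @return a \code{\link{CoverageSummary-class}} object.
#' @export
coverageSummary <- function(aln, contigs, totalBases) {
  pc <- contigMeanCoverage(aln, contigs)
  m <- modalCoverage(pc)
  methods::new("CoverageSummary", perContig = pc, modal = m,
               totalBases = as.numeric(totalBases),
               genomeSize = estimateGenomeSize(totalBases, m))
}
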