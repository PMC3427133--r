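#' Paired-end orientation concordance of an assembly
#'
#' Classifies long read pairs by how their best alignments fall on the
#' assembly. Alignments below the identity floor are discarded; a read's
#' "best alignments" are all hits within \code{tieWindow} of its top
#' identity (mappers emit co-optimal hits, so a near-tie window is needed
#' before "maps to one and only one contig" is well defined). A pair where
#' each read maps to exactly one contig is concordant when both hit the same
#' contig with opposite orientations; a pair where either read maps to
#' several contigs is concordant when at least one contig is hit by both
#' reads in opposite orientations.
#'
#' @param aln a \code{BlockAlignments} object covering both mates.
#' @param pairs data.frame with columns \code{fwd} and \code{rev} giving the
#'   paired read ids.
#' @param minIdentity per-alignment identity floor (default 0.90).
#' @param tieWindow identity width of the co-optimal window (default 0.005).
#' @return a \code{\link{ConcordanceReport-class}} object.
#' @export
pairConcordance <- function(aln, pairs, minIdentity = 0.90,
                            tieWindow = 0.005) {
  tb <- alnTable(aln)
  ident <- alnIdentity(aln)
  keep <- ident >= minIdentity
  tb <- tb[keep, , drop = FALSE]
  ident <- ident[keep]

  hitsOf <- function(id) {
    w <- which(tb$readId == id)
    if (!length(w)) return(NULL)
    top <- max(ident[w])
    w <- w[ident[w] >= top - tieWindow]
    unique(data.frame(contig = tb$contigId[w], strand = tb$strand[w]))
  }

  nP <- nrow(pairs)
  uu <- 0L; uuC <- 0L; mm <- 0L; mmC <- 0L; mapped <- 0L
  for (i in seq_len(nP)) {
    hf <- hitsOf(pairs$fwd[i])
    hr <- hitsOf(pairs$rev[i])
    if (is.null(hf) || is.null(hr)) next
    mapped <- mapped + 1L
    nfc <- length(unique(hf$contig)); nrc <- length(unique(hr$contig))
    shared <- intersect(hf$contig, hr$contig)
    opp <- any(vapply(shared, function(ct) {
      sf <- hf$strand[hf$contig == ct]
      sr <- hr$strand[hr$contig == ct]
      any(outer(sf, sr, `!=`))
    }, logical(1)))
    if (nfc == 1L && nrc == 1L) {
      uu <- uu + 1L
      if (length(shared) && opp) uuC <- uuC + 1L
    } else {
      mm <- mm + 1L
      if (length(shared) && opp) mmC <- mmC + 1L
    }
  }
  concordanceReport(totalPairs = nP, bothMapped = mapped,
                    uniqueUnique = uu, uniqueConcordant = uuC,
                    multiMap = mm, multiConcordant = mmC)
}

#' Assemble a concordance report from category counts
#'
#' The percentage logic lives here: each concordance percentage is 100 times
#' the ratio of its integer numerator and denominator, rounded to the
#' nearest whole percent (NA when the denominator is zero).
#'
#' @param totalPairs,bothMapped,uniqueUnique,uniqueConcordant,multiMap,multiConcordant
#'   integer counts.
#' @return a \code{\link{ConcordanceReport-class}} object.
#' @examples
#' concordanceReport(4833, 2275, 755, 551, 1520, 1239)
#' @export
concordanceReport <- function(totalPairs, bothMapped, uniqueUnique,
                              uniqueConcordant, multiMap, multiConcordant) {
  pct <- function(num, den) if (den > 0) .roundHalfUp(100 * num / den)
                            else NA_real_
  methods::new("ConcordanceReport",
               totalPairs = as.integer(totalPairs),
               bothMapped = as.integer(bothMapped),
               uniqueUnique = as.integer(uniqueUnique),
               uniqueConcordant = as.integer(uniqueConcordant),
               multiMap = as.integer(multiMap),
               multiConcordant = as.integer(multiConcordant),
               pctUnique = pct(uniqueConcordant, uniqueUnique),
               pctMulti = pct(multiConcordant, multiMap))
}
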