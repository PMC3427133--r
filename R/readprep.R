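#' Collapse duplicate reads into family representatives
#'
#' Reads are grouped into families by an exact prefix signature of length
#' \code{prefixLen} (for pairs, the concatenated signatures of both mates)
#' and each family is collapsed to a single representative with improved
#' quality scores: at every position the consensus base is the majority
#' among family members covering that position, ties broken first by higher
#' summed quality and then alphabetically, and the representative quality is
#' the maximum over members. This is a declared simplification of full
#' duplicate-collapsing pipelines, capturing their contract (one
#' representative per read family) rather than their clustering heuristics.
#'
#' @param reads a \code{QualityScaledDNAStringSet} of single-end reads, or a
#'   list of two such sets for paired reads (mates matched by position).
#' @param prefixLen signature length on each mate (default 30); must be
#'   between 1 and the shortest read length.
#' @return list with \code{representatives} (same container type as the
#'   input) and \code{familySizes} (integer vector, one per family, in
#'   representative order; sums to the input read count).
#' @export
collapseDuplicates <- function(reads, prefixLen = 30L) {
  paired <- is.list(reads) && !methods::is(reads, "XStringSet")
  if (paired) {
    stopifnot(length(reads) == 2L,
              length(reads[[1]]) == length(reads[[2]]))
    key1 <- .sigKey(reads[[1]], prefixLen)
    key2 <- .sigKey(reads[[2]], prefixLen)
    key <- paste(key1, key2, sep = "|")
    fam <- split(seq_along(key), factor(key, levels = unique(key)))
    rep1 <- .consensusSet(reads[[1]], fam)
    rep2 <- .consensusSet(reads[[2]], fam)
    list(representatives = list(rep1, rep2),
         familySizes = lengths(fam))
  } else {
    key <- .sigKey(reads, prefixLen)
    fam <- split(seq_along(key), factor(key, levels = unique(key)))
    list(representatives = .consensusSet(reads, fam),
         familySizes = lengths(fam))
  }
}

.sigKey <- function(reads, prefixLen) {
  w <- BiocGenerics::width(reads)
  if (prefixLen < 1L || prefixLen > min(w))
    stop("prefixLen must be between 1 and the shortest read length",
         call. = FALSE)
  substr(as.character(reads), 1L, prefixLen)
}

# collapse each family (list of member indices) to its consensus read
.consensusSet <- function(reads, fam) {
  sq <- as.character(reads)
  ql <- readQuals(reads)
  outSeq <- character(length(fam))
  outQual <- character(length(fam))
  for (f in seq_along(fam)) {
    idx <- fam[[f]]
    if (length(idx) == 1L) {
      outSeq[f] <- sq[idx]
      outQual[f] <- as.character(Biostrings::quality(reads)[idx])
      next
    }
    ws <- nchar(sq[idx])
    W <- max(ws)
    baseM <- matrix(NA_character_, nrow = length(idx), ncol = W)
    qualM <- matrix(NA_integer_, nrow = length(idx), ncol = W)
    for (r in seq_along(idx)) {
      baseM[r, seq_len(ws[r])] <- strsplit(sq[idx[r]], "")[[1]]
      qualM[r, seq_len(ws[r])] <- as.integer(ql[[idx[r]]])
    }
    cons <- character(W); cq <- integer(W)
    for (pos in seq_len(W)) {
      b <- baseM[, pos]; q <- qualM[, pos]
      ok <- !is.na(b)
      b <- b[ok]; q <- q[ok]
      nb <- table(b)
      top <- max(nb)
      cand <- names(nb)[nb == top]
      if (length(cand) > 1L) {
        qs <- vapply(cand, function(x) sum(q[b == x]), numeric(1))
        cand <- cand[qs == max(qs)]
        cand <- sort(cand)[1]          # lexicographic last resort
      }
      cons[pos] <- cand
      cq[pos] <- max(q)
    }
    outSeq[f] <- paste(cons, collapse = "")
    outQual[f] <- rawToChar(as.raw(pmin(cq, 60L) + 33L))
  }
  ids <- names(reads)[vapply(fam, `[`, integer(1), 1L)]
  Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(stats::setNames(outSeq, ids)),
    Biostrings::PhredQuality(Biostrings::BStringSet(outQual)))
}

#' Quality-trim a read to its longest clean window
#'
#' Returns, for each read, the longest contiguous substring in which every
#' base has quality at or above \code{minQ} (Q10 itself passes) and no base
#' is N; the leftmost such window wins length ties, and the result may be
#' empty. Trimming constrains the result (no surviving nucleotide below the
#' floor, no ambiguous base) rather than prescribing end-trimming.
#'
#' @param reads a \code{QualityScaledDNAStringSet}.
#' @param minQ quality floor, inclusive (default 10).
#' @return a \code{QualityScaledDNAStringSet} of trimmed reads (possibly
#'   zero-width).
#' @export
qualityTrim <- function(reads, minQ = 10L) {
  sq <- as.character(reads)
  ql <- readQuals(reads)
  n <- length(sq)
  starts <- integer(n); lens <- integer(n)
  for (i in seq_len(n)) {
    q <- as.integer(ql[[i]])
    bad <- q < minQ
    nm <- gregexpr("N", sq[i], fixed = TRUE)[[1]]
    if (nm[1] != -1L) bad[as.integer(nm)] <- TRUE
    r <- rle(!bad)
    ends <- cumsum(r$lengths)
    goodRuns <- which(r$values)
    if (!length(goodRuns)) { starts[i] <- 1L; lens[i] <- 0L; next }
    rl <- r$lengths[goodRuns]
    best <- goodRuns[which.max(rl)]    # first maximum = leftmost
    starts[i] <- ends[best] - r$lengths[best] + 1L
    lens[i] <- r$lengths[best]
  }
  IRanges::narrow(reads, start = starts, end = starts + lens - 1L)
}

#' Discard reads below a length floor
#'
#' @param reads a \code{QualityScaledDNAStringSet} (already trimmed).
#' @param minLen inclusive length floor in bp (default 45: a 45-bp read
#'   survives).
#' @return the surviving reads, order preserved.
#' @export
lengthFilter <- function(reads, minLen = 45L) {
  reads[BiocGenerics::width(reads) >= minLen]
}
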