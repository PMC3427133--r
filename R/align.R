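#' Align reads to contigs by exact k-mer seeding and un-gapped extension
#'
#' A deliberately simple, deterministic read mapper for the package's
#' simulations and validation procedures: an exact k-mer seed anchors the
#' read on a contig diagonal and the alignment is extended un-gapped to the
#' full read extent, clipped at contig boundaries. Seeds are tried at the
#' read start, middle and end on both strands, in that order; the first
#' seeded diagonal wins, and within the reference the first (leftmost, first
#' listed contig) k-mer occurrence is used, so ties break deterministically
#' toward the lower coordinate.
#'
#' Because extension is un-gapped the mapper is intended for data without
#' reference-relative indels (genomic reads against a haploid reference,
#' clone-end reads against their source contigs); gapped block alignments for
#' diploid simulations come from \code{\link{truthAlignments}} or from an
#' external mapper.
#'
#' @param reads a named \code{DNAStringSet}/\code{QualityScaledDNAStringSet}
#'   or named character vector; read length must be at least 20.
#' @param contigs a named \code{DNAStringSet} or named character vector.
#' @param k seed k-mer length.
#' @param allHits if TRUE, report every contig hit per read (one best
#'   alignment per contig) instead of only the first; quadratic in reference
#'   size per read, intended for small references such as the paired-end
#'   concordance check.
#' @param chunkBases approximate bases per match-counting chunk.
#' @return a \code{\link{BlockAlignments-class}} with single-block records.
#' @export
alignReads <- function(reads, contigs, k = 16L, allHits = FALSE,
                       chunkBases = 3e7) {
  rs <- .asSeqChar(reads)
  if (is.null(names(rs))) names(rs) <- sprintf("read%06d", seq_along(rs))
  cs <- .asSeqChar(contigs)
  if (is.null(names(cs))) stop("contigs must be named", call. = FALSE)
  Lr <- nchar(rs)
  if (any(Lr < 20L)) stop("reads shorter than 20 bp", call. = FALSE)
  if (any(Lr < k)) stop("reads shorter than the seed length", call. = FALSE)
  Lc <- nchar(cs)

  nk <- pmax(Lc - k + 1L, 0L)
  tabKmer <- unlist(lapply(seq_along(cs), function(i) {
    if (nk[i] <= 0L) return(character(0))
    substring(cs[i], seq_len(nk[i]), seq_len(nk[i]) + k - 1L)
  }), use.names = FALSE)
  tabContig <- rep(seq_along(cs), nk)
  tabPos <- unlist(lapply(nk, seq_len), use.names = FALSE)

  n <- length(rs)
  resContig <- integer(n); resStrand <- character(n)
  resQs <- integer(n); resTs <- integer(n); resLen <- integer(n)
  pending <- rep(TRUE, n)
  rcs <- NULL

  extra <- list()  # additional hits in allHits mode
  seedIndex <- NULL
  if (allHits) seedIndex <- split(seq_along(tabKmer), tabKmer)

  offsetsFor <- function(len, frac) pmax(1L, floor((len - k) * frac) + 1L)
  for (frac in c(0, 0.5, 1)) {
    for (strand in c("+", "-")) {
      idx <- which(pending)
      if (!length(idx)) break
      if (strand == "-" && is.null(rcs))
        rcs <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAStringSet(rs)))
      sq <- if (strand == "+") rs[idx] else rcs[idx]
      off <- offsetsFor(Lr[idx], frac)
      seed <- substring(sq, off, off + k - 1L)
      if (!allHits) {
        m <- match(seed, tabKmer)
        hit <- which(!is.na(m))
        if (!length(hit)) next
        i2 <- idx[hit]
        ci <- tabContig[m[hit]]
        tFull <- tabPos[m[hit]] - off[hit] + 1L
        qs <- pmax(1L, 2L - tFull)
        ts <- tFull + qs - 1L
        len <- pmin(Lr[i2] - qs + 1L, Lc[ci] - ts + 1L)
        ok <- len >= k
        i2 <- i2[ok]
        resContig[i2] <- ci[ok]; resStrand[i2] <- strand
        resQs[i2] <- qs[ok]; resTs[i2] <- ts[ok]; resLen[i2] <- len[ok]
        pending[i2] <- FALSE
      } else {
        for (j in seq_along(idx)) {
          hits <- seedIndex[[seed[j]]]
          if (is.null(hits)) next
          i0 <- idx[j]
          ci <- tabContig[hits]
          tFull <- tabPos[hits] - off[j] + 1L
          qs <- pmax(1L, 2L - tFull)
          ts <- tFull + qs - 1L
          len <- pmin(Lr[i0] - qs + 1L, Lc[ci] - ts + 1L)
          ok <- len >= k
          if (!any(ok)) next
          extra[[length(extra) + 1L]] <-
            data.frame(read = i0, strand = strand, contig = ci[ok],
                       qs = qs[ok], ts = ts[ok], len = len[ok])
          pending[i0] <- FALSE
        }
      }
    }
  }

  if (allHits) {
    if (!length(extra))
      return(.emptyBlockAlignments())
    df <- do.call(rbind, extra)
    # one best alignment per (read, strand, contig, diagonal); dedupe diagonals
    df <- df[!duplicated(df[c("read", "strand", "contig", "qs", "ts")]), ]
  } else {
    sel <- which(!pending)
    if (!length(sel)) return(.emptyBlockAlignments())
    df <- data.frame(read = sel, strand = resStrand[sel],
                     contig = resContig[sel], qs = resQs[sel],
                     ts = resTs[sel], len = resLen[sel])
  }

  # match counting, chunked
  nr <- nrow(df)
  matches <- integer(nr)
  csize <- max(1L, as.integer(chunkBases / max(mean(df$len), 1)))
  orient <- function(ii) {
    out <- rs[df$read[ii]]
    mi <- df$strand[ii] == "-"
    if (any(mi)) out[mi] <- rcs[df$read[ii]][mi]
    out
  }
  for (csr in seq(1L, nr, by = csize)) {
    ce <- min(csr + csize - 1L, nr)
    ii <- csr:ce
    sq <- orient(ii)
    rw <- substring(sq, df$qs[ii], df$qs[ii] + df$len[ii] - 1L)
    fw <- substring(cs[df$contig[ii]], df$ts[ii], df$ts[ii] + df$len[ii] - 1L)
    a <- charToRaw(paste(rw, collapse = ""))
    b <- charToRaw(paste(fw, collapse = ""))
    eq <- which(a == b)
    blockOf <- rep(seq_along(ii), df$len[ii])
    matches[ii] <- tabulate(blockOf[eq], nbins = length(ii))
  }

  if (allHits) {
    # keep the best hit per (read, contig): most matches, then leftmost
    o <- order(df$read, df$contig, -matches, df$ts)
    df <- df[o, ]; matches <- matches[o]
    keep <- !duplicated(df[c("read", "contig")])
    df <- df[keep, ]; matches <- matches[keep]
  }

  tb <- S4Vectors::DataFrame(
    readId = names(rs)[df$read],
    contigId = names(cs)[df$contig],
    strand = df$strand,
    qStart = IRanges::IntegerList(as.list(df$qs)),
    tStart = IRanges::IntegerList(as.list(df$ts)),
    blockLen = IRanges::IntegerList(as.list(df$len)),
    matches = matches,
    alignedBases = df$len,
    gaps = 0L,
    readLength = Lr[df$read])
  methods::new("BlockAlignments", table = tb)
}

.emptyBlockAlignments <- function() {
  methods::new("BlockAlignments", table = S4Vectors::DataFrame(
    readId = character(0), contigId = character(0), strand = character(0),
    qStart = IRanges::IntegerList(), tStart = IRanges::IntegerList(),
    blockLen = IRanges::IntegerList(), matches = integer(0),
    alignedBases = integer(0), gaps = integer(0), readLength = integer(0)))
}

#' Construct block alignments from plain vectors
#'
#' Convenience constructor, mainly for tests and for importing tabular
#' (PSL-like) alignments: one row per alignment, blocks given as lists of
#' integer vectors.
#'
#' @param readId,contigId,strand,matches,alignedBases,gaps,readLength
#'   per-alignment vectors.
#' @param qStart,tStart,blockLen lists of integer vectors (one per
#'   alignment); defaults describe a single full-length block.
#' @return a \code{\link{BlockAlignments-class}} object.
#' @export
blockAlignments <- function(readId, contigId, strand, qStart, tStart,
                            blockLen, matches, alignedBases = NULL,
                            gaps = NULL, readLength) {
  if (!is.list(qStart)) qStart <- as.list(qStart)
  if (!is.list(tStart)) tStart <- as.list(tStart)
  if (!is.list(blockLen)) blockLen <- as.list(blockLen)
  ab <- vapply(blockLen, function(x) sum(as.integer(x)), integer(1))
  if (is.null(alignedBases)) alignedBases <- ab
  if (is.null(gaps)) gaps <- vapply(blockLen, length, integer(1)) - 1L
  tb <- S4Vectors::DataFrame(
    readId = readId, contigId = contigId, strand = strand,
    qStart = IRanges::IntegerList(lapply(qStart, as.integer)),
    tStart = IRanges::IntegerList(lapply(tStart, as.integer)),
    blockLen = IRanges::IntegerList(lapply(blockLen, as.integer)),
    matches = as.integer(matches), alignedBases = as.integer(alignedBases),
    gaps = as.integer(gaps), readLength = as.integer(readLength))
  methods::new("BlockAlignments", table = tb)
}
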