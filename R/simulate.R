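#' Simulate a clonal diploid transcriptome with planted heterozygosity
#'
#' Generates a set of reference contigs with the length structure of a short-
#' read transcriptome assembly (right-skewed, floored at 200 bp, mode near the
#' short end) and a pair of haplotypes per contig: haplotype A equals the
#' reference, haplotype B carries planted heterozygous SNVs and small indels.
#' Every planted variant is recorded in a truth table so downstream callers
#' can be scored for recall and precision.
#'
#' Defaults encode the study conditions this package models: one SNV per
#' 808 bp, transitions outnumbering transversions 1.6:1 (the ratio implied by
#' the observed class counts), an indel about every 5.1 kb with sizes 1-8 bp
#' at monotonically decreasing frequency, and a log-normal contig-length law
#' reproducing a 453 bp median / 770 bp mean over a 200-13,061 bp range.
#'
#' @param nContigs number of contigs (ignored when \code{totalBp} is given).
#' @param totalBp if non-NULL, draw contigs until their summed length reaches
#'   this many base pairs.
#' @param snvRate expected heterozygous SNVs per bp.
#' @param tstvRatio expected transitions per transversion; a planted SNV is a
#'   transition with probability \code{tstvRatio / (1 + tstvRatio)}.
#' @param indelRate expected heterozygous indels per bp.
#' @param indelSizeWeights unnormalised weights for indel sizes 1..8; must be
#'   non-increasing.
#' @param minLen,maxLen contig length floor and cap (bp).
#' @param meanLog,sdLog log-normal parameters of the length law (lengths are
#'   \code{minLen + round(rlnorm)}).
#' @param endBuffer indels are never planted within this many bp of a contig
#'   end, avoiding edge-effect ambiguity in recovery scoring.
#' @param seed integer seed; the generator is a pure function of its
#'   arguments and the seed.
#' @return list with \code{reference} (\code{DNAStringSet}),
#'   \code{haplotypes} (list \code{A}, \code{B} of \code{DNAStringSet}) and
#'   \code{truth} (a \code{\link{SimTruth-class}}).
#' @examples
#' sim <- simulateDiploidTranscriptome(nContigs = 5, seed = 1)
#' truthVariants(sim$truth)
#' @export
simulateDiploidTranscriptome <- function(nContigs = 300, totalBp = NULL,
    snvRate = 1 / 808, tstvRatio = 1.6, indelRate = 8691 / 44.7e6,
    indelSizeWeights = c(5773, 1289, 862, 372, 165, 143, 57, 30),
    minLen = 200L, maxLen = 13061L,
    meanLog = log(253), sdLog = 1.274, endBuffer = 100L, seed = NULL) {
  stopifnot(snvRate >= 0, snvRate <= 1, indelRate >= 0, indelRate <= 1,
            tstvRatio >= 0, length(indelSizeWeights) == 8L)
  if (any(diff(indelSizeWeights) > 0))
    stop("indelSizeWeights must be non-increasing", call. = FALSE)
  if (minLen < 200L)
    stop("contigs shorter than 200 bp requested", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  drawLen <- function(n) pmin(maxLen, minLen + round(stats::rlnorm(n, meanLog, sdLog)))
  if (is.null(totalBp)) {
    lens <- drawLen(nContigs)
  } else {
    lens <- integer(0)
    while (sum(lens) < totalBp) lens <- c(lens, drawLen(256L))
    lens <- lens[seq_len(which(cumsum(lens) >= totalBp)[1])]
  }
  n <- length(lens)
  ids <- sprintf("contig%05d", seq_len(n))
  pTs <- if (is.infinite(tstvRatio)) 1 else tstvRatio / (1 + tstvRatio)
  wIndel <- indelSizeWeights / sum(indelSizeWeights)
  TS_PARTNER <- c(A = "G", G = "A", C = "T", T = "C")

  refs <- character(n); hapB <- character(n)
  maps <- vector("list", n); names(maps) <- ids
  tv <- list(contig = list(), pos = list(), type = list(), ref = list(),
             alt = list(), class = list(), len = list())
  push <- function(contig, pos, type, ref, alt, class, len) {
    k <- length(tv$pos) + 1L
    tv$contig[[k]] <<- rep_len(contig, length(pos)); tv$pos[[k]] <<- pos
    tv$type[[k]] <<- rep_len(type, length(pos)); tv$ref[[k]] <<- ref
    tv$alt[[k]] <<- alt; tv$class[[k]] <<- rep_len(class, length(pos))
    tv$len[[k]] <<- len
  }

  for (i in seq_len(n)) {
    L <- lens[i]
    refChr <- .randomDna(L)
    refRaw <- charToRaw(refChr)

    # indel anchors (left-flanking base positions), kept apart and off the ends
    anchors <- integer(0); itype <- character(0); ilen <- integer(0)
    zLo <- endBuffer; zHi <- L - endBuffer - 9L
    if (zHi > zLo) {
      nInd <- stats::rbinom(1L, zHi - zLo + 1L, indelRate)
      if (nInd > 0) {
        a <- sort(sample.int(zHi - zLo + 1L, min(nInd, zHi - zLo + 1L)) + zLo - 1L)
        a <- a[c(TRUE, diff(a) > 10L)]
        anchors <- a
        itype <- sample(c("ins", "del"), length(a), replace = TRUE)
        ilen <- sample.int(8L, length(a), replace = TRUE, prob = wIndel)
      }
    }

    # SNV sites, excluding deleted spans and indel anchors
    nSnv <- stats::rbinom(1L, L, snvRate)
    snvPos <- sort(sample.int(L, min(nSnv, L)))
    if (length(anchors)) {
      del <- itype == "del"
      banned <- c(anchors,
                  unlist(lapply(which(del), function(j)
                    anchors[j] + seq_len(ilen[j]))))
      snvPos <- setdiff(snvPos, banned)
    }

    # build haplotype B and the B->reference segment map
    segRef <- integer(0); segB <- integer(0); segLen <- integer(0)
    pieces <- list(); cur <- 1L; bcur <- 1L; pk <- 0L
    insSeq <- character(length(anchors)); delSeq <- character(length(anchors))
    for (j in seq_along(anchors)) {
      p <- anchors[j]
      segRef <- c(segRef, cur); segB <- c(segB, bcur)
      segLen <- c(segLen, p - cur + 1L)
      pk <- pk + 1L; pieces[[pk]] <- refRaw[cur:p]
      bcur <- bcur + (p - cur + 1L)
      if (itype[j] == "del") {
        delSeq[j] <- rawToChar(refRaw[(p + 1L):(p + ilen[j])])
        cur <- p + ilen[j] + 1L
      } else {
        ins <- .randomDna(ilen[j])
        insSeq[j] <- ins
        pk <- pk + 1L; pieces[[pk]] <- charToRaw(ins)
        bcur <- bcur + ilen[j]
        cur <- p + 1L
      }
    }
    segRef <- c(segRef, cur); segB <- c(segB, bcur)
    segLen <- c(segLen, L - cur + 1L)
    pk <- pk + 1L; pieces[[pk]] <- refRaw[cur:L]
    bRaw <- unlist(pieces, use.names = FALSE)
    maps[[i]] <- data.frame(bStart = segB, refStart = segRef, len = segLen)

    # plant SNVs on haplotype B (coordinates survive: SNVs are off indels)
    if (length(snvPos)) {
      seg <- findInterval(snvPos, segRef)
      bPos <- segB[seg] + (snvPos - segRef[seg])
      refBase <- strsplit(rawToChar(refRaw[snvPos]), "")[[1]]
      isTs <- stats::runif(length(snvPos)) < pTs
      alt <- character(length(snvPos))
      alt[isTs] <- TS_PARTNER[refBase[isTs]]
      if (any(!isTs)) {
        tvChoices <- vapply(refBase[!isTs], function(b)
          sample(setdiff(.DNA_LETTERS, c(b, TS_PARTNER[[b]])), 1L),
          character(1))
        alt[!isTs] <- tvChoices
      }
      bRaw[bPos] <- charToRaw(paste(alt, collapse = ""))
      push(ids[i], snvPos, "snv", refBase, alt,
           ifelse(isTs, "transition", "transversion"), rep(1L, length(snvPos)))
    }
    if (length(anchors)) {
      anchorBase <- strsplit(rawToChar(refRaw[anchors]), "")[[1]]
      push(ids[i], anchors, NA, anchorBase,
           ifelse(itype == "ins", paste0("+", insSeq), paste0("-", delSeq)),
           "indel", ilen)
      tv$type[[length(tv$type)]] <- itype
    }
    refs[i] <- refChr
    hapB[i] <- rawToChar(bRaw)
  }

  variants <- GenomicRanges::GRanges(
    seqnames = unlist(tv$contig, use.names = FALSE) %||% character(0),
    ranges = IRanges::IRanges(start = unlist(tv$pos) %||% integer(0), width = 1L),
    type = unlist(tv$type) %||% character(0),
    ref = unlist(tv$ref) %||% character(0),
    alt = unlist(tv$alt) %||% character(0),
    class = unlist(tv$class) %||% character(0),
    len = unlist(tv$len) %||% integer(0))
  variants <- BiocGenerics::sort(variants, ignore.strand = TRUE)

  reference <- Biostrings::DNAStringSet(stats::setNames(refs, ids))
  hapBset <- Biostrings::DNAStringSet(stats::setNames(hapB, ids))
  truth <- methods::new("SimTruth", variants = variants,
                        hairpins = S4Vectors::DataFrame(contig = character(0),
                                                        apex = integer(0)),
                        genomeSize = NA_real_, maps = maps)
  list(reference = reference,
       haplotypes = list(A = reference, B = hapBset),
       truth = truth)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a

#' Simulate uniform-coverage genomic short reads from haplotypes
#'
#' Draws fixed-length reads uniformly and in equal proportion from every
#' sequence of every haplotype, with uniform per-base substitution errors and
#' constant Q40 qualities. Coverage is fold-coverage of the haplotype set:
#' total emitted read bases approximate \code{coverage} times the summed
#' haplotype length, so a diploid pair yields about twice \code{coverage} in
#' read depth on the reference.
#'
#' Each haplotype sequence is padded with random flanking sequence (default
#' one read length per side) before sampling, emulating genomic reads that
#' run off the ends of a transcript into intron/UTR context; without the pad,
#' read depth would ramp artificially at contig ends in a way real
#' genomic-versus-transcriptome data does not.
#'
#' @param haplotypes a list of named \code{DNAStringSet}s, one per haplotype
#'   (e.g. \code{sim$haplotypes} from
#'   \code{\link{simulateDiploidTranscriptome}}).
#' @param coverage mean fold-coverage of the haplotype set.
#' @param readLength read length in bp.
#' @param errorRate per-base substitution error probability.
#' @param pad random flank length added to each end of each haplotype
#'   sequence before sampling.
#' @param seed integer seed.
#' @return list with \code{reads} (\code{QualityScaledDNAStringSet}; minus-
#'   strand reads stored reverse-complemented as sequenced),
#'   \code{provenance} (data.frame: readId, contig, hap, strand, start in
#'   padded-haplotype coordinates, readLength), \code{paddedHaplotypes} and
#'   \code{pad}.
#' @export
simulateGenomicReads <- function(haplotypes, coverage = 30, readLength = 100L,
                                 errorRate = 0.005, pad = readLength,
                                 seed = NULL) {
  stopifnot(coverage > 0, errorRate >= 0, errorRate <= 1, readLength >= 1)
  if (!is.null(seed)) set.seed(seed)
  hapNames <- names(haplotypes)
  if (is.null(hapNames)) hapNames <- LETTERS[seq_along(haplotypes)]
  minW <- min(vapply(haplotypes, function(h) min(BiocGenerics::width(h)),
                     numeric(1)))
  if (readLength > minW + 2 * pad)
    stop("readLength exceeds the shortest (padded) sequence", call. = FALSE)

  padded <- list(); seqTab <- list()
  for (h in seq_along(haplotypes)) {
    hs <- as.character(haplotypes[[h]])
    if (pad > 0) {
      lf <- vapply(seq_along(hs), function(i) .randomDna(pad), character(1))
      rf <- vapply(seq_along(hs), function(i) .randomDna(pad), character(1))
      hs <- paste0(lf, hs, rf)
    }
    names(hs) <- names(haplotypes[[h]])
    padded[[h]] <- hs
    seqTab[[h]] <- data.frame(hap = hapNames[h], contig = names(hs),
                              padLen = nchar(hs),
                              rawLen = nchar(hs) - 2L * pad)
  }
  tab <- do.call(rbind, seqTab)
  bigSeq <- paste(unlist(lapply(padded, unname)), collapse = "")
  offs <- c(0, cumsum(as.numeric(tab$padLen)))

  nReads <- pmax(1L, as.integer(round(coverage * tab$rawLen / readLength)))
  seqIdx <- rep(seq_len(nrow(tab)), nReads)
  total <- length(seqIdx)
  startLocal <- integer(total)
  span <- tab$padLen - readLength + 1L
  startLocal <- floor(stats::runif(total) * span[seqIdx]) + 1L
  gs <- offs[seqIdx] + startLocal

  reads <- substring(bigSeq, gs, gs + readLength - 1L)
  # substitution errors over the concatenated read bases
  nb <- total * readLength
  nErr <- stats::rbinom(1L, nb, errorRate)
  if (nErr > 0) {
    big <- charToRaw(paste(reads, collapse = ""))
    ep <- sample(nb, nErr)
    code <- .codeBases(big[ep])
    keep <- !is.na(code)
    shift <- sample.int(3L, sum(keep), replace = TRUE)
    big[ep[keep]] <- charToRaw("ACGT")[((code[keep] - 1L + shift) %% 4L) + 1L]
    bigc <- rawToChar(big)
    st <- (seq_len(total) - 1L) * readLength + 1L
    reads <- substring(bigc, st, st + readLength - 1L)
  }
  strand <- sample(c("+", "-"), total, replace = TRUE)
  minus <- strand == "-"
  if (any(minus)) {
    reads[minus] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(reads[minus])))
  }
  ids <- sprintf("r%08d", seq_len(total))
  dss <- Biostrings::DNAStringSet(stats::setNames(reads, ids))
  q <- Biostrings::PhredQuality(
    Biostrings::BStringSet(rep(strrep("I", readLength), total)))
  qreads <- Biostrings::QualityScaledDNAStringSet(dss, q)
  names(padded) <- hapNames
  list(reads = qreads,
       provenance = data.frame(readId = ids, contig = tab$contig[seqIdx],
                               hap = tab$hap[seqIdx], strand = strand,
                               start = startLocal, readLength = readLength),
       paddedHaplotypes = padded, pad = pad)
}

#' Project simulated reads onto reference coordinates
#'
#' Uses the simulator's provenance and the planted-indel segment maps to emit
#' the block alignments the reads would have against the reference, standing
#' in for an external read mapper. Reads from haplotype B that span planted
#' indels become multi-block (gapped) alignments; bases falling in the random
#' flanking pad are clipped. Matches are counted against the actual reference
#' so sequencing errors lower identity exactly as they would after mapping.
#'
#' @param greads result of \code{\link{simulateGenomicReads}}.
#' @param sim result of \code{\link{simulateDiploidTranscriptome}}.
#' @param chunkBases approximate bases per internal processing chunk.
#' @return a \code{\link{BlockAlignments-class}} object (reads entirely in
#'   the pad are absent).
#' @export
truthAlignments <- function(greads, sim, chunkBases = 3e7) {
  prov <- greads$provenance
  pad <- greads$pad
  refChr <- as.character(sim$reference)
  refLen <- nchar(refChr)
  hapBLen <- stats::setNames(BiocGenerics::width(sim$haplotypes$B),
                             names(sim$haplotypes$B))
  maps <- sim$truth@maps

  # one global axis over (hap, contig) in haplotype coordinates
  keyRead <- paste(prov$hap, prov$contig, sep = "\r")
  segKey <- c(paste("A", names(refChr), sep = "\r"),
              paste("B", names(refChr), sep = "\r"))
  segLenTot <- c(refLen, hapBLen[names(refChr)])
  axOff <- stats::setNames(c(0, cumsum(as.numeric(segLenTot)))[seq_along(segKey)],
                           segKey)

  # segment table: hap A identity + hap B maps
  nB <- vapply(maps, nrow, integer(1))
  segDf <- data.frame(
    key = c(paste("A", names(refChr), sep = "\r"),
            rep(paste("B", names(maps), sep = "\r"), nB)),
    contig = c(names(refChr), rep(names(maps), nB)),
    bStart = c(rep(1L, length(refChr)),
               unlist(lapply(maps, `[[`, "bStart"), use.names = FALSE)),
    refStart = c(rep(1L, length(refChr)),
                 unlist(lapply(maps, `[[`, "refStart"), use.names = FALSE)),
    len = c(refLen, unlist(lapply(maps, `[[`, "len"), use.names = FALSE)))
  segDf <- segDf[segDf$len > 0L, ]

  hapLenOf <- ifelse(prov$hap == "A", refLen[prov$contig],
                     hapBLen[prov$contig])
  s <- prov$start - pad
  e <- s + prov$readLength - 1L
  s2 <- pmax(s, 1L); e2 <- pmin(e, hapLenOf)
  keep <- which(s2 <= e2)

  qIR <- IRanges::IRanges(start = axOff[keyRead[keep]] + s2[keep],
                          end = axOff[keyRead[keep]] + e2[keep])
  sIR <- IRanges::IRanges(start = axOff[segDf$key] + segDf$bStart,
                          width = segDf$len)
  ov <- IRanges::findOverlaps(qIR, sIR)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  rIdx <- keep[qh]

  ovS <- pmax(IRanges::start(qIR)[qh], IRanges::start(sIR)[sh])
  ovE <- pmin(IRanges::end(qIR)[qh], IRanges::end(sIR)[sh])
  # back to local haplotype coordinates
  locS <- ovS - axOff[keyRead[rIdx]]
  qStart <- as.integer(locS - s[rIdx] + 1L)
  tStart <- as.integer(segDf$refStart[sh] + (locS - segDf$bStart[sh]))
  bl <- as.integer(ovE - ovS + 1L)

  # order blocks by read, then contig coordinate
  o <- order(qh, tStart)
  qh <- qh[o]; rIdx <- rIdx[o]; qStart <- qStart[o]
  tStart <- tStart[o]; bl <- bl[o]

  # oriented read sequences (plus strand of the haplotype)
  seqs <- as.character(greads$reads)
  minus <- prov$strand == "-"
  if (any(minus))
    seqs[minus] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seqs[minus])))

  # per-block match counts, chunked over blocks
  nBlocks <- length(qh)
  matchPerBlock <- integer(nBlocks)
  if (nBlocks) {
    csize <- max(1L, as.integer(chunkBases / max(mean(bl), 1)))
    starts <- seq(1L, nBlocks, by = csize)
    for (cs in starts) {
      ce <- min(cs + csize - 1L, nBlocks)
      ii <- cs:ce
      rw <- substring(seqs[rIdx[ii]], qStart[ii], qStart[ii] + bl[ii] - 1L)
      fw <- substring(refChr[prov$contig[rIdx[ii]]], tStart[ii],
                      tStart[ii] + bl[ii] - 1L)
      a <- charToRaw(paste(rw, collapse = ""))
      b <- charToRaw(paste(fw, collapse = ""))
      eq <- which(a == b)
      blockOf <- rep(seq_along(ii), bl[ii])
      matchPerBlock[ii] <- tabulate(blockOf[eq], nbins = length(ii))
    }
  }

  # collapse blocks to alignments
  firstOf <- !duplicated(qh)
  alnRead <- rIdx[firstOf]
  part <- IRanges::PartitioningByEnd(cumsum(S4Vectors::runLength(S4Vectors::Rle(qh))))
  qL <- IRanges::relist(qStart, part)
  tL <- IRanges::relist(tStart, part)
  bL <- IRanges::relist(bl, part)
  mm <- IRanges::relist(matchPerBlock, part)
  nAln <- sum(firstOf)
  # gap openings between consecutive blocks, computed flat
  gaps <- integer(nAln)
  if (nBlocks > 1L) {
    alnOf <- cumsum(firstOf)
    same <- which(qh[-1L] == qh[-nBlocks])
    if (length(same)) {
      tg <- tStart[same + 1L] - (tStart[same] + bl[same])
      qg <- qStart[same + 1L] - (qStart[same] + bl[same])
      gaps <- tabulate(alnOf[same[tg > 0L]], nbins = nAln) +
        tabulate(alnOf[same[qg > 0L]], nbins = nAln)
    }
  }
  tb <- S4Vectors::DataFrame(
    readId = prov$readId[alnRead],
    contigId = prov$contig[alnRead],
    strand = prov$strand[alnRead],
    qStart = qL, tStart = tL, blockLen = bL,
    matches = as.integer(sum(mm)),
    alignedBases = as.integer(sum(bL)),
    gaps = gaps,
    readLength = prov$readLength[alnRead])
  methods::new("BlockAlignments", table = tb)
}

#' Simulate long paired-end reads from opposite contig ends
#'
#' Emulates paired forward/reverse capillary ("Sanger-like") reads of a
#' size-selected cDNA clone: the forward read is taken from the 5' end of a
#' sampled insert on the plus strand and the reverse read from the 3' end on
#' the minus strand of the same source contig.
#'
#' @param contigs a named \code{DNAStringSet}.
#' @param nPairs number of pairs.
#' @param insertMean,insertSd normal insert-size law, truncated to fit.
#' @param readLength read length (must be shorter than the insert).
#' @param seed integer seed.
#' @return list with \code{reads} (\code{DNAStringSet} of 2*nPairs reads),
#'   \code{pairs} (data.frame fwd/rev read ids) and \code{truth}
#'   (data.frame with the source contig per pair).
#' @export
simulateSangerPairs <- function(contigs, nPairs = 100L, insertMean = 1950,
                                insertSd = 300, readLength = 700L,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  w <- BiocGenerics::width(contigs)
  elig <- which(w > readLength + 50L)
  if (!length(elig)) stop("no contig long enough for the insert", call. = FALSE)
  src <- sample(elig, nPairs, replace = TRUE)
  L <- w[src]
  ins <- pmin(L, pmax(readLength + 1L,
                      round(stats::rnorm(nPairs, insertMean, insertSd))))
  insStart <- floor(stats::runif(nPairs) * (L - ins + 1)) + 1L
  cchr <- .asSeqChar(contigs)
  fwd <- substring(cchr[src], insStart, insStart + readLength - 1L)
  insEnd <- insStart + ins - 1L
  rev <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(
    substring(cchr[src], insEnd - readLength + 1L, insEnd))))
  fids <- sprintf("pair%04d_F", seq_len(nPairs))
  rids <- sprintf("pair%04d_R", seq_len(nPairs))
  reads <- Biostrings::DNAStringSet(stats::setNames(c(fwd, rev), c(fids, rids)))
  list(reads = reads,
       pairs = data.frame(fwd = fids, rev = rids),
       truth = data.frame(pair = seq_len(nPairs),
                          contig = names(contigs)[src],
                          insStart = insStart, insertLen = ins))
}

#' Append an inverted-repeat arm to a contig (planted hairpin)
#'
#' Appends the reverse complement of the contig's last \code{armLength} bases,
#' producing the palindromic fold characteristic of a mis-assembled hairpin
#' contig; the apex (fold point) is returned as truth. \code{armLength = 0}
#' returns the input unchanged.
#'
#' @param contig a single DNA sequence (character).
#' @param armLength length of the inverted-repeat arm in bp.
#' @param nMut number of random substitutions to scatter in the appended arm
#'   (for testing identity thresholds).
#' @param seed integer seed (used only when \code{nMut > 0}).
#' @return list with \code{contig} (character) and \code{apex} (integer
#'   position of the fold; NA when \code{armLength = 0}).
#' @export
injectHairpin <- function(contig, armLength, nMut = 0L, seed = NULL) {
  stopifnot(length(contig) == 1L, armLength >= 0L)
  if (armLength == 0L) return(list(contig = contig, apex = NA_integer_))
  L <- nchar(contig)
  stopifnot(armLength <= L)
  arm <- revComp(substr(contig, L - armLength + 1L, L))
  if (nMut > 0L) {
    if (!is.null(seed)) set.seed(seed)
    pos <- sample.int(armLength, min(nMut, armLength))
    a <- charToRaw(arm)
    code <- .codeBases(a[pos])
    a[pos] <- charToRaw("ACGT")[(code %% 4L) + 1L]
    arm <- rawToChar(a)
  }
  list(contig = paste0(contig, arm), apex = L)
}

#' Simulate a genome with an embedded transcribed fraction
#'
#' Generates a random genome, designates non-overlapping intervals totalling
#' \code{transcribedFraction} of it as transcripts, and returns those
#' intervals as an assembled "transcriptome" alongside the genome — the setup
#' under which modal-coverage genome-size estimation can be scored end to end.
#'
#' @param genomeSize genome length in bp.
#' @param transcribedFraction fraction of the genome covered by transcripts.
#' @param minLen,maxLen,meanLog,sdLog transcript length law (as in
#'   \code{\link{simulateDiploidTranscriptome}}).
#' @param seed integer seed.
#' @return list with \code{genome} (\code{DNAStringSet} of length 1),
#'   \code{contigs} (\code{DNAStringSet}), \code{intervals} (data.frame) and
#'   \code{genomeSize}.
#' @export
simulateGenomeWithTranscriptome <- function(genomeSize = 5e6,
    transcribedFraction = 0.4, minLen = 200L, maxLen = 13061L,
    meanLog = log(253), sdLog = 1.274, seed = NULL) {
  stopifnot(transcribedFraction > 0, transcribedFraction < 1)
  if (!is.null(seed)) set.seed(seed)
  genome <- .randomDna(genomeSize)
  target <- transcribedFraction * genomeSize
  lens <- integer(0)
  while (sum(lens) < target)
    lens <- c(lens, pmin(maxLen, minLen + round(stats::rlnorm(256L, meanLog, sdLog))))
  lens <- lens[seq_len(which(cumsum(lens) >= target)[1])]
  n <- length(lens)
  slack <- genomeSize - sum(lens)
  if (slack < 0) stop("transcribed fraction does not fit", call. = FALSE)
  cuts <- sort(sample.int(slack + 1L, n, replace = TRUE)) - 1L
  starts <- cuts + c(0, cumsum(lens))[seq_len(n)] + 1L
  ids <- sprintf("tx%05d", seq_len(n))
  contigs <- Biostrings::DNAStringSet(
    stats::setNames(substring(genome, starts, starts + lens - 1L), ids))
  list(genome = Biostrings::DNAStringSet(c(genome = genome)),
       contigs = contigs,
       intervals = data.frame(contig = ids, start = starts,
                              end = starts + lens - 1L),
       genomeSize = genomeSize)
}

#' Write / read a planted-variant truth table as TSV
#'
#' @param truth a \code{SimTruth} object.
#' @param path output TSV path (columns contig, pos, type, ref, alt, class,
#'   len).
#' @export
writeTruthTable <- function(truth, path) {
  v <- truthVariants(truth)
  df <- data.frame(contig = as.character(GenomicRanges::seqnames(v)),
                   pos = GenomicRanges::start(v),
                   type = v$type, ref = v$ref, alt = v$alt,
                   class = v$class, len = v$len)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTruthTable
#' @param path path to a truth TSV.
#' @export
readTruthTable <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  GenomicRanges::GRanges(seqnames = df$contig,
                         ranges = IRanges::IRanges(df$pos, width = 1L),
                         type = df$type, ref = df$ref, alt = df$alt,
                         class = df$class, len = df$len)
}
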