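#' Call heterozygous SNVs and indels from a pileup
#'
#' At every site with depth at least \code{minCov}, the most frequent
#' non-reference base (ties broken alphabetically) is called an SNV when it
#' accounts for at least \code{minFrac} of the site depth; both thresholds
#' are inclusive. An indel is called at a site when the fraction of reads
#' opening an insertion (or deletion) there reaches the same thresholds; the
#' reported allele is the most frequent indel event at the site. The fraction
#' denominator is the total site depth, the most literal reading of
#' "fraction of the reads at that site". Sites where the reference base
#' itself falls below \code{minFrac} are still reported as single SNVs and
#' flagged (\code{refMinority}).
#'
#' @param pileup a \code{\link{Pileup-class}} object.
#' @param contigs the reference contigs the pileup was built over.
#' @param minCov minimum site depth (default 10).
#' @param minFrac minimum alternative-allele fraction of site depth
#'   (default 0.35).
#' @return a sorted \code{GRanges} with mcols \code{type} (\code{"SNV"},
#'   \code{"insertion"}, \code{"deletion"}), \code{ref}, \code{alt} (base, or
#'   \code{"+seq"}/\code{"-seq"} for indels anchored at the left-flanking
#'   position), \code{class} (transition/transversion/indel), \code{depth},
#'   \code{altCount}, \code{altFraction}, \code{len} and \code{refMinority}.
#' @export
callVariants <- function(pileup, contigs, minCov = 10L, minFrac = 0.35) {
  cs <- .asSeqChar(contigs)
  lens <- pileup@contigLens
  if (!setequal(names(cs), names(lens)) ||
      !all(nchar(cs)[names(lens)] == lens))
    stop("pileup/contig mismatch", call. = FALSE)
  cs <- cs[names(lens)]
  counts <- pileup@counts
  N <- ncol(counts)
  depth <- .colSums(counts, 4L, N)
  refCode <- .codeBases(charToRaw(paste(cs, collapse = "")))

  cand <- which(depth >= minCov & !is.na(refCode))
  out <- list()
  if (length(cand)) {
    m <- counts[, cand, drop = FALSE]
    ri <- refCode[cand]
    sel <- cbind(ri, seq_along(cand))
    refCount <- m[sel]
    m2 <- m
    m2[sel] <- -1L
    altIdx <- max.col(t(m2), ties.method = "first")
    altCount <- m[cbind(altIdx, seq_along(cand))]
    d <- depth[cand]
    isCall <- altCount >= minFrac * d & altCount > 0L
    if (any(isCall)) {
      g <- cand[isCall]
      ctgIdx <- findInterval(g - 1, c(0, cumsum(as.numeric(lens))),
                             rightmost.closed = FALSE)
      offs <- c(0, cumsum(as.numeric(lens)))
      pos <- as.integer(g - offs[ctgIdx])
      ref <- .DNA_LETTERS[ri[isCall]]
      alt <- .DNA_LETTERS[altIdx[isCall]]
      out$snv <- data.frame(
        contig = names(lens)[ctgIdx], pos = pos, type = "SNV",
        ref = ref, alt = alt,
        class = classifySubstitution(ref, alt),
        depth = d[isCall], altCount = altCount[isCall],
        len = 1L,
        refMinority = refCount[isCall] < minFrac * d[isCall])
    }
  }

  ev <- pileup@indelEvents
  if (nrow(ev)) {
    offs <- stats::setNames(pileup@offsets, names(lens))
    g <- offs[ev$contig] + ev$pos
    byType <- paste(ev$contig, ev$pos, ev$type, sep = "\r")
    openTotal <- if (nrow(ev)) {
      tot <- rowsum(as.numeric(ev$count), byType)
      as.numeric(tot[byType, 1])
    } else numeric(0)
    d <- depth[g]
    siteOk <- d >= minCov & openTotal >= minFrac * d
    if (any(siteOk)) {
      sub <- ev[siteOk, , drop = FALSE]
      dSub <- d[siteOk]; totSub <- openTotal[siteOk]
      keySub <- byType[siteOk]
      # representative event per site = highest count, then first seen
      o <- order(keySub, -sub$count)
      sub <- sub[o, , drop = FALSE]
      dSub <- dSub[o]; totSub <- totSub[o]; keySub <- keySub[o]
      first <- !duplicated(keySub)
      sub <- sub[first, , drop = FALSE]
      dSub <- dSub[first]; totSub <- totSub[first]
      anchor <- substr(cs[sub$contig], sub$pos, sub$pos)
      out$indel <- data.frame(
        contig = sub$contig, pos = sub$pos,
        type = ifelse(sub$type == "ins", "insertion", "deletion"),
        ref = anchor,
        alt = paste0(ifelse(sub$type == "ins", "+", "-"), sub$seq),
        class = "indel",
        depth = as.integer(dSub), altCount = as.integer(round(totSub)),
        len = sub$len,
        refMinority = FALSE)
    }
  }

  if (!length(out)) {
    return(GenomicRanges::GRanges(
      seqnames = character(0), ranges = IRanges::IRanges(),
      type = character(0), ref = character(0), alt = character(0),
      class = character(0), depth = integer(0), altCount = integer(0),
      altFraction = numeric(0), len = integer(0), refMinority = logical(0)))
  }
  df <- do.call(rbind, out)
  gr <- GenomicRanges::GRanges(
    seqnames = df$contig, ranges = IRanges::IRanges(df$pos, width = 1L),
    type = df$type, ref = df$ref, alt = df$alt, class = df$class,
    depth = df$depth, altCount = df$altCount,
    altFraction = df$altCount / df$depth, len = df$len,
    refMinority = df$refMinority)
  BiocGenerics::sort(gr, ignore.strand = TRUE)
}

#' Classify a base substitution as transition or transversion
#'
#' Transitions are the purine-purine and pyrimidine-pyrimidine exchanges
#' (A/G and C/T); every other pair is a transversion. The classification is
#' unordered: (A,G) and (G,A) are the same class.
#'
#' @param ref,alt base vectors over {A,C,G,T}; \code{ref != alt} elementwise.
#' @return character vector of \code{"transition"}/\code{"transversion"}.
#' @examples
#' classifySubstitution("A", "G")  # transition
#' classifySubstitution("G", "C")  # transversion
#' @export
classifySubstitution <- function(ref, alt) {
  if (!all(ref %in% .DNA_LETTERS) || !all(alt %in% .DNA_LETTERS))
    stop("bases must be A, C, G or T", call. = FALSE)
  if (any(ref == alt))
    stop("ref and alt must differ", call. = FALSE)
  pur <- c("A", "G")
  ifelse((ref %in% pur) == (alt %in% pur), "transition", "transversion")
}

#' SNV density as base pairs per SNV
#'
#' @param totalBp total contig base pairs surveyed.
#' @param nSnvs number of SNVs.
#' @return integer-rounded bp per SNV, or NA when \code{nSnvs} is zero (the
#'   density is undefined, not infinite).
#' @examples
#' snvDensity(44.7e6, 55300)  # 808
#' @export
snvDensity <- function(totalBp, nSnvs) {
  if (nSnvs == 0) return(NA_real_)
  round(totalBp / nSnvs)
}

#' Summarize a variant call set
#'
#' Tabulates SNVs by unordered base-pair class (A/G, C/T, A/C, G/C, A/T,
#' G/T), indels by size (1..8 with an overflow bin), and reports the SNV
#' density in bp per SNV.
#'
#' @param calls a \code{GRanges} from \code{\link{callVariants}}.
#' @param totalBp total contig base pairs the calls were made over.
#' @return a \code{\link{VariantSummary-class}} object.
#' @export
summarizeVariants <- function(calls, totalBp) {
  CLASSES <- c("A/G", "C/T", "A/C", "G/C", "A/T", "G/T")
  pairKey <- stats::setNames(
    c("A/G", "A/G", "C/T", "C/T", "A/C", "A/C", "G/C", "G/C",
      "A/T", "A/T", "G/T", "G/T"),
    c("A_G", "G_A", "C_T", "T_C", "A_C", "C_A", "G_C", "C_G",
      "A_T", "T_A", "G_T", "T_G"))
  snv <- calls[calls$type == "SNV"]
  cc <- stats::setNames(integer(6), CLASSES)
  if (length(snv)) {
    k <- pairKey[paste(snv$ref, snv$alt, sep = "_")]
    tt <- table(factor(k, levels = CLASSES))
    cc[] <- as.integer(tt)
  }
  ind <- calls[calls$class == "indel"]
  hl <- c(as.character(1:8), ">8")
  hh <- stats::setNames(integer(9), hl)
  if (length(ind)) {
    b <- ifelse(ind$len > 8L, ">8", as.character(ind$len))
    tt <- table(factor(b, levels = hl))
    hh[] <- as.integer(tt)
  }
  methods::new("VariantSummary",
               snvClassCounts = cc, indelCount = length(ind),
               indelSizeHist = hh, totalSnvs = length(snv),
               totalBp = as.numeric(totalBp),
               bpPerSnv = snvDensity(totalBp, length(snv)))
}

#' Write variant calls as minimal VCF 4.2
#'
#' SNVs are written at their 1-based position; indels are left-anchored with
#' the preceding reference base (REF = anchor + deleted bases for deletions;
#' ALT = anchor + inserted bases for insertions). INFO carries DP and AF.
#'
#' @param calls sorted \code{GRanges} from \code{\link{callVariants}}.
#' @param contigs the reference contigs (for header lengths).
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeVariantVcf <- function(calls, contigs, path) {
  o <- order(match(as.character(GenomicRanges::seqnames(calls)),
                   names(contigs)), GenomicRanges::start(calls))
  if (!identical(o, seq_along(calls)) &&
      !identical(order(as.character(GenomicRanges::seqnames(calls)),
                       GenomicRanges::start(calls)), seq_along(calls)))
    stop("calls must be sorted by contig and position", call. = FALSE)
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                   nchar(.asSeqChar(contigs))),
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Site depth\">",
           "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Alternative allele fraction\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  if (length(calls)) {
    ctg <- as.character(GenomicRanges::seqnames(calls))
    pos <- GenomicRanges::start(calls)
    ref <- calls$ref; alt <- calls$alt
    ins <- calls$type == "insertion"
    del <- calls$type == "deletion"
    ref[del] <- paste0(calls$ref[del], sub("^-", "", alt[del]))
    alt[del] <- calls$ref[del]
    alt[ins] <- paste0(calls$ref[ins], sub("^\\+", "", alt[ins]))
    rows <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tDP=%d;AF=%.4f",
                    ctg, pos, ref, alt, calls$depth, calls$altFraction)
  } else rows <- character(0)
  writeLines(c(hdr, rows), path)
  invisible(path)
}
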