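#' Detect a palindromic (hairpin) fold in a contig
#'
#' A hairpin mis-assembly reads the same molecule out and back, so the
#' second arm of the contig is (nearly) the reverse complement of the first.
#' The scan tests every candidate apex k: the suffix starting at k+1 is
#' compared un-gapped against the reverse complement of the prefix ending at
#' k, and the longest arm with identity at or above \code{minIdentity} is
#' taken. A call requires an arm of at least \code{minArm} bases; the apex
#' reported is the fold point (last base of the first arm), with ties broken
#' toward the lower coordinate.
#'
#' @param contig a single DNA sequence (character) or \code{DNAString}.
#' @param minArm minimum inverted-repeat arm length (bp).
#' @param minIdentity minimum fraction of arm positions matching.
#' @return a list (contig id-less hairpin call) with \code{apex},
#'   \code{armLength} and \code{identity}, or \code{NULL} when no hairpin is
#'   found (including contigs shorter than \code{2 * minArm}).
#' @export
detectHairpin <- function(contig, minArm = 100L, minIdentity = 0.95) {
  s <- as.character(contig)
  n <- nchar(s)
  if (n < 2L * minArm) return(NULL)
  x <- .codeBases(charToRaw(s))          # 1..4, NA for N
  compx <- c(4L, 3L, 2L, 1L)[x]          # complement codes (T,G,C,A)

  bestArm <- 0L; bestApex <- NA_integer_; bestIdent <- 0
  for (k in minArm:(n - minArm)) {
    amax <- min(k, n - k)
    v1 <- x[(k + 1L):(k + amax)]
    v2 <- compx[k:(k - amax + 1L)]
    m <- !is.na(v1) & !is.na(v2) & v1 == v2
    cm <- cumsum(m) / seq_len(amax)
    okA <- which(cm >= minIdentity)
    okA <- okA[okA >= minArm]
    if (length(okA)) {
      a <- okA[length(okA)]
      if (a > bestArm) {
        bestArm <- a; bestApex <- k; bestIdent <- cm[a]
      }
    }
  }
  if (bestArm < minArm) return(NULL)
  list(apex = bestApex, armLength = bestArm, identity = bestIdent)
}

#' Split a hairpin contig at its apex
#'
#' Returns the two halves \code{contig[1..apex]} and
#' \code{contig[(apex+1)..n]}; their concatenation reproduces the input
#' exactly. Ids are suffixed \code{".a"} and \code{".b"}.
#'
#' @param contig a single named DNA sequence (character with a name, or an
#'   element of a named set).
#' @param call a hairpin call from \code{\link{detectHairpin}}.
#' @param id contig identifier (defaults to the name of \code{contig}).
#' @return named character vector of the two contigs.
#' @export
splitHairpin <- function(contig, call, id = names(contig)) {
  s <- as.character(contig)
  n <- nchar(s)
  apex <- call$apex
  if (is.null(apex) || is.na(apex) || apex < 1L || apex >= n)
    stop("apex out of range", call. = FALSE)
  if (is.null(id)) id <- "contig"
  stats::setNames(c(substr(s, 1L, apex), substr(s, apex + 1L, n)),
                  paste0(id, c(".a", ".b")))
}

#' Detect and split hairpin contigs across an assembly
#'
#' Applies \code{\link{detectHairpin}} to every contig, splits each call at
#' its apex, and (by default) drops any resulting contig shorter than
#' \code{minLen}, mirroring the downstream 200-bp contig floor. Total bases
#' are conserved before the length filter.
#'
#' @param contigs a named \code{DNAStringSet} or character vector.
#' @param minArm,minIdentity detection parameters.
#' @param minLen length floor applied to the split products; set to 0 to
#'   disable.
#' @return list with \code{contigs} (repaired \code{DNAStringSet}) and
#'   \code{calls} (data.frame: contig, apex, armLength, identity).
#' @export
repairHairpins <- function(contigs, minArm = 100L, minIdentity = 0.95,
                           minLen = 200L) {
  cs <- .asSeqChar(contigs)
  calls <- list()
  out <- character(0)
  for (i in seq_along(cs)) {
    id <- names(cs)[i]
    hc <- detectHairpin(cs[i], minArm = minArm, minIdentity = minIdentity)
    if (is.null(hc)) {
      out <- c(out, stats::setNames(cs[i], id))
    } else {
      calls[[length(calls) + 1L]] <-
        data.frame(contig = id, apex = hc$apex, armLength = hc$armLength,
                   identity = hc$identity)
      out <- c(out, splitHairpin(cs[i], hc, id = id))
    }
  }
  if (minLen > 0L) out <- out[nchar(out) >= minLen]
  list(contigs = Biostrings::DNAStringSet(out),
       calls = if (length(calls)) do.call(rbind, calls)
               else data.frame(contig = character(0), apex = integer(0),
                               armLength = integer(0), identity = numeric(0)))
}
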