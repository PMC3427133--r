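#' Find open reading frames in all six frames
#'
#' ORFs are maximal stop-to-stop stretches (sequence ends count as
#' boundaries) of at least \code{minAa} residues, translated with the
#' standard genetic code. Coordinates are nucleotide positions on the
#' contig's plus strand, 1-based closed, and \code{(end - start + 1)} is
#' always divisible by 3. Ordering is deterministic: frames +1, +2, +3, -1,
#' -2, -3, then coordinate.
#'
#' @param contig a single DNA sequence (character or \code{DNAString}), or a
#'   named set (\code{DNAStringSet}/named character) scanned contig by
#'   contig.
#' @param minAa minimum protein length in residues (default 60; GLW-amide
#'   precursors carry many repeats and are long).
#' @return a \code{DataFrame} with columns \code{contig}, \code{frame}
#'   (+1..+3, -1..-3), \code{start}, \code{end}, \code{protein}.
#' @export
findOrfs <- function(contig, minAa = 60L) {
  cs <- .asSeqChar(contig)
  if (is.null(names(cs)))
    names(cs) <- if (length(cs) == 1L) "contig" else
      sprintf("contig%04d", seq_along(cs))
  rows <- list()
  for (ci in seq_along(cs)) {
    s <- cs[ci]
    n <- nchar(s)
    rcs <- revComp(s)
    for (fr in c(1L, 2L, 3L, -1L, -2L, -3L)) {
      tmpl <- if (fr > 0L) s else rcs
      off <- abs(fr)
      usable <- n - off + 1L
      usable <- usable - usable %% 3L
      if (usable < 3L) next
      aa <- as.character(Biostrings::translate(
        Biostrings::DNAString(substr(tmpl, off, off + usable - 1L)),
        if.fuzzy.codon = "X"))
      # maximal stop-to-stop segments
      stops <- gregexpr("*", aa, fixed = TRUE)[[1]]
      bounds <- c(0L, if (stops[1] != -1L) as.integer(stops),
                  nchar(aa) + 1L)
      for (b in seq_len(length(bounds) - 1L)) {
        aaS <- bounds[b] + 1L; aaE <- bounds[b + 1L] - 1L
        if (aaE - aaS + 1L < minAa) next
        prot <- substr(aa, aaS, aaE)
        ntS <- off + 3L * (aaS - 1L)            # on the template strand
        ntE <- off + 3L * aaE - 1L
        if (fr > 0L) { start <- ntS; end <- ntE }
        else { start <- n - ntE + 1L; end <- n - ntS + 1L }
        rows[[length(rows) + 1L]] <- data.frame(
          contig = names(cs)[ci], frame = fr, start = start, end = end,
          protein = prot, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(S4Vectors::DataFrame(contig = character(0), frame = integer(0),
                                start = integer(0), end = integer(0),
                                protein = character(0)))
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  S4Vectors::DataFrame(df)
}

#' Scan ORFs for repeated-GLW neuropeptide precursors
#'
#' A precursor candidate is an ORF whose protein contains at least
#' \code{minMotifs} occurrences of the tripeptide GLW. Each motif is
#' classified by the residues that follow it, which determine whether the
#' mature peptide can be C-terminally amidated (the amide is donated by a
#' glycine): G directly after the motif gives an amidated GLW-NH2 peptide;
#' CG gives a cysteine-extended amidated GLWC-NH2 peptide; a C without a
#' following G leaves a cysteine-extended but unamidated GLWC peptide;
#' anything else is classed other.
#'
#' @param orfs a \code{DataFrame} from \code{\link{findOrfs}} (or any table
#'   with \code{contig}, \code{frame}, \code{start}, \code{end},
#'   \code{protein}).
#' @param minMotifs minimum number of GLW motifs (default 3).
#' @return a \code{DataFrame} with the ORF columns plus \code{nMotifs},
#'   \code{motifPos} (an \code{IntegerList} of 1-based protein indices of
#'   each GLW) and \code{motifClass} (a \code{CharacterList} over
#'   \code{"amidated"}, \code{"cys-amidated"}, \code{"cys-unamidated"},
#'   \code{"other"}).
#' @export
scanGlwPrecursors <- function(orfs, minMotifs = 3L) {
  pos <- list(); cls <- list(); keep <- integer(0)
  for (i in seq_len(nrow(orfs))) {
    p <- orfs$protein[i]
    mp <- gregexpr("GLW", p, fixed = TRUE)[[1]]
    if (mp[1] == -1L || length(mp) < minMotifs) next
    mp <- as.integer(mp)
    nxt1 <- substr(rep(p, length(mp)), mp + 3L, mp + 3L)
    nxt2 <- substr(rep(p, length(mp)), mp + 4L, mp + 4L)
    cl <- ifelse(nxt1 == "G", "amidated",
          ifelse(nxt1 == "C" & nxt2 == "G", "cys-amidated",
          ifelse(nxt1 == "C", "cys-unamidated", "other")))
    keep <- c(keep, i)
    pos[[length(pos) + 1L]] <- mp
    cls[[length(cls) + 1L]] <- cl
  }
  out <- S4Vectors::DataFrame(orfs[keep, , drop = FALSE])
  out$nMotifs <- lengths(pos)
  out$motifPos <- IRanges::IntegerList(pos)
  out$motifClass <- methods::as(cls, "CharacterList")
  out
}

#' Predict mature peptides from a GLW precursor hit
#'
#' Applies the canonical pro-hormone processing grammar to each motif of a
#' precursor: the peptide is excised between the nearest basic residues
#' (K/R) upstream and downstream of the motif core (endoprotease cleavage
#' C-terminal to the basic residue); the C-terminal glycine is consumed by
#' amidation when the motif class provides one; X-Ala / X-Pro dipeptides are
#' then trimmed iteratively from the N-terminus (dipeptidylaminopeptidase
#' action); and a leading glutamine marks an N-terminal pyroglutamate.
#' Motifs with no basic residue on either side, or whose excised fragment
#' does not terminate at the motif core (plus donor glycine), are skipped
#' with a warning.
#'
#' @param hit one row of the \code{\link{scanGlwPrecursors}} output (a
#'   \code{DataFrame} row, or a list with \code{protein}, \code{motifPos},
#'   \code{motifClass}).
#' @return a \code{DataFrame} with columns \code{motifIndex},
#'   \code{sequence}, \code{nTerminalPyroglu}, \code{cTerminalAmide} and
#'   \code{display} (field notation, e.g. \code{"pEPLPIGLW-NH2"}).
#' @export
predictMaturePeptides <- function(hit) {
  prot <- if (is.list(hit) && !is.null(hit$protein)) hit$protein[[1]]
          else as.character(hit[, "protein"])
  mp <- unlist(hit$motifPos)
  cl <- unlist(hit$motifClass)
  res <- strsplit(prot, "")[[1]]
  basic <- which(res %in% c("K", "R"))

  rows <- list()
  for (j in seq_along(mp)) {
    p <- mp[j]
    coreEnd <- p + 2L + (cl[j] %in% c("cys-amidated", "cys-unamidated"))
    donor <- cl[j] %in% c("amidated", "cys-amidated")
    tailEnd <- coreEnd + donor
    up <- basic[basic < p]
    dn <- basic[basic > tailEnd]
    if (!length(up) || !length(dn)) {
      warning("motif ", j, ": no flanking basic residue; skipped",
              call. = FALSE)
      next
    }
    u <- max(up); d <- min(dn)
    if (d != tailEnd + 1L) {
      warning("motif ", j, ": fragment does not end at the motif core; ",
              "skipped", call. = FALSE)
      next
    }
    frag <- substr(prot, u + 1L, d - 1L)
    if (donor) frag <- substr(frag, 1L, nchar(frag) - 1L)
    # dipeptidylaminopeptidase trimming: remove leading X-A / X-P dipeptides;
    # a leading Q cyclises to pyroglutamate, which blocks further trimming
    while (nchar(frag) > 2L && substr(frag, 1L, 1L) != "Q" &&
           substr(frag, 2L, 2L) %in% c("A", "P"))
      frag <- substr(frag, 3L, nchar(frag))
    pyro <- substr(frag, 1L, 1L) == "Q"
    disp <- frag
    if (pyro) disp <- paste0("pE", substr(frag, 2L, nchar(frag)))
    if (donor) disp <- paste0(disp, "-NH2")
    rows[[length(rows) + 1L]] <- data.frame(
      motifIndex = j, sequence = frag, nTerminalPyroglu = pyro,
      cTerminalAmide = donor, display = disp, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(S4Vectors::DataFrame(motifIndex = integer(0),
                                sequence = character(0),
                                nTerminalPyroglu = logical(0),
                                cTerminalAmide = logical(0),
                                display = character(0)))
  S4Vectors::DataFrame(do.call(rbind, rows))
}

#' Parse a peptide query in field notation
#'
#' Accepts plain amino-acid strings or the customary notation with an
#' N-terminal pyroglutamate written \code{pE} (derived from a glutamine, so
#' it parses to Q) and a C-terminal amide written \code{-NH2} (or
#' \code{-NH_2_}).
#'
#' @param query the query string, e.g. \code{"pEPLPIGLW-NH2"}.
#' @return list with \code{core} (amino-acid string), \code{amidated} and
#'   \code{pyroglu} (logicals).
#' @examples
#' parsePeptideQuery("pEPLPIGLW-NH_2_")  # Hym-248: core QPLPIGLW, amidated
#' @export
parsePeptideQuery <- function(query) {
  stopifnot(length(query) == 1L, is.character(query))
  q <- query
  amid <- grepl("-NH_?2_?$", q)
  q <- sub("-NH_?2_?$", "", q)
  pyro <- grepl("^pE", q)
  if (pyro) q <- sub("^pE", "Q", q)
  if (!grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", q))
    stop("unparseable peptide query: ", query, call. = FALSE)
  list(core = q, amidated = amid, pyroglu = pyro)
}

#' Match a query peptide against predicted mature peptides
#'
#' An exact match requires the identical core sequence, the same amidation
#' state, and pyroglutamate compatibility (a pE query can only match a
#' peptide whose N-terminal residue is the glutamine it derives from).
#' C-terminal suffix matches — one core being a proper suffix of the other,
#' with the same amidation state — are reported separately.
#'
#' @param peptides a \code{DataFrame} from
#'   \code{\link{predictMaturePeptides}}.
#' @param query a query string (see \code{\link{parsePeptideQuery}}).
#' @return a \code{DataFrame} with one row per predicted peptide and columns
#'   \code{sequence}, \code{exact}, \code{suffix}.
#' @export
matchQueryPeptide <- function(peptides, query) {
  pq <- parsePeptideQuery(query)
  sq <- as.character(peptides$sequence)
  am <- as.logical(peptides$cTerminalAmide)
  exact <- sq == pq$core & am == pq$amidated &
    (!pq$pyroglu | startsWith(sq, "Q"))
  suff <- am == pq$amidated & sq != pq$core &
    (endsWith(pq$core, sq) | endsWith(sq, pq$core))
  S4Vectors::DataFrame(sequence = sq, exact = exact, suffix = suff)
}
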