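#' Read assembled contigs from a FASTA file
#'
#' Thin wrapper around \code{Biostrings::readDNAStringSet} that uppercases
#' sequences and rejects empty files and alphabets outside {A,C,G,T,N}: the
#' pileup logic downstream assumes the plain DNA alphabet, so IUPAC ambiguity
#' codes other than N are refused up front rather than silently miscounted.
#'
#' @param path path to a (optionally gzipped) FASTA file; multi-line records
#'   are allowed.
#' @return a \code{DNAStringSet}, one element per record, order preserved.
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">c1", "ACGT", ">c2", "ac", "gt"), tf)
#' readContigs(tf)
#' @export
readContigs <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) == 0L)
    stop("no FASTA records in ", path, call. = FALSE)
  chr <- toupper(as.character(x))
  .assertDnaAlphabet(chr, "FASTA sequence")
  out <- Biostrings::DNAStringSet(chr)
  names(out) <- sub("\\s.*$", "", names(x))   # id = first header token
  out
}

#' Write contigs to FASTA
#'
#' @param contigs a named \code{DNAStringSet} (or named character vector).
#' @param path output path. Sequence lines wrap at 70 columns.
#' @export
writeContigs <- function(contigs, path) {
  if (is.character(contigs))
    contigs <- Biostrings::DNAStringSet(contigs)
  Biostrings::writeXStringSet(contigs, path, width = 70L)
  invisible(path)
}

#' Read short reads with qualities from a FASTQ file
#'
#' Four-line FASTQ records with Phred+33 quality encoding (the modern
#' standard; no other dialect is supported). Record structure errors and
#' base/quality length mismatches are format errors.
#'
#' @param path path to a FASTQ file.
#' @return a \code{QualityScaledDNAStringSet} with \code{PhredQuality}
#'   qualities.
#' @export
readReads <- function(path) {
  nl <- length(readLines(path, warn = FALSE))
  if (nl == 0L || nl %% 4L != 0L)
    stop("malformed FASTQ in ", path, ": ", nl,
         " lines is not a multiple of 4", call. = FALSE)
  x <- tryCatch(
    suppressWarnings(
      Biostrings::readQualityScaledDNAStringSet(path,
                                                quality.scoring = "phred")),
    error = function(e) stop("malformed FASTQ in ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  if (length(x) == 0L) stop("no FASTQ records in ", path, call. = FALSE)
  if (!all(BiocGenerics::width(x) ==
           BiocGenerics::width(Biostrings::quality(x))))
    stop("FASTQ bases/qualities length mismatch in ", path, call. = FALSE)
  x
}

#' Write reads to FASTQ (Phred+33)
#'
#' @param reads a \code{QualityScaledDNAStringSet}.
#' @param path output path.
#' @export
writeReads <- function(reads, path) {
  Biostrings::writeXStringSet(reads, path, format = "fastq",
                              qualities = Biostrings::quality(reads))
  invisible(path)
}

#' Per-base integer quality scores
#'
#' @param reads a \code{QualityScaledDNAStringSet}.
#' @return an \code{IntegerList}, one element per read.
#' @export
readQuals <- function(reads) {
  methods::as(Biostrings::quality(reads), "IntegerList")
}

#' Reverse complement of DNA strings
#'
#' Character-vector convenience over \code{Biostrings::reverseComplement}.
#' An involution on {A,C,G,T,N}: N maps to N, anything else is an error.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @examples
#' revComp(c("ACGT", "AAC", "ANT"))  # "ACGT" "GTT" "ANT"
#' @export
revComp <- function(x) {
  .assertDnaAlphabet(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
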