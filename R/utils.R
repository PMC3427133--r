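# Internal low-level helpers shared across modules. All sequence payloads are
# plain uppercase character vectors over {A,C,G,T,N} unless a Biostrings
# container is stated; coordinates are 1-based closed throughout the package.

.DNA_LETTERS <- c("A", "C", "G", "T")
.DNA_RAW <- charToRaw("ACGTN")

.assertDnaAlphabet <- function(x, what = "sequence") {
  bad <- grepl("[^ACGTN]", x)
  if (any(bad))
    stop(what, " contains characters outside {A,C,G,T,N}: ",
         paste(utils::head(unique(unlist(strsplit(
           gsub("[ACGTN]", "", x[bad]), ""))), 5), collapse = ", "),
         call. = FALSE)
  invisible(TRUE)
}

# fast random DNA of length n
.randomDna <- function(n) {
  rawToChar(charToRaw("ACGT")[sample.int(4L, n, replace = TRUE)])
}

# complement lookup on raw bytes (A<->T, C<->G, N->N)
.COMP_TABLE <- local({
  tab <- as.raw(0:255)
  from <- charToRaw("ACGTN")
  to <- charToRaw("TGCAN")
  tab[as.integer(from) + 1L] <- to
  tab
})

.revCompChr <- function(x) {
  vapply(x, function(s) {
    rawToChar(rev(.COMP_TABLE[as.integer(charToRaw(s)) + 1L]))
  }, character(1), USE.NAMES = FALSE)
}

# base -> 1..4 integer codes (N and others -> NA), vectorised over a raw vector
.BASE_CODE <- local({
  code <- rep(NA_integer_, 256)
  code[as.integer(charToRaw("ACGT")) + 1L] <- 1:4
  code
})

.codeBases <- function(rawvec) .BASE_CODE[as.integer(rawvec) + 1L]

# round half away from zero (presentation rounding used in the report tables;
# base round() would round halves to even)
.roundHalfUp <- function(x) floor(x + 0.5)

.isSingleNumber <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# coerce a sequence container to character WITHOUT losing names
# (base as.character() strips attributes from character vectors)
.asSeqChar <- function(x) {
  if (is.character(x)) x else stats::setNames(as.character(x), names(x))
}
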