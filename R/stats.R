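#' Assembly summary statistics
#'
#' Contig count, total bases, length range, mean, median, N50 and a fixed
#' 400-bp length histogram anchored at 200 bp. N50 is the largest length L
#' such that contigs of length >= L contain at least half of the total
#' bases; the median is the middle order statistic (mean of the two middle
#' values for even counts); the mean is kept unrounded and only rounded at
#' report time.
#'
#' @param contigs a \code{DNAStringSet}, character vector of sequences, or
#'   numeric vector of contig lengths.
#' @param minLen length floor applied before computing statistics (default
#'   200 bp, the assembly's contig floor); set 0 to disable.
#' @return an \code{\link{AssemblyStats-class}} object.
#' @examples
#' n50(assemblyStats(c(5, 4, 3, 2, 1), minLen = 0))  # 4
#' @export
assemblyStats <- function(contigs, minLen = 200L) {
  lens <- if (is.numeric(contigs)) as.numeric(contigs)
          else as.numeric(nchar(as.character(contigs)))
  lens <- lens[lens >= minLen]
  if (!length(lens)) stop("no contigs at or above the length floor",
                          call. = FALSE)
  total <- sum(lens)
  sorted <- sort(lens, decreasing = TRUE)
  n50v <- sorted[which(cumsum(sorted) >= total / 2)[1]]
  lo <- 200
  breaks <- seq(lo, max(max(lens), lo) + 400, by = 400)
  cnt <- tabulate(findInterval(lens, breaks), nbins = length(breaks) - 1L)
  under <- sum(lens < lo)
  methods::new("AssemblyStats",
               n = length(lens), totalBp = total,
               minLen = as.integer(min(lens)), maxLen = as.integer(max(lens)),
               meanLen = total / length(lens),
               medianLen = stats::median(lens),
               n50 = as.integer(n50v),
               histBreaks = breaks[-length(breaks)],
               histCounts = as.integer(cnt))
}

#' Length-binned rate table
#'
#' Partitions contigs into half-open length bins and reports, per bin, the
#' total count, the count with the flag set (e.g. "has a database hit") and
#' the integer-rounded (half up) percentage. Contigs below the first edge
#' are collected in an underflow row.
#'
#' @param contigs sequences or numeric lengths (as in
#'   \code{\link{assemblyStats}}).
#' @param flags logical vector, one per contig.
#' @param binEdges increasing numeric edges; bins are
#'   \code{[e1, e2), [e2, e3), ..., [ek, Inf)}.
#' @return a data.frame with columns \code{range}, \code{total},
#'   \code{flagged}, \code{pct}.
#' @export
binnedRateTable <- function(contigs, flags,
                            binEdges = c(200, 600, 1000, 1400)) {
  lens <- if (is.numeric(contigs)) as.numeric(contigs)
          else as.numeric(nchar(as.character(contigs)))
  stopifnot(length(flags) == length(lens), is.logical(flags))
  bin <- findInterval(lens, binEdges)
  labs <- c(paste0("<", binEdges[1]),
            paste0(binEdges[-length(binEdges)], "-", binEdges[-1] - 1),
            paste0(">=", binEdges[length(binEdges)]))
  tot <- tabulate(bin + 1L, nbins = length(binEdges) + 1L)
  flg <- tabulate(bin[flags] + 1L, nbins = length(binEdges) + 1L)
  out <- data.frame(range = labs, total = tot, flagged = flg,
                    pct = ifelse(tot > 0, .roundHalfUp(100 * flg / tot), NA))
  if (out$total[1] == 0L) out <- out[-1, , drop = FALSE]
  else message(out$total[1], " contig(s) below the first bin edge counted ",
               "in an underflow row")
  rownames(out) <- NULL
  out
}
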