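#' GC-content profile of a sequence in fixed windows
#'
#' Cuts the sequence into consecutive non-overlapping windows (the
#' trailing partial window is dropped), computes each window's G+C
#' percentage and bins the windows into classes of \code{binWidth}
#' percentage points.  A window at 33\% GC falls into the "31-35" bin;
#' windows at 0\% fall into the first bin.
#'
#' @param sequence a \code{DNAString} or character string.
#' @param window window size in bases (default 200).
#' @param binWidth bin width in percentage points (default 5).
#' @return a \code{data.frame} with columns \code{bin} (label), \code{gcLo},
#'   \code{gcHi} (percent bounds) and \code{nWindows}; only non-empty bins
#'   plus all-zero bins in between are returned (bins with no windows and
#'   no neighbours are omitted).
#' @examples
#' gcProfile(strrep("A", 400))           # two windows in the 0-5% bin
#' @export
gcProfile <- function(sequence, window = 200L, binWidth = 5) {
  stopifnot(window > 0)
  seq <- .asDNAString(sequence)
  nWin <- base::length(seq) %/% window
  if (nWin == 0L)
    return(data.frame(bin = character(), gcLo = numeric(),
                      gcHi = numeric(), nWindows = integer()))
  v <- Biostrings::Views(seq, IRanges::IRanges(
    start = (seq_len(nWin) - 1L) * window + 1L, width = window))
  gc <- rowSums(Biostrings::letterFrequency(v, c("G", "C")))
  pct <- 100 * gc / window
  binIdx <- pmax(1L, as.integer(ceiling(pct / binWidth)))
  nBins <- as.integer(ceiling(100 / binWidth))
  counts <- tabulate(binIdx, nbins = nBins)
  keep <- which(counts > 0L)
  keep <- if (length(keep)) seq.int(min(keep), max(keep)) else integer()
  lo <- ifelse(keep == 1L, 0, binWidth * (keep - 1L) + 1)
  hi <- binWidth * keep
  data.frame(bin = sprintf("%g-%g%%", lo, hi), gcLo = lo, gcHi = hi,
             nWindows = counts[keep])
}

#' Partition indels by overlap with a set of intervals
#'
#' Half-open interval semantics on the indel footprint (deleted span, or
#' breakpoint-adjacent bases for insertions); used e.g. to stratify calls
#' into inside/outside annotated repeat elements.
#'
#' @param indels an \code{\linkS4class{IndelSet}} or indel \code{data.frame}.
#' @param intervals a \code{GRanges} (e.g. read from BED).
#' @return logical vector, TRUE for indels overlapping any interval.
#' @export
stratifyByIntervals <- function(indels, intervals) {
  df <- .indelFrame(indels)
  if (!nrow(df)) return(logical())
  fp <- GenomicRanges::GRanges(df$chrom, .indelFootprint(df))
  IRanges::overlapsAny(fp, intervals)
}
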