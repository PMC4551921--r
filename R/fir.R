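#' Enumerate all reads spanning an indel
#'
#' Simulates every possible read of the given length from the donor
#' sequence (the reference with the indel applied) that covers the event
#' entirely with at least 1 bp margin on both sides.  For a deletion
#' there are \code{readLength - 1} such reads (99 at 100 bp); for an
#' insertion of k bases, \code{readLength - 1 - k}.  An insertion of
#' \code{readLength - 1} or more bases admits no spanning read and is
#' flagged degenerate.
#'
#' @param reference the reference \code{DNAString}.
#' @param indel a one-row indel \code{data.frame} or length-1
#'   \code{\linkS4class{IndelSet}}.
#' @param readLength simulated read length (default 100).
#' @return a list with \code{reads} (a \code{DNAStringSet}),
#'   \code{nSimulated} and \code{degenerate}.
#' @export
enumerateSpanningReads <- function(reference, indel, readLength = 100L) {
  ref <- .asDNAString(reference)
  df <- .indelFrame(indel)
  stopifnot(nrow(df) == 1L)
  rl <- as.integer(readLength)
  donor <- applyIndels(ref, df)
  p <- df$pos                                   # donor coord of the event
  insLen <- if (df$kind == "ins") df$length else 0L
  ## 0-based starts: read must cover [p-1, p+insLen] within the donor
  lo <- max(0L, p + insLen + 1L - rl)
  hi <- min(p - 1L, base::length(donor) - rl)
  if (insLen >= rl - 1L || hi < lo) {
    return(list(reads = Biostrings::DNAStringSet(), nSimulated = 0L,
                degenerate = TRUE))
  }
  starts <- lo:hi
  reads <- Biostrings::extractAt(donor,
    IRanges::IRanges(starts + 1L, width = rl))
  names(reads) <- sprintf("span%03d", seq_along(reads))
  list(reads = reads, nSimulated = base::length(reads),
       degenerate = FALSE)
}

#' Fraction of informative reads for an indel
#'
#' A spanning read is \emph{uninformative} when it aligns end-to-end
#' without gaps somewhere on the unmodified reference (within the
#' mismatch tolerance) -- typically because the event sits in a repeat
#' whose unperturbed copy absorbs the read -- and \emph{informative}
#' otherwise.  The FIR is the informative fraction of all reads spanning
#' the event; an indel in unique sequence has FIR 1, and the FIR shrinks
#' as surrounding repeat copies approach the read length.
#'
#' @inheritParams enumerateSpanningReads
#' @param maxMismatches mismatch tolerance of the continuous-alignment
#'   check (default 0).
#' @param bothStrands search the reverse strand too.
#' @return a list with \code{nSimulated}, \code{nInformative} and
#'   \code{fir} (NA when no spanning read exists).
#' @examples
#' ref <- generateReference(GenomeSpec(2000, seed = 5))$sequence
#' del <- IndelSet("chrS", 1000L, "del",
#'                 substr(as.character(ref), 1001, 1001))
#' computeFIR(ref, del)$fir
#' @export
computeFIR <- function(reference, indel, readLength = 100L,
                       maxMismatches = 0L, bothStrands = TRUE) {
  ref <- .asDNAString(reference)
  sim <- enumerateSpanningReads(ref, indel, readLength)
  if (sim$degenerate || sim$nSimulated == 0L)
    return(list(nSimulated = 0L, nInformative = NA_integer_,
                fir = NA_real_))
  nInf <- 0L
  for (i in seq_len(sim$nSimulated)) {
    hits <- ungappedHits(sim$reads[[i]], ref, maxMismatches, bothStrands)
    if (!nrow(hits)) nInf <- nInf + 1L
  }
  list(nSimulated = sim$nSimulated, nInformative = nInf,
       fir = nInf / sim$nSimulated)
}

#' FIR for a whole call set
#'
#' @param reference the reference \code{DNAString}.
#' @param indels an \code{\linkS4class{IndelSet}} or indel
#'   \code{data.frame}.
#' @param ... passed to \code{\link{computeFIR}}.
#' @return a \code{data.frame}: the indel columns plus \code{nSimulated},
#'   \code{nInformative}, \code{fir}.
#' @export
firTable <- function(reference, indels, ...) {
  df <- .indelFrame(indels)
  res <- lapply(seq_len(nrow(df)), function(i)
    computeFIR(reference, df[i, , drop = FALSE], ...))
  df$nSimulated <- vapply(res, `[[`, integer(1L), "nSimulated")
  df$nInformative <- vapply(res, `[[`, integer(1L), "nInformative")
  df$fir <- vapply(res, `[[`, numeric(1L), "fir")
  df
}
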