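## Vectorized helpers for the greedy tract scan.  hpUnits[i]: number of
## consecutive equal bases starting at i.  dimerUnits[i]: number of
## consecutive copies of the 2-base unit starting at i (0 when the two
## bases are equal, i.e. the "dimer" is really a homopolymer).
.repeatUnitCounts <- function(chars) {
  n <- length(chars)
  r <- rle(chars)
  ends <- cumsum(r$lengths)
  hpUnits <- rep.int(ends, r$lengths) - seq_len(n) + 1L

  dimerUnits <- integer(n)
  ## consecutive-copy count along stride-2 chains: unit at i repeats at
  ## i+2 iff chars[i]==chars[i+2] and chars[i+1]==chars[i+3]
  if (n >= 2L) {
    rep2 <- rep(FALSE, n)
    if (n >= 4L) {
      i <- seq_len(n - 3L)
      rep2[i] <- chars[i] == chars[i + 2L] & chars[i + 1L] == chars[i + 3L]
    }
    consec <- integer(n)
    for (par in 1:2) {
      idx <- seq.int(par, n, by = 2L)
      v <- rep2[idx]
      if (!length(v)) next
      rr <- rle(v)
      ce <- cumsum(rr$lengths)
      cnt <- rep.int(ce, rr$lengths) - seq_along(v) + 1L
      cnt[!v] <- 0L
      consec[idx] <- cnt
    }
    valid <- c(chars[-n] != chars[-1L], FALSE)
    dimerUnits <- ifelse(valid, 1L + consec, 0L)
  }
  list(hpUnits = hpUnits, dimerUnits = as.integer(dimerUnits))
}

#' Annotate homopolymer and dimer tracts in a sequence
#'
#' Greedy left-to-right scan: at each position the run of the 1-base unit
#' and the run of the 2-base unit starting there are compared, the type
#' with more repeat units wins (ties go to the shorter unit), the tract is
#' emitted and the scan resumes immediately after it.  Tracts of fewer
#' than 2 units are not emitted, so the four-base sequence \code{ACAC} is
#' one dimer tract of 2 units while \code{ACGT} has no tracts at all.
#' Tract length is reported in reference coordinates
#' (\code{regionLength = nUnits * unit size}).
#'
#' @param sequence a \code{DNAString} or character string over A/C/G/T.
#' @param chrom chromosome name for the returned ranges.
#' @return a \code{GRanges} (sorted, non-overlapping) with metadata
#'   columns \code{unit}, \code{nUnits} and \code{regionLength}.
#' @examples
#' annotateRepeats("AAACACAC")
#' @export
annotateRepeats <- function(sequence, chrom = "chrS") {
  chars <- .seqToChars(sequence)
  if (length(chars) && !all(chars %in% DNA_BASES4))
    stop("sequence contains characters outside A/C/G/T")
  n <- length(chars)
  uc <- .repeatUnitCounts(chars)
  h <- uc$hpUnits; d <- uc$dimerUnits
  ## positions that can start a tract, for fast skipping
  cand <- which(h >= 2L | d >= 2L)
  starts <- integer(); widths <- integer(); units <- character()
  nunits <- integer()
  i <- 1L
  while (i <= n) {
    if (h[i] < 2L && d[i] < 2L) {
      nxt <- cand[findInterval(i, cand) + 1L]
      if (is.na(nxt)) break
      i <- nxt
      next
    }
    if (h[i] >= d[i]) {            # tie -> shorter unit
      starts <- c(starts, i); widths <- c(widths, h[i])
      units <- c(units, chars[i]); nunits <- c(nunits, h[i])
      i <- i + h[i]
    } else {
      starts <- c(starts, i); widths <- c(widths, 2L * d[i])
      units <- c(units, paste0(chars[i], chars[i + 1L]))
      nunits <- c(nunits, d[i])
      i <- i + 2L * d[i]
    }
  }
  GenomicRanges::GRanges(
    seqnames = rep(chrom, length(starts)),
    ranges = IRanges::IRanges(starts, width = widths),
    unit = units, nUnits = nunits, regionLength = widths)
}

## 1-based overlap footprint of each indel: the deleted span for
## deletions, the two breakpoint-adjacent bases for insertions
.indelFootprint <- function(df) {
  start <- ifelse(df$kind == "del", df$pos + 1L, pmax(df$pos, 1L))
  end <- ifelse(df$kind == "del", df$pos + df$length, df$pos + 1L)
  IRanges::IRanges(start, end)
}

#' Assign each indel to the longest repeat tract it overlaps
#'
#' A deletion overlaps a tract through its deleted span; an insertion
#' through the two bases flanking its breakpoint.  Among overlapping
#' tracts the one with the greatest \code{regionLength} wins; ties are
#' broken by the leftmost tract and flagged.
#'
#' @param indels an \code{\linkS4class{IndelSet}} or indel \code{data.frame}.
#' @param tracts a \code{GRanges} from \code{\link{annotateRepeats}}.
#' @return a \code{data.frame} with one row per indel: \code{tract} (index
#'   into \code{tracts}, NA if none), \code{regionLength}, \code{unit},
#'   \code{ambiguous}.
#' @export
assignIndelRepeat <- function(indels, tracts) {
  df <- .indelFrame(indels)
  out <- data.frame(tract = rep(NA_integer_, nrow(df)),
                    regionLength = rep(NA_integer_, nrow(df)),
                    unit = rep(NA_character_, nrow(df)),
                    ambiguous = rep(FALSE, nrow(df)))
  if (!nrow(df)) return(out)
  fp <- .indelFootprint(df)
  hits <- IRanges::findOverlaps(fp, IRanges::ranges(tracts))
  if (!length(hits)) return(out)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  rl <- tracts$regionLength[sh]
  for (q in unique(qh)) {
    sel <- which(qh == q)
    best <- sel[rl[sel] == max(rl[sel])]
    out$ambiguous[q] <- length(best) > 1L
    pick <- sh[best[which.min(BiocGenerics::start(tracts)[sh[best]])]]
    out$tract[q] <- pick
    out$regionLength[q] <- tracts$regionLength[pick]
    out$unit[q] <- tracts$unit[pick]
  }
  out
}

#' Indel density per repeat-length class
#'
#' Groups repeat-assigned indels by the reference-coordinate length of
#' their tract and reports, per length class, the number of indels per
#' 1 kbp of tract sequence of that class (totalled over \emph{all} tracts
#' of the class, with or without indels).  Classes with no tracts are
#' omitted.
#'
#' @param indels an \code{\linkS4class{IndelSet}} or indel \code{data.frame}.
#' @param tracts a \code{GRanges} from \code{\link{annotateRepeats}}.
#' @param unitLength restrict to tracts of this unit size (1 =
#'   homopolymers, 2 = dimers, NULL = all).
#' @return a \code{data.frame} with columns \code{regionLength},
#'   \code{nIndels}, \code{totalTractBases}, \code{density}.
#' @export
indelDensity <- function(indels, tracts, unitLength = NULL) {
  if (!is.null(unitLength))
    tracts <- tracts[nchar(tracts$unit) == unitLength]
  asg <- assignIndelRepeat(indels, tracts)
  classes <- sort(unique(tracts$regionLength))
  tot <- vapply(classes, function(cl)
    sum(BiocGenerics::width(tracts)[tracts$regionLength == cl]),
    numeric(1L))
  cnt <- vapply(classes, function(cl)
    sum(asg$regionLength == cl, na.rm = TRUE), numeric(1L))
  data.frame(regionLength = classes, nIndels = cnt,
             totalTractBases = tot, density = 1000 * cnt / tot)
}

#' Residual indel fraction by repeat length
#'
#' The proportion of repeat-assigned indels lying in tracts of the given
#' length \emph{or longer} (the reverse cumulative distribution over tract
#' length).  The value at the minimum observed length is 1 and the curve
#' is monotone non-increasing.
#'
#' @inheritParams indelDensity
#' @return a \code{data.frame(regionLength, fraction)}; empty when no
#'   indel is repeat-assigned.
#' @export
residualIndelFraction <- function(indels, tracts, unitLength = NULL) {
  if (!is.null(unitLength))
    tracts <- tracts[nchar(tracts$unit) == unitLength]
  asg <- assignIndelRepeat(indels, tracts)
  lens <- asg$regionLength[!is.na(asg$regionLength)]
  if (!length(lens))
    return(data.frame(regionLength = integer(), fraction = numeric()))
  grid <- seq.int(min(lens), max(lens) + 1L)
  data.frame(regionLength = grid,
             fraction = vapply(grid, function(L) mean(lens >= L),
                               numeric(1L)))
}
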