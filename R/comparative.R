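#' Normalized indel length distribution
#'
#' Counts indels of each length 1-10 bp and normalizes the counts by the
#' number of 1 bp indels, the convention used to compare length spectra
#' across strata and species.
#'
#' @param indels an \code{\linkS4class{IndelSet}} or indel \code{data.frame}.
#' @param stratum optional logical mask over the indels.
#' @return a list with \code{counts} (named integer, lengths "1".."10")
#'   and \code{normalized} (counts / count at 1 bp, or NA when no 1 bp
#'   indel exists).
#' @examples
#' x <- IndelSet("c", c(1L, 5L, 9L), "del", c("A", "A", "AC"))
#' normalizedLengthDistribution(x)$normalized
#' @export
normalizedLengthDistribution <- function(indels, stratum = NULL) {
  df <- .indelFrame(indels)
  if (!is.null(stratum)) df <- df[stratum, , drop = FALSE]
  counts <- tabulate(df$length[df$length >= 1L & df$length <= 10L],
                     nbins = 10L)
  names(counts) <- as.character(1:10)
  normalized <- if (counts[1L] > 0L) counts / counts[1L]
  else rep(NA_real_, 10L)
  names(normalized) <- names(counts)
  list(counts = counts, normalized = normalized)
}

## observable indels between an ancestor and a derived sequence: optimal
## global alignment with affine gaps, gap runs read off as single events,
## coordinates reported on the ancestor, then left-normalized
.alignmentIndels <- function(ancestor, derived, chrom = "chrS") {
  anc <- .asDNAString(ancestor); der <- .asDNAString(derived)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2)
  aln <- Biostrings::pairwiseAlignment(anc, der, type = "global",
                                       substitutionMatrix = mat,
                                       gapOpening = 6, gapExtension = 1)
  pa <- .seqToChars(as.character(Biostrings::alignedPattern(aln)))
  sa <- .seqToChars(as.character(Biostrings::alignedSubject(aln)))
  n <- length(pa)
  refPos <- cumsum(pa != "-")          # ancestor coordinate per column
  out <- .emptyIndelFrame()
  i <- 1L
  while (i <= n) {
    if (sa[i] == "-") {                # gap in derived = deletion
      j <- i
      while (j < n && sa[j + 1L] == "-") j <- j + 1L
      out <- rbind(out, data.frame(
        chrom = chrom, pos = refPos[i] - 1L, kind = "del",
        length = j - i + 1L,
        seq = paste(pa[i:j], collapse = ""), zygosity = "unknown",
        stringsAsFactors = FALSE))
      i <- j + 1L
    } else if (pa[i] == "-") {         # gap in ancestor = insertion
      j <- i
      while (j < n && pa[j + 1L] == "-") j <- j + 1L
      out <- rbind(out, data.frame(
        chrom = chrom, pos = refPos[i], kind = "ins",
        length = j - i + 1L,
        seq = paste(sa[i:j], collapse = ""), zygosity = "unknown",
        stringsAsFactors = FALSE))
      i <- j + 1L
    } else i <- i + 1L
  }
  if (nrow(out)) out <- .leftNormalizeChars(out, .seqToChars(anc))
  rownames(out) <- NULL
  out
}

#' Observable indels between an ancestor and a derived sequence
#'
#' Recovers the indels a sequence comparison can still see after any
#' number of historical events: the two sequences are globally aligned
#' (affine gap penalties) and each maximal run of gap columns is read off
#' as one insertion or deletion, left-normalized on ancestor coordinates.
#' Events that merged during evolution (e.g. repeated deletions inside
#' one homopolymer) surface as a single longer indel.
#'
#' @param ancestor,derived sequences (\code{DNAString} or character).
#' @param chrom chromosome label for the reported events.
#' @return an indel \code{data.frame} on ancestor coordinates.
#' @examples
#' observeIndels("CCCCAAAAAAAAAAGGGG", "CCCCAAAAAAAAGGGG")  # one 2 bp del
#' @export
observeIndels <- function(ancestor, derived, chrom = "chrS") {
  .alignmentIndels(ancestor, derived, chrom = chrom)
}

#' Evolve a sequence by sequential indel events and read back the
#' observable indels
#'
#' Applies \code{nEvents} insertion/deletion events one after another,
#' each on the \emph{current} sequence, with positions biased into
#' homopolymer runs by \code{repeatBias}; events inside a run insert or
#' delete copies of the run's base.  The observable indel list is then
#' recovered the way a resequencing comparison would see it: by globally
#' aligning ancestor and final sequence and reading each run of gap
#' columns as a single indel.  Sequential same-direction events inside
#' one homopolymer merge into one longer observable event, so the
#' observable list is never longer than the true event list; two 1 bp
#' deletions at opposite ends of a homopolymer surface as a single 2 bp
#' deletion, while the same two events 10 bp apart in unique sequence
#' stay two separate 1 bp deletions.
#'
#' @param ancestor the ancestral \code{DNAString} or character string.
#' @param nEvents number of sequential mutation events.
#' @param repeatBias weight multiplier for positions inside homopolymer
#'   runs >= 4 bp (default 20: indels are strongly slippage-driven).
#' @param pDeletion probability that an event is a deletion.
#' @param eventLengthProbs probabilities for event lengths 1..3 bp
#'   (default: all events 1 bp).
#' @param seed integer RNG seed.
#' @param chrom chromosome label for the reported events.
#' @return a list with \code{trueEvents} (data.frame of the applied
#'   events, positions on the sequence current at the time of each
#'   event), \code{observed} (indel \code{data.frame} on ancestor
#'   coordinates), and \code{final} (the derived \code{DNAString}).
#' @export
evolveAndObserve <- function(ancestor, nEvents, repeatBias = 20,
                             pDeletion = 0.5,
                             eventLengthProbs = c(1, 0, 0), seed = 1L,
                             chrom = "chrS") {
  cur <- .seqToChars(ancestor)
  stopifnot(nEvents >= 0)
  lenProbs <- eventLengthProbs / sum(eventLengthProbs)
  withSeed(seed, {
    events <- list()
    for (e in seq_len(nEvents)) {
      n <- length(cur)
      hp <- .hpRunLength(cur)
      w <- rep(1, n)
      w[hp >= 4L] <- repeatBias
      w[c(seq_len(min(5L, n)), seq.int(max(1L, n - 5L), n))] <- 0
      len <- sample.int(length(lenProbs), 1L, prob = lenProbs)
      isDel <- runif(1L) < pDeletion
      pos1 <- sample.int(n, 1L, prob = w)        # 1-based
      if (isDel) {
        len <- min(len, n - pos1)
        seqs <- paste(cur[pos1:(pos1 + len - 1L)], collapse = "")
        cur <- cur[-(pos1:(pos1 + len - 1L))]
        events[[e]] <- data.frame(pos = pos1 - 1L, kind = "del",
                                  length = len, seq = seqs)
      } else {
        ins <- if (hp[pos1] >= 4L) strrep(cur[pos1], len)
        else paste(sample(DNA_BASES4, len, replace = TRUE), collapse = "")
        cur <- append(cur, strsplit(ins, "")[[1L]], after = pos1 - 1L)
        events[[e]] <- data.frame(pos = pos1 - 1L, kind = "ins",
                                  length = len, seq = ins)
      }
    }
    trueEvents <- if (length(events)) do.call(rbind, events)
    else data.frame(pos = integer(), kind = character(),
                    length = integer(), seq = character())
    final <- Biostrings::DNAString(paste(cur, collapse = ""))
    observed <- .alignmentIndels(ancestor, final, chrom = chrom)
    list(trueEvents = trueEvents, observed = observed, final = final)
  })
}

#' Long-indel share as a function of evolutionary distance
#'
#' Runs \code{\link{evolveAndObserve}} at increasing event counts
#' (divergence levels) and reports, per level, the share of observable
#' indels of length >= 2 bp among those assigned to long (> 10 bp)
#' homopolymer tracts of the ancestor.  On homopolymer-rich ancestors
#' this share grows with divergence -- individual events merge into
#' longer observable indels -- while on unique sequence it stays flat.
#'
#' @param ancestor the ancestral sequence.
#' @param eventCounts increasing vector of event counts.
#' @param replicates simulation replicates per level.
#' @param minTract minimum ancestor homopolymer tract length for the
#'   stratum (default 11, i.e. > 10 bp).
#' @param seed integer RNG seed.
#' @param ... passed to \code{\link{evolveAndObserve}}.
#' @return a \code{data.frame} with columns \code{nEvents},
#'   \code{replicate}, \code{nObserved}, \code{longShare}.
#' @export
divergenceTrend <- function(ancestor, eventCounts, replicates = 5L,
                            minTract = 11L, seed = 1L, ...) {
  tracts <- annotateRepeats(ancestor)
  tracts <- tracts[nchar(tracts$unit) == 1L &
                     tracts$regionLength >= minTract]
  out <- list()
  withSeed(seed, {
    seeds <- matrix(sample.int(.Machine$integer.max,
                               length(eventCounts) * replicates),
                    nrow = length(eventCounts))
    for (ti in seq_along(eventCounts)) {
      for (r in seq_len(replicates)) {
        ev <- evolveAndObserve(ancestor, eventCounts[ti],
                               seed = seeds[ti, r], ...)
        obs <- ev$observed
        if (nrow(obs)) {
          asg <- assignIndelRepeat(obs, tracts)
          obs <- obs[!is.na(asg$tract), , drop = FALSE]
        }
        share <- if (nrow(obs)) mean(obs$length >= 2L) else 0
        out[[length(out) + 1L]] <- data.frame(
          nEvents = eventCounts[ti], replicate = r,
          nObserved = nrow(obs), longShare = share)
      }
    }
  })
  do.call(rbind, out)
}
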