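## per-position length of the maximal equal-base run (vectorized via rle)
.hpRunLength <- function(chars) {
  r <- rle(chars)
  rep.int(r$lengths, r$lengths)
}

#' Plant indels into a reference to produce a diploid truth set
#'
#' Places \code{nIndels} non-overlapping 1-10 bp indels on a reference,
#' left-normalizes them, assigns zygosity (homozygous calls go on both
#' haplotypes, heterozygous on a random one) and builds the two haplotype
#' sequences.  Positions are sampled with an enrichment factor
#' \code{repeatBias} inside homopolymer runs of at least 4 bp, emulating
#' the concentration of slippage indels in repeat tracts; inside a run,
#' inserted bases extend the run's unit so the event stays repeat-coherent.
#'
#' @param reference a \code{DNAString} (or the list returned by
#'   \code{\link{generateReference}}).
#' @param nIndels number of indels to plant.
#' @param lengthProbs probabilities for lengths 1..10 bp (normalized
#'   internally); the default halves the mass per extra base, matching the
#'   rapid decay of observed small-indel length spectra.
#' @param homFraction probability that an indel is homozygous (default 1/3,
#'   the expected homozygous share in an outbred diploid genome).
#' @param repeatBias sampling weight multiplier for positions inside
#'   homopolymer runs >= 4 bp.
#' @param seed integer RNG seed.
#' @param chrom chromosome name.
#' @param minSpacing minimum distance in bases between planted events
#'   (after normalization footprints are re-checked and violators
#'   resampled).
#' @return a \code{\linkS4class{SyntheticTruth}}.
#' @examples
#' ref <- generateReference(GenomeSpec(5000, seed = 2))
#' tr <- plantIndels(ref, nIndels = 5, seed = 3)
#' truthIndels(tr)
#' @export
plantIndels <- function(reference, nIndels, lengthProbs = 0.5^(0:9),
                        homFraction = 1 / 3, repeatBias = 5, seed = 1L,
                        chrom = "chrS", minSpacing = 25L) {
  if (is.list(reference)) reference <- reference$sequence
  ref <- .asDNAString(reference)
  n <- base::length(ref)
  stopifnot(nIndels >= 0)
  if (nIndels > 0 && n < nIndels * (minSpacing + 12L))
    stop("genome too small to place ", nIndels, " indels without overlap")
  refc <- .seqToChars(ref)
  hpRun <- .hpRunLength(refc)
  lengthProbs <- rep_len(lengthProbs, 10L) / sum(rep_len(lengthProbs, 10L))

  withSeed(seed, {
    if (nIndels == 0L) {
      df <- .emptyIndelFrame()
      df$hap <- character(); df$hpLength <- integer()
      return(new("SyntheticTruth", reference = ref, haplotypeA = ref,
                 haplotypeB = ref, indels = df, chrom = chrom))
    }
    w <- rep(1, n)
    w[hpRun >= 4L] <- repeatBias
    lo <- 30L; hi <- n - 45L          # keep events clear of the ends
    w[seq_len(min(lo, n))] <- 0
    if (hi < n) w[hi:n] <- 0

    accepted <- .emptyIndelFrame()
    guard <- 0L
    while (nrow(accepted) < nIndels && guard < 50L) {
      guard <- guard + 1L
      need <- nIndels - nrow(accepted)
      cand <- unique(sample.int(n, size = min(n, 4L * need + 64L),
                                replace = TRUE, prob = w))
      cand <- sort(cand)
      ## spacing against already-accepted positions (vectorized) ...
      taken <- sort(accepted$pos + 1L)
      if (length(taken)) {
        j <- findInterval(cand, taken)
        okL <- j == 0L | cand - taken[pmax(j, 1L)] >= minSpacing
        okR <- j >= length(taken) |
          taken[pmin(j + 1L, length(taken))] - cand >= minSpacing
        cand <- cand[okL & okR]
      }
      ## ... then a left-to-right sweep within the batch
      if (length(cand) > 1L) {
        keep <- logical(length(cand))
        last <- -minSpacing
        for (ci in seq_along(cand)) {
          if (cand[ci] - last >= minSpacing) {
            keep[ci] <- TRUE
            last <- cand[ci]
          }
        }
        cand <- cand[keep]
      }
      if (!length(cand)) next
      cand <- cand[seq_len(min(length(cand), need))]
      pos0 <- cand - 1L                      # to 0-based
      kind <- sample(c("del", "ins"), length(pos0), replace = TRUE)
      len <- sample.int(10L, length(pos0), replace = TRUE, prob = lengthProbs)
      seqs <- character(length(pos0))
      for (i in seq_along(pos0)) {
        p <- pos0[i]
        if (kind[i] == "del") {
          seqs[i] <- paste(refc[(p + 1L):(p + len[i])], collapse = "")
        } else if (hpRun[p + 1L] >= 4L) {
          seqs[i] <- strrep(refc[p + 1L], len[i])
        } else {
          seqs[i] <- paste(sample(DNA_BASES4, len[i], replace = TRUE),
                           collapse = "")
        }
      }
      batch <- data.frame(chrom = chrom, pos = pos0, kind = kind,
                          length = len, seq = seqs, zygosity = "unknown",
                          stringsAsFactors = FALSE)
      batch <- .leftNormalizeChars(batch, refc)
      pool <- rbind(accepted, batch)
      pool <- pool[order(pool$pos), , drop = FALSE]
      ## after normalization, drop any event whose footprint (plus 2 bp
      ## guard) touches its predecessor's
      endp <- pool$pos + ifelse(pool$kind == "del", pool$length, 0L)
      keep <- c(TRUE, pool$pos[-1L] > endp[-nrow(pool)] + 2L)
      pool <- pool[keep, , drop = FALSE]
      pool <- pool[!duplicated(pool$pos), , drop = FALSE]
      accepted <- pool
    }
    if (nrow(accepted) < nIndels)
      stop("genome too small to place ", nIndels, " indels without overlap")
    accepted <- accepted[seq_len(nIndels), , drop = FALSE]
    accepted <- accepted[order(accepted$pos), , drop = FALSE]

    accepted$zygosity <- ifelse(runif(nIndels) < homFraction, "hom", "het")
    accepted$hap <- ifelse(accepted$zygosity == "hom", "AB",
                           sample(c("A", "B"), nIndels, replace = TRUE))
    span <- ifelse(accepted$kind == "del", accepted$length, 1L)
    accepted$hpLength <- vapply(seq_len(nIndels), function(i) {
      idx <- (accepted$pos[i] + 1L):min(n, accepted$pos[i] + span[i])
      idx <- unique(c(max(1L, accepted$pos[i]), idx))
      max(hpRun[idx])
    }, integer(1L))
    rownames(accepted) <- NULL

    hapA <- applyIndels(ref, accepted[accepted$hap %in% c("A", "AB"), ])
    hapB <- applyIndels(ref, accepted[accepted$hap %in% c("B", "AB"), ])
    new("SyntheticTruth", reference = ref, haplotypeA = hapA,
        haplotypeB = hapB, indels = accepted, chrom = chrom)
  })
}

#' @export
setMethod("show", "SyntheticTruth", function(object) {
  df <- object@indels
  cat(sprintf("SyntheticTruth: %d bp reference, %d planted indel(s) (%d hom, %d het)\n",
              base::length(object@reference), nrow(df),
              sum(df$zygosity == "hom"), sum(df$zygosity == "het")))
})

#' Accessors for SyntheticTruth
#'
#' @param x a \code{\linkS4class{SyntheticTruth}}.
#' @return \code{refSequence}: the reference \code{DNAString};
#'   \code{haplotypes}: a \code{DNAStringSet} of the two haplotypes;
#'   \code{truthIndels}: the truth table as an \code{\linkS4class{IndelSet}}.
#' @name truth-accessors
NULL

#' @rdname truth-accessors
#' @export
refSequence <- function(x) x@reference

#' @rdname truth-accessors
#' @export
haplotypes <- function(x) {
  out <- Biostrings::DNAStringSet(list(A = x@haplotypeA, B = x@haplotypeB))
  out
}

#' @rdname truth-accessors
#' @export
truthIndels <- function(x) new("IndelSet", calls = x@indels)

## indels carried by one haplotype of a SyntheticTruth
.hapIndels <- function(truth, hap) {
  df <- truth@indels
  df[df$hap %in% c(hap, "AB"), , drop = FALSE]
}

## shift lookup: maps 0-based reference coordinates to 0-based haplotype
## coordinates for positions outside any event footprint
.shiftFun <- function(indels) {
  if (!nrow(indels)) return(function(p) p)
  thresh <- ifelse(indels$kind == "ins", indels$pos,
                   indels$pos + indels$length)
  delta <- ifelse(indels$kind == "ins", indels$length, -indels$length)
  o <- order(thresh)
  thresh <- thresh[o]
  cumdelta <- cumsum(delta[o])
  function(p) {
    i <- findInterval(p, thresh)
    p + ifelse(i > 0L, cumdelta[pmax(i, 1L)], 0)
  }
}
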