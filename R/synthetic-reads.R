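#' Construct a PlatformSpec
#'
#' @param readLength read length in bases.
#' @param meanCoverage mean fold coverage.
#' @param errorRate per-base substitution error probability.
#' @param paired paired-end layout flag (descriptive only).
#' @param seed integer RNG seed.
#' @return a \code{\linkS4class{PlatformSpec}}.
#' @examples
#' shortRead <- PlatformSpec(100, 47)
#' longRead <- PlatformSpec(700, 0.7)
#' @export
PlatformSpec <- function(readLength, meanCoverage, errorRate = 0,
                         paired = FALSE, seed = 1L) {
  new("PlatformSpec", readLength = as.integer(readLength),
      meanCoverage = as.numeric(meanCoverage),
      errorRate = as.numeric(errorRate), paired = paired,
      seed = as.integer(seed))
}

#' @export
setMethod("show", "PlatformSpec", function(object) {
  cat(sprintf("PlatformSpec: %d bp reads at %.2gx, error rate %.3g%s\n",
              object@readLength, object@meanCoverage, object@errorRate,
              if (object@paired) ", paired" else ""))
})

#' @export
setMethod("show", "ReadSet", function(object) {
  cat(sprintf("ReadSet: %d read(s) of %d bp (%d from A, %d from B)\n",
              base::length(object@reads), object@platform@readLength,
              sum(object@haplotype == "A"), sum(object@haplotype == "B")))
})

#' Accessors for ReadSet
#' @param x a \code{\linkS4class{ReadSet}}.
#' @return \code{readSequences}: the \code{DNAStringSet};
#'   \code{readHaplotype}: source haplotype per read ("A"/"B");
#'   \code{readStart}: 0-based start on the source haplotype.
#' @name readset-accessors
NULL

#' @rdname readset-accessors
#' @export
readSequences <- function(x) x@reads

#' @rdname readset-accessors
#' @export
readHaplotype <- function(x) x@haplotype

#' @rdname readset-accessors
#' @export
readStart <- function(x) x@start

#' Simulate shotgun reads from a diploid truth
#'
#' Draws a Poisson number of reads with mean
#' \code{coverage * length / readLength}, assigns each read to haplotype A
#' or B with probability 1/2 (so heterozygous loci experience binomial
#' allele sampling and, at low coverage, allele dropout), places it
#' uniformly on its haplotype and applies substitution errors at the
#' platform rate.
#'
#' @param truth a \code{\linkS4class{SyntheticTruth}}.
#' @param platform a \code{\linkS4class{PlatformSpec}}.
#' @return a \code{\linkS4class{ReadSet}}.
#' @examples
#' ref <- generateReference(GenomeSpec(5000, seed = 2))
#' tr <- plantIndels(ref, 5, seed = 3)
#' simulateReads(tr, PlatformSpec(100, 2, seed = 4))
#' @export
simulateReads <- function(truth, platform) {
  stopifnot(is(truth, "SyntheticTruth"), is(platform, "PlatformSpec"))
  rl <- platform@readLength
  lens <- c(A = base::length(truth@haplotypeA),
            B = base::length(truth@haplotypeB))
  if (rl > min(lens)) stop("readLength exceeds haplotype length")
  withSeed(platform@seed, {
    nReads <- rpois(1L, platform@meanCoverage *
                      base::length(truth@reference) / rl)
    if (nReads == 0L) {
      return(new("ReadSet", reads = Biostrings::DNAStringSet(),
                 haplotype = character(), start = integer(),
                 platform = platform))
    }
    hap <- sample(c("A", "B"), nReads, replace = TRUE)
    start0 <- integer(nReads)
    for (h in c("A", "B")) {
      idx <- which(hap == h)
      start0[idx] <- sample.int(lens[[h]] - rl + 1L, length(idx),
                                replace = TRUE) - 1L
    }
    reads <- Biostrings::DNAStringSet(c(
      if (any(hap == "A"))
        Biostrings::extractAt(truth@haplotypeA,
          IRanges::IRanges(start0[hap == "A"] + 1L, width = rl))
      else Biostrings::DNAStringSet(),
      if (any(hap == "B"))
        Biostrings::extractAt(truth@haplotypeB,
          IRanges::IRanges(start0[hap == "B"] + 1L, width = rl))
      else Biostrings::DNAStringSet()))
    ## restore per-read order (A block then B block -> original order)
    ord <- order(c(which(hap == "A"), which(hap == "B")))
    reads <- reads[ord]
    if (platform@errorRate > 0) {
      nerr <- rbinom(nReads, rl, platform@errorRate)
      for (i in which(nerr > 0L)) {
        chars <- .seqToChars(reads[[i]])
        at <- sample.int(rl, nerr[i])
        chars[at] <- vapply(chars[at], function(b)
          sample(setdiff(DNA_BASES4, b), 1L), character(1L))
        reads[[i]] <- Biostrings::DNAString(paste(chars, collapse = ""))
      }
    }
    names(reads) <- sprintf("read%06d/%s", seq_len(nReads), hap)
    new("ReadSet", reads = reads, haplotype = hap, start = start0,
        platform = platform)
  })
}

#' Tally long-platform allele support per indel locus
#'
#' For each query indel, counts simulated long-platform reads that span the
#' locus with at least 1 bp margin on both sides and reports how many
#' support the alternate versus the reference allele.  Support is resolved
#' by read provenance: a read drawn from a haplotype carrying the indel
#' supports the alternate allele, one drawn from a non-carrier haplotype
#' supports the reference (at heterozygous loci the haplotype of each read
#' is a fair coin flip by construction, giving the allele-dropout behaviour
#' of a low-coverage platform).  Calls at loci absent from the truth
#' (false positives) can only collect reference support.
#'
#' @param calls indel \code{data.frame} or \code{\linkS4class{IndelSet}};
#'   a column \code{truthIndex} (index into \code{truthIndels(truth)}, NA
#'   for false calls) links calls to the truth, otherwise calls are matched
#'   to truth by position and kind.
#' @param truth the \code{\linkS4class{SyntheticTruth}}.
#' @param readSet a \code{\linkS4class{ReadSet}} from
#'   \code{\link{simulateReads}}.
#' @return the calls \code{data.frame} with columns \code{sangerAlt} and
#'   \code{sangerRef} added.
#' @export
sangerSupport <- function(calls, truth, readSet) {
  df <- .indelFrame(calls)
  extra <- as.data.frame(df)
  if (!nrow(df)) {
    extra$sangerAlt <- integer(); extra$sangerRef <- integer()
    return(extra)
  }
  tr <- truth@indels
  if (is.null(df$truthIndex)) {
    key <- paste(df$pos, df$kind, df$seq)
    tkey <- paste(tr$pos, tr$kind, tr$seq)
    df$truthIndex <- match(key, tkey)
  }
  rl <- readSet@platform@readLength
  altLen <- ifelse(df$kind == "ins", df$length, 0L)
  refLen <- ifelse(df$kind == "del", df$length, 0L)
  nAlt <- integer(nrow(df)); nRef <- integer(nrow(df))
  for (h in c("A", "B")) {
    hin <- .hapIndels(truth, h)
    sf <- .shiftFun(hin)
    ridx <- which(readSet@haplotype == h)
    reads <- IRanges::IRanges(readSet@start[ridx] + 1L, width = rl)
    carried <- !is.na(df$truthIndex) &
      tr$hap[pmax(df$truthIndex, 1L)] %in% c(h, "AB")
    anchor <- df$pos + (sf(df$pos - 1L) - (df$pos - 1L))
    qstart <- anchor                       # 1-based: covers base anchor-1 (0-based)
    qend <- anchor + ifelse(carried, altLen, refLen) + 1L
    q <- IRanges::IRanges(pmax(qstart, 1L), qend)
    hits <- IRanges::countOverlaps(q, reads, type = "within")
    nAlt <- nAlt + ifelse(carried, hits, 0L)
    nRef <- nRef + ifelse(carried, 0L, hits)
  }
  extra$sangerAlt <- as.integer(nAlt)
  extra$sangerRef <- as.integer(nRef)
  extra$truthIndex <- df$truthIndex
  extra
}
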