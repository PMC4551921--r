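#' Build the glued alternate contig for an indel
#'
#' Constructs the short "indel sequence" representing the donor allele:
#' for a deletion the two flanking reference segments glued together, for
#' an insertion the flanks glued around the inserted bases.  Each flank is
#' \code{readLength - 1} bases (truncated at chromosome ends), so every
#' read overlapping the event by at least one base fits entirely inside
#' the contig: a 2 bp deletion at read length 100 gives a 198 bp contig,
#' a 1 bp insertion a 199 bp one.
#'
#' @param reference the reference \code{DNAString} (single chromosome).
#' @param indel a one-row indel \code{data.frame} or a length-1
#'   \code{\linkS4class{IndelSet}}.
#' @param readLength read length the contig is built for (>= 20).
#' @return an \code{\linkS4class{AltContig}}.
#' @examples
#' ref <- generateReference(GenomeSpec(1000, seed = 1))$sequence
#' del <- IndelSet("chrS", 500L, "del", substr(as.character(ref), 501, 502))
#' buildAltContig(ref, del, readLength = 100)
#' @export
buildAltContig <- function(reference, indel, readLength = 100L) {
  ref <- .asDNAString(reference)
  df <- .indelFrame(indel)
  stopifnot(nrow(df) == 1L, readLength >= 20L)
  n <- base::length(ref)
  p <- df$pos; L <- df$length
  delLen <- if (df$kind == "del") L else 0L
  if (p < 0L || p + delLen > n) stop("indel outside the reference sequence")
  rl <- as.integer(readLength)
  leftStart0 <- max(0L, p - (rl - 1L))
  rightStart0 <- p + delLen
  rightEnd0 <- min(n, rightStart0 + rl - 1L)
  left <- as.character(Biostrings::subseq(ref, leftStart0 + 1L, p))
  right <- if (rightStart0 < rightEnd0)
    as.character(Biostrings::subseq(ref, rightStart0 + 1L, rightEnd0))
  else ""
  insSeq <- if (df$kind == "ins") df$seq else ""
  contig <- Biostrings::DNAString(paste0(left, insSeq, right))
  flankL <- p - leftStart0
  flankR <- rightEnd0 - rightStart0
  insLen <- nchar(insSeq)
  span <- IRanges::IRanges(max(1L, flankL - 9L),
                           min(base::length(contig), flankL + insLen + 10L))
  new("AltContig", indel = df, sequence = contig, junctionSpan = span,
      flankLengths = c(flankL, flankR), readLength = rl)
}

#' @export
setMethod("show", "AltContig", function(object) {
  cat(sprintf("AltContig for %s of %d bp at %s:%d; contig %d bp (flanks %d + %d)\n",
              ifelse(object@indel$kind == "del", "deletion", "insertion"),
              object@indel$length, object@indel$chrom, object@indel$pos,
              base::length(object@sequence), object@flankLengths[1L],
              object@flankLengths[2L]))
})

#' Accessors for AltContig
#' @param x an \code{\linkS4class{AltContig}}.
#' @return the contig \code{DNAString}, the junction \code{IRanges}, or
#'   the integer flank lengths.
#' @name contig-accessors
NULL

#' @rdname contig-accessors
#' @export
contigSequence <- function(x) x@sequence

#' @rdname contig-accessors
#' @export
junctionSpan <- function(x) x@junctionSpan

#' @rdname contig-accessors
#' @export
flankLengths <- function(x) x@flankLengths

.asSubjectSet <- function(sequences) {
  if (is(sequences, "DNAStringSet")) {
    ss <- sequences
  } else if (is(sequences, "DNAString") || is.character(sequences)) {
    ss <- Biostrings::DNAStringSet(list(.asDNAString(sequences)))
  } else if (is.list(sequences)) {
    ss <- Biostrings::DNAStringSet(lapply(sequences, .asDNAString))
  } else stop("unsupported subject collection")
  if (is.null(names(ss)) || any(names(ss) == ""))
    names(ss) <- sprintf("seq%d", seq_along(ss))
  ss
}

#' All ungapped end-to-end placements of a read
#'
#' Finds every gap-free placement of \code{read} in each candidate
#' sequence with at most \code{maxMismatches} mismatches, on both strands
#' by default, with exact per-placement mismatch counts.  Results are
#' returned in deterministic (name, start, strand) order.
#'
#' @param read a \code{DNAString} or character string.
#' @param sequences a named \code{DNAStringSet} (or single sequence) to
#'   search.
#' @param maxMismatches maximum mismatches allowed.
#' @param bothStrands also search the reverse complement.
#' @return a \code{data.frame} with columns \code{name}, \code{start}
#'   (1-based), \code{strand}, \code{mismatches}.
#' @examples
#' ungappedHits("ACGT", Biostrings::DNAStringSet(c(chr = "TTACGTTT")),
#'              maxMismatches = 0)
#' @export
ungappedHits <- function(read, sequences, maxMismatches = 2L,
                         bothStrands = TRUE) {
  pat <- .asDNAString(read)
  subs <- .asSubjectSet(sequences)
  strands <- if (bothStrands) c("+", "-") else "+"
  out <- list()
  for (st in strands) {
    qp <- if (st == "+") pat else Biostrings::reverseComplement(pat)
    for (i in seq_along(subs)) {
      subj <- subs[[i]]
      if (base::length(qp) > base::length(subj)) next
      m <- Biostrings::matchPattern(qp, subj,
                                    max.mismatch = maxMismatches,
                                    with.indels = FALSE)
      if (!base::length(m)) next
      mm <- Biostrings::nmismatch(qp, m)
      out[[length(out) + 1L]] <- data.frame(
        name = names(subs)[i], start = BiocGenerics::start(m),
        strand = st, mismatches = as.integer(mm),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(name = character(), start = integer(),
                      strand = character(), mismatches = integer()))
  res <- do.call(rbind, out)
  res[order(res$name, res$start, res$strand), , drop = FALSE]
}

#' Classify reads as supporting the reference or the alternate allele
#'
#' Implements the dual-alignment counting rule: each read is placed
#' without gaps on the reference chromosome(s) and on the alternate
#' contig(s); only reads whose single best placement is \emph{strictly}
#' better on one side than any placement on the other are counted.  A read
#' supports the alternate allele when its unique best hit lies on
#' \code{contig} and overlaps the junction span (the indel with 10 bp
#' flanks); it supports the reference when its unique best hit overlaps
#' the indel locus window on the reference.  Reads placing equally well on
#' both sides are ambiguous (typical for reads contained in a repeat copy)
#' and reads with several equal-best placements on one side are discarded
#' as non-unique.
#'
#' @param reads a \code{DNAStringSet}, \code{\linkS4class{ReadSet}} or
#'   character vector.
#' @param reference the reference as a named \code{DNAStringSet} (one
#'   entry per chromosome) or a single \code{DNAString} (named after the
#'   indel's chromosome).
#' @param contig the \code{\linkS4class{AltContig}} under evaluation.
#' @param maxMismatches mismatch tolerance; default
#'   \code{max(1, floor(readLength / 50))}.
#' @param contigs optionally, all alternate contigs under consideration
#'   (the uniqueness universe); defaults to just \code{contig}.
#' @param bothStrands search the reverse strand too.
#' @return an \code{\linkS4class{AlleleCoverage}}.
#' @export
classifyReads <- function(reads, reference, contig,
                          maxMismatches = NULL, contigs = list(contig),
                          bothStrands = TRUE) {
  stopifnot(is(contig, "AltContig"))
  if (is(reads, "ReadSet")) reads <- reads@reads
  if (is.character(reads)) reads <- Biostrings::DNAStringSet(reads)
  refs <- .asSubjectSet(reference)
  if (is(reference, "DNAString") || is.character(reference))
    names(refs) <- contig@indel$chrom
  rl <- contig@readLength
  if (is.null(maxMismatches))
    maxMismatches <- max(1L, rl %/% 50L)
  cset <- Biostrings::DNAStringSet(lapply(contigs, function(x) x@sequence))
  names(cset) <- sprintf("..contig%d", seq_along(cset))
  self <- which(vapply(contigs, function(x)
    identical(x@indel, contig@indel), logical(1L)))[1L]
  selfName <- names(cset)[self]
  subjects <- c(refs, cset)

  p <- contig@indel$pos
  delLen <- if (contig@indel$kind == "del") contig@indel$length else 0L
  refWindow <- IRanges::IRanges(max(1L, p - (rl - 1L) + 1L),
                                p + delLen + (rl - 1L))
  counts <- c(ref = 0L, alt = 0L, amb = 0L, disc = 0L)
  for (i in seq_along(reads)) {
    hits <- ungappedHits(reads[[i]], subjects, maxMismatches, bothStrands)
    if (!nrow(hits)) { counts["disc"] <- counts["disc"] + 1L; next }
    best <- hits[hits$mismatches == min(hits$mismatches), , drop = FALSE]
    w <- nchar(as.character(reads[[i]]))
    onRef <- best$name %in% names(refs)
    onSelf <- best$name == selfName
    onOther <- !onRef & !onSelf
    if (any(onRef) && any(onSelf)) {
      counts["amb"] <- counts["amb"] + 1L
    } else if (any(onSelf)) {
      if (sum(onSelf) > 1L || any(onOther)) {
        counts["disc"] <- counts["disc"] + 1L
      } else {
        hit <- best[onSelf, ]
        ov <- IRanges::overlapsAny(
          IRanges::IRanges(hit$start, hit$start + w - 1L),
          contig@junctionSpan)
        if (ov) counts["alt"] <- counts["alt"] + 1L
        else counts["disc"] <- counts["disc"] + 1L
      }
    } else if (any(onRef)) {
      if (sum(onRef) > 1L || any(onOther)) {
        counts["disc"] <- counts["disc"] + 1L
      } else {
        hit <- best[onRef, ]
        ov <- hit$name == contig@indel$chrom &&
          IRanges::overlapsAny(
            IRanges::IRanges(hit$start, hit$start + w - 1L), refWindow)
        if (ov) counts["ref"] <- counts["ref"] + 1L
        else counts["disc"] <- counts["disc"] + 1L
      }
    } else {
      counts["disc"] <- counts["disc"] + 1L
    }
  }
  AlleleCoverage(nRef = counts[["ref"]], nAlt = counts[["alt"]],
                 nAmbiguous = counts[["amb"]],
                 nDiscarded = counts[["disc"]])
}
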