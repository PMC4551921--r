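#' Construct a GenomeSpec
#'
#' @param length genome length in bases.
#' @param gcFraction target G+C proportion.
#' @param homopolymerTracts \code{data.frame(unitLength, tractLength,
#'   count)} of tracts to plant verbatim, or \code{NULL}.
#' @param dispersedRepeats \code{data.frame(elementLength, copyNumber,
#'   divergence)} of near-identical interspersed elements, or \code{NULL}.
#' @param seed integer RNG seed.
#' @return a \code{\linkS4class{GenomeSpec}}.
#' @examples
#' GenomeSpec(1e4, gcFraction = 0.38, seed = 1)
#' @export
GenomeSpec <- function(length, gcFraction = 0.41,
                       homopolymerTracts = NULL, dispersedRepeats = NULL,
                       seed = 1L) {
  if (is.null(homopolymerTracts))
    homopolymerTracts <- data.frame(unitLength = integer(),
                                    tractLength = integer(),
                                    count = integer())
  if (is.null(dispersedRepeats))
    dispersedRepeats <- data.frame(elementLength = integer(),
                                   copyNumber = integer(),
                                   divergence = numeric())
  new("GenomeSpec", length = as.numeric(length),
      gcFraction = gcFraction,
      homopolymerTracts = as.data.frame(homopolymerTracts),
      dispersedRepeats = as.data.frame(dispersedRepeats),
      seed = as.integer(seed))
}

#' @export
setMethod("show", "GenomeSpec", function(object) {
  cat(sprintf("GenomeSpec: %.0f bp, GC %.2f, %d tract group(s), %d repeat family(ies), seed %d\n",
              object@length, object@gcFraction,
              nrow(object@homopolymerTracts),
              nrow(object@dispersedRepeats), object@seed))
})

## sample k non-overlapping placement windows of the given widths in
## [1, n], keeping >= gap bases between them; errors out when impossible
.placeNonOverlapping <- function(n, widths, occupied = NULL, gap = 2L,
                                 maxTries = 200L) {
  starts <- integer(length(widths))
  occ <- if (is.null(occupied)) IRanges::IRanges() else occupied
  for (i in seq_along(widths)) {
    w <- widths[i]
    if (w > n) stop("feature wider than the genome")
    ok <- FALSE
    for (t in seq_len(maxTries)) {
      s <- sample.int(n - w + 1L, 1L)
      cand <- IRanges::IRanges(s - gap, s + w - 1L + gap)
      if (!any(IRanges::overlapsAny(cand, occ))) {
        starts[i] <- s
        occ <- c(occ, IRanges::IRanges(s, s + w - 1L))
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("could not place features without overlap; genome too small")
  }
  list(starts = starts, occupied = occ)
}

#' Generate a synthetic reference sequence
#'
#' Emits a random sequence at the requested GC composition, then overwrites
#' it with the requested homopolymer/dimer tracts and dispersed repeat
#' copies at random non-overlapping positions.  No N bases are ever
#' generated.  The same spec (same seed) always yields the same sequence.
#'
#' @param spec a \code{\linkS4class{GenomeSpec}}.
#' @param chrom chromosome name used in the feature annotation.
#' @return a list with elements \code{sequence} (a \code{DNAString}) and
#'   \code{features} (a \code{GRanges} of planted tracts and repeat copies,
#'   with columns \code{type}, \code{unit}, \code{family}).
#' @examples
#' ref <- generateReference(GenomeSpec(2000, seed = 7))
#' ref$sequence
#' @export
generateReference <- function(spec, chrom = "chrS") {
  stopifnot(is(spec, "GenomeSpec"))
  validObject(spec)
  n <- as.integer(spec@length)
  withSeed(spec@seed, {
    gc <- spec@gcFraction
    base <- sample(DNA_BASES4, n, replace = TRUE,
                   prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
    feat_start <- integer(); feat_width <- integer()
    feat_type <- character(); feat_unit <- character()
    feat_family <- character()
    occ <- IRanges::IRanges()

    ht <- spec@homopolymerTracts
    if (nrow(ht)) {
      ht <- ht[rep(seq_len(nrow(ht)), ht$count), , drop = FALSE]
      pl <- .placeNonOverlapping(n, ht$tractLength, occ)
      occ <- pl$occupied
      for (i in seq_len(nrow(ht))) {
        ul <- ht$unitLength[i]; tl <- ht$tractLength[i]; s <- pl$starts[i]
        unit <- if (ul == 1L) sample(DNA_BASES4, 1L) else
          paste(sample(DNA_BASES4, 2L, replace = FALSE), collapse = "")
        tract <- strsplit(strrep(unit, ceiling(tl / ul)), "")[[1L]][seq_len(tl)]
        base[s:(s + tl - 1L)] <- tract
        feat_start <- c(feat_start, s); feat_width <- c(feat_width, tl)
        feat_type <- c(feat_type, if (ul == 1L) "homopolymer" else "dimer")
        feat_unit <- c(feat_unit, unit); feat_family <- c(feat_family, NA)
      }
    }

    dr <- spec@dispersedRepeats
    if (nrow(dr)) {
      for (f in seq_len(nrow(dr))) {
        el <- as.integer(dr$elementLength[f]); cn <- as.integer(dr$copyNumber[f])
        dv <- dr$divergence[f]
        element <- sample(DNA_BASES4, el, replace = TRUE)
        pl <- .placeNonOverlapping(n, rep(el, cn), occ)
        occ <- pl$occupied
        for (j in seq_len(cn)) {
          copy <- element
          nmut <- rbinom(1L, el, dv)
          if (nmut > 0L) {
            at <- sample.int(el, nmut)
            copy[at] <- vapply(copy[at], function(b)
              sample(setdiff(DNA_BASES4, b), 1L), character(1L))
          }
          s <- pl$starts[j]
          base[s:(s + el - 1L)] <- copy
          feat_start <- c(feat_start, s); feat_width <- c(feat_width, el)
          feat_type <- c(feat_type, "dispersed_repeat")
          feat_unit <- c(feat_unit, NA)
          feat_family <- c(feat_family, sprintf("family%d", f))
        }
      }
    }

    features <- GenomicRanges::GRanges(
      seqnames = rep(chrom, length(feat_start)),
      ranges = IRanges::IRanges(feat_start, width = feat_width),
      type = feat_type, unit = feat_unit, family = feat_family)
    features <- BiocGenerics::sort(features)
    list(sequence = Biostrings::DNAString(paste(base, collapse = "")),
         features = features)
  })
}
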