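#' IndelSet: a set of small insertion/deletion calls
#'
#' An \code{IndelSet} holds insertion/deletion events against one reference.
#' Coordinates are 0-based internally: for a deletion, \code{pos} is the
#' index of the first deleted base; for an insertion, the inserted bases go
#' immediately before the reference base at \code{pos}.  \code{seq} holds
#' the deleted (resp. inserted) bases and \code{length == nchar(seq)}.
#' Calls are expected to be left-normalized (see \code{\link{leftNormalize}})
#' so that equivalent events in repeat tracts compare equal.
#'
#' @slot calls a \code{data.frame} with columns \code{chrom}, \code{pos},
#'   \code{kind} (\code{"ins"} or \code{"del"}), \code{length}, \code{seq},
#'   \code{zygosity} (\code{"hom"}, \code{"het"} or \code{"unknown"}), plus
#'   any extra annotation columns (e.g. \code{hpLength}, read counts).
#'
#' @seealso \code{\link{IndelSet}} for the constructor,
#'   \code{\link{leftNormalize}}, \code{\link{matchCallSets}}
#' @exportClass IndelSet
setClass("IndelSet", representation(calls = "data.frame"))

setValidity("IndelSet", function(object) {
  df <- object@calls
  missing <- setdiff(INDEL_COLUMNS, names(df))
  if (length(missing))
    return(paste("missing columns:", paste(missing, collapse = ", ")))
  if (nrow(df) == 0L) return(TRUE)
  if (!all(df$kind %in% c("ins", "del")))
    return("kind must be 'ins' or 'del'")
  if (!all(df$zygosity %in% c("hom", "het", "unknown")))
    return("zygosity must be 'hom', 'het' or 'unknown'")
  if (any(df$pos < 0L)) return("pos must be >= 0 (0-based)")
  if (any(df$length != nchar(df$seq)))
    return("length must equal nchar(seq)")
  if (any(df$length < 1L)) return("length must be >= 1")
  TRUE
})

#' GenomeSpec: recipe for a synthetic reference genome
#'
#' Describes a random reference sequence with planted homopolymer/dimer
#' tracts and near-identical dispersed repeats, emulating the repeat
#' landscape that makes small-indel calling hard (homopolymer slippage
#' tracts, Alu-like interspersed elements, GC composition).
#'
#' @slot length genome length in bases.
#' @slot gcFraction target G+C proportion in [0, 1].
#' @slot homopolymerTracts \code{data.frame} with columns \code{unitLength}
#'   (1 or 2), \code{tractLength} (bases) and \code{count}.
#' @slot dispersedRepeats \code{data.frame} with columns
#'   \code{elementLength}, \code{copyNumber} and \code{divergence}
#'   (per-base substitution proportion in [0, 1)).
#' @slot seed integer RNG seed; identical seeds give identical sequences.
#' @exportClass GenomeSpec
setClass("GenomeSpec", representation(
  length = "numeric", gcFraction = "numeric",
  homopolymerTracts = "data.frame", dispersedRepeats = "data.frame",
  seed = "integer"))

setValidity("GenomeSpec", function(object) {
  if (object@length < 1) return("length must be positive")
  if (object@gcFraction < 0 || object@gcFraction > 1)
    return("gcFraction must be in [0, 1]")
  ht <- object@homopolymerTracts
  if (nrow(ht)) {
    if (!all(ht$unitLength %in% c(1L, 2L)))
      return("homopolymer/dimer unitLength must be 1 or 2")
    if (any(ht$tractLength > object@length))
      return("tract length exceeds genome length")
  }
  dr <- object@dispersedRepeats
  if (nrow(dr)) {
    if (any(dr$divergence < 0 | dr$divergence >= 1))
      return("divergence must be in [0, 1)")
    if (any(dr$elementLength > object@length))
      return("repeat element length exceeds genome length")
  }
  TRUE
})

#' PlatformSpec: a sequencing platform model
#'
#' Captures the two platform archetypes: a short-read high-coverage
#' platform (e.g. 100 bp at 47x) and a long-read low-coverage one
#' (e.g. 700 bp single-end traces at 0.7x).
#'
#' @slot readLength read length in bases (>= 20).
#' @slot meanCoverage mean fold coverage (> 0, or 0 for an empty read set).
#' @slot errorRate per-base substitution error probability.
#' @slot paired logical; paired-end layout flag (insert-size modelling is
#'   deliberately out of scope, the flag is descriptive).
#' @slot seed integer RNG seed.
#' @exportClass PlatformSpec
setClass("PlatformSpec", representation(
  readLength = "integer", meanCoverage = "numeric", errorRate = "numeric",
  paired = "logical", seed = "integer"))

setValidity("PlatformSpec", function(object) {
  if (object@readLength < 20L) return("readLength must be >= 20")
  if (object@meanCoverage < 0) return("meanCoverage must be >= 0")
  if (object@errorRate < 0 || object@errorRate > 1)
    return("errorRate must be in [0, 1]")
  TRUE
})

#' DetectorModel: a virtual indel caller with known error rates
#'
#' Stands in for a production short-read indel-calling pipeline.  Each true
#' indel is emitted with probability \code{baseSensitivity} times optional
#' piecewise multipliers keyed on homopolymer tract length and on the
#' fraction of informative reads (FIR) at the locus; false calls are added
#' at \code{fpPerMbp} per megabase.  Apparent allele-specific read counts
#' for each emitted call are simulated from the short-read platform depth.
#'
#' @slot baseSensitivity per-indel emission probability in [0, 1].
#' @slot fpPerMbp false calls per Mbp of reference.
#' @slot sensitivityByTract \code{data.frame(minLength, multiplier)}:
#'   multiplier applied when the indel lies in a homopolymer run of at
#'   least \code{minLength} bases (longest applicable row wins); empty
#'   frame = no modifier.
#' @slot sensitivityByFir \code{data.frame(maxFir, multiplier)}: multiplier
#'   applied when the locus FIR is at most \code{maxFir} (smallest
#'   applicable row wins); empty frame = no modifier.
#' @slot zygosityConfusion probability that the apparent allele counts of a
#'   true call are drawn from the wrong zygosity.
#' @slot fpHomFraction fraction of false calls whose fabricated counts look
#'   homozygous.
#' @exportClass DetectorModel
setClass("DetectorModel", representation(
  baseSensitivity = "numeric", fpPerMbp = "numeric",
  sensitivityByTract = "data.frame", sensitivityByFir = "data.frame",
  zygosityConfusion = "numeric", fpHomFraction = "numeric"))

setValidity("DetectorModel", function(object) {
  p <- c(object@baseSensitivity, object@zygosityConfusion,
         object@fpHomFraction)
  if (any(p < 0 | p > 1)) return("probabilities must be in [0, 1]")
  if (object@fpPerMbp < 0) return("fpPerMbp must be >= 0")
  TRUE
})

#' SyntheticTruth: a diploid genome with known planted indels
#'
#' Holds the reference, the two haplotypes obtained by applying the planted
#' indels, and the truth table itself.  Homozygous indels are present on
#' both haplotypes, heterozygous ones on exactly one (column \code{hap}).
#'
#' @slot reference a \code{DNAString}.
#' @slot haplotypeA,haplotypeB \code{DNAString} haplotype sequences.
#' @slot indels \code{data.frame}: the standard indel columns plus
#'   \code{hap} ("A", "B" or "AB") and \code{hpLength} (length of the
#'   homopolymer run context at the locus, 1 = unique sequence).
#' @slot chrom the single chromosome name used throughout.
#' @exportClass SyntheticTruth
setClass("SyntheticTruth", representation(
  reference = "DNAString", haplotypeA = "DNAString",
  haplotypeB = "DNAString", indels = "data.frame", chrom = "character"))

setValidity("SyntheticTruth", function(object) {
  df <- object@indels
  if (nrow(df) && !all(df$hap %in% c("A", "B", "AB")))
    return("hap must be 'A', 'B' or 'AB'")
  if (nrow(df) && any((df$zygosity == "hom") != (df$hap == "AB")))
    return("hom indels must be on both haplotypes, het on exactly one")
  TRUE
})

#' ReadSet: simulated reads with provenance
#'
#' @slot reads a \code{DNAStringSet}.
#' @slot haplotype character vector, source haplotype ("A"/"B") per read.
#' @slot start integer vector, 0-based start on the source haplotype.
#' @slot platform the \code{\linkS4class{PlatformSpec}} used.
#' @exportClass ReadSet
setClass("ReadSet", representation(
  reads = "DNAStringSet", haplotype = "character", start = "integer",
  platform = "PlatformSpec"))

setValidity("ReadSet", function(object) {
  n <- length(object@reads)
  if (length(object@haplotype) != n || length(object@start) != n)
    return("haplotype and start must parallel reads")
  TRUE
})

#' AltContig: the glued alternate-allele contig for one indel
#'
#' For a deletion the contig is left flank + right flank; for an insertion
#' left flank + inserted bases + right flank.  Flanks are
#' \code{readLength - 1} bases (truncated at chromosome ends) so that any
#' read overlapping the event by at least 1 bp fits inside the contig.
#'
#' @slot indel one-row indel \code{data.frame}.
#' @slot sequence the contig \code{DNAString}.
#' @slot junctionSpan \code{IRanges}: contig coordinates of the indel plus
#'   10 bp flanks on each side.
#' @slot flankLengths integer(2): left and right flank lengths actually used.
#' @slot readLength the read length the contig was built for.
#' @exportClass AltContig
setClass("AltContig", representation(
  indel = "data.frame", sequence = "DNAString", junctionSpan = "IRanges",
  flankLengths = "integer", readLength = "integer"))

#' AlleleCoverage: allele-specific unique read counts for one indel
#'
#' @slot nRef reads uniquely supporting the reference allele.
#' @slot nAlt reads uniquely supporting the alternate allele.
#' @slot nAmbiguous reads matching both alleles equally well.
#' @slot nDiscarded reads dropped as non-unique (several equal-best
#'   placements on the same side) or unplaced.
#' @exportClass AlleleCoverage
setClass("AlleleCoverage", representation(
  nRef = "integer", nAlt = "integer", nAmbiguous = "integer",
  nDiscarded = "integer"))

setValidity("AlleleCoverage", function(object) {
  if (any(c(object@nRef, object@nAlt, object@nAmbiguous,
            object@nDiscarded) < 0L))
    return("counts must be >= 0")
  TRUE
})

#' EstimationLedger: all counts entering the total-indel estimator
#'
#' @slot nHom,nHet short-read calls with >= 10 unique reads called
#'   homozygous / heterozygous.
#' @slot sHom,rHom homozygous calls whose covering long-platform reads all
#'   support the alternate (S) resp. all support the reference (R).
#' @slot sHet,rHet same tallies for heterozygous calls.
#' @slot nAnn benchmark annotation size.
#' @slot nHighcov benchmark indels with >= 10 short-platform reads (either
#'   allele).
#' @slot nUnsupported high-coverage benchmark indels with zero
#'   alternate-supporting short-platform reads.
#' @slot nUncovered benchmark indels with zero short-platform reads of
#'   either allele.
#' @slot sRaw raw pipeline sensitivity on the benchmark (proportion).
#' @exportClass EstimationLedger
setClass("EstimationLedger", representation(
  nHom = "numeric", nHet = "numeric", sHom = "numeric", rHom = "numeric",
  sHet = "numeric", rHet = "numeric", nAnn = "numeric",
  nHighcov = "numeric", nUnsupported = "numeric", nUncovered = "numeric",
  sRaw = "numeric"))

setValidity("EstimationLedger", function(object) {
  v <- c(object@nHom, object@nHet, object@sHom, object@rHom, object@sHet,
         object@rHet, object@nAnn, object@nHighcov, object@nUnsupported,
         object@nUncovered)
  if (any(v < 0)) return("counts must be >= 0")
  if (object@sHom + object@rHom > object@nHom)
    return("sHom + rHom must not exceed nHom")
  if (object@sHet + object@rHet > object@nHet)
    return("sHet + rHet must not exceed nHet")
  if (object@nUnsupported > object@nHighcov)
    return("nUnsupported must not exceed nHighcov")
  if (object@nHighcov + object@nUncovered > object@nAnn)
    return("nHighcov + nUncovered must not exceed nAnn")
  if (object@sRaw < 0 || object@sRaw > 1)
    return("sRaw must be in [0, 1]")
  TRUE
})

#' EstimateResult: the corrected genome-wide indel estimate
#'
#' All rates are proportions in [0, 1]; \code{nTotal} satisfies
#' \code{nTotal = (tpHom + tpHet) / sAdj}.
#'
#' @slot ledger the input \code{\linkS4class{EstimationLedger}}.
#' @slot fdrHom,fdrHet false discovery rates of homozygous and
#'   heterozygous calls.
#' @slot tpHom,tpHet adjusted true-positive call counts.
#' @slot fdrAnn benchmark annotation FDR.
#' @slot fnCount estimated true benchmark indels with no short-read
#'   coverage (false negatives of the data).
#' @slot nTrueAnn corrected benchmark size.
#' @slot fnrData coverage false-negative rate.
#' @slot sAdj adjusted pipeline sensitivity.
#' @slot nTotal estimated genome-wide indel count.
#' @exportClass EstimateResult
setClass("EstimateResult", representation(
  ledger = "EstimationLedger", fdrHom = "numeric", fdrHet = "numeric",
  tpHom = "numeric", tpHet = "numeric", fdrAnn = "numeric",
  fnCount = "numeric", nTrueAnn = "numeric", fnrData = "numeric",
  sAdj = "numeric", nTotal = "numeric"))
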