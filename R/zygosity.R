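#' Call indel zygosity from allele-specific unique read counts
#'
#' Applies the coverage-threshold rule used throughout the package: with a
#' total of at least \code{minTotal} uniquely aligned reads, a call is
#' \emph{homozygous} when at least \code{minAllele} reads support the
#' alternate allele and at most \code{maxRefForHom} support the reference
#' (one misaligned read tolerated), \emph{heterozygous} when both alleles
#' are supported by at least \code{minAllele} reads each, and
#' \emph{unknown} otherwise (including any total below \code{minTotal}).
#'
#' @param nRef,nAlt integer vectors of reads uniquely supporting the
#'   reference / alternate allele (ambiguous reads must be excluded
#'   beforehand).
#' @param minTotal minimum total unique coverage (default 10).
#' @param minAllele minimum reads per supported allele (default 3).
#' @param maxRefForHom maximum reference reads for a homozygous call
#'   (default 1).
#' @return character vector: \code{"hom"}, \code{"het"} or
#'   \code{"unknown"}.
#' @examples
#' callZygosity(nRef = c(0, 5, 2, 3), nAlt = c(10, 5, 8, 6))
#' @export
callZygosity <- function(nRef, nAlt, minTotal = 10L, minAllele = 3L,
                         maxRefForHom = 1L) {
  stopifnot(length(nRef) == length(nAlt), all(nRef >= 0), all(nAlt >= 0))
  total <- nRef + nAlt
  out <- rep("unknown", length(total))
  out[total >= minTotal & nAlt >= minAllele & nRef <= maxRefForHom] <- "hom"
  out[total >= minTotal & nAlt >= minAllele & nRef >= minAllele] <- "het"
  out
}

#' Exact misclassification probabilities for a heterozygous locus
#'
#' For a true heterozygous indel covered by exactly \code{nReads} uniquely
#' aligned reads, each read supports the alternate allele with probability
#' \code{pAllele} (1/2 under fair allele sampling).  Enumerating the
#' binomial distribution of the allele split and applying the
#' \code{\link{callZygosity}} rule to each split gives the exact
#' probabilities of the three outcomes.  At \code{nReads = 10} the locus
#' is misclassified as homozygous with probability 11/1024 (about 1.1\%)
#' and left unclassified with probability 101/1024 (about 9.9\%), a
#' combined error of 112/1024 (about 10.9\%); at 15 reads the homozygous
#' misclassification falls to 16/32768 (about 0.05\%).
#'
#' @param nReads total unique read count (>= 1).
#' @param pAllele per-read probability of sampling the alternate allele.
#' @param minTotal,minAllele,maxRefForHom thresholds as in
#'   \code{\link{callZygosity}}.
#' @return a list with \code{pHom}, \code{pUnknown}, \code{pHet} (summing
#'   to 1), plus \code{nReads} and \code{pAllele}.
#' @examples
#' hetMisclassification(10)$pHom * 100   # ~1.07%
#' @export
hetMisclassification <- function(nReads, pAllele = 0.5, minTotal = 10L,
                                 minAllele = 3L, maxRefForHom = 1L) {
  .assertScalarNum(nReads, "nReads", lower = 1)
  .assertScalarNum(pAllele, "pAllele", lower = 0, upper = 1)
  nAlt <- 0:nReads
  p <- dbinom(nAlt, nReads, pAllele)
  state <- callZygosity(nRef = nReads - nAlt, nAlt = nAlt,
                        minTotal = minTotal, minAllele = minAllele,
                        maxRefForHom = maxRefForHom)
  list(pHom = sum(p[state == "hom"]),
       pUnknown = sum(p[state == "unknown"]),
       pHet = sum(p[state == "het"]),
       nReads = as.integer(nReads), pAllele = pAllele)
}

#' @describeIn AlleleCoverage-class constructor
#' @param nRef,nAlt,nAmbiguous,nDiscarded non-negative counts.
#' @export
AlleleCoverage <- function(nRef = 0L, nAlt = 0L, nAmbiguous = 0L,
                           nDiscarded = 0L) {
  new("AlleleCoverage", nRef = as.integer(nRef), nAlt = as.integer(nAlt),
      nAmbiguous = as.integer(nAmbiguous),
      nDiscarded = as.integer(nDiscarded))
}

#' @export
setMethod("show", "AlleleCoverage", function(object) {
  cat(sprintf("AlleleCoverage: %d ref, %d alt, %d ambiguous, %d discarded\n",
              object@nRef, object@nAlt, object@nAmbiguous,
              object@nDiscarded))
})

#' Accessors for AlleleCoverage
#' @param x an \code{\linkS4class{AlleleCoverage}}.
#' @return the corresponding count.
#' @name coverage-accessors
NULL

#' @rdname coverage-accessors
#' @export
nRef <- function(x) x@nRef

#' @rdname coverage-accessors
#' @export
nAlt <- function(x) x@nAlt

#' @rdname coverage-accessors
#' @export
nAmbiguous <- function(x) x@nAmbiguous
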