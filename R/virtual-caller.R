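#' Construct a DetectorModel
#'
#' @param baseSensitivity probability that a true indel is emitted.
#' @param fpPerMbp false calls per Mbp of reference.  The default, together
#'   with \code{baseSensitivity = 0.6} and the study density of 1000 true
#'   indels per Mbp, yields a ~5\% false discovery rate in the call set.
#' @param sensitivityByTract optional \code{data.frame(minLength,
#'   multiplier)}; see \code{\linkS4class{DetectorModel}}.
#' @param sensitivityByFir optional \code{data.frame(maxFir, multiplier)}.
#' @param zygosityConfusion probability of drawing a true call's apparent
#'   counts from the wrong zygosity.
#' @param fpHomFraction fraction of false calls fabricated with
#'   homozygous-looking counts.
#' @return a \code{\linkS4class{DetectorModel}}.
#' @examples
#' DetectorModel(baseSensitivity = 0.6)
#' @export
DetectorModel <- function(baseSensitivity = 0.6, fpPerMbp = 31.6,
                          sensitivityByTract = NULL,
                          sensitivityByFir = NULL,
                          zygosityConfusion = 0, fpHomFraction = 1 / 3) {
  if (is.null(sensitivityByTract))
    sensitivityByTract <- data.frame(minLength = integer(),
                                     multiplier = numeric())
  if (is.null(sensitivityByFir))
    sensitivityByFir <- data.frame(maxFir = numeric(),
                                   multiplier = numeric())
  new("DetectorModel", baseSensitivity = baseSensitivity,
      fpPerMbp = fpPerMbp,
      sensitivityByTract = as.data.frame(sensitivityByTract),
      sensitivityByFir = as.data.frame(sensitivityByFir),
      zygosityConfusion = zygosityConfusion,
      fpHomFraction = fpHomFraction)
}

#' @export
setMethod("show", "DetectorModel", function(object) {
  cat(sprintf("DetectorModel: sensitivity %.2f, %.1f false calls/Mbp\n",
              object@baseSensitivity, object@fpPerMbp))
})

## per-indel detection probability under the model's piecewise modifiers
.detectionProb <- function(detector, hpLength, fir = NULL) {
  p <- rep(detector@baseSensitivity, length(hpLength))
  bt <- detector@sensitivityByTract
  if (nrow(bt)) {
    bt <- bt[order(bt$minLength), , drop = FALSE]
    i <- findInterval(hpLength, bt$minLength)
    p <- p * ifelse(i > 0L, bt$multiplier[pmax(i, 1L)], 1)
  }
  bf <- detector@sensitivityByFir
  if (!is.null(fir) && nrow(bf)) {
    bf <- bf[order(bf$maxFir), , drop = FALSE]
    mult <- rep(1, length(fir))
    for (r in rev(seq_len(nrow(bf))))
      mult[!is.na(fir) & fir <= bf$maxFir[r]] <- bf$multiplier[r]
    p <- p * mult
  }
  pmin(pmax(p, 0), 1)
}

## apparent short-platform allele counts for a locus
.htsCounts <- function(nTot, isHom) {
  nAlt <- ifelse(isHom, nTot, rbinom(length(nTot), nTot, 0.5))
  data.frame(nTot = nTot, nAlt = as.integer(nAlt),
             nRef = as.integer(nTot - nAlt))
}

#' Simulate a short-read call set and its long-platform support
#'
#' The virtual caller emits each truth indel with the model's detection
#' probability and adds false calls at the model's rate, attaching apparent
#' allele-specific short-read counts (total coverage Poisson at the
#' short-read platform depth; heterozygous loci split the reads
#' binomially).  Long-platform allele support per call is tallied from the
#' supplied read set by provenance (\code{\link{sangerSupport}}).  The
#' long-platform benchmark annotation -- every truth indel whose alternate
#' allele was sampled by at least one covering long read, plus optional
#' false annotation entries -- is returned alongside.
#'
#' @param truth a \code{\linkS4class{SyntheticTruth}}.
#' @param detector a \code{\linkS4class{DetectorModel}}.
#' @param sangerReads a \code{\linkS4class{ReadSet}} from the long-read
#'   low-coverage platform.
#' @param htsPlatform a \code{\linkS4class{PlatformSpec}} for the
#'   short-read platform whose depth drives the apparent counts.
#' @param fir optional numeric vector of per-truth-indel FIR values for
#'   FIR-dependent detection.
#' @param benchmarkFpPerMbp rate of false entries in the benchmark
#'   annotation (default 0: the long platform is simulated error-free).
#' @param seed integer RNG seed.
#' @return a list with \code{calls} (data.frame: indel columns, reported
#'   \code{zygosity}, \code{nTot}/\code{nRef}/\code{nAlt} short-read
#'   counts, \code{sangerAlt}/\code{sangerRef} long-read tallies,
#'   \code{truthIndex}, \code{hpLength}) and \code{benchmark} (data.frame:
#'   indel columns, \code{htsTot}/\code{htsAlt}, \code{truthIndex},
#'   \code{hpLength}).
#' @export
simulateCallSets <- function(truth, detector, sangerReads, htsPlatform,
                             fir = NULL, benchmarkFpPerMbp = 0,
                             seed = 1L) {
  stopifnot(is(truth, "SyntheticTruth"), is(detector, "DetectorModel"),
            is(sangerReads, "ReadSet"), is(htsPlatform, "PlatformSpec"))
  tr <- truth@indels
  n <- nrow(tr)
  glen <- base::length(truth@reference)
  cov <- htsPlatform@meanCoverage
  withSeed(seed, {
    ## per-truth-locus short-read counts, shared by calls and benchmark
    tTot <- rpois(n, cov)
    isHom <- tr$zygosity == "hom"
    if (detector@zygosityConfusion > 0) {
      flip <- runif(n) < detector@zygosityConfusion
      isHom <- xor(isHom, flip)
    }
    tCounts <- .htsCounts(tTot, isHom)

    pdet <- .detectionProb(detector, tr$hpLength, fir)
    called <- runif(n) < pdet
    calls <- tr[called, , drop = FALSE]
    calls$truthIndex <- which(called)
    calls$nTot <- tCounts$nTot[called]
    calls$nAlt <- tCounts$nAlt[called]
    calls$nRef <- tCounts$nRef[called]

    ## false calls at fresh positions, fabricated counts
    nFp <- rpois(1L, detector@fpPerMbp * glen / 1e6)
    if (nFp > 0L) {
      refc <- .seqToChars(truth@reference)
      occupied <- sort(tr$pos)
      fpPos <- integer(0)
      tries <- 0L
      while (length(fpPos) < nFp && tries < 20L) {
        tries <- tries + 1L
        cand <- sample.int(glen - 80L, 2L * nFp) + 30L
        j <- findInterval(cand, occupied)
        far <- (j == 0L | cand - occupied[pmax(j, 1L)] >= 25L) &
          (j >= length(occupied) |
             occupied[pmin(j + 1L, length(occupied))] - cand >= 25L)
        fpPos <- unique(c(fpPos, cand[far]))
      }
      fpPos <- fpPos[seq_len(min(nFp, length(fpPos)))]
      nFp <- length(fpPos)
      kind <- sample(c("del", "ins"), nFp, replace = TRUE)
      len <- sample.int(10L, nFp, replace = TRUE, prob = 0.5^(0:9))
      seqs <- vapply(seq_len(nFp), function(i) {
        if (kind[i] == "del")
          paste(refc[(fpPos[i] + 1L):(fpPos[i] + len[i])], collapse = "")
        else paste(sample(DNA_BASES4, len[i], replace = TRUE), collapse = "")
      }, character(1L))
      fp <- data.frame(chrom = truth@chrom, pos = fpPos, kind = kind,
                       length = len, seq = seqs, zygosity = "unknown",
                       stringsAsFactors = FALSE)
      fp <- .leftNormalizeChars(fp, refc)
      fp$hap <- "none"
      fp$hpLength <- 1L
      fp$truthIndex <- NA_integer_
      fpHom <- runif(nFp) < detector@fpHomFraction
      fpCounts <- .htsCounts(rpois(nFp, cov), fpHom)
      fp$nTot <- fpCounts$nTot; fp$nAlt <- fpCounts$nAlt
      fp$nRef <- fpCounts$nRef
      ## drop fabricated calls that collide with a truth call after
      ## normalization
      fp <- fp[!(paste(fp$pos, fp$kind, fp$seq) %in%
                   paste(tr$pos, tr$kind, tr$seq)), , drop = FALSE]
      calls <- rbind(calls[, names(fp)], fp)
    }
    calls <- calls[order(calls$pos), , drop = FALSE]
    rownames(calls) <- NULL
    ## reported zygosity: what the pipeline would say from its counts
    calls$zygosity <- callZygosity(calls$nRef, calls$nAlt)
    calls <- sangerSupport(calls, truth, sangerReads)

    ## benchmark: truth indels seen by the long platform
    bench <- sangerSupport(cbind(tr, truthIndex = seq_len(n)), truth,
                           sangerReads)
    bench$htsTot <- tCounts$nTot
    bench$htsAlt <- tCounts$nAlt
    bench <- bench[bench$sangerAlt >= 1L, , drop = FALSE]
    nBfp <- rpois(1L, benchmarkFpPerMbp * glen / 1e6)
    if (nBfp > 0L) {
      refc <- .seqToChars(truth@reference)
      bpPos <- sample.int(glen - 80L, nBfp) + 30L
      bpPos <- bpPos[!(bpPos %in% (tr$pos + 1L))]
      nBfp <- length(bpPos)
      bfp <- data.frame(chrom = truth@chrom, pos = bpPos - 1L,
                        kind = "del", length = 1L,
                        seq = refc[bpPos], zygosity = "unknown",
                        hap = "none", hpLength = 1L,
                        truthIndex = NA_integer_,
                        sangerAlt = 1L, sangerRef = 0L,
                        stringsAsFactors = FALSE)
      bfp <- .leftNormalizeChars(bfp, refc)
      bfp$htsTot <- rpois(nBfp, cov)
      bfp$htsAlt <- 0L
      bench <- rbind(bench[, names(bfp)], bfp)
    }
    bench <- bench[order(bench$pos), , drop = FALSE]
    rownames(bench) <- NULL
    list(calls = calls, benchmark = bench)
  })
}
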