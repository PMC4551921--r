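#' False discovery rate of homozygous calls from long-platform evidence
#'
#' Among homozygous short-read calls whose covering long-platform reads
#' are unanimous, those fully supporting the alternate allele are true
#' positives (S) and those fully supporting the reference are false
#' positives (R): the FDR is \code{R / (S + R)}.  With the published
#' counts S = 78,328 and R = 3,303 this gives 4.05\%.
#'
#' @param S calls with all covering long reads supporting the alternate.
#' @param R calls with all covering long reads supporting the reference.
#' @return the FDR as a proportion (NA when S + R = 0).
#' @export
fdrHomozygous <- function(S, R) {
  stopifnot(S >= 0, R >= 0)
  if (S + R == 0) return(NA_real_)
  R / (S + R)
}

#' False discovery rate of heterozygous calls
#'
#' For a true heterozygous indel, a set of covering long-platform reads is
#' as likely to be unanimously reference as unanimously alternate (each
#' read samples an allele fairly), so true calls contribute equally to
#' both unanimity tallies and the \emph{excess} of reference-unanimous
#' calls estimates the false positives:
#' \code{FDR = (R - S) / (S + R)}.  With the published counts S = 64,536
#' and R = 76,368 this gives 8.40\%.  A negative excess is clamped to 0
#' with a warning.
#'
#' @inheritParams fdrHomozygous
#' @return the FDR as a proportion (NA when S + R = 0).
#' @export
fdrHeterozygous <- function(S, R) {
  stopifnot(S >= 0, R >= 0)
  if (S + R == 0) return(NA_real_)
  if (R < S) {
    # a deficit beyond sampling noise signals a model violation; a small
    # one is the expected fluctuation of a clean call set
    if (S - R > 2 * sqrt(S + R))
      warning("reference-unanimous count below alternate-unanimous ",
              "count beyond sampling noise; clamping heterozygous FDR to 0")
    return(0)
  }
  (R - S) / (S + R)
}

#' Adjusted true-positive count
#'
#' @param N number of calls in the class.
#' @param fdr the class FDR (proportion).
#' @return \code{N * (1 - fdr)}, at full precision (round only at display).
#' @export
adjustedTP <- function(N, fdr) {
  stopifnot(N >= 0)
  if (is.na(fdr)) return(NA_real_)
  N * (1 - fdr)
}

#' Benchmark annotation FDR and coverage FNR
#'
#' From the short-platform coverage of the benchmark annotation:
#' high-coverage entries with no alternate-supporting reads are false
#' annotation entries (\code{fdrAnn = nUnsupported / nHighcov}); entries
#' with no reads at all are assumed true at the complementary rate
#' (\code{fn = round(nUncovered * (1 - fdrAnn))}, half-up); the corrected
#' benchmark size is the supported high-coverage entries plus those
#' false negatives, and \code{fnrData = fn / nTrueAnn}.  The published
#' chain (98,038 / 1,179 / 2,428) gives 1.20\%, 2,399, 99,258 and 2.42\%.
#'
#' @param nHighcov benchmark entries with >= 10 short-platform reads.
#' @param nUnsupported high-coverage entries with zero alternate support.
#' @param nUncovered benchmark entries with zero short-platform reads.
#' @return a list with \code{fdrAnn}, \code{fnCount}, \code{nTrueAnn},
#'   \code{fnrData}.
#' @export
annotationCorrection <- function(nHighcov, nUnsupported, nUncovered) {
  stopifnot(nUnsupported <= nHighcov, nUncovered >= 0)
  if (nHighcov == 0)
    return(list(fdrAnn = NA_real_, fnCount = NA_real_,
                nTrueAnn = NA_real_, fnrData = NA_real_))
  fdrAnn <- nUnsupported / nHighcov
  fn <- roundHalfUp(nUncovered * (1 - fdrAnn))
  nTrueAnn <- (nHighcov - nUnsupported) + fn
  fnr <- if (nTrueAnn > 0) fn / nTrueAnn else 0
  list(fdrAnn = fdrAnn, fnCount = fn, nTrueAnn = nTrueAnn, fnrData = fnr)
}

#' Adjusted pipeline sensitivity
#'
#' Composes the raw benchmark sensitivity with the annotation FDR and the
#' coverage FNR multiplicatively:
#' \code{sAdj = sRaw * (1 - fdrAnn) * (1 - fnrData)}; 64.07\% becomes
#' 61.77\% under the published correction factors.
#'
#' @param sRaw raw sensitivity on the benchmark (proportion).
#' @param fdrAnn benchmark annotation FDR.
#' @param fnrData coverage false-negative rate.
#' @return the adjusted sensitivity (proportion).
#' @export
adjustedSensitivity <- function(sRaw, fdrAnn, fnrData) {
  stopifnot(sRaw >= 0, sRaw <= 1)
  sRaw * (1 - fdrAnn) * (1 - fnrData)
}

#' Estimated genome-wide indel total
#'
#' @param tpHom,tpHet adjusted true-positive call counts.
#' @param sAdj adjusted sensitivity (> 0).
#' @return \code{(tpHom + tpHet) / sAdj} (NA when \code{sAdj} is 0/NA).
#' @export
estimateTotal <- function(tpHom, tpHet, sAdj) {
  if (is.na(sAdj) || sAdj == 0) return(NA_real_)
  (tpHom + tpHet) / sAdj
}

#' Construct an EstimationLedger
#'
#' @param nHom,nHet,sHom,rHom,sHet,rHet,nAnn,nHighcov,nUnsupported,nUncovered
#'   counts as documented in \code{\linkS4class{EstimationLedger}}.
#' @param sRaw raw benchmark sensitivity (proportion).
#' @return an \code{\linkS4class{EstimationLedger}}.
#' @export
EstimationLedger <- function(nHom, nHet, sHom, rHom, sHet, rHet, nAnn,
                             nHighcov, nUnsupported, nUncovered, sRaw) {
  new("EstimationLedger", nHom = nHom, nHet = nHet, sHom = sHom,
      rHom = rHom, sHet = sHet, rHet = rHet, nAnn = nAnn,
      nHighcov = nHighcov, nUnsupported = nUnsupported,
      nUncovered = nUncovered, sRaw = sRaw)
}

#' @export
setMethod("show", "EstimationLedger", function(object) {
  cat("EstimationLedger\n",
      sprintf("  calls >=10 reads: %0.f hom / %0.f het\n",
              object@nHom, object@nHet),
      sprintf("  unanimity (alt/ref): hom %0.f/%0.f, het %0.f/%0.f\n",
              object@sHom, object@rHom, object@sHet, object@rHet),
      sprintf("  benchmark: %0.f (%0.f high-cov, %0.f unsupported, %0.f uncovered)\n",
              object@nAnn, object@nHighcov, object@nUnsupported,
              object@nUncovered),
      sprintf("  raw sensitivity: %.2f%%\n", 100 * object@sRaw), sep = "")
})

#' Run the full estimation chain on a ledger of counts
#'
#' Executes the four-stage correction: (i) homozygous and heterozygous
#' FDRs from the unanimity tallies and the corresponding adjusted
#' true-positive counts; (ii) benchmark annotation FDR from unsupported
#' high-coverage entries; (iii) coverage FNR from uncovered entries;
#' (iv) adjusted sensitivity and the genome-wide total
#' \code{(tpHom + tpHet) / sAdj}.  All intermediates are carried at full
#' precision.
#'
#' @param ledger an \code{\linkS4class{EstimationLedger}}.
#' @return an \code{\linkS4class{EstimateResult}}.
#' @examples
#' led <- EstimationLedger(nHom = 230995, nHet = 402619,
#'                         sHom = 78328, rHom = 3303,
#'                         sHet = 64536, rHet = 76368,
#'                         nAnn = 120056, nHighcov = 98038,
#'                         nUnsupported = 1179, nUncovered = 2428,
#'                         sRaw = 0.6407)
#' estimateFromLedger(led)
#' @export
estimateFromLedger <- function(ledger) {
  stopifnot(is(ledger, "EstimationLedger"))
  validObject(ledger)
  fdrHom <- fdrHomozygous(ledger@sHom, ledger@rHom)
  fdrHet <- fdrHeterozygous(ledger@sHet, ledger@rHet)
  tpHom <- adjustedTP(ledger@nHom, fdrHom)
  tpHet <- adjustedTP(ledger@nHet, fdrHet)
  ann <- annotationCorrection(ledger@nHighcov, ledger@nUnsupported,
                              ledger@nUncovered)
  sAdj <- adjustedSensitivity(ledger@sRaw, ann$fdrAnn, ann$fnrData)
  nTotal <- estimateTotal(tpHom, tpHet, sAdj)
  new("EstimateResult", ledger = ledger, fdrHom = fdrHom,
      fdrHet = fdrHet, tpHom = tpHom, tpHet = tpHet,
      fdrAnn = ann$fdrAnn, fnCount = ann$fnCount,
      nTrueAnn = ann$nTrueAnn, fnrData = ann$fnrData, sAdj = sAdj,
      nTotal = nTotal)
}

#' @export
setMethod("show", "EstimateResult", function(object) {
  cat("EstimateResult\n",
      sprintf("  FDR hom %.2f%% -> %.0f true positives\n",
              100 * object@fdrHom, object@tpHom),
      sprintf("  FDR het %.2f%% -> %.0f true positives\n",
              100 * object@fdrHet, object@tpHet),
      sprintf("  annotation FDR %.2f%%, coverage FNR %.2f%% (%0.f true benchmark indels)\n",
              100 * object@fdrAnn, 100 * object@fnrData, object@nTrueAnn),
      sprintf("  sensitivity %.2f%% -> adjusted %.2f%%\n",
              100 * object@ledger@sRaw, 100 * object@sAdj),
      sprintf("  estimated genome-wide indel total: %.0f\n",
              object@nTotal), sep = "")
})

#' Accessors for EstimateResult
#' @param x an \code{\linkS4class{EstimateResult}}.
#' @return the corresponding value.
#' @name estimate-accessors
NULL

#' @rdname estimate-accessors
#' @export
nTotal <- function(x) x@nTotal

#' @rdname estimate-accessors
#' @export
adjustedSens <- function(x) x@sAdj

#' Match two left-normalized indel call sets
#'
#' Default matching is identity on (chrom, kind, length, normalized
#' position, sequence); an optional position tolerance relaxes only the
#' position.
#'
#' @param pipeline,benchmark \code{\linkS4class{IndelSet}}s or indel
#'   \code{data.frame}s on the same reference.
#' @param tolerance maximum position difference (default 0, up to 10).
#' @return a list with \code{nMatched}, \code{benchmarkMatched} (logical
#'   per benchmark row), \code{pipelineMatched} (logical per pipeline
#'   row).
#' @export
matchCallSets <- function(pipeline, benchmark, tolerance = 0L) {
  stopifnot(tolerance >= 0L, tolerance <= 10L)
  a <- .indelFrame(pipeline); b <- .indelFrame(benchmark)
  if (tolerance == 0L) {
    ka <- paste(a$chrom, a$kind, a$length, a$pos, a$seq)
    kb <- paste(b$chrom, b$kind, b$length, b$pos, b$seq)
    bm <- kb %in% ka
    pm <- ka %in% kb
  } else {
    # with a positional slack the sequences may be rotated relative to
    # one another, so matching keys drop the sequence
    bm <- logical(nrow(b)); pm <- logical(nrow(a))
    ga <- paste(a$chrom, a$kind, a$length)
    gb <- paste(b$chrom, b$kind, b$length)
    for (g in intersect(ga, gb)) {
      ia <- which(ga == g); ib <- which(gb == g)
      d <- abs(outer(b$pos[ib], a$pos[ia], "-")) <= tolerance
      bm[ib] <- bm[ib] | rowSums(d) > 0L
      pm[ia] <- pm[ia] | colSums(d) > 0L
    }
  }
  list(nMatched = sum(bm), benchmarkMatched = bm, pipelineMatched = pm)
}

#' Sensitivity, saturation and fold increase of a pipeline vs a benchmark
#'
#' Sensitivity is the fraction of benchmark indels recovered by the
#' pipeline; saturation the fraction of pipeline calls present in the
#' benchmark; fold increase the ratio of pipeline to matched counts (the
#' reciprocal of the saturation).
#'
#' @param pipeline,benchmark call sets (see \code{\link{matchCallSets}}),
#'   or omit \code{benchmark} and pass counts to the \code{n*} arguments.
#' @param tolerance position tolerance for matching.
#' @param nMatched,nBenchmark,nPipeline alternatively, precomputed counts.
#' @return a list with \code{sensitivity}, \code{saturation},
#'   \code{foldIncrease}, \code{nMatched}, \code{nBenchmark},
#'   \code{nPipeline}.
#' @examples
#' sensitivitySaturation(nMatched = 145944, nBenchmark = 226112,
#'                       nPipeline = 784319)
#' @export
sensitivitySaturation <- function(pipeline = NULL, benchmark = NULL,
                                  tolerance = 0L, nMatched = NULL,
                                  nBenchmark = NULL, nPipeline = NULL) {
  if (is.null(nMatched)) {
    m <- matchCallSets(pipeline, benchmark, tolerance)
    nMatched <- sum(m$pipelineMatched)
    nBenchmark <- nrow(.indelFrame(benchmark))
    nPipeline <- nrow(.indelFrame(pipeline))
    sensitivity <- if (nBenchmark > 0) m$nMatched / nBenchmark else NA_real_
  } else {
    sensitivity <- if (nBenchmark > 0) nMatched / nBenchmark else NA_real_
  }
  saturation <- if (nPipeline > 0) nMatched / nPipeline else NA_real_
  fold <- if (!is.na(saturation) && nMatched > 0)
    nPipeline / nMatched else NA_real_
  list(sensitivity = sensitivity, saturation = saturation,
       foldIncrease = fold, nMatched = nMatched,
       nBenchmark = nBenchmark, nPipeline = nPipeline)
}

#' Stratum filters for the estimation chain
#'
#' \code{stratumNonHpLe10} keeps indels outside homopolymers or in
#' homopolymer runs of at most 10 bp (the short-homopolymer stratum of
#' the stratified estimate).
#'
#' @param hpLength integer vector of homopolymer-context lengths.
#' @return logical vector.
#' @export
stratumNonHpLe10 <- function(hpLength) is.na(hpLength) | hpLength <= 10L

#' Run the full estimation pipeline on simulated call sets
#'
#' Orchestrates the chain on the output of
#' \code{\link{simulateCallSets}}: restricts both sets to 1-10 bp events
#' (and to an optional repeat-context stratum), recomputes zygosity from
#' the allele-specific short-read counts at the >= \code{minCoverage}
#' threshold, forms the long-platform unanimity tallies, derives the
#' benchmark coverage classes, measures the raw sensitivity by exact
#' set matching, and applies \code{\link{estimateFromLedger}}.
#'
#' @param calls the \code{calls} data.frame from
#'   \code{\link{simulateCallSets}} (short-read call set with
#'   \code{nRef}/\code{nAlt}/\code{nTot} and
#'   \code{sangerAlt}/\code{sangerRef} columns).
#' @param benchmark the \code{benchmark} data.frame (long-platform
#'   annotation with \code{htsTot}/\code{htsAlt} columns).
#' @param minCoverage minimum short-read coverage for the zygosity and
#'   benchmark-support analyses (default 10).
#' @param stratum optional function mapping the \code{hpLength} column to
#'   a logical keep-mask (e.g. \code{\link{stratumNonHpLe10}}).
#' @param lengthRange inclusive indel length window (default 1-10 bp).
#' @param tolerance position tolerance for benchmark matching.
#' @return an \code{\linkS4class{EstimateResult}}.
#' @export
runEstimation <- function(calls, benchmark, minCoverage = 10L,
                          stratum = NULL, lengthRange = c(1L, 10L),
                          tolerance = 0L) {
  keepLen <- function(df)
    df[df$length >= lengthRange[1L] & df$length <= lengthRange[2L], ,
       drop = FALSE]
  calls <- keepLen(calls); benchmark <- keepLen(benchmark)
  if (!is.null(stratum)) {
    calls <- calls[stratum(calls$hpLength), , drop = FALSE]
    benchmark <- benchmark[stratum(benchmark$hpLength), , drop = FALSE]
  }
  zyg <- callZygosity(calls$nRef, calls$nAlt, minTotal = minCoverage)
  isHom <- zyg == "hom"; isHet <- zyg == "het"
  unanimousAlt <- calls$sangerAlt >= 1L & calls$sangerRef == 0L
  unanimousRef <- calls$sangerRef >= 1L & calls$sangerAlt == 0L
  nHighcov <- sum(benchmark$htsTot >= minCoverage)
  nUnsupported <- sum(benchmark$htsTot >= minCoverage &
                        benchmark$htsAlt == 0L)
  nUncovered <- sum(benchmark$htsTot == 0L)
  sens <- sensitivitySaturation(calls, benchmark, tolerance = tolerance)
  ledger <- EstimationLedger(
    nHom = sum(isHom), nHet = sum(isHet),
    sHom = sum(isHom & unanimousAlt), rHom = sum(isHom & unanimousRef),
    sHet = sum(isHet & unanimousAlt), rHet = sum(isHet & unanimousRef),
    nAnn = nrow(benchmark), nHighcov = nHighcov,
    nUnsupported = nUnsupported, nUncovered = nUncovered,
    sRaw = sens$sensitivity)
  estimateFromLedger(ledger)
}
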