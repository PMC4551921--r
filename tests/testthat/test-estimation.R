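test_that("class FDR formulas reproduce the published rates", {
  expect_equal(round(100 * fdrHomozygous(78328, 3303), 2), 4.05)
  expect_equal(floor(adjustedTP(
    230995, fdrHomozygous(78328, 3303)) + 0.5), 221648)
  expect_equal(round(100 * fdrHeterozygous(64536, 76368), 2), 8.40)
  expect_equal(floor(adjustedTP(
    402619, fdrHeterozygous(64536, 76368)) + 0.5), 368810)
  # degenerate tallies
  expect_equal(fdrHomozygous(100, 0), 0)
  expect_equal(fdrHomozygous(0, 100), 1)
  expect_true(is.na(fdrHomozygous(0, 0)))
  expect_equal(fdrHeterozygous(50, 50), 0)   # perfect allele symmetry
  # a small deficit is sampling noise and clamps silently ...
  expect_no_warning(out <- fdrHeterozygous(60, 50))
  expect_equal(out, 0)
  # ... a large one signals a model violation
  expect_warning(fdrHeterozygous(1000, 800), "clamping")
})

test_that("annotation FDR and coverage FNR follow the published chain", {
  ann <- annotationCorrection(98038, 1179, 2428)
  expect_equal(round(100 * ann$fdrAnn, 2), 1.20)
  expect_equal(ann$fnCount, 2399)
  expect_equal(ann$nTrueAnn, 99258)
  expect_equal(round(100 * ann$fnrData, 2), 2.42)
  perfect <- annotationCorrection(1000, 0, 0)
  expect_equal(perfect$fdrAnn, 0)
  expect_equal(perfect$fnrData, 0)
  allFalse <- annotationCorrection(1000, 1000, 100)
  expect_equal(allFalse$fdrAnn, 1)
  expect_equal(allFalse$fnCount, 0)
  expect_equal(allFalse$fnrData, 0)
})

test_that("sensitivity adjustment composes the correction factors", {
  ann <- annotationCorrection(98038, 1179, 2428)
  expect_equal(round(100 * adjustedSensitivity(
    0.6407, ann$fdrAnn, ann$fnrData), 2), 61.77)
  expect_equal(adjustedSensitivity(0.5, 0, 0), 0.5)
  expect_equal(adjustedSensitivity(0, 0.1, 0.2), 0)
})

test_that("the full ledger chain reproduces every printed intermediate", {
  led <- EstimationLedger(nHom = 230995, nHet = 402619, sHom = 78328,
                          rHom = 3303, sHet = 64536, rHet = 76368,
                          nAnn = 120056, nHighcov = 98038,
                          nUnsupported = 1179, nUncovered = 2428,
                          sRaw = 0.6407)
  est <- estimateFromLedger(led)
  expect_equal(round(100 * est@fdrHom, 2), 4.05)
  expect_equal(round(100 * est@fdrHet, 2), 8.40)
  expect_equal(round(100 * est@fdrAnn, 2), 1.20)
  expect_equal(round(100 * est@fnrData, 2), 2.42)
  expect_equal(round(100 * adjustedSens(est), 2), 61.77)
  expect_equal(nTotal(est), 955839, tolerance = 1e-4)
  expect_equal(estimateTotal(100, 0, 0.5), 200)
  expect_true(is.na(estimateTotal(10, 10, 0)))
})

test_that("rounding intermediates to 4 decimals barely moves the total", {
  led <- EstimationLedger(230995, 402619, 78328, 3303, 64536, 76368,
                          120056, 98038, 1179, 2428, 0.6407)
  est <- estimateFromLedger(led)
  rounded <- estimateTotal(
    led@nHom * (1 - round(est@fdrHom, 4)),
    led@nHet * (1 - round(est@fdrHet, 4)),
    round(led@sRaw, 4) * (1 - round(est@fdrAnn, 4)) *
      (1 - round(est@fnrData, 4)))
  expect_lt(abs(rounded - nTotal(est)) / nTotal(est), 0.001)
})

test_that("call-set matching and sensitivity/saturation metrics", {
  ref <- Biostrings::DNAString(randomSeq(5000, seed = 70))
  g <- as.character(ref)
  mk <- function(pos) leftNormalize(IndelSet(
    "chrS", as.integer(pos), "del",
    substring(g, pos + 1, pos + 1)), ref)
  a <- do.call(rbind, lapply(c(100, 300, 500, 700, 900),
                             function(p) as.data.frame(mk(p))))
  b <- do.call(rbind, lapply(c(100, 300, 501),
                             function(p) as.data.frame(mk(p))))
  m <- matchCallSets(a, b)
  expect_equal(m$nMatched, 2L)
  ss <- sensitivitySaturation(a, b)
  expect_equal(ss$sensitivity, 2 / 3)
  expect_equal(ss$saturation, 2 / 5)
  # identical and disjoint sets
  same <- sensitivitySaturation(a, a)
  expect_equal(same$sensitivity, 1)
  expect_equal(same$saturation, 1)
  expect_equal(same$foldIncrease, 1)
  disj <- sensitivitySaturation(a[1:2, ], a[3:5, ])
  expect_equal(disj$sensitivity, 0)
  expect_true(is.na(disj$foldIncrease))
  # saturation x fold increase = 1 whenever matches exist
  expect_equal(ss$saturation * ss$foldIncrease, 1)
  # position tolerance rescues near misses
  mt <- matchCallSets(a, b, tolerance = 1L)
  expect_equal(mt$nMatched, 3L)
})

test_that("a perfect detector with a perfect benchmark recovers the truth", {
  ref <- generateReference(GenomeSpec(5e5, seed = 71L))
  tr <- plantIndels(ref, 500L, seed = 72L)
  sg <- simulateReads(tr, PlatformSpec(700L, 4, seed = 73L))
  cs <- simulateCallSets(tr, DetectorModel(1, fpPerMbp = 0), sg,
                         PlatformSpec(100L, 47), seed = 74L)
  est <- runEstimation(cs$calls, cs$benchmark)
  expect_equal(nTotal(est), 500, tolerance = 0.01)
})

test_that("estimates react to the knobs in the expected directions", {
  # total decreases in adjusted sensitivity, increases in TP counts
  expect_gt(estimateTotal(100, 100, 0.4), estimateTotal(100, 100, 0.6))
  expect_gt(estimateTotal(150, 100, 0.5), estimateTotal(100, 100, 0.5))
  # the stratum filter restricts both call and benchmark sets
  keep <- stratumNonHpLe10(c(1L, 5L, 11L, NA))
  expect_equal(keep, c(TRUE, TRUE, FALSE, TRUE))
})

test_that("injected het false calls are recovered by the excess rule", {
  ref <- generateReference(GenomeSpec(4e6, seed = 75L))
  tr <- plantIndels(ref, 4000L, homFraction = 0, seed = 76L)
  sg <- simulateReads(tr, PlatformSpec(700L, 0.7, seed = 77L))
  # ~5% FDR all fabricated as het-looking calls
  det <- DetectorModel(0.6, fpPerMbp = 4000 / 4 * 0.6 * 0.05 / 0.95,
                       fpHomFraction = 0)
  cs <- simulateCallSets(tr, det, sg, PlatformSpec(100L, 47), seed = 78L)
  est <- runEstimation(cs$calls, cs$benchmark)
  trueFdr <- mean(is.na(cs$calls$truthIndex))
  # the unanimity-excess estimator tracks the injected rate; the tally
  # probabilities differ slightly between true and false calls, so allow
  # a couple of points beyond sampling noise
  expect_lt(abs(est@fdrHet - trueFdr), 0.025)
})
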