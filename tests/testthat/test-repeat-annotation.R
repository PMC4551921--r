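test_that("annotateRepeats handles the canonical small cases", {
  # a four-nucleotide ACAC is one dimer tract of 2 units
  t1 <- annotateRepeats("ACAC")
  expect_equal(length(t1), 1L)
  expect_equal(t1$unit, "AC")
  expect_equal(t1$nUnits, 2L)
  expect_equal(t1$regionLength, 4L)
  # no repeated unit -> nothing emitted
  expect_equal(length(annotateRepeats("ACGT")), 0L)
  # homopolymer units beat the dimer reading of the same run
  t2 <- annotateRepeats("TTTTT")
  expect_equal(length(t2), 1L)
  expect_equal(t2$unit, "T")
  expect_equal(t2$nUnits, 5L)
  # mixed: A-run then CA-dimer, resolved by the greedy rule
  t3 <- annotateRepeats("AAACACAC")
  expect_equal(tractsToFrame(t3), oracleAnnotate("AAACACAC"))
  expect_error(annotateRepeats("ACGN"), "outside")
})

test_that("annotator agrees with the exhaustive oracle on random sequences", {
  set.seed(99)
  for (i in 1:60) {
    # low-entropy alphabets provoke dense, tie-rich repeat structure
    s <- paste(sample(c("A", "C", if (i %% 2) "G" else "A"), 120,
                      replace = TRUE), collapse = "")
    expect_equal(tractsToFrame(annotateRepeats(s)), oracleAnnotate(s),
                 info = paste("seq", i))
  }
})

test_that("tracts are non-overlapping, ordered, and at least 2 units", {
  s <- randomSeq(5000, seed = 17, gc = 0.3)
  tr <- annotateRepeats(s)
  st <- BiocGenerics::start(tr); en <- BiocGenerics::end(tr)
  expect_true(all(diff(st) > 0))
  expect_true(all(st[-1L] > en[-length(en)]))
  expect_true(all(tr$nUnits >= 2L))
  expect_true(all(tr$regionLength ==
                    tr$nUnits * nchar(tr$unit)))
  # dimers are true dimers: two different bases
  dimers <- tr$unit[nchar(tr$unit) == 2L]
  expect_true(all(substr(dimers, 1, 1) != substr(dimers, 2, 2)))
})

test_that("indels are assigned to the longest overlapping tract", {
  # an 8 bp A-run and a 12 bp Cc dimer tract side by side
  s <- paste0("GTCGTC", strrep("A", 8), strrep("GT", 6), "CCTGAC")
  tracts <- annotateRepeats(s)
  # deletion overlapping both tracts -> the 12 bp dimer wins
  del <- IndelSet("chrS", 12L, "del", substr(s, 13, 15))
  asg <- assignIndelRepeat(del, tracts)
  expect_equal(asg$regionLength, 12L)
  expect_equal(asg$unit, "GT")
  # 1 bp deletion inside the A-run -> that tract
  del2 <- IndelSet("chrS", 9L, "del", "A")
  expect_equal(assignIndelRepeat(del2, tracts)$unit, "A")
  # indel in unique sequence -> none
  del3 <- IndelSet("chrS", 2L, "del", substr(s, 3, 3))
  expect_true(is.na(assignIndelRepeat(del3, tracts)$tract))
})

test_that("indel density is count per kbp of tract sequence", {
  tracts <- GenomicRanges::GRanges(
    "chrS", IRanges::IRanges(c(1, 500, 1200, 2000),
                             width = c(8, 8, 8, 8)),
    unit = "A", nUnits = 8L, regionLength = 8L)
  # extend to 2000 bp of length-8 tracts: 250 tracts of 8 bp
  tracts <- GenomicRanges::GRanges(
    "chrS", IRanges::IRanges(seq(1, by = 20, length.out = 250), width = 8),
    unit = "A", nUnits = 8L, regionLength = 8L)
  idx <- seq(1, by = 20, length.out = 5)
  indels <- IndelSet("chrS", as.integer(idx + 2), "del", "A")
  d <- indelDensity(indels, tracts)
  expect_equal(d$nIndels, 5)
  expect_equal(d$totalTractBases, 2000)
  expect_equal(d$density, 2.5)
  # no indels -> zero densities, class rows kept
  d0 <- indelDensity(IndelSet(), tracts)
  expect_equal(d0$density, 0)
  # conservation: class counts sum to the number of assigned indels
  expect_equal(sum(d$nIndels),
               sum(!is.na(assignIndelRepeat(indels, tracts)$tract)))
})

test_that("residual indel fraction is a reverse CDF over tract length", {
  # uniform counts over tract lengths 6..10
  tracts <- GenomicRanges::GRanges(
    "chrS", IRanges::IRanges(seq(1, by = 30, length.out = 5),
                             width = 6:10),
    unit = "A", nUnits = 6:10, regionLength = 6:10)
  pos <- BiocGenerics::start(tracts) + 1L
  indels <- IndelSet("chrS", as.integer(pos), "del", "A")
  rf <- residualIndelFraction(indels, tracts)
  expect_equal(rf$fraction[rf$regionLength == 6], 1.0)
  expect_equal(rf$fraction[rf$regionLength == 8], 0.6)
  expect_equal(rf$fraction[rf$regionLength == 11], 0.0)
  expect_true(all(diff(rf$fraction) <= 0))
})

test_that("gcProfile bins whole windows and drops the partial tail", {
  p <- gcProfile(strrep("A", 400))
  expect_equal(sum(p$nWindows), 2L)
  expect_equal(p$gcLo[p$nWindows > 0], 0)
  # a window with 66 G/C of 200 is 33% -> the 31-35% bin
  w <- paste0(strrep("G", 66), strrep("A", 134), strrep("C", 100),
              strrep("T", 100))
  p2 <- gcProfile(w)
  expect_equal(p2$nWindows[p2$gcLo == 31], 1L)
  # 450 bp -> the trailing 50 bp are ignored
  expect_equal(sum(gcProfile(strrep("A", 450))$nWindows), 2L)
})

test_that("interval stratification uses half-open overlap", {
  bed <- GenomicRanges::GRanges("chrS", IRanges::IRanges(100, 200))
  inside <- IndelSet("chrS", 149L, "del", "A")
  outside <- IndelSet("chrS", 300L, "del", "A")
  expect_true(stratifyByIntervals(inside, bed))
  expect_false(stratifyByIntervals(outside, bed))
})

test_that("planted repeat bias shows up as higher density in tracts", {
  ref <- generateReference(GenomeSpec(
    4e5, homopolymerTracts = data.frame(unitLength = 1L,
                                        tractLength = 12L, count = 150L),
    seed = 55L))
  tr <- plantIndels(ref, 600L, repeatBias = 30, seed = 56L)
  df <- as.data.frame(truthIndels(tr))
  inTract <- mean(df$hpLength >= 4L)
  # tract bases are a small minority of the genome; with strong bias a
  # disproportionate share of indels must land there
  expect_gt(inTract, 0.10)
})
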