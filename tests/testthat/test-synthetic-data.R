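test_that("generateReference honours length, seed and planted tracts", {
  spec <- GenomeSpec(1000, gcFraction = 0.5,
                     homopolymerTracts = data.frame(
                       unitLength = 1L, tractLength = 14L, count = 1L),
                     seed = 7L)
  ref <- generateReference(spec)
  expect_equal(length(ref$sequence), 1000L)
  f <- ref$features
  expect_equal(length(f), 1L)
  planted <- as.character(Biostrings::subseq(
    ref$sequence, BiocGenerics::start(f), BiocGenerics::end(f)))
  expect_equal(planted, strrep(f$unit, 14L))
  # determinism: same spec twice -> identical sequence
  expect_identical(as.character(generateReference(spec)$sequence),
                   as.character(ref$sequence))
  # invalid specs are rejected
  expect_error(GenomeSpec(100, gcFraction = 1.4), "gcFraction")
  expect_error(generateReference(GenomeSpec(
    100, homopolymerTracts = data.frame(unitLength = 1L,
                                        tractLength = 200L, count = 1L))),
    "exceeds")
})

test_that("generated base composition tracks the requested GC", {
  ref <- generateReference(GenomeSpec(1e6, gcFraction = 0.38, seed = 3L))
  gc <- Biostrings::letterFrequency(ref$sequence, "GC", as.prob = TRUE)[[1L]]
  expect_gte(gc, 0.36)
  expect_lte(gc, 0.40)
})

test_that("plantIndels round-trips and respects zygosity structure", {
  ref <- generateReference(GenomeSpec(20000, seed = 2L))
  tr <- plantIndels(ref, nIndels = 40L, seed = 5L)
  df <- as.data.frame(truthIndels(tr))
  expect_equal(nrow(df), 40L)
  expect_true(all(df$length >= 1L & df$length <= 10L))
  # left-normalized truth: normalizing again is a no-op
  expect_equal(leftNormalize(df, refSequence(tr))$pos, df$pos)
  # hom on both haplotypes, het on exactly one
  expect_true(all((df$zygosity == "hom") == (df$hap == "AB")))
  # applying each haplotype's events reproduces that haplotype exactly
  haps <- haplotypes(tr)
  expect_identical(
    as.character(applyIndels(refSequence(tr),
                             df[df$hap %in% c("A", "AB"), ])),
    as.character(haps[["A"]]))
  expect_identical(
    as.character(applyIndels(refSequence(tr),
                             df[df$hap %in% c("B", "AB"), ])),
    as.character(haps[["B"]]))
})

test_that("plantIndels degenerate and error cases", {
  ref <- generateReference(GenomeSpec(5000, seed = 2L))
  tr0 <- plantIndels(ref, 0L, seed = 1L)
  expect_identical(as.character(haplotypes(tr0)[["A"]]),
                   as.character(refSequence(tr0)))
  expect_error(plantIndels(ref, 5000L, seed = 1L), "too small")
  # all-homozygous planting changes both haplotype lengths identically
  tr1 <- plantIndels(ref, 5L, homFraction = 1, seed = 9L)
  df <- as.data.frame(truthIndels(tr1))
  shift <- sum(ifelse(df$kind == "ins", df$length, -df$length))
  expect_equal(length(haplotypes(tr1)[["A"]]), 5000L + shift)
  expect_equal(length(haplotypes(tr1)[["B"]]), 5000L + shift)
})

test_that("homozygous fraction follows the binomial planting law", {
  ref <- generateReference(GenomeSpec(1e6, seed = 4L))
  tr <- plantIndels(ref, 2000L, homFraction = 1 / 3, seed = 6L)
  nHom <- sum(as.data.frame(truthIndels(tr))$zygosity == "hom")
  bounds <- qbinom(c(0.005, 0.995), 2000L, 1 / 3)
  expect_gte(nHom, bounds[1L])
  expect_lte(nHom, bounds[2L])
})

test_that("simulateReads obeys the coverage law and records provenance", {
  ref <- generateReference(GenomeSpec(1e6, seed = 8L))
  tr <- plantIndels(ref, 100L, seed = 8L)
  # 0.7x with 700 bp reads over 1 Mbp: Poisson mean 1000
  rs <- simulateReads(tr, PlatformSpec(700L, 0.7, seed = 10L))
  expect_gte(length(readSequences(rs)), 900L)
  expect_lte(length(readSequences(rs)), 1100L)
  # error-free reads are exact substrings of their source haplotype
  haps <- haplotypes(tr)
  for (i in head(seq_along(readSequences(rs)), 5L)) {
    h <- haps[[readHaplotype(rs)[i]]]
    expect_identical(
      as.character(readSequences(rs)[[i]]),
      as.character(Biostrings::subseq(h, readStart(rs)[i] + 1L,
                                      readStart(rs)[i] + 700L)))
  }
  # zero coverage -> empty set
  expect_equal(length(readSequences(
    simulateReads(tr, PlatformSpec(100L, 0, seed = 1L)))), 0L)
  # allele balance: reads split evenly between haplotypes
  nA <- sum(readHaplotype(rs) == "A")
  n <- length(readSequences(rs))
  expect_lt(abs(nA / n - 0.5), 3 * sqrt(0.25 / n))
})

test_that("the virtual caller hits its nominal sensitivity and FDR", {
  ref <- generateReference(GenomeSpec(3e6, seed = 31L))
  tr <- plantIndels(ref, 3000L, seed = 32L)
  sg <- simulateReads(tr, PlatformSpec(700L, 0.7, seed = 33L))
  hts <- PlatformSpec(100L, 47)
  # perfect detector: call set equals truth set
  cs1 <- simulateCallSets(tr, DetectorModel(1, fpPerMbp = 0), sg, hts,
                          seed = 34L)
  expect_equal(cs1$calls$pos, as.data.frame(truthIndels(tr))$pos)
  # blind detector: nothing but false positives at rate 0 -> empty
  cs0 <- simulateCallSets(tr, DetectorModel(0, fpPerMbp = 0), sg, hts,
                          seed = 34L)
  expect_equal(nrow(cs0$calls), 0L)
  # nominal sensitivity recovered within 3 binomial SEs
  cs <- simulateCallSets(tr, DetectorModel(0.6, fpPerMbp = 30), sg, hts,
                         seed = 35L)
  recall <- sum(!is.na(cs$calls$truthIndex)) / 3000
  expect_lt(abs(recall - 0.6), 3 * sqrt(0.6 * 0.4 / 3000))
  # false calls present at roughly the configured rate
  nFp <- sum(is.na(cs$calls$truthIndex))
  expect_gt(nFp, 50L)
  expect_lt(nFp, 140L)
})

test_that("long-read support tallies respect haplotype provenance", {
  ref <- generateReference(GenomeSpec(50000, seed = 41L))
  tr <- plantIndels(ref, 25L, seed = 42L)
  sg <- simulateReads(tr, PlatformSpec(700L, 20, seed = 43L))
  sup <- sangerSupport(as.data.frame(truthIndels(tr)), tr, sg)
  df <- as.data.frame(truthIndels(tr))
  hom <- df$zygosity == "hom"
  # hom loci: every covering read supports the alternate
  expect_true(all(sup$sangerRef[hom] == 0L))
  expect_true(all(sup$sangerAlt[hom] > 0L))   # 20x leaves no locus bare
  # het loci get support from both alleles at deep coverage
  expect_true(all(sup$sangerAlt[!hom] + sup$sangerRef[!hom] > 0L))
  expect_gt(sum(sup$sangerRef[!hom]), 0L)
})
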