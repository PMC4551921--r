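test_that("alt contigs follow the gluing construction", {
  ref <- Biostrings::DNAString(randomSeq(2000, seed = 1))
  refStr <- as.character(ref)
  del <- IndelSet("chrS", 1000L, "del", substr(refStr, 1001, 1002))
  ac <- buildAltContig(ref, del, readLength = 100L)
  expect_equal(length(contigSequence(ac)), 198L)       # 99 + 99
  expect_equal(flankLengths(ac), c(99L, 99L))
  expect_equal(as.character(contigSequence(ac)),
               paste0(substr(refStr, 902, 1000), substr(refStr, 1003, 1101)))
  ins <- IndelSet("chrS", 1000L, "ins", "G")
  expect_equal(length(contigSequence(buildAltContig(ref, ins, 100L))),
               199L)                                   # 99 + 1 + 99
  # truncation at the chromosome start
  del2 <- IndelSet("chrS", 3L, "del", substr(refStr, 4, 4))
  ac2 <- buildAltContig(ref, del2, 100L)
  expect_equal(flankLengths(ac2)[1L], 3L)
  expect_error(buildAltContig(ref, IndelSet("chrS", 2500L, "del", "A"),
                              100L), "outside")
})

test_that("ungappedHits finds exactly the brute-force placements", {
  g <- randomSeq(3000, seed = 2)
  subj <- Biostrings::DNAStringSet(c(chr1 = g))
  # unique substring: one hit, zero mismatches
  read <- substr(g, 501, 550)
  h <- ungappedHits(read, subj, maxMismatches = 0L)
  expect_equal(nrow(h), 1L)
  expect_equal(h$start, 501L)
  expect_equal(h$mismatches, 0L)
  # absent sequence: no hits at mm 0
  expect_equal(nrow(ungappedHits(strrep("A", 40), subj, 0L)), 0L)
  # two-copy dispersed repeat: both copies found
  g2 <- paste0(substr(g, 1, 1000), substr(g, 2001, 2100),
               substr(g, 1001, 2000), substr(g, 2001, 2100))
  read2 <- substr(g, 2011, 2060)
  h2 <- ungappedHits(read2, Biostrings::DNAStringSet(c(chr1 = g2)), 0L)
  expect_equal(nrow(h2), 2L)
  # oracle equivalence including mismatch counts and both strands
  for (i in 1:10) {
    r <- substr(g, 100 * i, 100 * i + 39)
    if (i %% 2 == 0) r <- revComp(r)
    if (i %% 3 == 0)                    # corrupt one base
      substr(r, 7, 7) <- setdiff(c("A", "C", "G", "T"),
                                 substr(r, 7, 7))[1L]
    got <- ungappedHits(r, subj, maxMismatches = 2L)
    want <- oracleHits(r, c(chr1 = g), maxMismatches = 2L)
    rownames(got) <- NULL
    expect_equal(got, want, info = paste("read", i))
  }
})

test_that("reads classify to the allele they uniquely support", {
  ref <- Biostrings::DNAString(randomSeq(3000, seed = 3))
  refStr <- as.character(ref)
  del <- IndelSet("chrS", 1500L, "del", substr(refStr, 1501, 1502),
                  zygosity = "het")
  ac <- buildAltContig(ref, del, 100L)
  hap <- applyIndels(ref, del)
  # junction-spanning donor reads support the alternate; starts chosen so
  # every read covers the junction (0-based 1500) with margin
  altReads <- Biostrings::DNAStringSet(lapply(1410 + 10 * (0:9),
    function(s) Biostrings::subseq(hap, s, s + 99)))
  # reference reads spanning the deleted bases support the reference
  refReads <- Biostrings::DNAStringSet(lapply(1410 + 10 * (0:9),
    function(s) Biostrings::subseq(ref, s, s + 99)))
  cov <- classifyReads(c(altReads, refReads), ref, ac, maxMismatches = 0L)
  expect_equal(nAlt(cov), 10L)
  expect_equal(nRef(cov), 10L)
  expect_equal(nAmbiguous(cov), 0L)
})

test_that("reads inside a tandem repeat copy are ambiguous", {
  set.seed(4)
  copy <- randomSeq(60, seed = 44)
  g <- paste0(randomSeq(500, seed = 45), copy, copy,
              randomSeq(500, seed = 46))
  ref <- Biostrings::DNAString(g)
  # deletion of the second copy (pos 560, 0-based), normalized
  del <- leftNormalize(
    IndelSet("chrS", 560L, "del", copy), ref)
  ac <- buildAltContig(ref, del, 100L)
  # a read lying entirely within one repeat copy matches the reference
  # twice and the contig once, all equally well -> ambiguous
  inside <- substr(g, 511, 540)
  # pad to a sensible read length using flanking repeat sequence
  inside <- substr(g, 503, 552)
  cov <- classifyReads(Biostrings::DNAStringSet(inside), ref, ac,
                       maxMismatches = 0L)
  expect_equal(nAmbiguous(cov), 1L)
  expect_equal(nAlt(cov) + nRef(cov), 0L)
})

test_that("allele swap symmetry: ref and alt counts exchange", {
  ref <- Biostrings::DNAString(randomSeq(2000, seed = 5))
  refStr <- as.character(ref)
  del <- IndelSet("chrS", 900L, "del", substr(refStr, 901, 903))
  donor <- applyIndels(ref, del)
  ac <- buildAltContig(ref, del, 100L)
  altReads <- Biostrings::DNAStringSet(lapply(c(850, 860, 870),
    function(s) Biostrings::subseq(donor, s, s + 99)))
  refReads <- Biostrings::DNAStringSet(lapply(c(850, 855),
    function(s) Biostrings::subseq(ref, s, s + 99)))
  fwd <- classifyReads(c(altReads, refReads), ref, ac, maxMismatches = 0L)
  # flip roles: treat the donor as the reference and the re-insertion as
  # the variant
  rev <- leftNormalize(IndelSet("chrS", 900L, "ins", indelSeq(del)), donor)
  acRev <- buildAltContig(donor, rev, 100L)
  bwd <- classifyReads(c(altReads, refReads), donor, acRev,
                       maxMismatches = 0L)
  expect_equal(nRef(bwd), nAlt(fwd))
  expect_equal(nAlt(bwd), nRef(fwd))
})

test_that("classifier matches the oracle on a small genome with repeats", {
  g <- paste0(randomSeq(800, seed = 6), substr(randomSeq(900, seed = 6), 31, 80),
              randomSeq(700, seed = 7))
  ref <- Biostrings::DNAString(g)
  del <- leftNormalize(IndelSet("chrS", 1200L, "del",
                                substr(g, 1201, 1202)), ref)
  ac <- buildAltContig(ref, del, 50L)
  donor <- applyIndels(ref, del)
  set.seed(8)
  reads <- c(
    vapply(sample(1130:1195, 8), function(s)
      as.character(Biostrings::subseq(donor, s, s + 49)), character(1)),
    vapply(sample(1130:1195, 8), function(s)
      as.character(Biostrings::subseq(ref, s, s + 49)), character(1)),
    vapply(sample(1:700, 4), function(s)       # off-locus reads
      as.character(Biostrings::subseq(ref, s, s + 49)), character(1)))
  got <- classifyReads(Biostrings::DNAStringSet(reads), ref, ac,
                       maxMismatches = 0L)
  js <- junctionSpan(ac)
  p <- indelPos(del)
  want <- oracleClassify(
    reads, g, as.character(contigSequence(ac)),
    BiocGenerics::start(js), BiocGenerics::end(js), "chrS",
    max(1L, p - 49L + 1L), p + indelSize(del) + 49L, maxMismatches = 0L)
  expect_equal(nRef(got), unname(want["ref"]))
  expect_equal(nAlt(got), unname(want["alt"]))
  expect_equal(nAmbiguous(got), unname(want["amb"]))
})
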