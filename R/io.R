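#' Read and write indel call sets as VCF
#'
#' Uses the standard anchor-base convention: an event at internal 0-based
#' position \code{pos} is written with 1-based \code{POS = pos} pointing
#' at the base immediately left of the event, with the anchor base
#' prepended to REF and ALT.  Genotypes are written as \code{1/1}
#' (homozygous), \code{0/1} (heterozygous) or \code{./.}.
#'
#' @param indels an \code{\linkS4class{IndelSet}} or indel \code{data.frame}.
#' @param reference the reference \code{DNAString} the calls sit on.
#' @param file output path.
#' @param sampleName sample column name.
#' @return \code{writeIndelVcf}: the path, invisibly;
#'   \code{readIndelVcf}: an \code{\linkS4class{IndelSet}}.
#' @export
writeIndelVcf <- function(indels, reference, file, sampleName = "sample") {
  df <- .indelFrame(indels)
  refc <- .seqToChars(reference)
  if (any(df$pos < 1L))
    stop("VCF output needs an anchor base: events at position 0 unsupported")
  anchor <- refc[df$pos]                       # base at 0-based pos-1
  refAllele <- ifelse(df$kind == "del", paste0(anchor, df$seq), anchor)
  altAllele <- ifelse(df$kind == "ins", paste0(anchor, df$seq), anchor)
  gt <- c(hom = "1/1", het = "0/1", unknown = "./.")[df$zygosity]
  vr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(df$pos, width = nchar(refAllele)))
  names(vr) <- sprintf("indel%05d", seq_len(nrow(df)))
  fixed <- S4Vectors::DataFrame(
    REF = Biostrings::DNAStringSet(refAllele),
    ALT = Biostrings::DNAStringSetList(as.list(altAllele)),
    QUAL = rep(NA_real_, nrow(df)),
    FILTER = rep("PASS", nrow(df)))
  hdr <- VariantAnnotation::VCFHeader(
    samples = sampleName,
    header = IRanges::DataFrameList(
      fileformat = S4Vectors::DataFrame(Value = "VCFv4.2",
                                        row.names = "fileformat"),
      FORMAT = S4Vectors::DataFrame(
        Number = "1", Type = "String", Description = "Genotype",
        row.names = "GT")))
  geno <- S4Vectors::SimpleList(
    GT = matrix(unname(gt), ncol = 1L,
                dimnames = list(names(vr), sampleName)))
  vcf <- VariantAnnotation::VCF(rowRanges = vr, fixed = fixed,
                                colData = S4Vectors::DataFrame(
                                  Samples = 1L, row.names = sampleName),
                                exptData = list(header = hdr),
                                geno = geno)
  VariantAnnotation::writeVcf(vcf, file)
  invisible(file)
}

#' @rdname writeIndelVcf
#' @export
readIndelVcf <- function(file) {
  vcf <- VariantAnnotation::readVcf(file)
  rr <- SummarizedExperiment::rowRanges(vcf)
  refA <- as.character(rr$REF)
  altA <- vapply(rr$ALT, function(a) as.character(a)[1L], character(1L))
  pos1 <- BiocGenerics::start(rr)
  isDel <- nchar(refA) > nchar(altA)
  kind <- ifelse(isDel, "del", "ins")
  seqs <- ifelse(isDel, substring(refA, 2L), substring(altA, 2L))
  zyg <- rep("unknown", base::length(rr))
  if ("GT" %in% names(VariantAnnotation::geno(vcf))) {
    gt <- VariantAnnotation::geno(vcf)$GT[, 1L]
    zyg[gt %in% c("1/1", "1|1")] <- "hom"
    zyg[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- "het"
  }
  IndelSet(chrom = as.character(GenomicRanges::seqnames(rr)),
           pos = pos1, kind = kind, seq = seqs, zygosity = zyg)
}

#' Write a reference (or haplotype) sequence as FASTA
#'
#' @param sequence a \code{DNAString} or \code{DNAStringSet}.
#' @param file output path.
#' @param name sequence name when a single \code{DNAString} is given.
#' @return the path, invisibly.
#' @export
writeReferenceFasta <- function(sequence, file, name = "chrS") {
  ss <- if (is(sequence, "DNAStringSet")) sequence
  else setNames(Biostrings::DNAStringSet(list(sequence)), name)
  Biostrings::writeXStringSet(ss, filepath = file)
  invisible(file)
}

#' @rdname writeReferenceFasta
#' @export
readReferenceFasta <- function(file) {
  Biostrings::readDNAStringSet(file)
}

#' Write simulated reads as FASTQ
#'
#' Base qualities are written as a constant high quality; quality realism
#' is deliberately out of scope.
#'
#' @param readSet a \code{\linkS4class{ReadSet}}.
#' @param file output path.
#' @return the path, invisibly.
#' @export
writeReadsFastq <- function(readSet, file) {
  reads <- readSet@reads
  quals <- Biostrings::BStringSet(strrep("I", BiocGenerics::width(reads)))
  Biostrings::writeXStringSet(reads, filepath = file, format = "fastq",
                              qualities = quals)
  invisible(file)
}

#' Write repeat tracts as BED
#'
#' BED intervals are 0-based half-open; the name field carries the repeat
#' unit and the score the unit count.
#'
#' @param tracts a \code{GRanges} from \code{\link{annotateRepeats}}.
#' @param file output path.
#' @return the path, invisibly.
#' @export
writeTractsBed <- function(tracts, file) {
  gr <- tracts
  gr$name <- gr$unit
  gr$score <- gr$nUnits
  rtracklayer::export(gr, file, format = "BED")
  invisible(file)
}

#' @rdname writeTractsBed
#' @export
readIntervalsBed <- function(file) {
  rtracklayer::import(file, format = "BED")
}

#' Write a complete simulation to disk
#'
#' Emits the reference FASTA, the truth VCF, per-platform FASTQ files and
#' the planted-feature BED into a directory, giving a fully file-based
#' view of a synthetic experiment.
#'
#' @param truth a \code{\linkS4class{SyntheticTruth}}.
#' @param dir output directory (created if needed).
#' @param reads optional named list of \code{\linkS4class{ReadSet}}s.
#' @param features optional \code{GRanges} of planted features.
#' @return the directory, invisibly.
#' @export
writeSimulation <- function(truth, dir, reads = list(), features = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeReferenceFasta(truth@reference, file.path(dir, "reference.fa"),
                      name = truth@chrom)
  writeReferenceFasta(haplotypes(truth), file.path(dir, "haplotypes.fa"))
  if (nrow(truth@indels))
    writeIndelVcf(truth@indels, truth@reference,
                  file.path(dir, "truth.vcf"))
  for (nm in names(reads))
    writeReadsFastq(reads[[nm]], file.path(dir, paste0(nm, ".fastq")))
  if (!is.null(features) && base::length(features))
    rtracklayer::export(features, file.path(dir, "features.bed"),
                        format = "BED")
  invisible(dir)
}
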