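# Independent brute-force oracles.  These deliberately avoid the package's
# implementation paths (no matchPattern, no vectorized run-length tricks):
# plain positional arithmetic on character vectors.

seqChars <- function(x) strsplit(as.character(x), "", fixed = TRUE)[[1L]]

randomSeq <- function(n, seed, gc = 0.5) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

revComp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(seqChars(s)), collapse = ""))
}

# every end-to-end ungapped placement of `read` in each named sequence,
# computed by sliding-window mismatch counting
oracleHits <- function(read, sequences, maxMismatches = 0L,
                       bothStrands = TRUE) {
  if (!is.list(sequences) && length(sequences) == 1L &&
      is.null(names(sequences)))
    sequences <- c(seq1 = as.character(sequences))
  out <- list()
  pats <- list(`+` = as.character(read))
  if (bothStrands) pats[["-"]] <- revComp(read)
  for (st in names(pats)) {
    r <- seqChars(pats[[st]])
    w <- length(r)
    for (nm in names(sequences)) {
      g <- seqChars(sequences[[nm]])
      nOff <- length(g) - w + 1L
      if (nOff < 1L) next
      mm <- integer(nOff)
      for (i in seq_len(w))
        mm <- mm + (g[seq.int(i, i + nOff - 1L)] != r[i])
      hit <- which(mm <= maxMismatches)
      if (length(hit))
        out[[length(out) + 1L]] <- data.frame(
          name = nm, start = hit, strand = st,
          mismatches = mm[hit], stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(name = character(), start = integer(),
                      strand = character(), mismatches = integer()))
  res <- do.call(rbind, out)
  res <- res[order(res$name, res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# greedy repeat-tract scan written as direct per-position loops
oracleAnnotate <- function(sequence) {
  s <- seqChars(sequence)
  n <- length(s)
  rows <- list()
  i <- 1L
  while (i <= n) {
    h <- 1L
    while (i + h <= n && s[i + h] == s[i]) h <- h + 1L
    d <- 0L
    if (i + 1L <= n && s[i] != s[i + 1L]) {
      d <- 1L
      while (i + 2L * d + 1L <= n && s[i + 2L * d] == s[i] &&
             s[i + 2L * d + 1L] == s[i + 1L]) d <- d + 1L
    }
    if (h >= d && h >= 2L) {
      rows[[length(rows) + 1L]] <- data.frame(
        start = i, width = h, unit = s[i], nUnits = h,
        stringsAsFactors = FALSE)
      i <- i + h
    } else if (d > h && d >= 2L) {
      rows[[length(rows) + 1L]] <- data.frame(
        start = i, width = 2L * d, unit = paste0(s[i], s[i + 1L]),
        nUnits = d, stringsAsFactors = FALSE)
      i <- i + 2L * d
    } else i <- i + 1L
  }
  if (!length(rows))
    return(data.frame(start = integer(), width = integer(),
                      unit = character(), nUnits = integer()))
  do.call(rbind, rows)
}

tractsToFrame <- function(gr) {
  data.frame(start = BiocGenerics::start(gr),
             width = BiocGenerics::width(gr),
             unit = gr$unit, nUnits = gr$nUnits,
             stringsAsFactors = FALSE)
}

# FIR by brute force: enumerate spanning windows of the mutated sequence
# by hand and test each against oracleHits on the reference
oracleFIR <- function(reference, pos0, kind, seqStr, readLength = 100L,
                      maxMismatches = 0L) {
  refc <- seqChars(reference)
  L <- nchar(seqStr)
  donor <- if (kind == "del") {
    c(refc[seq_len(pos0)], refc[seq.int(pos0 + L + 1L, length(refc))])
  } else {
    append(refc, seqChars(seqStr), after = pos0)
  }
  insLen <- if (kind == "ins") L else 0L
  lo <- max(0L, pos0 + insLen + 1L - readLength)
  hi <- min(pos0 - 1L, length(donor) - readLength)
  if (hi < lo) return(list(nSimulated = 0L, fir = NA_real_))
  inf <- 0L
  for (s0 in lo:hi) {
    read <- paste(donor[(s0 + 1L):(s0 + readLength)], collapse = "")
    h <- oracleHits(read, c(ref = as.character(reference)), maxMismatches)
    if (nrow(h) == 0L) inf <- inf + 1L
  }
  list(nSimulated = hi - lo + 1L, nInformative = inf,
       fir = inf / (hi - lo + 1L))
}

# classification by the published rule, driven entirely by oracleHits
oracleClassify <- function(reads, reference, contigSeq, junctionStart,
                           junctionEnd, chrom, refWindowStart,
                           refWindowEnd, maxMismatches = 0L) {
  subs <- c(setNames(as.character(reference), chrom),
            contig = as.character(contigSeq))
  counts <- c(ref = 0L, alt = 0L, amb = 0L, disc = 0L)
  for (r in reads) {
    h <- oracleHits(r, as.list(subs), maxMismatches)
    if (!nrow(h)) { counts["disc"] <- counts["disc"] + 1L; next }
    best <- h[h$mismatches == min(h$mismatches), , drop = FALSE]
    w <- nchar(r)
    onRef <- best$name == chrom
    onC <- best$name == "contig"
    if (any(onRef) && any(onC)) counts["amb"] <- counts["amb"] + 1L
    else if (any(onC)) {
      if (sum(onC) > 1L) counts["disc"] <- counts["disc"] + 1L
      else {
        st <- best$start[onC]
        if (st <= junctionEnd && st + w - 1L >= junctionStart)
          counts["alt"] <- counts["alt"] + 1L
        else counts["disc"] <- counts["disc"] + 1L
      }
    } else {
      if (sum(onRef) > 1L) counts["disc"] <- counts["disc"] + 1L
      else {
        st <- best$start[onRef]
        if (st <= refWindowEnd && st + w - 1L >= refWindowStart)
          counts["ref"] <- counts["ref"] + 1L
        else counts["disc"] <- counts["disc"] + 1L
      }
    }
  }
  counts
}

# deterministic helper: a deletion position whose neighbourhood is unique
# in the genome (20-mer around the locus occurs once, no local repeat run)
uniqueContextDeletion <- function(g, width = 1L) {
  chars <- seqChars(g)
  n <- length(chars)
  for (p in seq.int(200L, n - 200L)) {
    ctx <- substr(g, p - 9L, p + 10L)
    if (chars[p] != chars[p + 1L] && chars[p + 1L] != chars[p + 2L] &&
        length(gregexpr(ctx, g, fixed = TRUE)[[1L]]) == 1L)
      return(IndelSet("chrS", as.integer(p),
                      "del", substr(g, p + 1L, p + width)))
  }
  stop("no unique context found")
}

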