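#' Construct an IndelSet
#'
#' @param chrom,pos,kind,length,seq,zygosity vectors describing the calls;
#'   see \code{\linkS4class{IndelSet}} for the coordinate conventions.
#'   \code{length} defaults to \code{nchar(seq)}.
#' @param ... extra annotation columns of the same length (recycled if
#'   scalar), e.g. allele-specific read counts.
#'
#' @return an \code{\linkS4class{IndelSet}}.
#' @examples
#' IndelSet(chrom = "chrS", pos = 10L, kind = "del", seq = "AC")
#' @export
IndelSet <- function(chrom = character(), pos = integer(),
                     kind = character(), seq = character(),
                     length = nchar(seq), zygosity = "unknown", ...) {
  n <- base::length(pos)
  df <- data.frame(chrom = rep_len(as.character(chrom), n),
                   pos = as.integer(pos),
                   kind = rep_len(as.character(kind), n),
                   length = rep_len(as.integer(length), n),
                   seq = rep_len(toupper(as.character(seq)), n),
                   zygosity = rep_len(as.character(zygosity), n),
                   stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- rep_len(extra[[nm]], n)
  if (n == 0L) df <- .emptyIndelFrame()
  new("IndelSet", calls = df)
}

## Coerce IndelSet / data.frame input to the canonical calls data.frame.
.indelFrame <- function(x) {
  if (is(x, "IndelSet")) return(x@calls)
  if (is.data.frame(x)) {
    missing <- setdiff(INDEL_COLUMNS, names(x))
    if ("zygosity" %in% missing) {
      x$zygosity <- "unknown"
      missing <- setdiff(missing, "zygosity")
    }
    if (length(missing))
      stop("indel table lacks columns: ", paste(missing, collapse = ", "))
    return(x)
  }
  stop("expected an IndelSet or an indel data.frame")
}

#' @describeIn IndelSet number of calls
#' @param x an \code{IndelSet}
#' @export
setMethod("length", "IndelSet", function(x) nrow(x@calls))

#' @export
setMethod("show", "IndelSet", function(object) {
  df <- object@calls
  cat(sprintf("IndelSet with %d call(s)\n", nrow(df)))
  if (nrow(df)) {
    cat(sprintf("  kinds: %d del, %d ins; lengths %d-%d bp\n",
                sum(df$kind == "del"), sum(df$kind == "ins"),
                min(df$length), max(df$length)))
    print(utils::head(df, 5L))
    if (nrow(df) > 5L) cat(sprintf("  ... and %d more\n", nrow(df) - 5L))
  }
  invisible(NULL)
})

#' @export
setMethod("as.data.frame", "IndelSet",
          function(x, row.names = NULL, optional = FALSE, ...) x@calls)

#' @export
setMethod("[", "IndelSet", function(x, i, j, ..., drop = TRUE) {
  new("IndelSet", calls = x@calls[i, , drop = FALSE])
})

#' Accessors for indel call fields
#'
#' @param x an \code{\linkS4class{IndelSet}} or indel \code{data.frame}.
#' @return the corresponding column vector.
#' @name indel-accessors
NULL

#' @rdname indel-accessors
#' @export
indelPos <- function(x) .indelFrame(x)$pos

#' @rdname indel-accessors
#' @export
indelKind <- function(x) .indelFrame(x)$kind

#' @rdname indel-accessors
#' @export
indelSize <- function(x) .indelFrame(x)$length

#' @rdname indel-accessors
#' @export
indelSeq <- function(x) .indelFrame(x)$seq

#' @rdname indel-accessors
#' @export
indelZygosity <- function(x) .indelFrame(x)$zygosity

#' Left-normalize indel calls
#'
#' Shifts each indel to its leftmost equivalent position: while the
#' reference base immediately left of the event equals the last base of the
#' event's sequence, the event slides one base left (the classic VCF
#' normalization loop).  Within a repeat tract all equivalent placements of
#' the same event therefore normalize to one canonical call, making set
#' comparison well-defined.
#'
#' @param indels an \code{\linkS4class{IndelSet}} or indel \code{data.frame}.
#' @param reference the reference \code{DNAString} (or character string)
#'   the calls are placed on.
#' @return an object of the same class with normalized \code{pos}/\code{seq}.
#' @examples
#' ref <- Biostrings::DNAString("GGAAAATT")
#' x <- IndelSet("chrS", pos = 5L, kind = "del", seq = "A")
#' indelPos(leftNormalize(x, ref))  # slides to the start of the A run
#' @export
leftNormalize <- function(indels, reference) {
  df <- .indelFrame(indels)
  if (!nrow(df)) return(indels)
  out <- .leftNormalizeChars(df, .seqToChars(reference))
  if (is(indels, "IndelSet")) new("IndelSet", calls = out) else out
}

.leftNormalizeChars <- function(df, refc) {
  for (i in seq_len(nrow(df))) {
    p <- df$pos[i]
    s <- .seqToChars(df$seq[i])
    L <- length(s)
    while (p > 0L && refc[p] == s[L]) {   # refc[p] is base at 0-based p-1
      s <- c(refc[p], s[-L])
      p <- p - 1L
    }
    df$pos[i] <- p
    df$seq[i] <- paste(s, collapse = "")
  }
  df
}

#' Apply indels to a reference sequence
#'
#' Splices a set of non-overlapping indels into \code{reference}: deletions
#' remove their bases, insertions add theirs immediately before the
#' reference base at \code{pos}.  This is the inverse of calling: applying
#' a truth table to the reference reproduces the donor haplotype exactly.
#'
#' @param reference a \code{DNAString} or character string.
#' @param indels an \code{\linkS4class{IndelSet}} or indel \code{data.frame}
#'   (0-based \code{pos}).
#' @return a \code{DNAString}.
#' @examples
#' applyIndels(Biostrings::DNAString("ACGTACGT"),
#'             IndelSet("chrS", 2L, "del", "GT"))
#' @export
applyIndels <- function(reference, indels) {
  ref <- .asDNAString(reference)
  df <- .indelFrame(indels)
  if (!nrow(df)) return(ref)
  df <- df[order(df$pos), , drop = FALSE]
  delspan <- ifelse(df$kind == "del", df$length, 0L)
  if (any(df$pos + delspan > base::length(ref)))
    stop("indel outside the reference sequence")
  if (nrow(df) > 1L) {
    endprev <- df$pos[-nrow(df)] + delspan[-nrow(df)]
    if (any(df$pos[-1L] < endprev)) stop("overlapping indels")
  }
  at <- IRanges::IRanges(
    start = df$pos + 1L,
    end = ifelse(df$kind == "del", df$pos + df$length, df$pos))
  value <- ifelse(df$kind == "del", "", df$seq)
  Biostrings::replaceAt(ref, at = at, value = value)
}
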