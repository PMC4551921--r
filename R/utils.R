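#' @importFrom methods new validObject is slot setValidity show as
#' @importFrom stats rpois rbinom runif dbinom setNames
#' @importFrom utils head tail
NULL

DNA_BASES4 <- c("A", "C", "G", "T")

## Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state
## afterwards so seeded simulations never perturb the global stream.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_seed) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  force(expr)
}

## round-half-up at integer precision (base round() is round-half-even)
roundHalfUp <- function(x) floor(x + 0.5)

.assertScalarNum <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper)
    stop(sprintf("'%s' must be a single number in [%s, %s]", name, lower, upper),
         call. = FALSE)
  invisible(x)
}

.asDNAString <- function(x) {
  if (is(x, "DNAString")) x else Biostrings::DNAString(as.character(x))
}

.seqToChars <- function(x) {
  strsplit(as.character(x), "", fixed = TRUE)[[1L]]
}

## columns every indel table carries, in canonical order
INDEL_COLUMNS <- c("chrom", "pos", "kind", "length", "seq", "zygosity")

.emptyIndelFrame <- function() {
  data.frame(chrom = character(), pos = integer(), kind = character(),
             length = integer(), seq = character(), zygosity = character(),
             stringsAsFactors = FALSE)
}
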