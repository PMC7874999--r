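# Internal helpers shared across modules.

#' @importFrom data.table data.table setorder :=
NULL

.datatable.aware <- TRUE

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a fixed RNG seed, restoring the caller's state
#' @noRd
.withSeed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(expr)
}

# Deterministic derived seeds so independent strains/features never share a
# stream. Kept below 2^31 - 1.
.deriveSeed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (v in utf8ToInt(key)) h <- (h * 131 + v) %% 2147483629
  as.integer(h + 1)
}

.randomBases <- function(n, gc = 0.38) {
  at <- (1 - gc) / 2
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c(at, gc / 2, gc / 2, at))
}

.randomSeq <- function(n, gc = 0.38) paste(.randomBases(n, gc), collapse = "")

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

.assertThat <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)

.isCount <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 1 && x == round(x)

.isFraction <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 0 && x <= 1

# Scoring matrix over A,C,G,T,N in which N never matches anything (including
# N itself); used by every local alignment in the package.
.dnaScoreMatrix <- function(match = 1, mismatch = -1, nScore = -6) {
  letters5 <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(letters5, letters5))
  diag(m) <- match
  m["N", ] <- nScore
  m[, "N"] <- nScore
  m
}

#' Empty seed / block / SV data.frames with canonical column types
#' @noRd
.emptySeeds <- function() {
  data.frame(ref_start = integer(), qry_start = integer(),
             length = integer(), strand = character(),
             stringsAsFactors = FALSE)
}

.emptyBlocks <- function() {
  data.frame(ref_chrom = character(), ref_start = integer(), ref_end = integer(),
             ref_len = integer(),
             qry_chrom = character(), qry_start = integer(), qry_end = integer(),
             qry_len = integer(),
             stringsAsFactors = FALSE) -> d
  d$strand <- character()
  d$identity <- numeric()
  d$n_seeds <- integer()
  d$seeds <- list()
  d
}

.emptySVs <- function() {
  data.frame(type = character(),
             ref_chrom = character(), ref_start = integer(), ref_end = integer(),
             qry_chrom = character(), qry_start = integer(), qry_end = integer(),
             size = integer(), tandem = logical(),
             stringsAsFactors = FALSE)
}
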