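# Maximal-exact-match seeding. A MEM is an exact substring match between the
# reference and query that cannot be extended in either direction; `N` never
# matches anything. MEMs of length >= minLen are enumerated as maximal runs
# of shared minLen-mers along each alignment diagonal: a run of consecutive
# shared k-mer start positions on one diagonal covers exactly one maximal
# match, and its flanking positions are guaranteed mismatches (or N, or the
# sequence end), so the run is a MEM. The k-mer join uses data.table.

#' Find all maximal exact matches between two sequences
#'
#' Enumerates every maximal exact match of length at least `minLen` between
#' `ref` and `qry`, on both strands. `N` bases never match (including
#' N-vs-N). Coordinates are 0-based; query coordinates of `-`-strand seeds
#' are reported on the forward strand of the query. Output is deterministic,
#' sorted by (ref_start, qry_start, strand).
#'
#' @param ref,qry character (or DNAString) sequences over `{A,C,G,T,N}`.
#' @param minLen minimum match length (>= 8).
#' @return data.frame with columns `ref_start`, `qry_start`, `length`,
#'   `strand`. Empty input sequences yield an empty result.
#' @examples
#' findMEMs("ACGTACGTACGTACGT", "ACGTACGTACGTACGT", minLen = 16)
#' @export
findMEMs <- function(ref, qry, minLen = 20L) {
  .assertThat(.isCount(minLen) && minLen >= 8, "minLen must be a count >= 8")
  ref <- as.character(ref); qry <- as.character(qry)
  fwd <- .memsOneStrand(ref, qry, as.integer(minLen))
  if (nrow(fwd)) fwd$strand <- "+"
  nq <- nchar(qry)
  rev <- .memsOneStrand(ref, .revcomp(qry), as.integer(minLen))
  if (nrow(rev)) {
    rev$qry_start <- nq - (rev$qry_start + rev$length)
    rev$strand <- "-"
  }
  out <- rbind(if (nrow(fwd)) fwd else NULL, if (nrow(rev)) rev else NULL)
  if (is.null(out) || !nrow(out)) return(.emptySeeds())
  out <- out[order(out$ref_start, out$qry_start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.validKmerStarts <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(integer())
  starts <- seq_len(n - k + 1L)
  npos <- gregexpr("N", s, fixed = TRUE)[[1]]
  if (npos[1] == -1L) return(starts)
  bad <- unique(unlist(lapply(npos, function(p) max(1L, p - k + 1L):min(p, n - k + 1L))))
  setdiff(starts, bad)
}

.memsOneStrand <- function(r, q, k) {
  empty <- data.frame(ref_start = integer(), qry_start = integer(),
                      length = integer(), stringsAsFactors = FALSE)
  ri <- .validKmerStarts(r, k)
  qi <- .validKmerStarts(q, k)
  if (!length(ri) || !length(qi)) return(empty)
  dtr <- data.table::data.table(kmer = substring(r, ri, ri + k - 1L), i = ri)
  dtq <- data.table::data.table(kmer = substring(q, qi, qi + k - 1L), j = qi)
  m <- dtr[dtq, on = "kmer", allow.cartesian = TRUE, nomatch = NULL]
  if (!nrow(m)) return(empty)
  m[, `:=`(d = i - j)]
  data.table::setorder(m, d, i)
  newrun <- c(TRUE, diff(m$i) != 1L | diff(m$d) != 0L)
  run <- cumsum(newrun)
  i0 <- m$i[newrun]
  j0 <- m$j[newrun]
  lens <- tabulate(run) + k - 1L
  data.frame(ref_start = i0 - 1L, qry_start = j0 - 1L, length = lens,
             stringsAsFactors = FALSE)
}
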