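# Collinear chaining of match seeds into alignment blocks.
#
# Seeds are partitioned by (ref_chrom, qry_chrom, strand), then greedily
# peeled into maximal-weight collinear chains: a weighted DP (weight = seed
# length) links seed u -> v when v advances on both sequences (strand-aware
# on the query) and neither inter-seed gap exceeds maxGap (small overlaps up
# to `overlapTol` bp are allowed: breakpoint micro-homology makes flanking
# seeds overrun real junctions by a few bases). The best chain is extracted,
# its seeds removed, and the DP repeated until every seed is assigned.
# Chains whose span falls below minBlock are dropped.

#' Chain match seeds into collinear alignment blocks
#'
#' @param seeds data.frame of seeds as returned by [findMEMs()], optionally
#'   carrying `ref_chrom` / `qry_chrom` columns (mixed contexts are
#'   partitioned internally).
#' @param maxGap maximum inter-seed gap (bp) on either sequence within a
#'   chain.
#' @param minBlock chains spanning fewer bp than this (on both sequences)
#'   are dropped.
#' @param overlapTol tolerated inter-seed overlap (bp).
#' @param refLen,qryLen optional sequence lengths, propagated into blocks
#'   for PAF output.
#' @return data.frame of alignment blocks: `ref_chrom`, `ref_start`,
#'   `ref_end`, `ref_len`, `qry_chrom`, `qry_start`, `qry_end`, `qry_len`,
#'   `strand`, `identity` (seed-covered columns / block columns x 100),
#'   `n_seeds`, and a `seeds` list-column holding each block's member seeds.
#'   Query coordinates are always on the forward strand.
#' @export
chainSeeds <- function(seeds, maxGap = 100L, minBlock = 1000L, overlapTol = 25L,
                       refLen = NA_integer_, qryLen = NA_integer_) {
  if (is.null(seeds) || !nrow(seeds)) return(.emptyBlocks())
  if (is.null(seeds$ref_chrom)) seeds$ref_chrom <- "ref"
  if (is.null(seeds$qry_chrom)) seeds$qry_chrom <- "qry"
  if (is.null(seeds$ref_len)) seeds$ref_len <- as.integer(refLen)
  if (is.null(seeds$qry_len)) seeds$qry_len <- as.integer(qryLen)
  parts <- split(seeds, list(seeds$ref_chrom, seeds$qry_chrom, seeds$strand),
                 drop = TRUE)
  blocks <- lapply(parts, .chainPartition, maxGap = maxGap,
                   minBlock = minBlock, overlapTol = overlapTol)
  blocks <- blocks[vapply(blocks, nrow, 1L) > 0L]
  if (!length(blocks)) return(.emptyBlocks())
  out <- do.call(rbind, blocks)
  out <- out[order(out$ref_chrom, out$ref_start, out$qry_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.chainPartition <- function(s, maxGap, minBlock, overlapTol) {
  s <- s[order(s$ref_start, s$qry_start), , drop = FALSE]
  n <- nrow(s)
  minus <- s$strand[1] == "-"
  rs <- s$ref_start; re <- s$ref_start + s$length
  qs <- s$qry_start; qe <- s$qry_start + s$length
  assigned <- rep(FALSE, n)
  chains <- list()
  while (!all(assigned)) {
    idx <- which(!assigned)
    m <- length(idx)
    score <- s$length[idx]
    back <- rep(0L, m)
    if (m > 1L) {
      for (v in 2L:m) {
        iv <- idx[v]
        ju <- idx[seq_len(v - 1L)]
        rgap <- rs[iv] - re[ju]
        qgap <- if (minus) qs[ju] - qe[iv] else qs[iv] - qe[ju]
        feas <- rs[iv] > rs[ju] & rgap <= maxGap & rgap >= -overlapTol &
          qgap <= maxGap & qgap >= -overlapTol &
          (if (minus) qe[iv] < qe[ju] else qs[iv] > qs[ju])
        if (any(feas)) {
          cand <- score[seq_len(v - 1L)]
          cand[!feas] <- -Inf
          b <- which.max(cand)
          if (is.finite(cand[b])) {
            score[v] <- score[v] + cand[b]
            back[v] <- b
          }
        }
      }
    }
    end <- which.max(score)
    chain <- integer()
    v <- end
    while (v != 0L) { chain <- c(v, chain); v <- back[v] }
    assigned[idx[chain]] <- TRUE
    chains[[length(chains) + 1L]] <- s[idx[chain], , drop = FALSE]
  }
  rows <- lapply(chains, function(cs) {
    refSpan <- max(cs$ref_start + cs$length) - min(cs$ref_start)
    qrySpan <- max(cs$qry_start + cs$length) - min(cs$qry_start)
    if (max(refSpan, qrySpan) < minBlock) return(NULL)
    cov <- .unionLength(cs$ref_start, cs$ref_start + cs$length)
    d <- data.frame(ref_chrom = cs$ref_chrom[1],
                    ref_start = min(cs$ref_start),
                    ref_end = max(cs$ref_start + cs$length),
                    ref_len = cs$ref_len[1],
                    qry_chrom = cs$qry_chrom[1],
                    qry_start = min(cs$qry_start),
                    qry_end = max(cs$qry_start + cs$length),
                    qry_len = cs$qry_len[1],
                    strand = cs$strand[1],
                    identity = 100 * cov / max(refSpan, qrySpan),
                    n_seeds = nrow(cs),
                    stringsAsFactors = FALSE)
    d$seeds <- list(cs[, c("ref_start", "qry_start", "length", "strand")])
    d
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) return(.emptyBlocks())
  do.call(rbind, rows)
}

.unionLength <- function(starts, ends) {
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  tot <- 0L; curS <- starts[1]; curE <- ends[1]
  for (i in seq_along(starts)[-1]) {
    if (starts[i] > curE) { tot <- tot + (curE - curS); curS <- starts[i]; curE <- ends[i] }
    else curE <- max(curE, ends[i])
  }
  tot + (curE - curS)
}

#' Align two genomes into collinear blocks
#'
#' Runs [findMEMs()] and [chainSeeds()] for every chromosome pair and
#' returns the blocks in reference coordinate order. Repeats may yield
#' overlapping blocks; they are passed through and resolved by the SV
#' classifier.
#'
#' @param ref,qry [Genome-class] objects.
#' @param minSeed minimum exact-match seed length.
#' @param maxGap,minBlock,overlapTol chaining parameters (see
#'   [chainSeeds()]).
#' @return data.frame of alignment blocks (see [chainSeeds()]).
#' @export
alignGenomes <- function(ref, qry, minSeed = 20L, maxGap = 100L,
                         minBlock = 1000L, overlapTol = 25L) {
  .assertThat(length(chromNames(ref)) > 0 && length(chromNames(qry)) > 0,
              "both genomes must contain at least one chromosome")
  rlen <- chromLengths(ref); qlen <- chromLengths(qry)
  all <- list()
  for (rc in chromNames(ref)) {
    rseq <- getChrom(ref, rc)
    for (qc in chromNames(qry)) {
      seeds <- findMEMs(rseq, getChrom(qry, qc), minLen = minSeed)
      if (!nrow(seeds)) next
      seeds$ref_chrom <- rc; seeds$qry_chrom <- qc
      seeds$ref_len <- rlen[[rc]]; seeds$qry_len <- qlen[[qc]]
      all[[paste(rc, qc)]] <- seeds
    }
  }
  if (!length(all)) return(.emptyBlocks())
  chainSeeds(do.call(rbind, all), maxGap = maxGap, minBlock = minBlock,
             overlapTol = overlapTol)
}
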