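# Structural-variant classification from alignment blocks. Five event
# types: DEL, INS, DUP, INV, TRA, called at >= minSize (default 50 bp).
#
# Classification operates at two resolutions:
#  * between consecutive blocks (events large enough to split chains):
#    gap rule (a) for DEL/INS, interval-reuse rule (b) for DUP, strand rule
#    (c) for INV, query-chromosome rule (d) for TRA;
#  * within blocks, from seed-to-seed gaps: chaining bridges events smaller
#    than maxGap, so indels in [minSize, maxGap) are recovered from the net
#    gap difference (ref_gap - qry_gap), which is exact even when
#    breakpoint micro-homology lets flanking seeds overrun the junction
#    (the overrun inflates both gaps equally).
#
# The duplication rule is applied symmetrically: a duplication carried by
# the query genome shows up as reference-interval reuse (two query copies
# aligning onto one reference copy), a duplication carried by the reference
# as query-interval reuse; both are classified DUP.

#' Classify structural variants from alignment blocks
#'
#' @param blocks data.frame of alignment blocks for one reference/query
#'   genome pair (see [alignGenomes()]).
#' @param minSize minimum event size in bp (applied to the event's larger
#'   side: ref span for DEL/INV, qry span for INS/DUP, moved-segment length
#'   for TRA).
#' @return data.frame of calls: `type`, `ref_chrom`, `ref_start`, `ref_end`,
#'   `qry_chrom`, `qry_start`, `qry_end`, `size`, `tandem` (DUP only, NA
#'   otherwise). Coordinates 0-based half-open; query coordinates of
#'   `-`-strand events on the forward strand. Each event is reported once,
#'   leftmost representation; duplicates with identical (type, ref interval)
#'   are merged.
#' @export
callSVs <- function(blocks, minSize = 50L) {
  .assertThat(.isCount(minSize), "minSize must be a positive count")
  if (is.null(blocks) || !nrow(blocks)) return(.emptySVs())
  need <- c("ref_chrom", "ref_start", "ref_end", "qry_chrom", "qry_start",
            "qry_end", "strand")
  .assertThat(all(need %in% names(blocks)), "blocks missing required columns")
  events <- list()
  add <- function(type, rc, rs, re, qc, qs, qe, size, tandem = NA) {
    events[[length(events) + 1L]] <<- data.frame(
      type = type, ref_chrom = rc, ref_start = as.integer(rs),
      ref_end = as.integer(re), qry_chrom = qc, qry_start = as.integer(qs),
      qry_end = as.integer(qe), size = as.integer(size), tandem = tandem,
      stringsAsFactors = FALSE)
  }
  for (rc in unique(blocks$ref_chrom)) {
    B <- blocks[blocks$ref_chrom == rc, , drop = FALSE]
    B <- B[order(B$ref_start, B$qry_start), , drop = FALSE]
    span <- B$ref_end - B$ref_start
    # (d) translocation: blocks joining this reference chromosome to a query
    # chromosome other than its dominant context. Context is the query
    # chromosome backing the most blocks (span breaks ties): a large
    # translocated terminal segment arrives as a single block, while the
    # retained context is interrupted by other variation into several.
    nblk <- table(B$qry_chrom)
    tspan <- tapply(span, B$qry_chrom, sum)
    cand <- names(nblk)[nblk == max(nblk)]
    domQry <- cand[which.max(tspan[cand])]
    off <- B$qry_chrom != domQry
    if (any(off)) {
      r <- rle(off)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      for (k in which(r$values)) {
        idx <- starts[k]:ends[k]
        size <- sum(span[idx])
        if (size >= minSize)
          add("TRA", rc, min(B$ref_start[idx]), max(B$ref_end[idx]),
              B$qry_chrom[idx[1]], min(B$qry_start[idx]), max(B$qry_end[idx]),
              size)
      }
    }
    Bc <- B[!off, , drop = FALSE]
    if (!nrow(Bc)) next
    spanC <- Bc$ref_end - Bc$ref_start
    # (c) inversion: minority-strand runs within the collinear context
    domStrand <- names(which.max(tapply(spanC, Bc$strand, sum)))
    inv <- Bc$strand != domStrand
    if (any(inv)) {
      r <- rle(inv)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      for (k in which(r$values)) {
        idx <- starts[k]:ends[k]
        size <- sum(spanC[idx])
        if (size >= minSize)
          add("INV", rc, min(Bc$ref_start[idx]), max(Bc$ref_end[idx]),
              Bc$qry_chrom[idx[1]], min(Bc$qry_start[idx]), max(Bc$qry_end[idx]),
              size)
      }
    }
    # (a)/(b) gap and interval-reuse analysis between consecutive
    # dominant-strand blocks
    keep <- which(!inv)
    if (length(keep) >= 2L) {
      for (t in seq_len(length(keep) - 1L)) {
        if (keep[t + 1L] != keep[t] + 1L) next  # an inversion sits between
        b1 <- Bc[keep[t], ]; b2 <- Bc[keep[t + 1L], ]
        g <- .pairGaps(b1, b2, domStrand)
        ev <- .classifyGap(g$rgap, g$qgap, minSize)
        for (e in ev) {
          if (e$type == "DEL")
            add("DEL", rc, b1$ref_end, b1$ref_end + e$size, b1$qry_chrom,
                g$q1, g$q1, e$size)
          else if (e$type == "INS")
            add("INS", rc, b1$ref_end, b1$ref_end, b1$qry_chrom,
                g$q0, g$q1, e$size)
          else if (e$type == "DUP") {
            if (e$side == "ref_reuse")
              # one reference copy, two query copies: report the reused
              # reference interval and the query span of both copies
              add("DUP", rc, b2$ref_start, b1$ref_end, b1$qry_chrom,
                  min(b1$qry_end, b2$qry_start) - e$size,
                  max(b1$qry_end, b2$qry_start) + e$size,
                  e$size, tandem = e$tandem)
            else
              add("DUP", rc, b1$ref_end - e$size, b2$ref_start + e$size,
                  b1$qry_chrom, b2$qry_start, b1$qry_end,
                  e$size, tandem = e$tandem)
          }
        }
      }
    }
    # within-block seed-level indels
    for (t in seq_len(nrow(Bc))) {
      sd <- Bc$seeds[[t]]
      if (is.null(sd) || nrow(sd) < 2L) next
      sd <- sd[order(sd$ref_start, sd$qry_start), , drop = FALSE]
      minus <- Bc$strand[t] == "-"
      for (u in seq_len(nrow(sd) - 1L)) {
        s1 <- sd[u, ]; s2 <- sd[u + 1L, ]
        rgap <- s2$ref_start - (s1$ref_start + s1$length)
        qgap <- if (minus) s1$qry_start - (s2$qry_start + s2$length)
                else s2$qry_start - (s1$qry_start + s1$length)
        net <- rgap - qgap
        if (net >= minSize && (qgap - min(rgap, 0)) < minSize) {
          add("DEL", rc, s1$ref_start + s1$length,
              s1$ref_start + s1$length + net, Bc$qry_chrom[t],
              if (minus) s2$qry_start + s2$length else s1$qry_start + s1$length,
              if (minus) s2$qry_start + s2$length else s1$qry_start + s1$length,
              net)
        } else if (-net >= minSize && (rgap - min(qgap, 0)) < minSize) {
          qa <- if (minus) s2$qry_start + s2$length else s1$qry_start + s1$length
          qb <- if (minus) s1$qry_start else s2$qry_start
          add("INS", rc, s1$ref_start + s1$length, s1$ref_start + s1$length,
              Bc$qry_chrom[t], min(qa, qb), max(qa, qb), -net)
        }
      }
    }
  }
  if (!length(events)) return(.emptySVs())
  out <- do.call(rbind, events)
  # duplicate suppression: identical (type, ref interval) merged, leftmost wins
  key <- paste(out$type, out$ref_chrom, out$ref_start, out$ref_end)
  out <- out[!duplicated(key), , drop = FALSE]
  out <- out[order(out$ref_chrom, out$ref_start, out$type), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Gaps between two consecutive blocks in the dominant orientation; also
# returns the query coordinates framing the junction (q0 < q1).
.pairGaps <- function(b1, b2, domStrand) {
  rgap <- b2$ref_start - b1$ref_end
  if (domStrand == "+") {
    qgap <- b2$qry_start - b1$qry_end
    list(rgap = rgap, qgap = qgap, q0 = b1$qry_end, q1 = b2$qry_start)
  } else {
    qgap <- b1$qry_start - b2$qry_end
    list(rgap = rgap, qgap = qgap, q0 = b2$qry_end, q1 = b1$qry_start)
  }
}

.classifyGap <- function(rgap, qgap, minSize) {
  ev <- list()
  if (rgap <= -minSize && qgap > -minSize) {
    # reference-interval reuse: duplication carried by the query
    ev[[1]] <- list(type = "DUP", size = -rgap, tandem = abs(qgap) < minSize,
                    side = "ref_reuse")
  } else if (qgap <= -minSize && rgap > -minSize) {
    # query-interval reuse: duplication carried by the reference
    ev[[1]] <- list(type = "DUP", size = -qgap, tandem = abs(rgap) < minSize,
                    side = "qry_reuse")
  } else if (rgap > -minSize && qgap > -minSize) {
    rg <- rgap - min(qgap, 0)
    qg <- qgap - min(rgap, 0)
    # single-sided gaps: the net difference is exact under seed erosion at
    # the junction (erosion inflates both gaps equally)
    if (rg >= minSize && qg < minSize) ev[[length(ev) + 1L]] <- list(type = "DEL", size = rgap - qgap)
    else if (qg >= minSize && rg < minSize) ev[[length(ev) + 1L]] <- list(type = "INS", size = qgap - rgap)
    else if (rg >= minSize && qg >= minSize) {
      ev[[length(ev) + 1L]] <- list(type = "DEL", size = rg)
      ev[[length(ev) + 1L]] <- list(type = "INS", size = qg)
    }
  }
  ev
}

#' Enumerate the exhaustive ordered pairwise comparison design
#'
#' All ordered (reference, query) pairs over a strain panel, self pairs
#' excluded: n strains give n*(n-1) comparisons (15 strains: 210).
#'
#' @param strains character vector of strain names.
#' @return data.frame with columns `ref`, `qry`.
#' @export
svComparisonDesign <- function(strains) {
  .assertThat(!anyDuplicated(strains), "duplicate strain names")
  .assertThat(length(strains) >= 2L, "need at least two strains")
  g <- expand.grid(qry = strains, ref = strains, stringsAsFactors = FALSE)
  g <- g[g$ref != g$qry, c("ref", "qry")]
  rownames(g) <- NULL
  g
}

#' All-vs-all pairwise SV matrix
#'
#' For every ordered (reference, query) pair of the panel, aligns the
#' genomes and classifies SVs, tabulating per-type counts and totals.
#'
#' @param genomes list of [Genome-class] objects with unique strain names.
#' @param minSize minimum SV size (bp).
#' @param ... alignment parameters passed to [alignGenomes()].
#' @return An [SVMatrix-class].
#' @export
pairwiseSVMatrix <- function(genomes, minSize = 50L, ...) {
  strains <- vapply(genomes, strainName, character(1))
  .assertThat(!anyDuplicated(strains), "duplicate strain names")
  .assertThat(length(genomes) >= 2L, "need at least two genomes")
  names(genomes) <- strains
  design <- svComparisonDesign(strains)
  types <- c("DEL", "INS", "DUP", "INV", "TRA")
  cnt <- matrix(0L, nrow(design), length(types), dimnames = list(NULL, types))
  for (i in seq_len(nrow(design))) {
    blocks <- alignGenomes(genomes[[design$ref[i]]], genomes[[design$qry[i]]], ...)
    calls <- callSVs(blocks, minSize = minSize)
    if (nrow(calls)) {
      tb <- table(factor(calls$type, types))
      cnt[i, ] <- as.integer(tb)
    }
  }
  counts <- cbind(design, as.data.frame(cnt))
  counts$total <- as.integer(rowSums(cnt))
  new("SVMatrix", strains = strains, counts = counts)
}

#' Per-strain SV summary (strain-as-reference)
#'
#' For each strain serving as reference: mean, min and max of the total SV
#' counts across its comparisons, plus per-type means.
#'
#' @param matrix an [SVMatrix-class].
#' @param strainOrder optional output row order.
#' @return data.frame: `strain`, `n_comparisons`, `mean_total`, `min_total`,
#'   `max_total`, `mean_DEL` ... `mean_TRA`.
#' @export
summarizeSV <- function(matrix, strainOrder = NULL) {
  cnt <- svCounts(matrix)
  .assertThat(nrow(cnt) > 0, "empty SV matrix")
  strains <- strainOrder %||% svStrains(matrix)
  .assertThat(all(strains %in% svStrains(matrix)), "unknown strain in strainOrder")
  rows <- lapply(strains, function(s) {
    x <- cnt[cnt$ref == s, , drop = FALSE]
    data.frame(strain = s, n_comparisons = nrow(x),
               mean_total = mean(x$total), min_total = min(x$total),
               max_total = max(x$total),
               mean_DEL = mean(x$DEL), mean_INS = mean(x$INS),
               mean_DUP = mean(x$DUP), mean_INV = mean(x$INV),
               mean_TRA = mean(x$TRA), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write SV calls as BEDPE (plus flat TSV)
#'
#' BEDPE columns: ref_chrom, ref_start, ref_end, qry_chrom, qry_start,
#' qry_end, name (= type), score (= size), strand1, strand2. 0-based
#' half-open.
#'
#' @param calls data.frame from [callSVs()].
#' @param bedpePath,tsvPath output paths (either may be NULL to skip).
#' @return invisible NULL.
#' @export
writeSVCalls <- function(calls, bedpePath = NULL, tsvPath = NULL) {
  if (!is.null(bedpePath)) {
    bed <- data.frame(calls$ref_chrom, calls$ref_start, calls$ref_end,
                      calls$qry_chrom, calls$qry_start, calls$qry_end,
                      calls$type, calls$size, "+",
                      ifelse(calls$type == "INV", "-", "+"))
    utils::write.table(bed, bedpePath, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(tsvPath))
    utils::write.table(calls[, setdiff(names(calls), "seeds")], tsvPath,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
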