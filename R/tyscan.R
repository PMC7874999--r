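# Ty retrotransposon annotation: component scanning (seed-and-extend local
# alignment of each LTR / internal consensus against the genome), greedy
# state classification (complete / truncated / solo_LTR), viability
# assessment (premature stop or frameshift in the internal coding regions),
# the 10-kb flank test separating segmental duplication from independent
# transposition, and per-strain composition tables.

#' Scan a genome for Ty component hits
#'
#' Seed-and-extend search: exact-match seeds of each consensus part (LTR or
#' internal region, per class) locate candidate windows, which are then
#' locally aligned to the consensus. Hits are kept when the alignment
#' identity reaches `minIdentity` and covers at least `minPartFraction` of
#' the consensus part. Both strands are scanned. When a hit location
#' matches several classes (e.g. the near-identical Ty1/Ty2 LTRs), the
#' higher-identity class wins; exact ties get the joint label
#' `"Ty1/Ty2"`-style.
#'
#' @param genome a [Genome-class].
#' @param library a [TyLibrary-class].
#' @param minIdentity minimum percent identity of a component hit.
#' @param minPartFraction minimum covered fraction of the consensus part.
#' @param seedLen exact-match seed length for candidate discovery.
#' @return data.frame of component hits: `class`, `part` (`LTR` or
#'   `internal`), `chrom`, `start`, `end` (0-based half-open), `strand`,
#'   `identity`, `part_fraction`.
#' @export
scanTy <- function(genome, library, minIdentity = 80, minPartFraction = 0.5,
                   seedLen = 16L) {
  hits <- list()
  for (cls in names(library@classes)) {
    e <- library@classes[[cls]]
    for (part in c("LTR", "internal")) {
      cons <- as.character(if (part == "LTR") e$ltr else e$internal)
      plen <- nchar(cons)
      for (chrom in chromNames(genome)) {
        seq <- getChrom(genome, chrom)
        seeds <- findMEMs(cons, seq, minLen = seedLen)
        if (!nrow(seeds)) next
        for (strand in c("+", "-")) {
          ss <- seeds[seeds$strand == strand, , drop = FALSE]
          if (!nrow(ss)) next
          for (win in .clusterWindows(ss$qry_start, ss$qry_start + ss$length,
                                      gap = plen, margin = 200L,
                                      maxPos = nchar(seq))) {
            target <- substr(seq, win[1] + 1L, win[2])
            q <- if (strand == "+") cons else .revcomp(cons)
            sub <- .windowSubHits(q, target, floorScore = 50)
            if (is.null(sub)) next
            merged <- .mergeSubHits(sub, mergeGap = 500L)
            for (r in merged) {
              frac <- r$pat_cov / plen
              if (r$identity >= minIdentity && frac >= minPartFraction) {
                hits[[length(hits) + 1L]] <- data.frame(
                  class = cls, part = part, chrom = chrom,
                  start = win[1] + r$start, end = win[1] + r$end,
                  strand = strand, identity = r$identity, part_fraction = frac,
                  stringsAsFactors = FALSE)
              }
            }
          }
        }
      }
    }
  }
  if (!length(hits))
    return(data.frame(class = character(), part = character(),
                      chrom = character(), start = integer(), end = integer(),
                      strand = character(), identity = numeric(),
                      part_fraction = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  out <- .resolveClassTies(out)
  out <- out[order(out$chrom, out$start, out$class), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Iterative masked alignment inside one candidate window: record the best
# local hit, mask it, realign, until the score falls below floorScore.
# Recovers elements fragmented by internal deletions, which a single local
# alignment cannot bridge (the gap penalty exceeds the gain).
.windowSubHits <- function(q, target, floorScore = 50, maxIter = 8L) {
  sub <- list()
  for (iter in seq_len(maxIter)) {
    r <- localAlign(q, target)
    if (r$score < floorScore) break
    sub[[length(sub) + 1L]] <- r
    target <- paste0(substr(target, 1L, r$target_start),
                     strrep("N", r$target_end - r$target_start),
                     substr(target, r$target_end + 1L, nchar(target)))
  }
  if (!length(sub)) return(NULL)
  sub
}

# Defragment: sub-hits separated by at most mergeGap bp on the genome are
# one component hit; identity is span-weighted, consensus coverage is the
# union of the pattern intervals.
.mergeSubHits <- function(sub, mergeGap = 500L) {
  d <- do.call(rbind, lapply(sub, function(r)
    data.frame(start = r$target_start, end = r$target_end,
               q0 = r$query_start, q1 = r$query_end,
               identity = r$identity, stringsAsFactors = FALSE)))
  d <- d[order(d$start), , drop = FALSE]
  grp <- cumsum(c(TRUE, d$start[-1] - cummax(d$end)[-nrow(d)] > mergeGap))
  lapply(split(d, grp), function(g) {
    list(start = min(g$start), end = max(g$end),
         identity = sum(g$identity * (g$end - g$start)) / sum(g$end - g$start),
         pat_cov = .unionLength(g$q0, g$q1))
  })
}

# Merge seed positions into candidate windows: positions closer than `gap`
# share a window, extended by `margin` on both sides.
.clusterWindows <- function(starts, ends, gap, margin, maxPos) {
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  wins <- list()
  curS <- starts[1]; curE <- ends[1]
  flush <- function(s, e) c(max(0L, s - margin), min(maxPos, e + margin))
  for (i in seq_along(starts)[-1]) {
    if (starts[i] - curE > gap) {
      wins[[length(wins) + 1L]] <- flush(curS, curE)
      curS <- starts[i]; curE <- ends[i]
    } else curE <- max(curE, ends[i])
  }
  wins[[length(wins) + 1L]] <- flush(curS, curE)
  wins
}

# Same-part hits of different classes covering the same locus: keep the
# higher identity; exact ties get a joint "A/B" label.
.resolveClassTies <- function(hits) {
  drop <- rep(FALSE, nrow(hits))
  for (i in seq_len(nrow(hits))) {
    if (drop[i]) next
    for (j in seq_len(nrow(hits))) {
      if (i >= j || drop[j]) next
      if (hits$part[i] != hits$part[j] || hits$chrom[i] != hits$chrom[j] ||
          hits$class[i] == hits$class[j]) next
      ov <- min(hits$end[i], hits$end[j]) - max(hits$start[i], hits$start[j])
      shorter <- min(hits$end[i] - hits$start[i], hits$end[j] - hits$start[j])
      if (ov < 0.5 * shorter) next
      if (hits$identity[i] > hits$identity[j]) drop[j] <- TRUE
      else if (hits$identity[j] > hits$identity[i]) drop[i] <- TRUE
      else {
        hits$class[i] <- paste(sort(c(hits$class[i], hits$class[j])),
                               collapse = "/")
        drop[j] <- TRUE
      }
    }
  }
  hits[!drop, , drop = FALSE]
}

#' Group component hits into Ty elements
#'
#' Greedy left-to-right grouping of same-class, same-strand hits within
#' `pairingWindow`: LTR + internal + LTR becomes a `complete` element
#' (provided the internal hit covers at least `fullSpanFraction` of the
#' internal consensus, otherwise `truncated`); an internal hit with at most
#' one flanking LTR is `truncated`; a lone LTR is a `solo_LTR`. Each hit is
#' assigned to at most one element.
#'
#' @param hits data.frame from [scanTy()].
#' @param pairingWindow maximum distance (bp) between grouped components.
#' @param fullSpanFraction internal consensus coverage required to call an
#'   element complete.
#' @return data.frame of elements: `class`, `state`, `viability` (set to
#'   `not_applicable` for solo LTRs, `NA` otherwise until
#'   [assessViability()] fills it), `chrom`, `start`, `end`, `strand`, and
#'   a `components` list-column of the member hits.
#' @export
classifyElements <- function(hits, pairingWindow = 10000L,
                             fullSpanFraction = 0.9) {
  out <- list()
  if (!is.null(hits) && nrow(hits)) {
    for (key in unique(paste(hits$chrom, hits$class, hits$strand))) {
      sel <- paste(hits$chrom, hits$class, hits$strand) == key
      h <- hits[sel, , drop = FALSE]
      h <- h[order(h$start), , drop = FALSE]
      used <- rep(FALSE, nrow(h))
      i <- 1L
      while (i <= nrow(h)) {
        if (used[i]) { i <- i + 1L; next }
        near <- function(a, b) h$start[b] - h$end[a] <= pairingWindow
        if (h$part[i] == "LTR" && i + 1L <= nrow(h) && !used[i + 1L] &&
            h$part[i + 1L] == "internal" && near(i, i + 1L)) {
          if (i + 2L <= nrow(h) && !used[i + 2L] && h$part[i + 2L] == "LTR" &&
              near(i + 1L, i + 2L)) {
            idx <- i:(i + 2L)
            state <- if (h$part_fraction[i + 1L] >= fullSpanFraction)
              "complete" else "truncated"
          } else {
            idx <- i:(i + 1L)
            state <- "truncated"
          }
        } else if (h$part[i] == "internal") {
          if (i + 1L <= nrow(h) && !used[i + 1L] && h$part[i + 1L] == "LTR" &&
              near(i, i + 1L)) idx <- i:(i + 1L) else idx <- i
          state <- "truncated"
        } else {
          idx <- i
          state <- "solo_LTR"
        }
        used[idx] <- TRUE
        el <- data.frame(class = h$class[i], state = state,
                         viability = if (state == "solo_LTR")
                           "not_applicable" else NA_character_,
                         chrom = h$chrom[i], start = min(h$start[idx]),
                         end = max(h$end[idx]), strand = h$strand[i],
                         stringsAsFactors = FALSE)
        el$components <- list(h[idx, , drop = FALSE])
        out[[length(out) + 1L]] <- el
        i <- max(idx) + 1L
      }
    }
  }
  if (!length(out))
    return({
      d <- data.frame(class = character(), state = character(),
                      viability = character(), chrom = character(),
                      start = integer(), end = integer(), strand = character(),
                      stringsAsFactors = FALSE)
      d$components <- list(); d
    })
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Assess the viability of a Ty element
#'
#' Elements whose internal coding regions contain a premature stop codon or
#' an extensive frameshift are putatively reproductively inviable
#' (loss of function). The element's internal sequence is extracted,
#' globally aligned to the internal consensus, and each declared coding
#' region is inspected: a net coding indel that is not a multiple of 3, any
#' single indel run of at least `frameshiftExtensiveBp`, or a stop codon
#' before the consensus stop marks the element `loss_of_function`; otherwise
#' it is `functional`. Elements without an internal component (solo LTRs)
#' return `not_applicable`.
#'
#' @param element one row of the [classifyElements()] output.
#' @param genome the [Genome-class] the element was annotated on.
#' @param library a [TyLibrary-class].
#' @param frameshiftExtensiveBp cumulative out-of-frame run treated as an
#'   extensive frameshift.
#' @return one of `"functional"`, `"loss_of_function"`, `"not_applicable"`.
#' @export
assessViability <- function(element, genome, library,
                            frameshiftExtensiveBp = 30L) {
  comp <- element$components[[1]]
  int <- comp[comp$part == "internal", , drop = FALSE]
  if (!nrow(int)) return("not_applicable")
  cls <- element$class
  if (!cls %in% names(library@classes)) {
    # joint labels like "Ty1/Ty2": use the first named class
    cls <- strsplit(cls, "/", fixed = TRUE)[[1]][1]
  }
  e <- library@classes[[cls]]
  seq <- getChrom(genome, element$chrom, int$start[1], int$end[1])
  if (element$strand == "-") seq <- .revcomp(seq)
  cons <- as.character(e$internal)
  aln <- globalAlign(cons, seq)
  pc <- strsplit(aln$pattern, "")[[1]]
  sc <- strsplit(aln$subject, "")[[1]]
  patPos <- cumsum(pc != "-")      # consensus coordinate per column (1-based)
  for (k in seq_len(nrow(e$coding))) {
    cstart <- e$coding$start[k]; cend <- e$coding$end[k]
    frame <- e$coding$frame[k]
    colSel <- which(patPos > cstart & patPos <= cend)
    if (!length(colSel)) return("loss_of_function")  # coding region absent
    insGap <- pc[colSel] == "-"
    delGap <- sc[colSel] == "-"
    net <- sum(insGap) - sum(delGap)
    runs <- rle(ifelse(insGap, "I", ifelse(delGap, "D", "M")))
    maxRun <- if (any(runs$values != "M")) max(runs$lengths[runs$values != "M"]) else 0L
    if (net %% 3L != 0L || maxRun >= frameshiftExtensiveBp)
      return("loss_of_function")
    cds <- paste(sc[colSel][sc[colSel] != "-"], collapse = "")
    cds <- substr(cds, frame + 1L, frame + 3L * ((nchar(cds) - frame) %/% 3L))
    if (nchar(cds) < 3L) return("loss_of_function")
    aa <- suppressWarnings(as.character(Biostrings::translate(
      Biostrings::DNAString(cds), if.fuzzy.codon = "solve")))
    stops <- which(strsplit(aa, "")[[1]] == "*")
    if (length(stops) && any(stops < nchar(aa))) return("loss_of_function")
  }
  "functional"
}

#' Annotate all Ty elements of a genome
#'
#' Convenience wrapper: [scanTy()], [classifyElements()], then
#' [assessViability()] per element.
#'
#' @inheritParams scanTy
#' @inheritParams classifyElements
#' @inheritParams assessViability
#' @return element data.frame (see [classifyElements()]) with `viability`
#'   filled in and a `strain` column.
#' @export
annotateTy <- function(genome, library, minIdentity = 80,
                       minPartFraction = 0.5, seedLen = 16L,
                       pairingWindow = 10000L, fullSpanFraction = 0.9,
                       frameshiftExtensiveBp = 30L) {
  hits <- scanTy(genome, library, minIdentity = minIdentity,
                 minPartFraction = minPartFraction, seedLen = seedLen)
  els <- classifyElements(hits, pairingWindow = pairingWindow,
                          fullSpanFraction = fullSpanFraction)
  if (nrow(els)) {
    for (i in seq_len(nrow(els))) {
      if (is.na(els$viability[i]))
        els$viability[i] <- assessViability(els[i, ], genome, library,
                                            frameshiftExtensiveBp)
    }
    els <- cbind(strain = strainName(genome), els, stringsAsFactors = FALSE)
  } else {
    els$strain <- character()
  }
  els
}

#' Flank test: segmental duplication vs independent transposition
#'
#' Two similar elements of one strain and class either arose by segmental
#' duplication of a region containing the element (shared flanks) or by
#' independent transposition (unrelated flanks). The regions containing
#' each element (element plus `flankContext`/2 bp on each side, clipped at
#' chromosome ends, element sequence masked with N) are compared: left
#' flanks aligned to left flanks and right to right. If the combined
#' aligned span covers at least half of the shorter region's flanks at
#' `flankIdentityThreshold` identity or better (inclusive), the pair is a
#' `segmental_duplication`; if the flanks are essentially unalignable
#' (coverage below 0.2 or identity below 75), `independent_transposition`;
#' anything in between is `indeterminate`.
#'
#' @param e1,e2 element rows (same strain and class).
#' @param genome the [Genome-class] carrying both elements.
#' @param flankContext total flanking context in bp (default 10000).
#' @param flankIdentityThreshold percent identity for shared flanks.
#' @return one of `"segmental_duplication"`, `"independent_transposition"`,
#'   `"indeterminate"`.
#' @export
transpositionVsDuplication <- function(e1, e2, genome, flankContext = 10000L,
                                       flankIdentityThreshold = 90) {
  .assertThat(e1$class == e2$class, "elements must share a Ty class")
  for (e in list(e1, e2))
    .assertThat(e$chrom %in% chromNames(genome),
                sprintf("element chromosome '%s' missing from genome", e$chrom))
  half <- as.integer(flankContext) %/% 2L
  flanks <- lapply(list(e1, e2), function(e) {
    len <- chromLengths(genome)[[e$chrom]]
    list(left = getChrom(genome, e$chrom, max(0L, e$start - half), e$start),
         right = getChrom(genome, e$chrom, e$end, min(len, e$end + half)))
  })
  tot <- 0; spans <- 0; wId <- 0
  for (side in c("left", "right")) {
    a <- flanks[[1]][[side]]; b <- flanks[[2]][[side]]
    shorter <- min(nchar(a), nchar(b))
    if (shorter == 0) next
    tot <- tot + shorter
    r <- localAlign(a, b)
    spans <- spans + min(r$aligned_span, shorter)
    wId <- wId + r$identity * min(r$aligned_span, shorter)
  }
  if (tot == 0) return("indeterminate")
  coverage <- spans / tot
  identity <- if (spans > 0) wId / spans else 0
  if (identity >= flankIdentityThreshold && coverage >= 0.5)
    "segmental_duplication"
  else if (coverage < 0.2 || identity < 75)
    "independent_transposition"
  else "indeterminate"
}

#' Per-strain Ty composition table
#'
#' Counts and cumulative lengths per strain x class x state, optionally
#' with the per-category normalization x / x_max (each class-state category
#' scaled by its maximum across strains) used for visual comparison of
#' composition profiles.
#'
#' @param elements element data.frame with a `strain` column (rbind of
#'   [annotateTy()] outputs).
#' @param normalize add a `norm_count` column (x / x_max within each
#'   class-state category).
#' @return data.frame: `strain`, `class`, `state`, `count`, `total_bp`
#'   (+ `norm_count`).
#' @export
tySummary <- function(elements, normalize = FALSE) {
  .assertThat(!is.null(elements$strain), "elements need a strain column")
  if (!nrow(elements))
    return(data.frame(strain = character(), class = character(),
                      state = character(), count = integer(),
                      total_bp = integer(), stringsAsFactors = FALSE))
  key <- interaction(elements$strain, elements$class, elements$state, drop = TRUE)
  agg <- do.call(rbind, lapply(split(elements, key), function(x)
    data.frame(strain = x$strain[1], class = x$class[1], state = x$state[1],
               count = nrow(x), total_bp = sum(x$end - x$start),
               stringsAsFactors = FALSE)))
  if (normalize) {
    cat_key <- paste(agg$class, agg$state)
    mx <- tapply(agg$count, cat_key, max)
    agg$norm_count <- agg$count / as.numeric(mx[cat_key])
  }
  agg <- agg[order(agg$strain, agg$class, agg$state), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}
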