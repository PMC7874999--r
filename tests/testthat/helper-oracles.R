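# Independent oracles used across the suite. Each reimplements the checked
# quantity by direct enumeration or via an unrelated library routine, never
# by calling the code path under test.

rc <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

randSeq <- function(n, letters = c("A", "C", "G", "T")) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

# Quadratic maximal-exact-match enumeration: sweep every alignment diagonal
# and take runs of matching characters (N never matches).
bruteMEMs <- function(ref, qry, minLen) {
  one <- function(r, q) {
    a <- strsplit(r, "")[[1]]; b <- strsplit(q, "")[[1]]
    n <- length(a); m <- length(b)
    out <- list()
    if (n == 0 || m == 0) {
      return(data.frame(ref_start = integer(), qry_start = integer(),
                        length = integer()))
    }
    for (d in (-(m - 1)):(n - 1)) {
      i <- max(1, 1 + d):min(n, m + d)
      j <- i - d
      eq <- a[i] == b[j] & a[i] != "N" & b[j] != "N"
      r1 <- rle(eq)
      ends <- cumsum(r1$lengths); starts <- ends - r1$lengths + 1
      for (k in which(r1$values & r1$lengths >= minLen)) {
        out[[length(out) + 1]] <- data.frame(
          ref_start = i[starts[k]] - 1L, qry_start = j[starts[k]] - 1L,
          length = r1$lengths[k])
      }
    }
    if (!length(out))
      return(data.frame(ref_start = integer(), qry_start = integer(),
                        length = integer()))
    do.call(rbind, out)
  }
  fwd <- one(ref, qry)
  fwd$strand <- rep("+", nrow(fwd))
  rev <- one(ref, rc(qry))
  if (nrow(rev)) {
    rev$qry_start <- nchar(qry) - (rev$qry_start + rev$length)
    rev$strand <- "-"
  } else rev$strand <- character(0)
  out <- rbind(fwd, rev)
  out <- out[order(out$ref_start, out$qry_start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Exhaustive maximal-weight collinear chain by depth-first enumeration of
# every feasible chain (weights = seed lengths); used to peel a full
# partition for comparison with the chaining DP.
bruteBestChain <- function(seeds, maxGap, overlapTol) {
  n <- nrow(seeds)
  rs <- seeds$ref_start; re <- rs + seeds$length
  qs <- seeds$qry_start; qe <- qs + seeds$length
  feas <- function(u, v) {
    rgap <- rs[v] - re[u]; qgap <- qs[v] - qe[u]
    rs[v] > rs[u] && qs[v] > qs[u] &&
      rgap <= maxGap && rgap >= -overlapTol &&
      qgap <= maxGap && qgap >= -overlapTol
  }
  best <- list(w = -1, chain = integer())
  walk <- function(chain, w) {
    if (w > best$w) best <<- list(w = w, chain = chain)
    last <- chain[length(chain)]
    for (v in seq_len(n)) {
      if (v %in% chain) next
      if (feas(last, v)) walk(c(chain, v), w + seeds$length[v])
    }
  }
  for (s in seq_len(n)) walk(s, seeds$length[s])
  best
}

brutePeelPartition <- function(seeds, maxGap, overlapTol) {
  left <- seq_len(nrow(seeds))
  parts <- list()
  while (length(left)) {
    b <- bruteBestChain(seeds[left, , drop = FALSE], maxGap, overlapTol)
    ids <- left[b$chain]
    parts[[length(parts) + 1]] <- sort(ids)
    left <- setdiff(left, ids)
  }
  parts
}

# Set-comprehension oracles for the two gene-loss definitions.
oracleCandidateLosses <- function(m, roles, focal) {
  others <- setdiff(names(roles)[roles %in% c("focal", "other_conspecific")],
                    focal)
  og <- names(roles)[roles == "outgroup"]
  keep <- vapply(rownames(m), function(g)
    any(m[g, others]) && any(m[g, og]) && !any(m[g, focal]), TRUE)
  rownames(m)[keep]
}

oracleMissingCore <- function(m, roles, focal) {
  others <- setdiff(names(roles)[roles %in% c("focal", "other_conspecific")],
                    focal)
  keep <- vapply(rownames(m), function(g)
    all(m[g, others]) && !any(m[g, focal]), TRUE)
  rownames(m)[keep]
}

randomPAM <- function(nGenes = 200, seed) {
  set.seed(seed)
  strains <- c(paste0("F", 1:3), paste0("O", 1:9), paste0("G", 1:3))
  roles <- setNames(c(rep("focal", 3), rep("other_conspecific", 9),
                      rep("outgroup", 3)), strains)
  m <- matrix(runif(nGenes * length(strains)) < 0.6, nGenes, length(strains),
              dimnames = list(sprintf("g%04d", seq_len(nGenes)), strains))
  PresenceAbsenceMatrix(m, roles)
}

# Independent affine-gap local alignment via Biostrings (score oracle).
biostringsLocalScore <- function(a, b, match = 1, mismatch = -1,
                                 gapOpen = 4, gapExtend = 1) {
  Biostrings::score(Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match, mismatch, baseOnly = TRUE),
    gapOpening = gapOpen, gapExtension = gapExtend))
}
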