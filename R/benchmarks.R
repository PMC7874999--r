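# Seeded benchmark fixtures with planted truth. These encode the standing
# study conditions for the recovery analyses: panel sizes, chromosome
# lengths, event sizes (200 bp - 80 kb, including the ~80-kb terminal
# translocation analog), Ty element states, and introgression divergence
# (8 percent). Positions are jittered per seed inside disjoint windows so
# features never collide.

#' Structural-variant recovery benchmark
#'
#' Six strains: one ancestor plus five derived strains, each derived strain
#' carrying one planted event of every type. Two chromosomes (100 kb and
#' 150 kb); event sizes DEL 500, INS 300, INV 2000, DUP 400 and an 80-kb
#' terminal translocation from the long chromosome onto the short one.
#' Derived strains sit at 0.005 substitutions/site from the ancestor, with
#' planted intervals (plus a one-seed margin) protected.
#'
#' @param seed master seed.
#' @return list with `ancestor`, `derived` (named list of [Genome-class]),
#'   and `truth` (data.frame: strain, type, chrom, pos, end, size,
#'   to_chrom).
#' @export
simulateSVBenchmark <- function(seed) {
  anc <- generateAncestor(2, c(100000L, 150000L), gc = 0.38,
                          seed = .deriveSeed(seed, "svb-anc"))
  derived <- list(); truthRows <- list()
  for (k in 1:5) {
    s <- sprintf("S%d", k)
    jit <- .withSeed(.deriveSeed(seed, "svb-jit", k),
                     as.integer(floor(stats::runif(4) * 50) * 100))
    plan <- data.frame(
      type = c("DEL", "INS", "INV", "DUP", "TRA"),
      chrom = c("chrI", "chrI", "chrII", "chrII", "chrII"),
      pos = c(15000L + jit[1], 55000L + jit[2], 20000L + jit[3],
              45000L + jit[4], 70000L),
      size = c(500L, 300L, 2000L, 400L, 80000L),
      to_chrom = c(NA, NA, NA, NA, "chrI"),
      stringsAsFactors = FALSE)
    ex <- data.frame(chrom = plan$chrom,
                     start = pmax(0L, plan$pos - SUBST_MARGIN),
                     end = ifelse(plan$type == "INS", plan$pos,
                                  plan$pos + plan$size) + SUBST_MARGIN)
    g <- applySubstitutions(anc, 0.005,
                            seed = .deriveSeed(seed, "svb-sub", k),
                            exclude = ex, strain = s)$genome
    delta <- c(chrI = 0L, chrII = 0L)
    for (i in order(plan$type == "TRA", plan$pos)) {
      p <- plan[i, ]
      r <- plantSV(g, p$type, p$chrom, p$pos + delta[[p$chrom]], p$size,
                   payloadSeed = .deriveSeed(seed, "svb-ins", k, i),
                   toChrom = if (is.na(p$to_chrom)) NA_character_ else p$to_chrom)
      g <- r$genome
      delta[[p$chrom]] <- delta[[p$chrom]] + switch(
        p$type, DEL = -p$size, INS = p$size, DUP = p$size, INV = 0L, TRA = 0L)
    }
    derived[[s]] <- g
    truthRows[[s]] <- cbind(strain = s, plan, stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, c(truthRows, list(make.row.names = FALSE)))
  truth$end <- truth$pos + truth$size
  list(ancestor = anc, derived = derived, truth = truth)
}

#' Compare SV calls against a planted truth table
#'
#' A call matches a truth row when the types correspond and the reference
#' interval sits within `tol` bp of the truth interval (insertions are
#' matched on the insertion point and query span). Calls are made with the
#' ancestor as reference, so truth coordinates (ancestor frame) are
#' compared directly.
#'
#' @param calls data.frame from [callSVs()] (ancestor as reference).
#' @param truth truth rows for one strain (ancestor-frame coordinates).
#' @param tol positional tolerance in bp.
#' @return list with logical vector `recovered` (per truth row), and
#'   `spurious` (calls matching no truth row).
#' @export
matchSVCalls <- function(calls, truth, tol = 10L) {
  recovered <- logical(nrow(truth))
  usedCall <- rep(FALSE, nrow(calls))
  for (i in seq_len(nrow(truth))) {
    tr <- truth[i, ]
    for (j in seq_len(nrow(calls))) {
      if (usedCall[j]) next
      cl <- calls[j, ]
      if (cl$type != tr$type || cl$ref_chrom != tr$chrom) next
      if (tr$type == "INS") {
        posOk <- abs(cl$ref_start - tr$pos) <= tol
        sizeOk <- abs(cl$size - tr$size) <= tol
      } else if (tr$type == "TRA") {
        posOk <- abs(cl$ref_start - tr$pos) <= tol &&
          abs(cl$ref_end - tr$end) <= tol
        sizeOk <- abs(cl$size - tr$size) <= tol
      } else {
        posOk <- abs(cl$ref_start - tr$pos) <= tol &&
          abs(cl$ref_end - tr$end) <= tol
        sizeOk <- abs(cl$size - tr$size) <= tol
      }
      if (posOk && sizeOk) { recovered[i] <- TRUE; usedCall[j] <- TRUE; break }
    }
  }
  list(recovered = recovered, spurious = calls[!usedCall, , drop = FALSE])
}

#' Ty annotation recovery benchmark
#'
#' Per strain: three solo Ty1 LTRs, one complete functional Ty1, one
#' complete Ty2 with a planted premature stop, one complete Ty3 with a
#' planted 1-bp coding deletion (frameshift), and one Ty5 with a 2-kb
#' internal truncation. Elements are spaced at least ~13 kb apart on two
#' 60-kb chromosomes; positions are jittered per seed.
#'
#' @param seed master seed.
#' @param nStrains number of strains.
#' @param library a [TyLibrary-class].
#' @return list with `genomes` (named list) and `truth` (data.frame:
#'   strain, class, state, viability, chrom, start, end).
#' @export
simulateTyBenchmark <- function(seed, nStrains = 2L,
                                library = defaultTyLibrary()) {
  genomes <- list(); rows <- list()
  plan <- data.frame(
    class = c("Ty1", "Ty1", "Ty1", "Ty1", "Ty2", "Ty3", "Ty5"),
    state = c("solo_LTR", "solo_LTR", "solo_LTR", "complete", "complete",
              "complete", "truncated"),
    viability = c("not_applicable", "not_applicable", "not_applicable",
                  "functional", "loss_of_function", "loss_of_function",
                  "loss_of_function"),
    lesion = c(NA, NA, NA, NA, "premature_stop", "frameshift", NA),
    chrom = c("chrI", "chrI", "chrI", "chrI", "chrII", "chrII", "chrII"),
    base = c(5000L, 20000L, 35000L, 48000L, 5000L, 25000L, 45000L),
    stringsAsFactors = FALSE)
  for (k in seq_len(nStrains)) {
    s <- sprintf("T%d", k)
    g <- generateAncestor(2, c(60000L, 60000L), gc = 0.38,
                          seed = .deriveSeed(seed, "tyb", k), strain = s)
    jit <- .withSeed(.deriveSeed(seed, "tyb-jit", k),
                     as.integer(floor(stats::runif(nrow(plan)) * 20) * 50))
    delta <- c(chrI = 0L, chrII = 0L)
    for (i in seq_len(nrow(plan))) {
      p <- plan[i, ]
      pos <- p$base + jit[i] + delta[[p$chrom]]
      r <- plantTyElement(g, library, p$class, p$state, p$viability,
                          p$chrom, pos,
                          lesion = if (is.na(p$lesion)) "premature_stop" else p$lesion)
      g <- r$genome
      rows[[length(rows) + 1L]] <- cbind(strain = s, r$record,
                                         stringsAsFactors = FALSE)
      delta[[p$chrom]] <- delta[[p$chrom]] + (r$record$end - r$record$start)
    }
    genomes[[s]] <- g
  }
  list(genomes = genomes,
       truth = do.call(rbind, c(rows, list(make.row.names = FALSE))))
}

#' Flank-test benchmark: one duplicated pair, one independent pair
#'
#' The duplicated pair is built by copying the 10-kb region containing a
#' planted element to another chromosome (a segmental duplication); the
#' independent pair consists of two same-class elements planted at
#' unrelated random positions.
#'
#' @param seed master seed.
#' @param library a [TyLibrary-class].
#' @return list with `genome`, `dupPair` and `indepPair` (each a 2-row
#'   element data.frame compatible with [transpositionVsDuplication()]).
#' @export
simulateFlankBenchmark <- function(seed, library = defaultTyLibrary()) {
  g <- generateAncestor(3, c(40000L, 40000L, 40000L), gc = 0.38,
                        seed = .deriveSeed(seed, "flank"), strain = "FL")
  e <- library@classes[["Ty1"]]
  elLen <- 2L * length(e$ltr) + length(e$internal)
  # element 1 on chrI; copy its containing region onto chrII
  p1 <- 15000L
  g <- plantTyElement(g, library, "Ty1", "complete", "functional", "chrI",
                      p1)$genome
  regionStart <- p1 - 5000L
  regionEnd <- p1 + elLen + 5000L
  region <- getChrom(g, "chrI", regionStart, regionEnd)
  insAt <- 20000L
  s2 <- getChrom(g, "chrII")
  g <- .setChrom(g, "chrII", paste0(substr(s2, 1, insAt), region,
                                    substr(s2, insAt + 1L, nchar(s2))))
  # independent pair on chrIII (plus element 1 reused)
  q1 <- 8000L; q2 <- 28000L
  g <- plantTyElement(g, library, "Ty2", "complete", "functional", "chrIII",
                      q1)$genome
  el2Len <- 2L * length(library@classes[["Ty2"]]$ltr) +
    length(library@classes[["Ty2"]]$internal)
  g <- plantTyElement(g, library, "Ty2", "complete", "functional", "chrIII",
                      q2 + el2Len)$genome
  mk <- function(class, chrom, start, end)
    data.frame(class = class, chrom = chrom, start = start, end = end,
               strand = "+", stringsAsFactors = FALSE)
  list(genome = g,
       dupPair = rbind(mk("Ty1", "chrI", p1, p1 + elLen),
                       mk("Ty1", "chrII", insAt + 5000L, insAt + 5000L + elLen)),
       indepPair = rbind(mk("Ty2", "chrIII", q1, q1 + el2Len),
                         mk("Ty2", "chrIII", q2 + el2Len, q2 + 2L * el2Len)))
}

#' Introgression-filter boundary benchmark
#'
#' ORF catalogs for a 3-focal + 2-other panel with controlled
#' constructions: `intro_pass` (8 percent shared divergence in all three
#' focal strains; passes all four criteria), `cov074` (diverged over only
#' 74 percent of its length; fails the coverage criterion alone),
#' `two_of_three` (present in two focal strains; fails the presence
#' criterion alone), `id_above95` (mean identity just above 95 percent with
#' exactly two-thirds of the alignments at or below 95; fails the mean
#' identity criterion alone), plus undiverged core ORFs as background.
#'
#' @param seed master seed.
#' @param orfLength ORF length (bp).
#' @return list with `catalogs`, `focal`, `others`.
#' @export
simulateIntrogressionBenchmark <- function(seed, orfLength = 999L) {
  focal <- c("F1", "F2", "F3"); others <- c("O1", "O2")
  nCore <- 4L
  base <- .withSeed(.deriveSeed(seed, "intro-base"), {
    ids <- c(sprintf("core%02d", seq_len(nCore)), "intro_pass", "cov074",
             "two_of_three", "id_above95")
    stats::setNames(vapply(ids, function(i) .randomSeq(orfLength, 0.40),
                           character(1)), ids)
  })
  catalogs <- list()
  for (s in c(focal, others))
    catalogs[[s]] <- base
  # intro_pass: one 8%-diverged copy shared by the focal clade
  r <- plantIntrogressedORFs(lapply(catalogs, Biostrings::DNAStringSet),
                             "intro_pass", 0.08, focal,
                             seed = .deriveSeed(seed, "intro-pass"))
  catalogs <- lapply(r$catalogs, as.character)
  # cov074: first 74% diverged at 8%, remainder replaced with unrelated
  # sequence (still full length) in every focal copy
  keep <- as.integer(floor(orfLength * 0.74))
  head74 <- substr(base[["cov074"]], 1, keep)
  nsub <- .withSeed(.deriveSeed(seed, "cov-div"), {
    hit <- which(stats::runif(keep) < 0.08)
    list(hit = hit, pick = sample.int(3L, length(hit), replace = TRUE))
  })
  divHead <- .substituteAt(head74, nsub$hit, nsub$pick)
  tail26 <- .withSeed(.deriveSeed(seed, "cov-tail"),
                      .randomSeq(orfLength - keep, 0.40))
  for (f in focal) catalogs[[f]][["cov074"]] <- paste0(divHead, tail26)
  # two_of_three: 8%-diverged in F1/F2, absent from F3
  n23 <- .withSeed(.deriveSeed(seed, "two3"), {
    hit <- which(stats::runif(orfLength) < 0.08)
    list(hit = hit, pick = sample.int(3L, length(hit), replace = TRUE))
  })
  div23 <- .substituteAt(base[["two_of_three"]], n23$hit, n23$pick)
  catalogs[["F1"]][["two_of_three"]] <- div23
  catalogs[["F2"]][["two_of_three"]] <- div23
  catalogs[["F3"]] <- catalogs[["F3"]][names(catalogs[["F3"]]) != "two_of_three"]
  # id_above95: F1/F2 copies at identity (L-51)/L ~ 94.9 (counted as low),
  # F3 copy at (L-44)/L ~ 95.6 (not low): mean ~ 95.13 > 95, low fraction
  # exactly 2/3
  lowCopy <- substituteExact(base[["id_above95"]], 51L,
                             seed = .deriveSeed(seed, "id95-low"))
  hiCopy <- substituteExact(base[["id_above95"]], 44L,
                            seed = .deriveSeed(seed, "id95-hi"))
  catalogs[["F1"]][["id_above95"]] <- lowCopy
  catalogs[["F2"]][["id_above95"]] <- lowCopy
  catalogs[["F3"]][["id_above95"]] <- hiCopy
  list(catalogs = lapply(catalogs, Biostrings::DNAStringSet),
       focal = focal, others = others)
}
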