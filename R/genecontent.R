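# Gene presence/absence, the two gene-loss definitions, the
# introgression-candidate ORF filter, and plain genome-content summaries.
#
# Gene-loss vocabulary: the pangenome is the cumulative (union) gene set of
# a strain group, the core genome its consensus (intersection). A candidate
# gene loss in the focal clade is a gene present in the pangenome of the
# other conspecific strains, overlapping the outgroup pangenome, and absent
# from every focal strain; a missing core gene is one present in every
# non-focal conspecific strain and absent from every focal strain.

#' Build a presence/absence matrix from ortholog groups
#'
#' One row per ortholog group; presence means the strain contributes at
#' least one member. Row order follows the first appearance of each group
#' in the table; column order follows `panel`.
#'
#' @param groups data.frame with columns `group_id`, `strain`, `gene_id`.
#' @param panel ordered character vector of all panel strains.
#' @param roles named character vector of strain roles (`focal`,
#'   `other_conspecific`, `outgroup`), one per panel strain.
#' @return A [PresenceAbsenceMatrix-class].
#' @export
buildPresenceAbsence <- function(groups, panel, roles) {
  .assertThat(all(c("group_id", "strain", "gene_id") %in% names(groups)),
              "groups must have columns group_id, strain, gene_id")
  .assertThat(!anyDuplicated(panel), "duplicate strain in panel")
  bad <- setdiff(unique(groups$strain), panel)
  .assertThat(length(bad) == 0,
              sprintf("strain(s) in groups but not in panel: %s",
                      paste(bad, collapse = ", ")))
  gid <- unique(groups$group_id)
  m <- matrix(FALSE, length(gid), length(panel), dimnames = list(gid, panel))
  if (nrow(groups))
    m[cbind(match(groups$group_id, gid), match(groups$strain, panel))] <- TRUE
  PresenceAbsenceMatrix(m, roles)
}

.checkFocal <- function(pam, focal) {
  roles <- strainRoles(pam)
  .assertThat(length(focal) >= 1, "focal strain set must be non-empty")
  .assertThat(all(focal %in% paStrains(pam)), "unknown focal strain")
  .assertThat(all(roles[focal] %in% c("focal", "other_conspecific")),
              "focal strains must be conspecific")
  .assertThat(any(roles == "outgroup"), "panel needs at least one outgroup strain")
  list(other = setdiff(names(roles)[roles %in% c("focal", "other_conspecific")],
                       focal),
       outgroup = names(roles)[roles == "outgroup"])
}

#' Candidate gene losses in a focal clade
#'
#' Genes present in the pangenome (union) of the non-focal conspecific
#' strains, also present in at least one outgroup strain, and absent from
#' every focal strain.
#'
#' @param pam a [PresenceAbsenceMatrix-class].
#' @param focal focal strain names (defaults to the strains tagged `focal`).
#' @return character vector of gene ids, in matrix row order.
#' @export
candidateGeneLosses <- function(pam, focal = NULL) {
  focal <- focal %||% names(strainRoles(pam))[strainRoles(pam) == "focal"]
  grp <- .checkFocal(pam, focal)
  m <- paMatrix(pam)
  sel <- rowSums(m[, grp$other, drop = FALSE]) >= 1 &
    rowSums(m[, grp$outgroup, drop = FALSE]) >= 1 &
    rowSums(m[, focal, drop = FALSE]) == 0
  rownames(m)[sel]
}

#' Missing core genes in a focal clade
#'
#' Genes present in the consensus (intersection) gene set of every
#' non-focal conspecific strain and absent from every focal strain.
#'
#' @inheritParams candidateGeneLosses
#' @return character vector of gene ids, in matrix row order.
#' @export
missingCoreGenes <- function(pam, focal = NULL) {
  focal <- focal %||% names(strainRoles(pam))[strainRoles(pam) == "focal"]
  grp <- .checkFocal(pam, focal)
  m <- paMatrix(pam)
  sel <- rowSums(m[, grp$other, drop = FALSE]) == length(grp$other) &
    rowSums(m[, focal, drop = FALSE]) == 0
  rownames(m)[sel]
}

#' Default thresholds for the introgression-candidate ORF filter
#'
#' Candidates must be present in every focal strain, show a mean identity
#' to their non-focal best hits of at most 95 percent, have the aligned
#' region cover at least 75 percent of the query ORF, and have at least
#' two-thirds of the clade's alignments at no more than 95 percent
#' identity. All comparisons are inclusive.
#'
#' @param maxMeanIdentity percent.
#' @param minQueryCoverage fraction.
#' @param minLowIdentityFraction fraction of alignments that must sit at or
#'   below `lowIdentityCutoff`.
#' @param lowIdentityCutoff percent.
#' @param minOrthologIdentity percent identity for the reciprocal-best
#'   ortholog grouping within the focal clade.
#' @param minHitScore alignment score below which a best hit is treated as
#'   absent (`no_hit`).
#' @param coverageMode `mean` (default) or `min`: how per-alignment query
#'   coverages aggregate into the coverage criterion.
#' @return named list of thresholds.
#' @export
filterThresholds <- function(maxMeanIdentity = 95, minQueryCoverage = 0.75,
                             minLowIdentityFraction = 2 / 3,
                             lowIdentityCutoff = 95,
                             minOrthologIdentity = 80, minHitScore = 30,
                             coverageMode = c("mean", "min")) {
  coverageMode <- match.arg(coverageMode)
  .assertThat(maxMeanIdentity >= 0 && maxMeanIdentity <= 100 &&
                .isFraction(minQueryCoverage) &&
                .isFraction(minLowIdentityFraction), "threshold out of range")
  list(maxMeanIdentity = maxMeanIdentity, minQueryCoverage = minQueryCoverage,
       minLowIdentityFraction = minLowIdentityFraction,
       lowIdentityCutoff = lowIdentityCutoff,
       minOrthologIdentity = minOrthologIdentity, minHitScore = minHitScore,
       coverageMode = coverageMode)
}

#' Introgression-candidate ORF filter
#'
#' For each focal-clade ORF group: every focal member is aligned against
#' every non-focal strain's catalog and the best-scoring hit per strain
#' retained (score ties broken by the lexicographically smallest target
#' id). An ORF passes when (i) its ortholog group (reciprocal best local
#' alignment within the focal clade at `minOrthologIdentity` or better) has
#' a member in every focal strain, (ii) the mean identity across all
#' non-focal best hits is at most `maxMeanIdentity`, (iii) the aligned
#' region covers at least `minQueryCoverage` of the query ORF, and (iv) the
#' fraction of the clade's alignments at or below `lowIdentityCutoff`
#' identity is at least `minLowIdentityFraction`. Focal ORFs with no
#' alignable non-focal hit are flagged `no_hit` and excluded with that
#' reason rather than silently dropped.
#'
#' @param catalogs named list of `DNAStringSet` ORF catalogs, one per strain.
#' @param focal focal strain names (at least one).
#' @param others non-focal strain names to compare against.
#' @param thresholds list from [filterThresholds()].
#' @return data.frame with one row per focal ORF group: `orf_id` (anchor
#'   member id), `n_focal` (focal strains carrying the group), per-criterion
#'   measurements (`mean_identity`, `mean_coverage`, `low_identity_fraction`),
#'   per-criterion flags (`pass_presence`, `pass_identity`, `pass_coverage`,
#'   `pass_low_fraction`), the overall `pass` (conjunction of the flags) and
#'   a `reason` column (`ok`, `no_hit`, or the failed criteria).
#' @export
introgressionCandidates <- function(catalogs, focal, others,
                                    thresholds = filterThresholds()) {
  .assertThat(length(focal) >= 1, "need at least one focal strain")
  .assertThat(all(c(focal, others) %in% names(catalogs)),
              "catalog missing for a listed strain")
  for (s in c(focal, others))
    .assertThat(length(catalogs[[s]]) > 0, sprintf("empty catalog for '%s'", s))
  groups <- .focalOrthologGroups(catalogs, focal, thresholds)
  rows <- lapply(groups, function(grp) {
    aligns <- list()
    noHit <- FALSE
    for (f in names(grp$members)) {
      qseq <- as.character(catalogs[[f]][[grp$members[[f]]]])
      bestAny <- FALSE
      for (s in others) {
        hits <- .localAlignSet(qseq, catalogs[[s]])
        hits <- hits[hits$score >= thresholds$minHitScore, , drop = FALSE]
        if (!nrow(hits)) next
        hits <- hits[order(-hits$score, hits$target), , drop = FALSE]
        aligns[[length(aligns) + 1L]] <- cbind(
          focal_strain = f, other_strain = s, hits[1, , drop = FALSE])
        bestAny <- TRUE
      }
      if (!bestAny) noHit <- TRUE
    }
    passPresence <- length(grp$members) == length(focal)
    if (!length(aligns)) {
      return(data.frame(
        orf_id = grp$anchor, n_focal = length(grp$members),
        mean_identity = NA_real_, mean_coverage = NA_real_,
        low_identity_fraction = NA_real_,
        pass_presence = passPresence, pass_identity = FALSE,
        pass_coverage = FALSE, pass_low_fraction = FALSE, pass = FALSE,
        reason = "no_hit", stringsAsFactors = FALSE))
    }
    a <- do.call(rbind, aligns)
    meanId <- mean(a$identity)
    cov <- if (thresholds$coverageMode == "min") min(a$query_coverage)
           else mean(a$query_coverage)
    lowFrac <- mean(a$identity <= thresholds$lowIdentityCutoff)
    passId <- meanId <= thresholds$maxMeanIdentity
    passCov <- cov >= thresholds$minQueryCoverage
    passLow <- lowFrac >= thresholds$minLowIdentityFraction
    pass <- passPresence && passId && passCov && passLow && !noHit
    reason <- if (noHit) "no_hit" else if (pass) "ok" else
      paste(c("presence", "identity", "coverage", "low_fraction")[
        !c(passPresence, passId, passCov, passLow)], collapse = ",")
    data.frame(orf_id = grp$anchor, n_focal = length(grp$members),
               mean_identity = meanId, mean_coverage = cov,
               low_identity_fraction = lowFrac,
               pass_presence = passPresence, pass_identity = passId,
               pass_coverage = passCov, pass_low_fraction = passLow,
               pass = pass, reason = reason, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$orf_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Ortholog groups within the focal clade by reciprocal best local alignment
# at >= minOrthologIdentity. Anchors are taken strain by strain (panel
# order), id order within a strain; an ORF already claimed by a group is
# not re-anchored.
.focalOrthologGroups <- function(catalogs, focal, thresholds) {
  used <- lapply(focal, function(f) character())
  names(used) <- focal
  groups <- list()
  for (f in focal) {
    for (orf in sort(names(catalogs[[f]]))) {
      if (orf %in% used[[f]]) next
      members <- stats::setNames(list(orf), f)
      qseq <- as.character(catalogs[[f]][[orf]])
      for (g in setdiff(focal, f)) {
        cand <- catalogs[[g]][!names(catalogs[[g]]) %in% used[[g]]]
        if (!length(cand)) next
        fw <- .localAlignSet(qseq, cand)
        fw <- fw[order(-fw$score, fw$target), , drop = FALSE]
        best <- fw[1, ]
        if (best$score < thresholds$minHitScore ||
            best$identity < thresholds$minOrthologIdentity) next
        # reciprocal check back into strain f
        bk <- .localAlignSet(as.character(catalogs[[g]][[best$target]]),
                             catalogs[[f]])
        bk <- bk[order(-bk$score, bk$target), , drop = FALSE]
        if (bk$target[1] == orf) members[[g]] <- best$target
      }
      for (g in names(members)) used[[g]] <- c(used[[g]], members[[g]])
      groups[[length(groups) + 1L]] <- list(anchor = orf, members = members)
    }
  }
  groups
}

#' Genome content summary
#'
#' Plain descriptive summary of a genome and its annotation: genome size,
#' gene count, cumulative gene length, coding fraction, noncoding bp, and
#' intron count/length when intron features are annotated.
#'
#' @param genome a [Genome-class].
#' @param annotation GFF3 path or a `GRanges` of features (types `gene` and
#'   optionally `intron`).
#' @return one-row data.frame.
#' @export
genomeContentSummary <- function(genome, annotation) {
  gr <- if (is.character(annotation)) rtracklayer::import(annotation)
        else annotation
  len <- chromLengths(genome)
  .assertThat(all(as.character(GenomicRanges::seqnames(gr)) %in% names(len)),
              "annotation names a chromosome missing from the genome")
  ends <- GenomicRanges::end(gr)
  .assertThat(all(ends <= len[as.character(GenomicRanges::seqnames(gr))]),
              "gene interval out of chromosome bounds")
  genes <- gr[gr$type == "gene"]
  introns <- gr[gr$type == "intron"]
  genomeBp <- sum(len)
  cumGene <- sum(GenomicRanges::width(genes))
  codingBp <- sum(GenomicRanges::width(GenomicRanges::reduce(genes)))
  data.frame(genome_bp = genomeBp,
             gene_count = length(genes),
             cumulative_gene_bp = cumGene,
             coding_fraction = codingBp / genomeBp,
             noncoding_bp = genomeBp - codingBp,
             intron_count = length(introns),
             intron_bp = sum(GenomicRanges::width(introns)),
             stringsAsFactors = FALSE)
}
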