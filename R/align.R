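# Local alignment (affine gaps) and gene-presence span scanning. The DP
# kernel lives in src/align.cpp (Gotoh): BLASTN-like scoring with match +1,
# mismatch -1, gap open -4, gap extend -1 by default (a gap of length L
# costs |gapOpen| + L * |gapExtend|), and N never matching anything.

#' Optimal local alignment with identity and coverage reporting
#'
#' Smith-Waterman local alignment under affine-gap scoring. Identity is
#' matches / aligned columns x 100 (gap columns count as columns, not
#' matches); query coverage is the fraction of the query length inside the
#' aligned region.
#'
#' @param query,target character (or DNAString) sequences.
#' @param match,mismatch,gapOpen,gapExtend scoring parameters (penalties
#'   are given as the usual negative values).
#' @return list with `identity` (percent), `query_coverage` (fraction),
#'   `aligned_span` (bp on target), `score`, and 0-based half-open
#'   `query_start`, `query_end`, `target_start`, `target_end`.
#' @examples
#' localAlign("ACGTACGTAC", "ACGTACGTAC")$identity
#' @export
localAlign <- function(query, target, match = 1, mismatch = -1,
                       gapOpen = -4, gapExtend = -1) {
  query <- as.character(query); target <- as.character(target)
  .assertThat(nzchar(query) && nzchar(target), "sequences must be non-empty")
  r <- cpp_align_local(query, target, match, abs(mismatch) * -1,
                       abs(gapOpen), abs(gapExtend), -6)
  if (r$score <= 0 || r$columns == 0L) {
    return(list(identity = 0, query_coverage = 0, aligned_span = 0L,
                score = 0, query_start = 0L, query_end = 0L,
                target_start = 0L, target_end = 0L))
  }
  list(identity = 100 * r$nmatch / r$columns,
       query_coverage = (r$query_end - r$query_start) / nchar(query),
       aligned_span = r$target_end - r$target_start,
       score = r$score,
       query_start = r$query_start, query_end = r$query_end,
       target_start = r$target_start, target_end = r$target_end)
}

#' Global (end-to-end) alignment returning the gapped aligned strings
#'
#' Needleman-Wunsch with the same affine-gap scheme as [localAlign()]. Used
#' internally for coding-region inspection; exported because it is handy
#' for examining planted lesions.
#'
#' @inheritParams localAlign
#' @return list with `score`, `pattern`, `subject` (gapped strings of equal
#'   length).
#' @export
globalAlign <- function(query, target, match = 1, mismatch = -1,
                        gapOpen = -4, gapExtend = -1) {
  query <- as.character(query); target <- as.character(target)
  .assertThat(nzchar(query) && nzchar(target), "sequences must be non-empty")
  cpp_align_global(query, target, match, abs(mismatch) * -1,
                   abs(gapOpen), abs(gapExtend), -6)
}

# Best-hit search: align one query against a catalog, returning per-target
# summaries. Used by the introgression filter.
.localAlignSet <- function(query, targets) {
  if (!length(targets)) return(NULL)
  query <- as.character(query)
  rows <- lapply(names(targets), function(nm) {
    r <- localAlign(query, as.character(targets[[nm]]))
    data.frame(target = nm, identity = r$identity,
               query_coverage = r$query_coverage, score = r$score,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Scan for the longest aligned spans of a gene in a subject
#'
#' Reports the best local-alignment span of `gene` against each subject
#' sequence (each chromosome of a [Genome-class], or each read of a
#' `DNAStringSet`), sorted by score. Supports the "longest aligned span much
#' shorter than the gene" diagnosis pattern used for hard-to-assemble loci:
#' a gene present in full yields a top span equal to its length at identity
#' 100, while a subject carrying only a fragment caps the span at the
#' fragment length.
#'
#' @param gene character or DNAString gene sequence.
#' @param subject a [Genome-class] or named `DNAStringSet`.
#' @param minReport minimum alignment score to report.
#' @return data.frame: `subject`, `span` (bp on subject), `identity`,
#'   `start`, `end` (0-based half-open on the subject sequence), `strand`,
#'   `score`; sorted by decreasing score.
#' @export
scanGenePresence <- function(gene, subject, minReport = 25) {
  gene <- as.character(gene)
  .assertThat(nzchar(gene), "gene must be non-empty")
  seqs <- if (is(subject, "Genome")) as.character(chromSeqs(subject))
          else as.character(subject)
  .assertThat(!is.null(names(seqs)), "subject sequences must be named")
  rows <- list()
  for (nm in names(seqs)) {
    for (strand in c("+", "-")) {
      g <- if (strand == "+") gene else .revcomp(gene)
      r <- localAlign(g, seqs[[nm]])
      if (r$score >= minReport) {
        rows[[length(rows) + 1L]] <- data.frame(
          subject = nm, span = r$aligned_span, identity = r$identity,
          start = r$target_start, end = r$target_end, strand = strand,
          score = r$score, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(subject = character(), span = integer(),
                      identity = numeric(), start = integer(), end = integer(),
                      strand = character(), score = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(-out$score, out$subject), , drop = FALSE]
  rownames(out) <- NULL
  out
}
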