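# Synthetic-genome primitives: ancestor generation, per-branch substitution,
# and planting of structural variants, Ty elements and diverged ORFs, each
# returning machine-readable truth records. All coordinates are 0-based
# half-open.

#' Generate a random ancestral genome
#'
#' Draws i.i.d. bases at the requested GC content. Deterministic for a fixed
#' seed: the same call yields byte-identical sequences.
#'
#' @param nChroms number of chromosomes.
#' @param chromLengths integer vector of chromosome lengths (bp), length
#'   `nChroms`.
#' @param gc GC fraction in `[0, 1]`.
#' @param seed integer RNG seed.
#' @param strain strain name for the returned genome.
#' @param chromNames optional chromosome names (default `chrI`, `chrII`, ...).
#' @return A [Genome-class].
#' @examples
#' anc <- generateAncestor(2, c(10000, 8000), gc = 0.38, seed = 7)
#' chromLengths(anc)
#' @export
generateAncestor <- function(nChroms, chromLengths, gc = 0.38, seed,
                             strain = "ancestor", chromNames = NULL) {
  .assertThat(.isCount(nChroms), "nChroms must be a positive count")
  .assertThat(length(chromLengths) == nChroms,
              "chromLengths must have one entry per chromosome")
  .assertThat(all(chromLengths > 0), "chromosome lengths must be positive")
  .assertThat(.isFraction(gc), "gc must lie in [0, 1]")
  if (is.null(chromNames)) {
    rom <- as.character(utils::as.roman(seq_len(nChroms)))
    chromNames <- paste0("chr", rom)
  }
  .assertThat(!anyDuplicated(chromNames), "chromosome names must be unique")
  seqs <- .withSeed(seed, {
    vapply(chromLengths, function(n) .randomSeq(n, gc), character(1))
  })
  names(seqs) <- chromNames
  Genome(strain, seqs)
}

#' Apply i.i.d. substitutions along a branch
#'
#' Each site is independently substituted with probability `rate` to a
#' uniformly chosen different base. Sites inside `exclude` intervals are
#' left untouched (used to keep planted-feature coordinates and gene
#' sequences exact). Genome length is unchanged.
#'
#' @param genome a [Genome-class].
#' @param rate substitutions per site in `[0, 0.25]`.
#' @param seed integer RNG seed.
#' @param exclude optional data.frame (chrom, start, end), 0-based half-open,
#'   of intervals protected from substitution.
#' @param strain name for the returned genome (default: unchanged).
#' @return list with `genome` (the mutated [Genome-class]) and
#'   `substitutions` (data.frame: chrom, pos, ref_base, alt_base; pos 0-based).
#' @export
applySubstitutions <- function(genome, rate, seed, exclude = NULL, strain = NULL) {
  .assertThat(is.numeric(rate) && length(rate) == 1L && rate >= 0 && rate <= 0.25,
              "rate must lie in [0, 0.25]")
  seqs <- as.character(chromSeqs(genome))
  recs <- list()
  alt1 <- c(A = "C", C = "A", G = "A", T = "A")
  alt2 <- c(A = "G", C = "G", G = "C", T = "C")
  alt3 <- c(A = "T", C = "T", G = "T", T = "G")
  .withSeed(seed, {
    for (chrom in names(seqs)) {
      n <- nchar(seqs[[chrom]])
      if (rate == 0 || n == 0L) next
      hit <- which(stats::runif(n) < rate)   # 1-based site indices
      if (!is.null(exclude)) {
        ex <- exclude[exclude$chrom == chrom, , drop = FALSE]
        if (nrow(ex)) {
          keep <- rep(TRUE, length(hit))
          for (i in seq_len(nrow(ex)))
            keep <- keep & !(hit > ex$start[i] & hit <= ex$end[i])
          hit <- hit[keep]
        }
      }
      if (!length(hit)) next
      ch <- strsplit(seqs[[chrom]], "", fixed = TRUE)[[1]]
      ref <- ch[hit]
      ok <- ref %in% c("A", "C", "G", "T")
      hit <- hit[ok]; ref <- ref[ok]
      if (!length(hit)) next
      pick <- sample.int(3L, length(hit), replace = TRUE)
      alt <- ifelse(pick == 1L, alt1[ref], ifelse(pick == 2L, alt2[ref], alt3[ref]))
      ch[hit] <- alt
      seqs[[chrom]] <- paste(ch, collapse = "")
      recs[[chrom]] <- data.frame(chrom = chrom, pos = hit - 1L,
                                  ref_base = unname(ref), alt_base = unname(alt),
                                  stringsAsFactors = FALSE)
    }
  })
  subs <- if (length(recs)) do.call(rbind, recs) else
    data.frame(chrom = character(), pos = integer(),
               ref_base = character(), alt_base = character(),
               stringsAsFactors = FALSE)
  rownames(subs) <- NULL
  out <- Genome(strain %||% strainName(genome), seqs)
  list(genome = out, substitutions = subs)
}

#' Plant one structural variant
#'
#' Applies a single event of one of the five types to the current genome:
#' `DEL` removes `size` bp at `pos`; `INS` inserts `size` random bp at `pos`;
#' `DUP` appends an adjacent tandem copy of `[pos, pos+size)`; `INV` replaces
#' the segment with its reverse complement; `TRA` moves the terminal segment
#' `[pos, chromLength)` of `chrom` onto the end of `toChrom` (terminal
#' translocation; `size` must equal `chromLength - pos`).
#'
#' Positions refer to the genome as passed in. Builders planting several
#' events track coordinate shifts themselves (see [simulatePanel()]).
#'
#' @param genome a [Genome-class].
#' @param type one of `DEL`, `INS`, `DUP`, `INV`, `TRA`.
#' @param chrom chromosome carrying the event (the donor for `TRA`).
#' @param pos 0-based start of the affected segment.
#' @param size event size in bp (>= 1).
#' @param payloadSeed RNG seed for `INS` payload sequence.
#' @param toChrom acceptor chromosome (TRA only).
#' @param gc GC fraction of inserted payload.
#' @return list with `genome` and `record`, a one-row data.frame
#'   (type, chrom, pos, end, size, to_chrom, to_pos) where `to_pos` is the
#'   0-based start of the moved segment on the acceptor (TRA) or `NA`.
#' @export
plantSV <- function(genome, type, chrom, pos, size, payloadSeed = 1L,
                    toChrom = NA_character_, gc = 0.38) {
  type <- match.arg(type, c("DEL", "INS", "DUP", "INV", "TRA"))
  len <- chromLengths(genome)
  .assertThat(chrom %in% names(len), sprintf("unknown chromosome '%s'", chrom))
  .assertThat(.isCount(size), "size must be a positive count")
  n <- len[[chrom]]
  .assertThat(pos >= 0 && pos <= n, "pos out of bounds")
  toPos <- NA_integer_
  s <- getChrom(genome, chrom)
  if (type == "TRA") {
    .assertThat(!is.na(toChrom) && toChrom %in% names(len) && toChrom != chrom,
                "TRA needs a distinct acceptor chromosome")
    .assertThat(pos + size == n,
                "TRA is modeled as terminal-segment transfer: pos + size must equal the donor length")
    seg <- substr(s, pos + 1L, n)
    genome <- .setChrom(genome, chrom, substr(s, 1L, pos))
    acc <- getChrom(genome, toChrom)
    toPos <- nchar(acc)
    genome <- .setChrom(genome, toChrom, paste0(acc, seg))
  } else {
    .assertThat(pos + size <= n || type == "INS",
                sprintf("interval [%d,%d) out of bounds for %s", pos, pos + size, chrom))
    if (type == "DEL") {
      genome <- .setChrom(genome, chrom,
                          paste0(substr(s, 1L, pos), substr(s, pos + size + 1L, n)))
    } else if (type == "INS") {
      payload <- .withSeed(payloadSeed, .randomSeq(size, gc))
      genome <- .setChrom(genome, chrom,
                          paste0(substr(s, 1L, pos), payload, substr(s, pos + 1L, n)))
    } else if (type == "DUP") {
      seg <- substr(s, pos + 1L, pos + size)
      genome <- .setChrom(genome, chrom,
                          paste0(substr(s, 1L, pos + size), seg, substr(s, pos + size + 1L, n)))
    } else if (type == "INV") {
      seg <- substr(s, pos + 1L, pos + size)
      genome <- .setChrom(genome, chrom,
                          paste0(substr(s, 1L, pos), .revcomp(seg), substr(s, pos + size + 1L, n)))
    }
  }
  record <- data.frame(type = type, chrom = chrom, pos = as.integer(pos),
                       end = as.integer(pos + size), size = as.integer(size),
                       to_chrom = toChrom, to_pos = toPos,
                       stringsAsFactors = FALSE)
  list(genome = genome, record = record)
}

#' Plant one Ty element
#'
#' Inserts a retrotransposon locus built from the library consensus at `pos`:
#' `solo_LTR` inserts one LTR copy; `complete` inserts LTR + internal + LTR;
#' `truncated` inserts LTR + internal-with-a-deleted-central-block + LTR.
#' For states carrying coding sequence, `viability = "loss_of_function"`
#' introduces a lesion: an in-frame premature stop codon (default) or a 1-bp
#' coding deletion (`lesion = "frameshift"`). Truncated elements are
#' loss-of-function by construction (a large internal deletion).
#'
#' @param genome a [Genome-class].
#' @param library a [TyLibrary-class].
#' @param class Ty class name present in the library.
#' @param state one of `complete`, `truncated`, `solo_LTR`.
#' @param viability `functional`, `loss_of_function`, or `not_applicable`
#'   (mandatory and only valid for `solo_LTR`).
#' @param chrom,pos insertion site (0-based).
#' @param lesion lesion type for loss-of-function: `premature_stop` or
#'   `frameshift`.
#' @param truncationBp size of the internal block deleted in `truncated`
#'   state (default 2000 bp, centered on the internal region).
#' @return list with `genome` and `record` (one-row data.frame: class, state,
#'   viability, chrom, start, end, lesion).
#' @export
plantTyElement <- function(genome, library, class, state, viability, chrom, pos,
                           lesion = c("premature_stop", "frameshift"),
                           truncationBp = 2000L) {
  .assertThat(class %in% names(library@classes), sprintf("unknown Ty class '%s'", class))
  state <- match.arg(state, c("complete", "truncated", "solo_LTR"))
  viability <- match.arg(viability, c("functional", "loss_of_function", "not_applicable"))
  lesion <- match.arg(lesion)
  if (state == "solo_LTR") {
    .assertThat(viability == "not_applicable",
                "solo_LTR carries no coding sequence: viability must be not_applicable")
  } else {
    .assertThat(viability != "not_applicable",
                "states carrying coding sequence need functional or loss_of_function")
  }
  if (state == "truncated")
    .assertThat(viability == "loss_of_function",
                "a truncated internal region implies loss_of_function")
  e <- library@classes[[class]]
  ltr <- as.character(e$ltr)
  internal <- as.character(e$internal)
  lesionApplied <- "none"
  if (state == "complete" && viability == "loss_of_function") {
    internal <- .applyCodingLesion(internal, e$coding, lesion)
    lesionApplied <- lesion
  }
  if (state == "truncated") {
    ilen <- nchar(internal)
    .assertThat(truncationBp < ilen, "truncation must be smaller than the internal region")
    from <- max(1L, as.integer((ilen - truncationBp) %/% 2))
    internal <- paste0(substr(internal, 1L, from - 1L),
                       substr(internal, from + truncationBp, ilen))
    lesionApplied <- sprintf("internal_deletion_%dbp", truncationBp)
  }
  insert <- switch(state,
                   solo_LTR = ltr,
                   complete = paste0(ltr, internal, ltr),
                   truncated = paste0(ltr, internal, ltr))
  s <- getChrom(genome, chrom)
  .assertThat(pos >= 0 && pos <= nchar(s), "pos out of bounds")
  genome <- .setChrom(genome, chrom,
                      paste0(substr(s, 1L, pos), insert, substr(s, pos + 1L, nchar(s))))
  record <- data.frame(class = class, state = state, viability = viability,
                       chrom = chrom, start = as.integer(pos),
                       end = as.integer(pos + nchar(insert)),
                       lesion = lesionApplied, stringsAsFactors = FALSE)
  list(genome = genome, record = record)
}

# Introduce a loss-of-function lesion into the first coding region of an
# internal consensus: an in-frame stop codon at ~40% of the region, or a
# 1-bp deletion at the same point.
.applyCodingLesion <- function(internal, coding, lesion) {
  cd <- coding[1, ]
  codons <- (cd$end - cd$start) %/% 3L
  at <- cd$start + cd$frame + 3L * floor(codons * 0.4)   # codon-aligned, 0-based
  if (lesion == "premature_stop") {
    paste0(substr(internal, 1L, at), "TAA",
           substr(internal, at + 4L, nchar(internal)))
  } else {
    paste0(substr(internal, 1L, at),
           substr(internal, at + 2L, nchar(internal)))
  }
}

#' Plant diverged (introgressed-like) ORF copies in focal strains
#'
#' Applies substitutions at the target divergence to the listed ORFs in
#' every focal strain's catalog, modelling a single introgression event:
#' one substitution set is drawn per ORF and shared by all focal copies,
#' so focal copies stay identical to each other while diverging from the
#' untouched non-focal copies. Lengths are preserved (substitution-only).
#'
#' @param catalogs named list of `DNAStringSet` ORF catalogs (one per strain).
#' @param orfIds ORF ids to diverge; must exist in all focal catalogs.
#' @param divergence substitutions per site in `[0, 0.25]`.
#' @param focalStrains names of the focal-clade strains.
#' @param seed integer RNG seed.
#' @return list with `catalogs` (modified) and `truth` (data.frame: orf_id,
#'   divergence, n_substitutions, focal_strains).
#' @export
plantIntrogressedORFs <- function(catalogs, orfIds, divergence, focalStrains, seed) {
  .assertThat(is.numeric(divergence) && divergence >= 0 && divergence <= 0.25,
              "divergence must lie in [0, 0.25]")
  .assertThat(all(focalStrains %in% names(catalogs)), "unknown focal strain")
  for (f in focalStrains)
    .assertThat(all(orfIds %in% names(catalogs[[f]])),
                sprintf("ORF id missing from focal catalog '%s'", f))
  truth <- data.frame(orf_id = character(), divergence = numeric(),
                      n_substitutions = integer(), focal_strains = character(),
                      stringsAsFactors = FALSE)
  for (orf in orfIds) {
    template <- as.character(catalogs[[focalStrains[1]]][[orf]])
    n <- nchar(template)
    mut <- .withSeed(.deriveSeed(seed, "introgress", orf), {
      hit <- which(stats::runif(n) < divergence)
      list(hit = hit, pick = sample.int(3L, length(hit), replace = TRUE))
    })
    diverged <- .substituteAt(template, mut$hit, mut$pick)
    for (f in focalStrains) {
      cat_f <- as.character(catalogs[[f]])
      cat_f[[orf]] <- diverged
      catalogs[[f]] <- Biostrings::DNAStringSet(cat_f)
    }
    truth <- rbind(truth, data.frame(
      orf_id = orf, divergence = divergence, n_substitutions = length(mut$hit),
      focal_strains = paste(focalStrains, collapse = ","),
      stringsAsFactors = FALSE))
  }
  list(catalogs = catalogs, truth = truth)
}

# Substitute at 1-based sites using a 1..3 "which other base" pick.
.substituteAt <- function(seq, hit, pick) {
  if (!length(hit)) return(seq)
  alt1 <- c(A = "C", C = "A", G = "A", T = "A")
  alt2 <- c(A = "G", C = "G", G = "C", T = "C")
  alt3 <- c(A = "T", C = "T", G = "T", T = "G")
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  ref <- ch[hit]
  ch[hit] <- ifelse(pick == 1L, alt1[ref], ifelse(pick == 2L, alt2[ref], alt3[ref]))
  paste(ch, collapse = "")
}

#' Substitute a sequence at an exact number of evenly spaced sites
#'
#' Deterministic helper for boundary fixtures: places exactly `nSubs`
#' substitutions at evenly spaced positions (never in the first or last
#' `margin` bp), so downstream identity is controlled to the base.
#'
#' @param seq character sequence.
#' @param nSubs exact number of substitutions.
#' @param seed RNG seed (chooses replacement bases only).
#' @param margin bp at each end kept substitution-free.
#' @return modified character sequence.
#' @export
substituteExact <- function(seq, nSubs, seed = 1L, margin = 10L) {
  n <- nchar(seq)
  .assertThat(nSubs <= n - 2L * margin, "too many substitutions for sequence length")
  if (nSubs == 0L) return(seq)
  sites <- round(seq.int(margin + 1L, n - margin, length.out = nSubs))
  sites <- unique(as.integer(sites))
  .assertThat(length(sites) == nSubs, "could not place distinct evenly spaced sites")
  pick <- .withSeed(seed, sample.int(3L, nSubs, replace = TRUE))
  .substituteAt(seq, sites, pick)
}
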