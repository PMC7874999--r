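# Ty consensus library: construction, validation, and FASTA+YAML interchange.

#' Construct a TyLibrary
#'
#' @param classes named list; each element a list with `ltr`, `internal`
#'   (character or DNAString) and `coding` (data.frame: start, end, frame;
#'   0-based half-open on the internal consensus).
#' @return A [TyLibrary-class].
#' @export
TyLibrary <- function(classes) {
  classes <- lapply(classes, function(e) {
    list(ltr = Biostrings::DNAString(as.character(e$ltr)),
         internal = Biostrings::DNAString(as.character(e$internal)),
         coding = data.frame(start = as.integer(e$coding$start),
                             end = as.integer(e$coding$end),
                             frame = as.integer(e$coding$frame)))
  })
  new("TyLibrary", classes = classes)
}

# Random open reading frame: ATG + non-stop codons + TAA, length bp total
# (length must be a multiple of 3).
.randomORF <- function(length) {
  stopifnot(length %% 3 == 0, length >= 9)
  nCodon <- length %/% 3 - 2L
  bases <- c("A", "C", "G", "T")
  codons <- character(nCodon)
  i <- 1L
  while (i <= nCodon) {
    cd <- paste(sample(bases, 3, replace = TRUE), collapse = "")
    if (!cd %in% c("TAA", "TAG", "TGA")) { codons[i] <- cd; i <- i + 1L }
  }
  paste0("ATG", paste(codons, collapse = ""), "TAA")
}

#' Synthetic default Ty consensus library
#'
#' Builds a deterministic synthetic stand-in for a curated Ty1-Ty5 consensus
#' set: per class, a random LTR consensus and an internal consensus whose
#' coding region(s) form intact reading frames (ATG ... stop). Class
#' consensus sequences are mutually unrelated random sequences; LTR and
#' internal lengths are in the range of real yeast elements (LTRs ~250-370
#' bp; internal regions ~5 kb, with the Ty5 internal region 4972 bp so a
#' 2-kb truncation removes ~40% of it). Entirely synthetic - it reproduces
#' the structure of a Ty library, not real consensus sequence.
#'
#' @param seed RNG seed (fixed default so every caller sees one library).
#' @return A [TyLibrary-class].
#' @export
defaultTyLibrary <- function(seed = 1003L) {
  lengths <- list(
    Ty1 = list(ltr = 334L, coding = c(1302L, 3897L)),  # two ORFs, gag/pol-like
    Ty2 = list(ltr = 332L, coding = c(5199L)),
    Ty3 = list(ltr = 340L, coding = c(4701L)),
    Ty4 = list(ltr = 371L, coding = c(5403L)),
    Ty5 = list(ltr = 251L, coding = c(4902L))
  )
  classes <- .withSeed(seed, {
    out <- list()
    for (nm in names(lengths)) {
      sp <- lengths[[nm]]
      ltr <- .randomSeq(sp$ltr, gc = 0.40)
      lead <- .randomSeq(30L, gc = 0.40)     # non-coding leader
      orfs <- vapply(sp$coding, .randomORF, character(1))
      spacer <- if (length(orfs) > 1L) .randomSeq(12L, gc = 0.40) else ""
      tail <- .randomSeq(40L, gc = 0.40)
      internal <- paste0(lead, paste(orfs, collapse = spacer), tail)
      starts <- integer(length(orfs)); ends <- integer(length(orfs))
      at <- nchar(lead)
      for (i in seq_along(orfs)) {
        starts[i] <- at
        ends[i] <- at + nchar(orfs[i])
        at <- ends[i] + nchar(spacer)
      }
      out[[nm]] <- list(ltr = ltr, internal = internal,
                        coding = data.frame(start = starts, end = ends,
                                            frame = 0L))
    }
    out
  })
  TyLibrary(classes)
}

#' Write / read a Ty library (FASTA with class|part headers + YAML frames)
#'
#' The FASTA holds one record per class and part, named `<class>|LTR` and
#' `<class>|internal`; the YAML file maps each class to its coding regions
#' (`start`, `end`, `frame`; 0-based half-open).
#'
#' @param library a [TyLibrary-class].
#' @param fastaPath,yamlPath output (or input) paths.
#' @return `writeTyLibrary` returns the paths invisibly; `readTyLibrary`
#'   returns a [TyLibrary-class].
#' @export
writeTyLibrary <- function(library, fastaPath, yamlPath) {
  seqs <- list()
  coding <- list()
  for (nm in names(library@classes)) {
    e <- library@classes[[nm]]
    seqs[[paste0(nm, "|LTR")]] <- as.character(e$ltr)
    seqs[[paste0(nm, "|internal")]] <- as.character(e$internal)
    coding[[nm]] <- lapply(seq_len(nrow(e$coding)), function(i)
      list(start = e$coding$start[i], end = e$coding$end[i],
           frame = e$coding$frame[i]))
  }
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(unlist(seqs)), fastaPath,
                              width = 60L)
  yaml::write_yaml(coding, yamlPath)
  invisible(c(fastaPath, yamlPath))
}

#' @rdname writeTyLibrary
#' @export
readTyLibrary <- function(fastaPath, yamlPath) {
  seqs <- Biostrings::readDNAStringSet(fastaPath)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  coding <- yaml::read_yaml(yamlPath)
  classes <- list()
  for (nm in names(coding)) {
    ltrKey <- paste0(nm, "|LTR"); intKey <- paste0(nm, "|internal")
    .assertThat(all(c(ltrKey, intKey) %in% names(seqs)),
                sprintf("library FASTA missing records for class '%s'", nm))
    cd <- do.call(rbind, lapply(coding[[nm]], as.data.frame))
    classes[[nm]] <- list(ltr = as.character(seqs[[ltrKey]]),
                          internal = as.character(seqs[[intKey]]),
                          coding = cd)
  }
  TyLibrary(classes)
}
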