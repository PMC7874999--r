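# Accessors and methods for the Genome class.

#' @describeIn Genome strain name accessor
#' @param object,x a `Genome`
#' @export
setGeneric("strainName", function(x) standardGeneric("strainName"))

#' @rdname Genome
#' @export
setMethod("strainName", "Genome", function(x) x@strain)

#' @describeIn Genome chromosome names
#' @export
setGeneric("chromNames", function(x) standardGeneric("chromNames"))

#' @rdname Genome
#' @export
setMethod("chromNames", "Genome", function(x) names(x@seqs))

#' @describeIn Genome named vector of chromosome lengths (bp)
#' @export
setGeneric("chromLengths", function(x) standardGeneric("chromLengths"))

#' @rdname Genome
#' @export
setMethod("chromLengths", "Genome", function(x) {
  stats::setNames(Biostrings::width(x@seqs), names(x@seqs))
})

#' @describeIn Genome the chromosome sequences as a `DNAStringSet`
#' @export
setGeneric("chromSeqs", function(x) standardGeneric("chromSeqs"))

#' @rdname Genome
#' @export
setMethod("chromSeqs", "Genome", function(x) x@seqs)

#' Extract a chromosome (or a 0-based half-open slice of it) as character
#'
#' @param genome a [Genome-class].
#' @param chrom chromosome name.
#' @param start,end optional 0-based half-open interval.
#' @return character sequence.
#' @export
getChrom <- function(genome, chrom, start = NULL, end = NULL) {
  .assertThat(chrom %in% chromNames(genome),
              sprintf("unknown chromosome '%s' in strain '%s'", chrom, strainName(genome)))
  s <- genome@seqs[[chrom]]
  if (is.null(start)) return(as.character(s))
  .assertThat(start >= 0 && end <= length(s) && end >= start,
              sprintf("interval [%d,%d) out of bounds for %s (length %d)",
                      start, end, chrom, length(s)))
  if (end == start) return("")
  as.character(Biostrings::subseq(s, start + 1L, end))
}

#' Replace a chromosome sequence (internal)
#' @noRd
.setChrom <- function(genome, chrom, seq) {
  seqs <- as.character(genome@seqs)
  seqs[[chrom]] <- seq
  Genome(genome@strain, seqs)
}

setMethod("show", "Genome", function(object) {
  len <- chromLengths(object)
  cat(sprintf("Genome of strain '%s': %d chromosome(s), %s bp total\n",
              object@strain, length(len), format(sum(len), big.mark = ",")))
  for (nm in names(len)) cat(sprintf("  %-12s %9d bp\n", nm, len[[nm]]))
})

setMethod("show", "TyLibrary", function(object) {
  cat(sprintf("TyLibrary with %d class(es)\n", length(object@classes)))
  for (nm in names(object@classes)) {
    e <- object@classes[[nm]]
    cat(sprintf("  %-8s LTR %4d bp, internal %5d bp, %d coding region(s)\n",
                nm, length(e$ltr), length(e$internal), nrow(e$coding)))
  }
})

setMethod("show", "PresenceAbsenceMatrix", function(object) {
  m <- object@mat
  tab <- table(factor(object@roles, c("focal", "other_conspecific", "outgroup")))
  cat(sprintf("PresenceAbsenceMatrix: %d gene(s) x %d strain(s) [%d focal, %d other, %d outgroup]\n",
              nrow(m), ncol(m), tab[["focal"]], tab[["other_conspecific"]],
              tab[["outgroup"]]))
  cat(sprintf("  present cells: %d / %d\n", sum(m), length(m)))
})

setMethod("show", "SVMatrix", function(object) {
  cat(sprintf("SVMatrix: %d strain(s), %d ordered comparison(s), %d SV call(s) total\n",
              length(object@strains), nrow(object@counts), sum(object@counts$total)))
})

#' @describeIn PresenceAbsenceMatrix gene ids (row order)
#' @param x a `PresenceAbsenceMatrix`
#' @export
setGeneric("paGenes", function(x) standardGeneric("paGenes"))

#' @rdname PresenceAbsenceMatrix
#' @export
setMethod("paGenes", "PresenceAbsenceMatrix", function(x) rownames(x@mat))

#' @describeIn PresenceAbsenceMatrix strain names (column order)
#' @export
setGeneric("paStrains", function(x) standardGeneric("paStrains"))

#' @rdname PresenceAbsenceMatrix
#' @export
setMethod("paStrains", "PresenceAbsenceMatrix", function(x) colnames(x@mat))

#' @describeIn PresenceAbsenceMatrix named role vector
#' @export
setGeneric("strainRoles", function(x) standardGeneric("strainRoles"))

#' @rdname PresenceAbsenceMatrix
#' @export
setMethod("strainRoles", "PresenceAbsenceMatrix", function(x) x@roles)

#' @describeIn PresenceAbsenceMatrix the logical incidence matrix
#' @export
setGeneric("paMatrix", function(x) standardGeneric("paMatrix"))

#' @rdname PresenceAbsenceMatrix
#' @export
setMethod("paMatrix", "PresenceAbsenceMatrix", function(x) x@mat)

#' @describeIn SVMatrix per-pair count table
#' @param x an `SVMatrix`
#' @export
setGeneric("svCounts", function(x) standardGeneric("svCounts"))

#' @rdname SVMatrix
#' @export
setMethod("svCounts", "SVMatrix", function(x) x@counts)

#' @describeIn SVMatrix panel strain names
#' @export
setGeneric("svStrains", function(x) standardGeneric("svStrains"))

#' @rdname SVMatrix
#' @export
setMethod("svStrains", "SVMatrix", function(x) x@strains)
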