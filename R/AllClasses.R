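#' @import methods
#' @importFrom Biostrings DNAString DNAStringSet reverseComplement
NULL

#' Genome: chromosome sequences for one strain
#'
#' A thin container pairing a strain name with its chromosome sequences
#' (a [Biostrings::DNAStringSet]). All comparome coordinates on a `Genome`
#' are 0-based half-open; conversion to 1-based happens only in the GFF3 and
#' report writers.
#'
#' @slot strain single strain name.
#' @slot seqs named `DNAStringSet`, one record per chromosome.
#' @export
setClass("Genome", representation(strain = "character", seqs = "DNAStringSet"))

setValidity("Genome", function(object) {
  msg <- character()
  if (length(object@strain) != 1L || is.na(object@strain) || !nzchar(object@strain))
    msg <- c(msg, "strain must be a single non-empty name")
  nm <- names(object@seqs)
  if (length(object@seqs) == 0L)
    msg <- c(msg, "genome must contain at least one chromosome")
  if (is.null(nm) || anyDuplicated(nm) || any(!nzchar(nm)))
    msg <- c(msg, "chromosomes must have unique non-empty names")
  if (length(msg)) msg else TRUE
})

#' Construct a Genome
#'
#' @param strain strain name.
#' @param seqs named `DNAStringSet` or named character vector of sequences.
#' @return A [Genome-class] object.
#' @examples
#' g <- Genome("toy", c(chrI = "ACGTACGT"))
#' chromLengths(g)
#' @export
Genome <- function(strain, seqs) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  new("Genome", strain = as.character(strain), seqs = seqs)
}

#' TyLibrary: consensus sequences for Ty retrotransposon classes
#'
#' Per class (Ty1..Ty5 by default): an LTR consensus, an internal-region
#' consensus, and the coding regions on the internal consensus. Coding
#' regions are 0-based half-open `(start, end)` with a `frame` offset
#' (0, 1, or 2) relative to `start`.
#'
#' @slot classes named list; each element a list with components `ltr`
#'   (DNAString), `internal` (DNAString), and `coding`
#'   (data.frame: start, end, frame).
#' @export
setClass("TyLibrary", representation(classes = "list"))

setValidity("TyLibrary", function(object) {
  msg <- character()
  cl <- object@classes
  if (length(cl) == 0L || is.null(names(cl)) || anyDuplicated(names(cl)))
    msg <- c(msg, "classes must be a uniquely named non-empty list")
  for (nm in names(cl)) {
    e <- cl[[nm]]
    if (is.null(e$ltr) || length(e$ltr) == 0L)
      msg <- c(msg, sprintf("%s: empty LTR consensus", nm))
    if (is.null(e$internal) || length(e$internal) == 0L)
      msg <- c(msg, sprintf("%s: empty internal consensus", nm))
    cd <- e$coding
    if (!is.data.frame(cd) || !all(c("start", "end", "frame") %in% names(cd)))
      msg <- c(msg, sprintf("%s: coding must be a data.frame(start, end, frame)", nm))
    else if (nrow(cd) && (any(cd$start < 0) || any(cd$end > length(e$internal)) ||
                          any(cd$end <= cd$start)))
      msg <- c(msg, sprintf("%s: coding regions must lie within the internal consensus", nm))
  }
  if (length(msg)) msg else TRUE
})

#' PresenceAbsenceMatrix: genes x strains incidence with strain roles
#'
#' Boolean incidence of gene (ortholog-group) presence across a strain
#' panel. Each strain carries a role tag: `focal` (the clade under test),
#' `other_conspecific`, or `outgroup` (stand-in for other species). The
#' gene-loss and introgression logic consume these roles.
#'
#' @slot mat logical matrix, rows = genes, columns = strains.
#' @slot roles named character vector (one per strain).
#' @export
setClass("PresenceAbsenceMatrix",
         representation(mat = "matrix", roles = "character"))

setValidity("PresenceAbsenceMatrix", function(object) {
  msg <- character()
  m <- object@mat
  if (!is.logical(m)) msg <- c(msg, "matrix cells must be logical")
  if ((nrow(m) > 0 && is.null(rownames(m))) || anyDuplicated(rownames(m)))
    msg <- c(msg, "gene ids must be unique row names")
  if (is.null(colnames(m)) || anyDuplicated(colnames(m)))
    msg <- c(msg, "strain names must be unique column names")
  if (anyNA(m)) msg <- c(msg, "every cell must be defined (no NA)")
  if (!identical(sort(names(object@roles)), sort(colnames(m))))
    msg <- c(msg, "roles must be named by the strain columns")
  if (!all(object@roles %in% c("focal", "other_conspecific", "outgroup")))
    msg <- c(msg, "roles must be focal / other_conspecific / outgroup")
  if (length(msg)) msg else TRUE
})

#' Construct a PresenceAbsenceMatrix
#'
#' @param mat logical matrix with gene row names and strain column names.
#' @param roles named character vector of strain roles
#'   (`focal`, `other_conspecific`, `outgroup`).
#' @return A [PresenceAbsenceMatrix-class].
#' @export
PresenceAbsenceMatrix <- function(mat, roles) {
  mode(mat) <- "logical"
  new("PresenceAbsenceMatrix", mat = mat, roles = roles[colnames(mat)])
}

#' SVMatrix: per-pair structural-variant counts for a strain panel
#'
#' One row per ordered (reference, query) strain pair (self pairs excluded:
#' n strains give n*(n-1) rows) with per-type counts and the total.
#'
#' @slot strains ordered strain names.
#' @slot counts data.frame: ref, qry, DEL, INS, DUP, INV, TRA, total.
#' @export
setClass("SVMatrix", representation(strains = "character", counts = "data.frame"))

setValidity("SVMatrix", function(object) {
  msg <- character()
  n <- length(object@strains)
  cnt <- object@counts
  need <- c("ref", "qry", "DEL", "INS", "DUP", "INV", "TRA", "total")
  if (!all(need %in% names(cnt))) msg <- c(msg, "counts missing required columns")
  else {
    if (any(cnt$ref == cnt$qry)) msg <- c(msg, "self pairs must be excluded")
    if (nrow(cnt) != n * (n - 1L))
      msg <- c(msg, sprintf("expected %d ordered pairs, got %d", n * (n - 1L), nrow(cnt)))
    if (!all(cnt$total == cnt$DEL + cnt$INS + cnt$DUP + cnt$INV + cnt$TRA))
      msg <- c(msg, "total must equal the sum of per-type counts")
  }
  if (length(msg)) msg else TRUE
})
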