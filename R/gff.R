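# Minimal GFF3 emission (1-based inclusive, ##gff-version 3). Reading goes
# through rtracklayer::import.

# features: data.frame(seqid, type, start, end, strand, id) with 0-based
# half-open start/end as used internally; converted here.
.writeGFF3 <- function(features, path, source = "comparome") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(features)) {
    lines <- sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\tID=%s",
                     features$seqid, source, features$type,
                     features$start + 1L, features$end, features$strand,
                     features$id)
    writeLines(lines, con)
  }
  invisible(path)
}

#' Write annotated Ty elements as GFF3
#'
#' Elements become `LTR_retrotransposon` features; solo LTRs become
#' `long_terminal_repeat` features. State, viability and class are carried
#' in the attributes.
#'
#' @param elements element data.frame from [annotateTy()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeTyGFF3 <- function(elements, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(elements)) {
    type <- ifelse(elements$state == "solo_LTR", "long_terminal_repeat",
                   "LTR_retrotransposon")
    lines <- sprintf(
      "%s\tcomparome\t%s\t%d\t%d\t.\t%s\t.\tID=ty%0d;class=%s;state=%s;viability=%s",
      elements$chrom, type, elements$start + 1L, elements$end,
      elements$strand, seq_len(nrow(elements)), elements$class,
      elements$state, elements$viability)
    writeLines(lines, con)
  }
  invisible(path)
}
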