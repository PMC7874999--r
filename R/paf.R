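# PAF interchange for alignment blocks. Standard 12-column PAF, 0-based
# half-open, query coordinates on the forward strand (column 5 is the
# strand). An `ns:i:` tag carries the seed count so a write/read round trip
# preserves every block field (nmatch holds the seed-covered column count,
# so identity reconstructs exactly). The per-seed detail is not serialized.

#' Write alignment blocks to a PAF file
#'
#' @param blocks data.frame of blocks from [alignGenomes()] / [chainSeeds()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writePAF <- function(blocks, path) {
  lines <- character(nrow(blocks))
  for (i in seq_len(nrow(blocks))) {
    b <- blocks[i, ]
    alen <- max(b$ref_end - b$ref_start, b$qry_end - b$qry_start)
    nmatch <- as.integer(round(b$identity * alen / 100))
    lines[i] <- paste(
      b$qry_chrom, b$qry_len, b$qry_start, b$qry_end, b$strand,
      b$ref_chrom, b$ref_len, b$ref_start, b$ref_end,
      nmatch, alen, 255L,
      sprintf("ns:i:%d", b$n_seeds),
      sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read alignment blocks from a PAF file
#'
#' @param path PAF file path.
#' @return data.frame of alignment blocks (the `seeds` list-column is empty:
#'   PAF does not carry per-seed detail, so SV calling on PAF-loaded blocks
#'   uses block-level gap analysis only).
#' @export
readPAF <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(.emptyBlocks())
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 12L)
      stop(sprintf("malformed PAF line %d: expected >= 12 columns, got %d",
                   i, length(f)), call. = FALSE)
    if (!f[5] %in% c("+", "-"))
      stop(sprintf("malformed PAF line %d: bad strand '%s'", i, f[5]), call. = FALSE)
    nseeds <- NA_integer_
    tags <- f[-(1:12)]
    ns <- grep("^ns:i:", tags, value = TRUE)
    if (length(ns)) nseeds <- as.integer(sub("^ns:i:", "", ns[1]))
    num <- suppressWarnings(as.numeric(f[c(2:4, 7:11)]))
    if (anyNA(num))
      stop(sprintf("malformed PAF line %d: non-numeric coordinate field", i),
           call. = FALSE)
    alen <- as.numeric(f[11])
    d <- data.frame(
      ref_chrom = f[6], ref_start = as.integer(f[8]), ref_end = as.integer(f[9]),
      ref_len = as.integer(f[7]),
      qry_chrom = f[1], qry_start = as.integer(f[3]), qry_end = as.integer(f[4]),
      qry_len = as.integer(f[2]),
      strand = f[5],
      identity = if (alen > 0) 100 * as.numeric(f[10]) / alen else 0,
      n_seeds = nseeds,
      stringsAsFactors = FALSE)
    d$seeds <- list(NULL)
    rows[[i]] <- d
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
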