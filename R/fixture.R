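# Fixture emission: write a simulated panel to disk (FASTA + GFF3 + ORF
# catalogs + truth TSVs + JSON manifest) and read the truth back. Output is
# a pure function of the configuration, so identical seeds give
# byte-identical trees (the manifest carries md5 checksums, no timestamps).

#' Default simulation configuration: a 7-strain panel
#'
#' Three focal strains (F1-F3) forming the clade under test, three other
#' conspecific strains (O1-O3) and one diverged outgroup stand-in (OG1),
#' evolved along a fixed tree (conspecific branches 0.002-0.004
#' substitutions/site, outgroup branch 0.10). Two chromosomes (40 kb gene
#' space, 60 kb variant space), 18 genes with mixed presence patterns
#' (core, focal-absent, sporadic), one planted SV per conspecific strain
#' covering all five types (including a terminal translocation), planted
#' Ty elements in several states, and two ORFs introgressed into the focal
#' clade at 8 percent divergence.
#'
#' @param seed master seed.
#' @return a [simConfig()] object.
#' @export
defaultSimConfig <- function(seed = 20260101L) {
  tree <- list(rate = 0, children = list(
    list(rate = 0.10, strain = "OG1"),
    list(rate = 0.004, children = list(
      list(rate = 0.004, strain = "O1"),
      list(rate = 0.004, strain = "O2"),
      list(rate = 0.004, strain = "O3"),
      list(rate = 0.004, children = list(
        list(rate = 0.002, strain = "F1"),
        list(rate = 0.002, strain = "F2"),
        list(rate = 0.002, strain = "F3")))))))
  roles <- c(F1 = "focal", F2 = "focal", F3 = "focal",
             O1 = "other_conspecific", O2 = "other_conspecific",
             O3 = "other_conspecific", OG1 = "outgroup")
  genes <- data.frame(
    gene_id = sprintf("gene%02d", 1:18), chrom = "chrI",
    start = 2000L + (0:17) * 2000L, length = 999L,
    pattern = c(rep("core", 12), "focal_absent", "focal_absent",
                "absent_in:O1;F1;F2;F3", "absent_in:OG1", "absent_in:F3",
                "core"),
    stringsAsFactors = FALSE)
  sv <- data.frame(
    strain = c("F1", "F2", "F3", "O1", "O3", "O2"),
    type = c("DEL", "INS", "INV", "DUP", "DEL", "TRA"),
    chrom = "chrII",
    pos = c(5000L, 15000L, 20000L, 28000L, 25000L, 52000L),
    size = c(300L, 250L, 400L, 220L, 500L, 8000L),
    to_chrom = c(NA, NA, NA, NA, NA, "chrI"),
    stringsAsFactors = FALSE)
  ty <- data.frame(
    strain = c("F1", "F2", "O2"),
    class = c("Ty1", "Ty3", "Ty5"),
    state = c("solo_LTR", "complete", "solo_LTR"),
    viability = c("not_applicable", "functional", "not_applicable"),
    chrom = "chrII",
    pos = c(10000L, 31000L, 40000L),
    lesion = NA_character_,
    stringsAsFactors = FALSE)
  intro <- data.frame(orf_id = c("gene03", "gene07"), divergence = 0.08,
                      stringsAsFactors = FALSE)
  simConfig(seed = seed, chromLengths = c(chrI = 40000L, chrII = 60000L),
            gc = 0.38, tree = tree, roles = roles, genePlan = genes,
            svPlan = sv, tyPlan = ty, introgressionPlan = intro)
}

#' Emit a simulated panel as a fixture directory
#'
#' Writes per-strain genome FASTA (60-column wrap), gene GFF3 and ORF
#' FASTA, the ancestor FASTA, the truth TSVs and a JSON manifest with md5
#' checksums. Identical configuration (including seed) yields a
#' byte-identical output tree.
#'
#' @param config a [simConfig()] object.
#' @param outdir output directory (created if missing).
#' @return the manifest, invisibly (also written as `manifest.json`).
#' @export
emitFixture <- function(config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  .assertThat(dir.exists(outdir), sprintf("cannot create output dir '%s'", outdir))
  panel <- simulatePanel(config)
  files <- character()
  wr <- function(rel) { files <<- c(files, rel); file.path(outdir, rel) }
  Biostrings::writeXStringSet(chromSeqs(panel$ancestor), wr("ancestor.fa"),
                              width = 60L)
  for (s in names(panel$genomes)) {
    Biostrings::writeXStringSet(chromSeqs(panel$genomes[[s]]),
                                wr(sprintf("%s.fa", s)), width = 60L)
    .writeGFF3(panel$annotations[[s]], wr(sprintf("%s.gff3", s)))
    Biostrings::writeXStringSet(panel$catalogs[[s]],
                                wr(sprintf("%s_orfs.fa", s)), width = 60L)
  }
  writeTruthTables(panel$truth, outdir)
  files <- c(files, paste0("truth_", names(panel$truth), ".tsv"))
  manifest <- list(
    seed = config$seed,
    strains = lapply(names(panel$genomes), function(s)
      list(strain = s, role = unname(panel$roles[[s]]),
           genome = sprintf("%s.fa", s), annotation = sprintf("%s.gff3", s),
           orfs = sprintf("%s_orfs.fa", s))),
    chrom_lengths = as.list(config$chromLengths),
    files = lapply(sort(files), function(f)
      list(path = f, md5 = unname(tools::md5sum(file.path(outdir, f))))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Write / read the truth tables of a simulated panel
#'
#' Five TSVs with headers (`truth_substitutions.tsv`, `truth_svs.tsv`,
#' `truth_ty.tsv`, `truth_gene_presence.tsv`,
#' `truth_introgressed_orfs.tsv`); the round trip is lossless.
#'
#' @param truth the `truth` list from [simulatePanel()].
#' @param dir directory.
#' @return `writeTruthTables` the dir, invisibly; `readTruthTables` the
#'   truth list.
#' @export
writeTruthTables <- function(truth, dir) {
  gp <- truth$gene_presence
  gpd <- data.frame(gene_id = rownames(gp),
                    as.data.frame(gp, optional = TRUE) * 1L,
                    check.names = FALSE, stringsAsFactors = FALSE)
  tabs <- list(substitutions = truth$substitutions, svs = truth$svs,
               ty = truth$ty, gene_presence = gpd,
               introgressed_orfs = truth$introgressed_orfs)
  for (nm in names(tabs))
    utils::write.table(tabs[[nm]], file.path(dir, sprintf("truth_%s.tsv", nm)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname writeTruthTables
#' @export
readTruthTables <- function(dir) {
  rd <- function(nm, colClasses = NA)
    utils::read.table(file.path(dir, sprintf("truth_%s.tsv", nm)),
                      sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                      colClasses = colClasses, check.names = FALSE)
  gpd <- rd("gene_presence")
  gp <- as.matrix(gpd[, -1, drop = FALSE]) == 1
  rownames(gp) <- gpd$gene_id
  list(substitutions = rd("substitutions"),
       svs = rd("svs", colClasses = c(to_chrom = "character")),
       ty = rd("ty"),
       gene_presence = gp,
       introgressed_orfs = rd("introgressed_orfs"))
}
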