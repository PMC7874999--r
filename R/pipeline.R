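# Pipeline orchestration: simulate -> align -> sv -> ty -> genes from one
# configuration, with a consolidated JSON report. Stages run in dependency
# order, fail fast with stage-named errors, and write into a write-once
# output tree. Every output is a pure function of the configuration and
# seed, so reruns are reproducible record for record.

.RUN_DEFAULTS <- list(
  seed = 1L,
  out = "comparome_run",
  stages = c("simulate", "align", "sv", "ty", "genes"),
  min_seed = 20L, max_gap = 100L, min_block = 1000L,
  sv_min_size = 50L,
  ty_min_identity = 80, ty_min_part_fraction = 0.5,
  align_strains = "conspecific"  # or "all"
)

#' Validate and normalize a run configuration
#'
#' Accepts a YAML path or a list; unknown keys are rejected by name,
#' defaults are filled in, and the normalized configuration re-validates
#' to itself.
#'
#' @param config YAML file path or named list.
#' @return normalized configuration list (class `RunConfig`).
#' @export
validateRunConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  .assertThat(is.list(config), "run config must be a list or YAML file")
  unknown <- setdiff(names(config), names(.RUN_DEFAULTS))
  if (length(unknown))
    stop(sprintf("unknown run-config key(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  cfg <- utils::modifyList(.RUN_DEFAULTS, config)
  .assertThat(all(cfg$stages %in% .RUN_DEFAULTS$stages),
              "stages must be a subset of simulate/align/sv/ty/genes")
  .assertThat(cfg$align_strains %in% c("conspecific", "all"),
              "align_strains must be 'conspecific' or 'all'")
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- c("RunConfig", "list")
  cfg
}

#' Run the full pipeline
#'
#' Executes the enabled stages in dependency order on a simulated panel:
#' `simulate` writes the fixture (genomes, annotations, ORF catalogs, truth
#' tables), `align` writes per-pair PAF alignments, `sv` classifies and
#' tabulates structural variants, `ty` annotates Ty elements and writes
#' composition tables, `genes` builds the presence/absence matrix, the two
#' gene-loss sets, the introgression candidates and per-strain content
#' summaries. A `report.json` with per-stage record counts and output
#' paths is written last.
#'
#' @param config run configuration (list or YAML path; see
#'   [validateRunConfig()]).
#' @param simConfig optional [simConfig()] object; by default
#'   [defaultSimConfig()] seeded from the run seed.
#' @return the report, invisibly.
#' @export
runPipeline <- function(config = list(), simConfig = NULL) {
  cfg <- validateRunConfig(config)
  t0 <- Sys.time()
  out <- cfg$out
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  sc <- simConfig %||% defaultSimConfig(seed = cfg$seed)
  report <- list(parameters = cfg[setdiff(names(cfg), "stages")],
                 stages = list())
  stageDirs <- list(simulate = "fixture", align = "align", sv = "sv",
                    ty = "ty", genes = "genes")
  fail <- function(stage, msg) stop(sprintf("[%s] %s", stage, msg), call. = FALSE)
  panel <- NULL; blocks <- NULL
  for (stage in .RUN_DEFAULTS$stages) {
    if (!stage %in% cfg$stages) next
    sdir <- file.path(out, stageDirs[[stage]])
    if (dir.exists(sdir) && length(list.files(sdir)))
      fail(stage, sprintf("output directory '%s' already populated (write-once tree)", sdir))
    dir.create(sdir, showWarnings = FALSE)
    if (stage == "simulate") {
      emitFixture(sc, sdir)
      panel <- simulatePanel(sc)
      report$stages$simulate <- list(
        dir = stageDirs$simulate, n_strains = length(panel$genomes),
        n_truth_svs = nrow(panel$truth$svs),
        n_truth_ty = nrow(panel$truth$ty),
        n_genes = nrow(panel$truth$gene_presence))
    } else if (stage == "align") {
      if (is.null(panel)) fail(stage, "missing upstream fixture: enable the simulate stage")
      strains <- names(panel$genomes)
      if (cfg$align_strains == "conspecific")
        strains <- strains[panel$roles[strains] != "outgroup"]
      design <- svComparisonDesign(strains)
      blocks <- list(); n <- 0L
      for (i in seq_len(nrow(design))) {
        key <- paste(design$ref[i], design$qry[i], sep = "__")
        b <- alignGenomes(panel$genomes[[design$ref[i]]],
                          panel$genomes[[design$qry[i]]],
                          minSeed = cfg$min_seed, maxGap = cfg$max_gap,
                          minBlock = cfg$min_block)
        blocks[[key]] <- b
        writePAF(b, file.path(sdir, paste0(key, ".paf")))
        n <- n + nrow(b)
      }
      report$stages$align <- list(dir = stageDirs$align,
                                  n_comparisons = nrow(design), n_blocks = n)
    } else if (stage == "sv") {
      if (is.null(blocks)) fail(stage, "missing upstream alignments: enable the align stage")
      allCalls <- list()
      for (key in names(blocks)) {
        calls <- callSVs(blocks[[key]], minSize = cfg$sv_min_size)
        if (nrow(calls)) {
          pair <- strsplit(key, "__", fixed = TRUE)[[1]]
          allCalls[[key]] <- cbind(ref_strain = pair[1], qry_strain = pair[2],
                                   calls, stringsAsFactors = FALSE)
        }
      }
      flat <- if (length(allCalls))
        do.call(rbind, c(allCalls, list(make.row.names = FALSE))) else
        cbind(ref_strain = character(), qry_strain = character(), .emptySVs())
      utils::write.table(flat, file.path(sdir, "calls.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      writeSVCalls(flat[, setdiff(names(flat), c("ref_strain", "qry_strain"))],
                   bedpePath = file.path(sdir, "calls.bedpe"))
      # per-pair count matrix from the calls
      pairs <- strsplit(names(blocks), "__", fixed = TRUE)
      cnt <- data.frame(ref = vapply(pairs, `[`, "", 1),
                        qry = vapply(pairs, `[`, "", 2),
                        stringsAsFactors = FALSE)
      for (ty in c("DEL", "INS", "DUP", "INV", "TRA"))
        cnt[[ty]] <- vapply(names(blocks), function(k) {
          if (is.null(allCalls[[k]])) 0L else sum(allCalls[[k]]$type == ty)
        }, 1L)
      cnt$total <- rowSums(cnt[, c("DEL", "INS", "DUP", "INV", "TRA")])
      mat <- new("SVMatrix", strains = unique(c(cnt$ref, cnt$qry)), counts = cnt)
      utils::write.table(cnt, file.path(sdir, "matrix.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      utils::write.table(summarizeSV(mat), file.path(sdir, "summary.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      report$stages$sv <- list(dir = stageDirs$sv, n_calls = nrow(flat),
                               n_pairs = nrow(cnt))
    } else if (stage == "ty") {
      if (is.null(panel)) fail(stage, "missing upstream fixture: enable the simulate stage")
      els <- list()
      for (s in names(panel$genomes)) {
        e <- annotateTy(panel$genomes[[s]], sc$tyLibrary,
                        minIdentity = cfg$ty_min_identity,
                        minPartFraction = cfg$ty_min_part_fraction)
        if (nrow(e)) {
          els[[s]] <- e
          writeTyGFF3(e, file.path(sdir, sprintf("%s_ty.gff3", s)))
        }
      }
      allEls <- if (length(els))
        do.call(rbind, c(els, list(make.row.names = FALSE))) else
        cbind(strain = character(), classifyElements(NULL))
      flat <- allEls[, setdiff(names(allEls), "components")]
      utils::write.table(flat, file.path(sdir, "elements.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      comp <- tySummary(allEls, normalize = TRUE)
      utils::write.table(comp, file.path(sdir, "composition.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      report$stages$ty <- list(dir = stageDirs$ty, n_elements = nrow(allEls))
    } else if (stage == "genes") {
      if (is.null(panel)) fail(stage, "missing upstream fixture: enable the simulate stage")
      pres <- panel$truth$gene_presence
      groups <- do.call(rbind, lapply(colnames(pres), function(s) {
        g <- rownames(pres)[pres[, s]]
        if (!length(g)) return(NULL)
        data.frame(group_id = g, strain = s, gene_id = g,
                   stringsAsFactors = FALSE)
      }))
      pam <- buildPresenceAbsence(groups, colnames(pres), panel$roles)
      losses <- candidateGeneLosses(pam)
      core <- missingCoreGenes(pam)
      focal <- names(panel$roles)[panel$roles == "focal"]
      nonFocal <- setdiff(names(panel$roles), focal)
      cands <- introgressionCandidates(panel$catalogs, focal, nonFocal)
      pm <- paMatrix(pam)
      utils::write.table(
        data.frame(gene_id = rownames(pm), pm * 1L, check.names = FALSE),
        file.path(sdir, "presence.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
      writeLines(losses, file.path(sdir, "candidate_losses.txt"))
      writeLines(core, file.path(sdir, "missing_core.txt"))
      utils::write.table(cands, file.path(sdir, "introgression.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      jsonlite::write_json(cands, file.path(sdir, "introgression.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
      summ <- do.call(rbind, lapply(names(panel$genomes), function(s) {
        ann <- panel$annotations[[s]]
        gr <- GenomicRanges::GRanges(
          ann$seqid, IRanges::IRanges(ann$start + 1L, ann$end),
          type = ann$type)
        cbind(strain = s, genomeContentSummary(panel$genomes[[s]], gr),
              stringsAsFactors = FALSE)
      }))
      utils::write.table(summ, file.path(sdir, "content_summary.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      report$stages$genes <- list(
        dir = stageDirs$genes, n_genes = nrow(pm),
        n_candidate_losses = length(losses), n_missing_core = length(core),
        n_introgression_pass = sum(cands$pass))
    }
  }
  report$software_version <- as.character(utils::packageVersion("comparome"))
  report$runtime_seconds <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(report)
}
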