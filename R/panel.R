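# Strain-panel simulation: a configured clade of genomes evolved along a
# strain tree, with planted structural variants, Ty elements,
# clade-restricted gene absences and diverged ORFs, plus exact truth tables
# for every planted feature.
#
# Design rules that keep the truth exact:
#  * substitutions are applied along the tree BEFORE planting, and planted
#    intervals (plus a one-seed margin) and gene intervals are excluded
#    from substitution;
#  * planted features and genes never overlap one another (validated);
#  * per strain, features are planted in ascending coordinate order
#    (terminal translocations last), tracking the per-chromosome length
#    offset so every truth record carries both ancestor-frame and
#    derived-frame coordinates.

SUBST_MARGIN <- 20L  # bp excluded around planted intervals (one seed length)

#' Build and validate a simulation configuration
#'
#' @param seed master RNG seed; every derived stream comes from it.
#' @param chromLengths named or unnamed integer vector of chromosome
#'   lengths.
#' @param gc GC fraction.
#' @param tree nested list describing the strain tree: internal nodes are
#'   `list(rate =, children = list(...))`, leaves are
#'   `list(rate =, strain = "name")`; `rate` is the substitution rate of
#'   the branch above the node (substitutions/site, in `[0, 0.25]`).
#' @param roles named character vector tagging every strain `focal`,
#'   `other_conspecific` or `outgroup`; at least 3 focal, 3 non-focal
#'   conspecific and 1 outgroup strains.
#' @param genePlan data.frame: `gene_id`, `chrom`, `start` (0-based),
#'   `length`, `pattern` (`core`, `focal_absent`, or `absent_in:A;B`).
#' @param svPlan data.frame: `strain`, `type`, `chrom`, `pos`, `size`,
#'   `to_chrom` (TRA only; NA otherwise). Ancestor coordinates.
#' @param tyPlan data.frame: `strain`, `class`, `state`, `viability`,
#'   `chrom`, `pos`, `lesion` (NA for none).
#' @param introgressionPlan data.frame: `orf_id`, `divergence`.
#' @param tyLibrary a [TyLibrary-class] (default [defaultTyLibrary()]).
#' @return validated config (class `SimConfig`, a list).
#' @export
simConfig <- function(seed, chromLengths, gc = 0.38, tree, roles,
                      genePlan = NULL, svPlan = NULL, tyPlan = NULL,
                      introgressionPlan = NULL, tyLibrary = defaultTyLibrary()) {
  cfg <- list(seed = as.integer(seed), chromLengths = chromLengths, gc = gc,
              tree = tree, roles = roles,
              genePlan = genePlan, svPlan = svPlan, tyPlan = tyPlan,
              introgressionPlan = introgressionPlan, tyLibrary = tyLibrary)
  class(cfg) <- c("SimConfig", "list")
  validateSimConfig(cfg)
  cfg
}

#' @rdname simConfig
#' @param config a `SimConfig`.
#' @export
validateSimConfig <- function(config) {
  .assertThat(all(config$chromLengths > 0), "chromosome lengths must be positive")
  .assertThat(.isFraction(config$gc), "gc must lie in [0, 1]")
  strains <- .treeStrains(config$tree)
  .assertThat(!anyDuplicated(strains), "strain names must be unique")
  .assertThat(all(sort(names(config$roles)) == sort(strains)),
              "roles must cover exactly the tree strains")
  .assertThat(sum(config$roles == "focal") >= 3,
              "panel needs a focal clade of at least 3 strains")
  .assertThat(sum(config$roles == "other_conspecific") >= 3,
              "panel needs at least 3 non-focal conspecific strains")
  .assertThat(sum(config$roles == "outgroup") >= 1,
              "panel needs at least 1 outgroup strain")
  rates <- .treeRates(config$tree)
  .assertThat(all(rates >= 0 & rates <= 0.25), "branch rates must lie in [0, 0.25]")
  chromNames <- .chromNamesFor(config)
  # planted intervals: within bounds and mutually non-overlapping per strain
  # (gene intervals count for every strain)
  per <- list()
  addIv <- function(strain, chrom, s, e, what) {
    .assertThat(chrom %in% chromNames, sprintf("%s names unknown chromosome '%s'", what, chrom))
    n <- config$chromLengths[[match(chrom, chromNames)]]
    .assertThat(s >= 0 && e <= n, sprintf("%s interval [%d,%d) out of bounds on %s", what, s, e, chrom))
    key <- strain
    per[[key]] <<- rbind(per[[key]],
                         data.frame(chrom = chrom, s = s, e = e, what = what))
  }
  if (!is.null(config$genePlan)) {
    for (i in seq_len(nrow(config$genePlan))) {
      g <- config$genePlan[i, ]
      for (s in strains) addIv(s, g$chrom, g$start, g$start + g$length,
                               paste0("gene ", g$gene_id))
    }
  }
  if (!is.null(config$svPlan)) {
    for (i in seq_len(nrow(config$svPlan))) {
      v <- config$svPlan[i, ]
      e <- if (v$type == "INS") v$pos + 1L else v$pos + v$size
      addIv(v$strain, v$chrom, v$pos, e, paste0("sv ", v$type))
      if (v$type == "TRA") {
        n <- config$chromLengths[[match(v$chrom, chromNames)]]
        .assertThat(v$pos + v$size == n, "TRA must move a terminal segment")
      }
    }
  }
  if (!is.null(config$tyPlan)) {
    for (i in seq_len(nrow(config$tyPlan))) {
      t <- config$tyPlan[i, ]
      .assertThat(t$class %in% names(config$tyLibrary@classes),
                  sprintf("tyPlan names unknown class '%s'", t$class))
      addIv(t$strain, t$chrom, t$pos, t$pos + 1L, paste0("ty ", t$class))
    }
  }
  for (s in names(per)) {
    iv <- per[[s]]
    for (ch in unique(iv$chrom)) {
      x <- iv[iv$chrom == ch, , drop = FALSE]
      x <- x[order(x$s), , drop = FALSE]
      if (nrow(x) > 1) {
        bad <- which(x$s[-1] < x$e[-nrow(x)])
        .assertThat(length(bad) == 0,
                    sprintf("planted features overlap in strain %s on %s (%s / %s)",
                            s, ch, x$what[bad[1]], x$what[bad[1] + 1L]))
      }
    }
  }
  invisible(config)
}

.treeStrains <- function(node) {
  if (!is.null(node$strain)) return(node$strain)
  unlist(lapply(node$children, .treeStrains))
}

.treeRates <- function(node) {
  c(node$rate %||% 0,
    if (is.null(node$strain)) unlist(lapply(node$children, .treeRates)))
}

.chromNamesFor <- function(config) {
  nm <- names(config$chromLengths)
  if (is.null(nm)) paste0("chr", as.character(utils::as.roman(
    seq_along(config$chromLengths)))) else nm
}

#' Simulate a full strain panel with truth tables
#'
#' Generates the ancestor, evolves it along the strain tree, applies gene
#' absences, plants the configured SVs and Ty elements, extracts per-strain
#' ORF catalogs and applies the introgression plan. Everything is a pure
#' function of the configuration (including its seed).
#'
#' @param config a [simConfig()] object.
#' @return list with `ancestor` ([Genome-class]), `genomes` (named list of
#'   panel [Genome-class]), `catalogs` (named list of `DNAStringSet`),
#'   `annotations` (named list of gene feature data.frames, 0-based
#'   half-open), `roles`, and `truth` (list of data.frames:
#'   `substitutions`, `svs`, `ty`, `gene_presence` as data.frame,
#'   `introgressed_orfs`).
#' @export
simulatePanel <- function(config) {
  validateSimConfig(config)
  chromNames <- .chromNamesFor(config)
  anc <- generateAncestor(length(config$chromLengths),
                          unname(config$chromLengths), gc = config$gc,
                          seed = .deriveSeed(config$seed, "ancestor"),
                          chromNames = chromNames)
  exclude <- .substitutionExclusions(config, chromNames)
  leaves <- .evolveTree(config$tree, anc, config$seed, exclude)
  strains <- .treeStrains(config$tree)
  genomes <- list(); subsAll <- list(); svAll <- list(); tyAll <- list()
  presence <- .genePresence(config, strains)
  catalogs <- list(); annots <- list()
  for (s in strains) {
    g <- Genome(s, as.character(chromSeqs(leaves[[s]])))
    subsAll[[s]] <- .diffGenomes(anc, g, s)
    g <- .applyGeneAbsences(g, config, presence, s)
    planted <- .plantStrainFeatures(g, config, s)
    g <- planted$genome
    if (nrow(planted$svs)) svAll[[s]] <- planted$svs
    if (nrow(planted$ty)) tyAll[[s]] <- planted$ty
    genomes[[s]] <- g
    ext <- .extractGenes(g, config, presence, s, planted$shifts)
    catalogs[[s]] <- ext$catalog
    annots[[s]] <- ext$features
  }
  introTruth <- data.frame(orf_id = character(), divergence = numeric(),
                           n_substitutions = integer(),
                           focal_strains = character(), stringsAsFactors = FALSE)
  if (!is.null(config$introgressionPlan) && nrow(config$introgressionPlan)) {
    focal <- names(config$roles)[config$roles == "focal"]
    for (i in seq_len(nrow(config$introgressionPlan))) {
      p <- config$introgressionPlan[i, ]
      r <- plantIntrogressedORFs(catalogs, p$orf_id, p$divergence, focal,
                                 seed = .deriveSeed(config$seed, "intro", p$orf_id))
      catalogs <- r$catalogs
      introTruth <- rbind(introTruth, r$truth)
    }
  }
  emptySubs <- data.frame(strain = character(), chrom = character(),
                          pos = integer(), ref_base = character(),
                          alt_base = character(), stringsAsFactors = FALSE)
  truth <- list(
    substitutions = if (length(subsAll)) do.call(rbind, c(subsAll, list(make.row.names = FALSE))) else emptySubs,
    svs = if (length(svAll)) do.call(rbind, c(svAll, list(make.row.names = FALSE))) else .emptyTruthSVs(),
    ty = if (length(tyAll)) do.call(rbind, c(tyAll, list(make.row.names = FALSE))) else .emptyTruthTy(),
    gene_presence = presence,
    introgressed_orfs = introTruth)
  list(ancestor = anc, genomes = genomes, catalogs = catalogs,
       annotations = annots, roles = config$roles, truth = truth)
}

.emptyTruthSVs <- function() {
  data.frame(strain = character(), type = character(), chrom = character(),
             pos = integer(), end = integer(), size = integer(),
             to_chrom = character(), to_pos = integer(),
             qry_pos = integer(), qry_end = integer(), stringsAsFactors = FALSE)
}

.emptyTruthTy <- function() {
  data.frame(strain = character(), class = character(), state = character(),
             viability = character(), chrom = character(), anc_pos = integer(),
             start = integer(), end = integer(), lesion = character(),
             stringsAsFactors = FALSE)
}

# Union of protected intervals (ancestor coordinates): every gene interval
# and every planted interval +- SUBST_MARGIN.
.substitutionExclusions <- function(config, chromNames) {
  iv <- list()
  add <- function(chrom, s, e)
    iv[[length(iv) + 1L]] <<- data.frame(chrom = chrom, start = max(0L, s - SUBST_MARGIN),
                                         end = e + SUBST_MARGIN)
  if (!is.null(config$genePlan))
    for (i in seq_len(nrow(config$genePlan))) {
      g <- config$genePlan[i, ]
      add(g$chrom, g$start, g$start + g$length)
    }
  if (!is.null(config$svPlan))
    for (i in seq_len(nrow(config$svPlan))) {
      v <- config$svPlan[i, ]
      add(v$chrom, v$pos, if (v$type == "INS") v$pos else v$pos + v$size)
    }
  if (!is.null(config$tyPlan))
    for (i in seq_len(nrow(config$tyPlan))) {
      t <- config$tyPlan[i, ]
      add(t$chrom, t$pos, t$pos)
    }
  if (!length(iv)) return(NULL)
  do.call(rbind, iv)
}

# Recursive branch evolution; returns named list of leaf genomes.
.evolveTree <- function(node, genome, seed, exclude, path = "root") {
  rate <- node$rate %||% 0
  if (rate > 0)
    genome <- applySubstitutions(genome, rate,
                                 seed = .deriveSeed(seed, "branch", path),
                                 exclude = exclude)$genome
  if (!is.null(node$strain)) {
    out <- list(genome)
    names(out) <- node$strain
    return(out)
  }
  res <- list()
  for (k in seq_along(node$children))
    res <- c(res, .evolveTree(node$children[[k]], genome, seed, exclude,
                              path = paste0(path, "/", k)))
  res
}

# Net substitution differences of a (pre-planting) strain vs the ancestor.
.diffGenomes <- function(anc, g, strain) {
  rows <- list()
  for (ch in chromNames(anc)) {
    a <- strsplit(getChrom(anc, ch), "", fixed = TRUE)[[1]]
    b <- strsplit(getChrom(g, ch), "", fixed = TRUE)[[1]]
    d <- which(a != b)
    if (length(d))
      rows[[ch]] <- data.frame(strain = strain, chrom = ch, pos = d - 1L,
                               ref_base = a[d], alt_base = b[d],
                               stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(strain = character(), chrom = character(),
                      pos = integer(), ref_base = character(),
                      alt_base = character(), stringsAsFactors = FALSE))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

.genePresence <- function(config, strains) {
  gp <- config$genePlan
  if (is.null(gp) || !nrow(gp))
    return(matrix(logical(), 0, length(strains),
                  dimnames = list(NULL, strains)))
  focal <- names(config$roles)[config$roles == "focal"]
  m <- matrix(TRUE, nrow(gp), length(strains),
              dimnames = list(gp$gene_id, strains))
  for (i in seq_len(nrow(gp))) {
    pat <- gp$pattern[i]
    if (pat == "core") next
    if (pat == "focal_absent") m[i, focal] <- FALSE
    else if (startsWith(pat, "absent_in:")) {
      absent <- strsplit(sub("^absent_in:", "", pat), ";", fixed = TRUE)[[1]]
      .assertThat(all(absent %in% strains),
                  sprintf("gene pattern names unknown strain: %s", pat))
      m[i, absent] <- FALSE
    } else stop(sprintf("unknown gene pattern '%s'", pat), call. = FALSE)
  }
  m
}

# Replace the intervals of absent genes with neutral random sequence
# (length-preserving, so coordinates stay stable).
.applyGeneAbsences <- function(g, config, presence, strain) {
  gp <- config$genePlan
  if (is.null(gp) || !nrow(gp)) return(g)
  for (i in seq_len(nrow(gp))) {
    if (presence[gp$gene_id[i], strain]) next
    neutral <- .withSeed(.deriveSeed(config$seed, "absent", strain, gp$gene_id[i]),
                         .randomSeq(gp$length[i], config$gc))
    ch <- gp$chrom[i]; s <- gp$start[i]
    seq <- getChrom(g, ch)
    g <- .setChrom(g, ch, paste0(substr(seq, 1L, s), neutral,
                                 substr(seq, s + gp$length[i] + 1L, nchar(seq))))
  }
  g
}

# Plant the strain's SVs and Ty elements in ascending ancestor-coordinate
# order (TRA last), tracking per-chromosome offsets. Returns the planted
# genome, truth rows in both frames, and the shift table for gene
# extraction.
.plantStrainFeatures <- function(g, config, strain) {
  sv <- config$svPlan
  ty <- config$tyPlan
  sv <- if (is.null(sv)) NULL else sv[sv$strain == strain, , drop = FALSE]
  ty <- if (is.null(ty)) NULL else ty[ty$strain == strain, , drop = FALSE]
  feats <- list()
  if (!is.null(sv) && nrow(sv))
    for (i in seq_len(nrow(sv)))
      feats[[length(feats) + 1L]] <- c(list(kind = "sv"), as.list(sv[i, ]))
  if (!is.null(ty) && nrow(ty))
    for (i in seq_len(nrow(ty)))
      feats[[length(feats) + 1L]] <- c(list(kind = "ty"), as.list(ty[i, ]))
  svRows <- .emptyTruthSVs(); tyRows <- .emptyTruthTy()
  delta <- stats::setNames(rep(0L, length(chromNames(g))), chromNames(g))
  if (length(feats)) {
    isTra <- vapply(feats, function(f) f$kind == "sv" && f$type == "TRA", TRUE)
    ord <- order(isTra, vapply(feats, function(f) f$pos, 1))
    feats <- feats[ord]
    for (f in feats) {
      cur <- f$pos + delta[[f$chrom]]
      if (f$kind == "sv") {
        r <- plantSV(g, f$type, f$chrom, cur, f$size,
                     payloadSeed = .deriveSeed(config$seed, "ins", strain, f$pos),
                     toChrom = if (is.na(f$to_chrom)) NA_character_ else f$to_chrom,
                     gc = config$gc)
        g <- r$genome
        rec <- r$record
        svRows <- rbind(svRows, data.frame(
          strain = strain, type = f$type, chrom = f$chrom, pos = f$pos,
          end = f$pos + f$size, size = f$size, to_chrom = rec$to_chrom,
          to_pos = rec$to_pos, qry_pos = cur, qry_end = cur + f$size,
          stringsAsFactors = FALSE))
        delta[[f$chrom]] <- delta[[f$chrom]] + switch(
          f$type, DEL = -f$size, INS = f$size, DUP = f$size, INV = 0L,
          TRA = 0L)  # TRA planted last; offsets no longer used
      } else {
        r <- plantTyElement(g, config$tyLibrary, f$class, f$state, f$viability,
                            f$chrom, cur,
                            lesion = if (is.na(f$lesion)) "premature_stop" else f$lesion)
        g <- r$genome
        rec <- r$record
        tyRows <- rbind(tyRows, data.frame(
          strain = strain, class = f$class, state = f$state,
          viability = f$viability, chrom = f$chrom, anc_pos = f$pos,
          start = rec$start, end = rec$end, lesion = rec$lesion,
          stringsAsFactors = FALSE))
        delta[[f$chrom]] <- delta[[f$chrom]] + (rec$end - rec$start)
      }
    }
  }
  list(genome = g, svs = svRows, ty = tyRows, delta = delta,
       shifts = .shiftTable(feats))
}

# Per-chromosome breakpoints for coordinate shifting: each feature at
# ancestor pos p adds `shift` to every position > p.
.shiftTable <- function(feats) {
  if (!length(feats)) return(NULL)
  rows <- lapply(feats, function(f) {
    shift <- if (f$kind == "ty") NA_integer_ else switch(
      f$type, DEL = -f$size, INS = f$size, DUP = f$size, INV = 0L, TRA = 0L)
    data.frame(chrom = f$chrom, pos = f$pos, shift = shift,
               kind = f$kind, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

.shiftFor <- function(shifts, config, strain, chrom, pos) {
  if (is.null(shifts)) return(0L)
  x <- shifts[shifts$chrom == chrom & shifts$pos < pos, , drop = FALSE]
  if (!nrow(x)) return(0L)
  total <- 0L
  for (i in seq_len(nrow(x))) {
    if (x$kind[i] == "ty") {
      # Ty insert length depends on class/state; recompute from the plan
      tp <- config$tyPlan
      t <- tp[tp$strain == strain & tp$chrom == chrom & tp$pos == x$pos[i], ]
      e <- config$tyLibrary@classes[[t$class]]
      ltr <- length(e$ltr); int <- length(e$internal)
      total <- total + switch(t$state, solo_LTR = ltr,
                              complete = 2L * ltr + int,
                              truncated = 2L * ltr + int - 2000L)
    } else total <- total + x$shift[i]
  }
  total
}

# Extract the strain's present genes as its ORF catalog plus annotation rows.
.extractGenes <- function(g, config, presence, strain, shifts) {
  gp <- config$genePlan
  feats <- data.frame(seqid = character(), type = character(),
                      start = integer(), end = integer(), strand = character(),
                      id = character(), stringsAsFactors = FALSE)
  if (is.null(gp) || !nrow(gp))
    return(list(catalog = Biostrings::DNAStringSet(), features = feats))
  seqs <- character(); ids <- character()
  for (i in seq_len(nrow(gp))) {
    if (!presence[gp$gene_id[i], strain]) next
    sh <- .shiftFor(shifts, config, strain, gp$chrom[i], gp$start[i])
    s <- gp$start[i] + sh
    e <- s + gp$length[i]
    seqs <- c(seqs, getChrom(g, gp$chrom[i], s, e))
    ids <- c(ids, gp$gene_id[i])
    feats <- rbind(feats, data.frame(
      seqid = gp$chrom[i], type = "gene", start = s, end = e, strand = "+",
      id = gp$gene_id[i], stringsAsFactors = FALSE))
  }
  names(seqs) <- ids
  list(catalog = Biostrings::DNAStringSet(seqs), features = feats)
}
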