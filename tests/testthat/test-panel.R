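# Panel simulation: configuration validation, truth/emission consistency,
# conservation, fixture round trips.

test_that("configuration invariants are enforced", {
  cfg <- defaultSimConfig(seed = 5L)
  expect_s3_class(cfg, "SimConfig")
  # overlapping planted features are rejected
  bad <- cfg
  bad$svPlan$pos[1] <- bad$genePlan$start[1]
  bad$svPlan$chrom[1] <- "chrI"
  expect_error(validateSimConfig(bad), "overlap")
  bad2 <- cfg
  bad2$tree$children[[1]]$rate <- 0.5
  expect_error(validateSimConfig(bad2), "rate")
  bad3 <- cfg
  bad3$svPlan$pos[1] <- 10^7
  expect_error(validateSimConfig(bad3), "bounds")
})

test_that("every planted feature is recoverable by coordinate lookup", {
  cfg <- defaultSimConfig(seed = 11L)
  panel <- simulatePanel(cfg)
  anc <- panel$ancestor
  # Ty truth coordinates resolve to the exact inserted construct
  for (i in seq_len(nrow(panel$truth$ty))) {
    tr <- panel$truth$ty[i, ]
    lib <- cfg$tyLibrary@classes[[tr$class]]
    got <- getChrom(panel$genomes[[tr$strain]], tr$chrom, tr$start, tr$end)
    if (tr$state == "solo_LTR")
      expect_identical(got, as.character(lib$ltr))
    if (tr$state == "complete" && tr$viability == "functional")
      expect_identical(got, paste0(lib$ltr, lib$internal, lib$ltr))
  }
  # SV truths resolve in the derived frame
  for (i in seq_len(nrow(panel$truth$svs))) {
    tr <- panel$truth$svs[i, ]
    g <- panel$genomes[[tr$strain]]
    if (tr$type == "INV")
      expect_identical(getChrom(g, tr$chrom, tr$qry_pos, tr$qry_end),
                       rc(getChrom(anc, tr$chrom, tr$pos, tr$end)))
    if (tr$type == "DUP")
      expect_identical(getChrom(g, tr$chrom, tr$qry_end, tr$qry_end + tr$size),
                       getChrom(anc, tr$chrom, tr$pos, tr$end))
    if (tr$type == "TRA")
      expect_identical(chromLengths(g)[[tr$to_chrom]],
                       chromLengths(anc)[[tr$to_chrom]] + tr$size)
  }
  # substitution records replay exactly: applying them to the ancestor
  # reproduces the pre-planting strain sequence at those sites
  subs <- panel$truth$substitutions
  s1 <- subs[subs$strain == "O3" & subs$chrom == "chrI", ]
  a <- strsplit(getChrom(anc, "chrI"), "")[[1]]
  expect_identical(a[s1$pos + 1], s1$ref_base)
  expect_true(all(s1$ref_base != s1$alt_base))
})

test_that("sequence length obeys the conservation law", {
  cfg <- defaultSimConfig(seed = 13L)
  panel <- simulatePanel(cfg)
  ancTotal <- sum(chromLengths(panel$ancestor))
  sv <- panel$truth$svs; ty <- panel$truth$ty
  for (s in names(panel$genomes)) {
    gain <- sum(sv$size[sv$strain == s & sv$type %in% c("INS", "DUP")]) +
      sum((ty$end - ty$start)[ty$strain == s])
    loss <- sum(sv$size[sv$strain == s & sv$type == "DEL"])
    expect_identical(sum(chromLengths(panel$genomes[[s]])),
                     ancTotal + gain - loss)   # INV and TRA conserve length
  }
})

test_that("gene presence truth matches the emitted annotations exactly", {
  cfg <- defaultSimConfig(seed = 17L)
  out <- tempfile("fix")
  emitFixture(cfg, out)
  panel <- simulatePanel(cfg)
  for (s in names(panel$genomes)) {
    gr <- rtracklayer::import(file.path(out, sprintf("%s.gff3", s)))
    annotated <- as.character(gr$ID[gr$type == "gene"])
    expect_setequal(annotated,
                    rownames(panel$truth$gene_presence)[
                      panel$truth$gene_presence[, s]])
    # ORF catalog sequences equal the genome slice at the annotated interval
    orfs <- Biostrings::readDNAStringSet(file.path(out, sprintf("%s_orfs.fa", s)))
    g <- panel$genomes[[s]]
    plain <- which(!as.character(gr$ID) %in% cfg$introgressionPlan$orf_id)
    for (k in head(plain, 3)) {
      id <- as.character(gr$ID[k])
      got <- getChrom(g, as.character(GenomicRanges::seqnames(gr)[k]),
                      GenomicRanges::start(gr)[k] - 1L, GenomicRanges::end(gr)[k])
      expect_identical(got, as.character(orfs[[id]]))
    }
  }
})

test_that("fixtures are byte-identical across reruns and truth round-trips", {
  cfg <- defaultSimConfig(seed = 19L)
  d1 <- tempfile("fixA"); d2 <- tempfile("fixB")
  m1 <- emitFixture(cfg, d1)
  m2 <- emitFixture(cfg, d2)
  f1 <- vapply(m1$files, function(f) f$md5, "")
  f2 <- vapply(m2$files, function(f) f$md5, "")
  expect_identical(f1, f2)
  # truth tables survive TSV serialization losslessly
  panel <- simulatePanel(cfg)
  back <- readTruthTables(d1)
  expect_equal(back$svs, panel$truth$svs)
  expect_equal(back$ty, panel$truth$ty)
  expect_identical(back$gene_presence, panel$truth$gene_presence)
  expect_equal(back$substitutions, panel$truth$substitutions)
  expect_equal(back$introgressed_orfs, panel$truth$introgressed_orfs)
})
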