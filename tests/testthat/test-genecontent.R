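# Presence/absence matrices, gene-loss definitions, introgression filter,
# content summaries.

test_that("matrix construction tabulates groups with stable ordering", {
  groups <- data.frame(
    group_id = c("g1", "g1", "g2", "g3", "g3", "g3"),
    strain = c("A", "B", "C", "A", "B", "C"),
    gene_id = c("a1", "b1", "c2", "a3", "b3", "c3"),
    stringsAsFactors = FALSE)
  roles <- c(A = "focal", B = "other_conspecific", C = "outgroup")
  pam <- buildPresenceAbsence(groups, c("A", "B", "C"), roles)
  expect_identical(paGenes(pam), c("g1", "g2", "g3"))
  expect_identical(paStrains(pam), c("A", "B", "C"))
  expect_identical(unname(paMatrix(pam)["g1", ]), c(TRUE, TRUE, FALSE))
  expect_identical(unname(paMatrix(pam)["g2", ]), c(FALSE, FALSE, TRUE))
  # empty table: zero rows
  expect_identical(nrow(paMatrix(buildPresenceAbsence(groups[0, ],
                                                      c("A", "B", "C"), roles))), 0L)
  expect_error(buildPresenceAbsence(
    data.frame(group_id = "g", strain = "Z", gene_id = "z"),
    c("A", "B", "C"), roles), "Z")
})

test_that("loss definitions follow their set rules on labelled examples", {
  strains <- c("F1", "F2", "F3", paste0("O", 1:4), "G1", "G2")
  roles <- setNames(c(rep("focal", 3), rep("other_conspecific", 4),
                      rep("outgroup", 2)), strains)
  m <- matrix(TRUE, 4, 9, dimnames = list(paste0("g", 1:4), strains))
  m["g1", c("F1", "F2", "F3")] <- FALSE              # missing core + candidate
  m["g2", c("F1", "F2", "F3", "O1")] <- FALSE         # candidate, not core
  m["g3", c("F1", "F2", "F3", "G1", "G2")] <- FALSE   # no outgroup: not candidate
  m["g4", "F1"] <- FALSE                              # still in focal: neither
  pam <- PresenceAbsenceMatrix(m, roles)
  expect_setequal(candidateGeneLosses(pam), c("g1", "g2"))
  # the core definition ignores outgroups: g3 is core-missing but, lacking
  # any outgroup presence, not a candidate loss
  expect_identical(missingCoreGenes(pam), c("g1", "g3"))
  expect_error(candidateGeneLosses(pam, focal = character()), "non-empty")
})

test_that("loss sets match set-comprehension oracles on random matrices", {
  for (trial in 1:200) {
    pam <- randomPAM(60, seed = 1000 + trial)
    focal <- paste0("F", 1:3)
    expect_identical(candidateGeneLosses(pam, focal),
                     oracleCandidateLosses(paMatrix(pam), strainRoles(pam), focal))
    expect_identical(missingCoreGenes(pam, focal),
                     oracleMissingCore(paMatrix(pam), strainRoles(pam), focal))
    # missing core genes that survive in an outgroup are always candidates
    core <- missingCoreGenes(pam, focal)
    og <- paste0("G", 1:3)
    inOg <- core[rowSums(paMatrix(pam)[core, og, drop = FALSE]) >= 1]
    expect_true(all(inOg %in% candidateGeneLosses(pam, focal)))
  }
})

test_that("the introgression filter passes planted ORFs and fails each boundary", {
  fx <- simulateIntrogressionBenchmark(seed = 91)
  res <- introgressionCandidates(fx$catalogs, fx$focal, fx$others)
  r <- function(id) res[res$orf_id == id, ]
  p <- r("intro_pass")
  expect_true(p$pass)
  # identity ~ 92% within the central 99.9% binomial band for 8% divergence
  band <- 100 * (999 - rev(qbinom(c(0.0005, 0.9995), 999, 0.08))) / 999
  expect_gte(p$mean_identity, band[1])
  expect_lte(p$mean_identity, band[2])
  # coverage boundary: only the coverage criterion fails
  cv <- r("cov074")
  expect_false(cv$pass)
  expect_identical(cv$reason, "coverage")
  expect_lt(cv$mean_coverage, 0.75)
  expect_true(cv$pass_presence && cv$pass_identity && cv$pass_low_fraction)
  # presence boundary: found in two of three focal strains
  tw <- r("two_of_three")
  expect_false(tw$pass)
  expect_identical(tw$reason, "presence")
  expect_identical(tw$n_focal, 2L)
  expect_true(tw$pass_identity && tw$pass_coverage && tw$pass_low_fraction)
  # mean identity just above the cutoff, low fraction exactly two-thirds
  id95 <- r("id_above95")
  expect_false(id95$pass)
  expect_identical(id95$reason, "identity")
  expect_gt(id95$mean_identity, 95)
  expect_lt(id95$mean_identity, 95.3)
  expect_equal(id95$low_identity_fraction, 2 / 3)
  expect_true(id95$pass_presence && id95$pass_coverage && id95$pass_low_fraction)
  # undiverged background ORFs fail on identity
  expect_true(all(!res$pass[grepl("^core", res$orf_id)]))
  # mean identity exactly at the cutoff passes (inclusive comparison)
  expect_true(res$pass_identity[res$orf_id == "intro_pass"])
})

test_that("the filter is deterministic including best-hit tie-breaking", {
  fx <- simulateIntrogressionBenchmark(seed = 93)
  # duplicate one non-focal ORF under two ids: equal best scores, the
  # lexicographically smaller id must win, and reruns must be identical
  o1 <- fx$catalogs$O1
  dup <- as.character(o1)
  dup[["aaa_copy"]] <- dup[["intro_pass"]]
  fx$catalogs$O1 <- Biostrings::DNAStringSet(dup)
  r1 <- introgressionCandidates(fx$catalogs, fx$focal, fx$others)
  r2 <- introgressionCandidates(fx$catalogs, fx$focal, fx$others)
  expect_identical(r1, r2)
})

test_that("genome content summary reports sizes, coding fraction, introns", {
  g <- Genome("t", c(chrI = strrep("ACGTACGTAC", 1000)))  # 10 kb
  gr <- GenomicRanges::GRanges("chrI",
                               IRanges::IRanges(c(1, 3001, 6001), width = 1000),
                               type = "gene")
  s <- genomeContentSummary(g, gr)
  expect_identical(s$genome_bp, 10000L)
  expect_identical(s$gene_count, 3L)
  expect_identical(s$cumulative_gene_bp, 3000L)
  expect_equal(s$coding_fraction, 0.3)
  expect_identical(s$noncoding_bp, 7000L)
  # empty annotation
  s0 <- genomeContentSummary(g, gr[0])
  expect_identical(s0$gene_count, 0L)
  expect_identical(s0$noncoding_bp, 10000L)
  # out-of-bounds interval rejected
  bad <- GenomicRanges::GRanges("chrI", IRanges::IRanges(9800, 10400),
                                type = "gene")
  expect_error(genomeContentSummary(g, bad), "bounds")
})
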