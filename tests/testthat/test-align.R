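# Local alignment, identity/coverage reporting, gene-presence scanning.

test_that("identity and coverage contracts hold on constructed pairs", {
  set.seed(41)
  orf <- randSeq(300)
  r <- localAlign(orf, orf)
  expect_equal(r$identity, 100)
  expect_equal(r$query_coverage, 1.0)
  expect_equal(r$aligned_span, 300L)
  # exactly 15 substitutions, no indels: 285/300 matched columns
  mut <- substituteExact(orf, 15, seed = 2)
  r <- localAlign(orf, mut)
  expect_equal(r$identity, 95.0)
  expect_equal(r$query_coverage, 1.0)
  # target holding only the first half bounds coverage at one half
  r <- localAlign(orf, substr(orf, 1, 150))
  expect_equal(r$query_coverage, 0.5)
})

test_that("alignment scores agree with an independent DP implementation", {
  set.seed(43)
  for (trial in 1:25) {
    a <- randSeq(sample(50:300, 1))
    b <- randSeq(sample(50:300, 1))
    if (trial %% 2 == 0) b <- paste0(substr(a, 10, 120), b)  # related pair
    expect_equal(localAlign(a, b)$score, biostringsLocalScore(a, b))
  }
  # and on a controlled substitution pair the identity matches the
  # independent alignment's matched-column fraction
  a <- randSeq(400)
  b <- substituteExact(a, 20, seed = 1)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(1, -1, baseOnly = TRUE),
    gapOpening = 4, gapExtension = 1)
  expect_equal(localAlign(a, b)$identity,
               100 * Biostrings::nmatch(aln) / Biostrings::nchar(aln))
})

test_that("adding substitutions never increases identity (monotonicity)", {
  set.seed(47)
  a <- randSeq(400)
  sites <- sample(11:390, 60)
  picks <- sample.int(3, 60, replace = TRUE)
  prev <- 100
  for (k in seq(0, 60, by = 10)) {
    b <- comparome:::.substituteAt(a, sites[seq_len(k)], picks[seq_len(k)])
    id <- localAlign(a, b)$identity
    expect_lte(id, prev + 1e-9)
    prev <- id
  }
})

test_that("N bases never match in alignment", {
  a <- "ACGTACGTACGTNNNNACGTACGTACGT"
  r <- localAlign(a, a)
  # crossing the N block costs more than it gains, so the optimal local
  # alignment is one 12-bp arm
  expect_equal(r$score, 12)
  expect_equal(r$identity, 100)
  b <- localAlign("NNNNNNNN", "NNNNNNNN")
  expect_equal(b$score, 0)
})

test_that("gene-presence scan reports spans that diagnose truncation", {
  set.seed(51)
  gene <- randSeq(483)   # a short conserved gene
  background <- randSeq(8000)
  full <- Genome("s1", c(m = paste0(substr(background, 1, 3000), gene,
                                    substr(background, 3001, 8000))))
  hits <- scanGenePresence(gene, full)
  expect_identical(hits$span[1], 483L)
  expect_equal(hits$identity[1], 100)
  expect_identical(hits$start[1], 3000L)
  # subject carrying only the first 150 bp caps the reported span
  frag <- Genome("s2", c(m = paste0(substr(background, 1, 3000),
                                    substr(gene, 1, 150),
                                    substr(background, 3001, 8000))))
  hitsF <- scanGenePresence(gene, frag)
  expect_lte(hitsF$span[1], 160L)
  # absent gene: nothing above the reporting threshold
  none <- scanGenePresence(gene, Genome("s3", c(m = randSeq(4000))),
                           minReport = 60)
  expect_identical(nrow(none), 0L)
  # reverse-strand presence is found
  rev <- Genome("s4", c(m = paste0(substr(background, 1, 2000), rc(gene),
                                   substr(background, 2001, 4000))))
  hitsR <- scanGenePresence(gene, rev)
  expect_identical(hitsR$strand[1], "-")
  expect_identical(hitsR$span[1], 483L)
})
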