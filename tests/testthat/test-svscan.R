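# Structural-variant classification.

mkBlock <- function(rs, re, qs, qe, strand = "+", rc = "chrI", qc = "chrI") {
  d <- data.frame(ref_chrom = rc, ref_start = as.integer(rs),
                  ref_end = as.integer(re), ref_len = 1000000L,
                  qry_chrom = qc, qry_start = as.integer(qs),
                  qry_end = as.integer(qe), qry_len = 1000000L,
                  strand = strand, identity = 100, n_seeds = 1L,
                  stringsAsFactors = FALSE)
  d$seeds <- list(NULL)
  d
}

test_that("gap rule separates deletions, insertions and the size threshold", {
  # 500-bp reference gap, 0-bp query gap: one DEL of size 500
  b <- rbind(mkBlock(0, 2000, 0, 2000), mkBlock(2500, 5000, 2000, 4500))
  calls <- callSVs(b)
  expect_identical(calls$type, "DEL")
  expect_identical(calls$size, 500L)
  expect_identical(calls$ref_start, 2000L)
  # 49-bp gap: below the size floor, no call
  b <- rbind(mkBlock(0, 2000, 0, 2000), mkBlock(2049, 5000, 2000, 4951))
  expect_identical(nrow(callSVs(b)), 0L)
  # 50-bp: called
  b <- rbind(mkBlock(0, 2000, 0, 2000), mkBlock(2050, 5000, 2000, 4950))
  expect_identical(callSVs(b)$type, "DEL")
  # query-side gap: INS
  b <- rbind(mkBlock(0, 2000, 0, 2000), mkBlock(2000, 5000, 2300, 5300))
  calls <- callSVs(b)
  expect_identical(calls$type, "INS")
  expect_identical(calls$size, 300L)
  # both gaps large: one DEL and one INS
  b <- rbind(mkBlock(0, 2000, 0, 2000), mkBlock(2400, 5000, 2300, 4900))
  expect_setequal(callSVs(b)$type, c("DEL", "INS"))
})

test_that("a minus-strand block flanked by plus blocks is an inversion", {
  b <- rbind(mkBlock(0, 2000, 0, 2000),
             mkBlock(2000, 3000, 2000, 3000, strand = "-"),
             mkBlock(3000, 5000, 3000, 5000))
  calls <- callSVs(b)
  expect_identical(calls$type, "INV")
  expect_identical(calls$size, 1000L)
  # no spurious indels across the inversion junctions
  expect_identical(nrow(calls), 1L)
})

test_that("interval reuse is classified as duplication on either side", {
  # reference interval reused by two query copies (duplication in query)
  b <- rbind(mkBlock(0, 2400, 0, 2400), mkBlock(2000, 5000, 2400, 5400))
  calls <- callSVs(b)
  expect_identical(calls$type, "DUP")
  expect_identical(calls$size, 400L)
  expect_true(calls$tandem)
  expect_identical(calls$ref_start, 2000L)
  expect_identical(calls$ref_end, 2400L)
  # query interval reused (duplication in reference)
  b <- rbind(mkBlock(0, 2400, 0, 2400), mkBlock(2400, 5400, 2000, 5000))
  calls <- callSVs(b)
  expect_identical(calls$type, "DUP")
  expect_identical(calls$size, 400L)
})

test_that("a block joining another query chromosome is a translocation", {
  # context: the majority of blocks keep chrI -> chrI; the terminal block
  # joins chrII
  b <- rbind(mkBlock(0, 40000, 0, 40000, qc = "chrI"),
             mkBlock(40000, 70000, 40000, 70000, qc = "chrI"),
             mkBlock(70000, 150000, 99800, 179800, qc = "chrII"))
  calls <- callSVs(b)
  expect_identical(calls$type, "TRA")
  expect_identical(calls$size, 80000L)
  expect_identical(calls$qry_chrom, "chrII")
})

test_that("within-block seed gaps recover indels smaller than the chain gap", {
  seeds <- data.frame(ref_start = c(0L, 1060L), qry_start = c(0L, 1000L),
                      length = c(1000L, 1000L), strand = "+",
                      stringsAsFactors = FALSE)
  b <- mkBlock(0, 2060, 0, 2000)
  b$seeds <- list(seeds)
  calls <- callSVs(b)
  expect_identical(calls$type, "DEL")
  expect_identical(calls$size, 60L)
  # micro-homology overrun: ref gap 45, qry overlap -15, net 60
  seeds2 <- data.frame(ref_start = c(0L, 1045L), qry_start = c(0L, 985L),
                       length = c(1000L, 1000L), strand = "+",
                       stringsAsFactors = FALSE)
  b$seeds <- list(seeds2)
  calls <- callSVs(b)
  expect_identical(calls$type, "DEL")
  expect_identical(calls$size, 60L)
})

test_that("identical genomes produce zero calls at any parameter setting", {
  g <- generateAncestor(2, c(8000, 6000), gc = 0.4, seed = 71)
  for (minSeed in c(12L, 20L, 32L)) {
    calls <- callSVs(alignGenomes(g, g, minSeed = minSeed))
    expect_identical(nrow(calls), 0L)
  }
})

test_that("the pairwise design enumerates n(n-1) ordered comparisons", {
  d <- svComparisonDesign(sprintf("s%02d", 1:15))
  expect_identical(nrow(d), 210L)
  expect_false(any(d$ref == d$qry))
  expect_identical(nrow(svComparisonDesign(c("a", "b"))), 2L)
  expect_error(svComparisonDesign(c("a", "a")), "duplicate")
})

test_that("pairwise SV matrix tabulates totals additively", {
  g <- generateAncestor(1, 15000, gc = 0.4, seed = 73)
  a <- applySubstitutions(g, 0.004, seed = 74, strain = "A",
                          exclude = data.frame(chrom = "chrI", start = 4980,
                                               end = 5520))$genome
  a <- plantSV(a, "DEL", "chrI", 5000, 500)$genome
  b2 <- applySubstitutions(g, 0.004, seed = 75, strain = "B")$genome
  m <- pairwiseSVMatrix(list(a, b2))
  cnt <- svCounts(m)
  expect_identical(nrow(cnt), 2L)
  expect_identical(cnt$total, cnt$DEL + cnt$INS + cnt$DUP + cnt$INV + cnt$TRA)
  # two byte-identical strains: zero counts everywhere
  m0 <- pairwiseSVMatrix(list(Genome("x", as.character(chromSeqs(g))),
                              Genome("y", as.character(chromSeqs(g)))))
  expect_true(all(svCounts(m0)$total == 0))
  expect_error(pairwiseSVMatrix(list(a, a)), "duplicate")
})

test_that("per-strain summaries aggregate the raw pair counts exactly", {
  cnt <- data.frame(ref = c("A", "A", "B", "B", "C", "C"),
                    qry = c("B", "C", "A", "C", "A", "B"),
                    DEL = c(5, 10, 5, 2, 10, 2), INS = 0, DUP = 0, INV = 0,
                    TRA = c(5, 10, 5, 2, 10, 2))
  cnt$total <- cnt$DEL + cnt$INS + cnt$DUP + cnt$INV + cnt$TRA
  m <- new("SVMatrix", strains = c("A", "B", "C"), counts = cnt)
  s <- summarizeSV(m)
  expect_equal(s$mean_total[s$strain == "A"], mean(c(10, 20)))
  expect_equal(s$min_total[s$strain == "B"], 4)
  expect_equal(s$mean_DEL[s$strain == "C"], 6)
  # recomputation from the raw table agrees
  for (st in c("A", "B", "C")) {
    x <- cnt[cnt$ref == st, ]
    expect_equal(s$mean_total[s$strain == st], mean(x$total))
  }
  expect_error(summarizeSV(new("SVMatrix", strains = character(),
                               counts = cnt[0, ])), "empty")
})
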