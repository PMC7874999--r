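# Collinear chaining of seeds into blocks.

mkSeeds <- function(rs, qs, len, strand = "+", ref_chrom = "r", qry_chrom = "q") {
  data.frame(ref_start = as.integer(rs), qry_start = as.integer(qs),
             length = as.integer(len), strand = strand,
             ref_chrom = ref_chrom, qry_chrom = qry_chrom,
             stringsAsFactors = FALSE)
}

test_that("collinear seeds within the gap limit merge into one block", {
  s <- mkSeeds(c(0, 110), c(0, 110), c(100, 100))
  b <- chainSeeds(s, maxGap = 50, minBlock = 100)
  expect_identical(nrow(b), 1L)
  expect_identical(b$ref_start, 0L)
  expect_identical(b$ref_end, 210L)
  expect_identical(b$n_seeds, 2L)
  # gap beyond the limit splits the chain
  s2 <- mkSeeds(c(0, 200), c(0, 200), c(100, 100))
  b2 <- chainSeeds(s2, maxGap = 50, minBlock = 100)
  expect_identical(nrow(b2), 2L)
})

test_that("seeds on different query chromosomes are never merged", {
  s <- rbind(mkSeeds(0, 0, 100, qry_chrom = "q1"),
             mkSeeds(110, 110, 100, qry_chrom = "q2"))
  b <- chainSeeds(s, maxGap = 500, minBlock = 50)
  expect_gte(nrow(b), 2L)
  expect_setequal(b$qry_chrom, c("q1", "q2"))
})

test_that("chains below the block threshold are dropped", {
  s <- rbind(mkSeeds(0, 0, 2000), mkSeeds(50000, 50000, 100))
  b <- chainSeeds(s, maxGap = 100, minBlock = 1000)
  expect_identical(nrow(b), 1L)
  expect_identical(b$ref_end, 2000L)
})

test_that("block identity is seed-covered columns over block columns", {
  s <- mkSeeds(c(0, 150), c(0, 150), c(100, 100))
  b <- chainSeeds(s, maxGap = 100, minBlock = 100)
  expect_equal(b$identity, 100 * 200 / 250)
})

test_that("chain partition matches the exhaustive enumeration optimum", {
  set.seed(21)
  for (trial in 1:40) {
    n <- sample(4:12, 1)
    # scatter seeds along a rough diagonal with jitter, distinct lengths
    rs <- sort(sample(0:600, n))
    qs <- rs + sample(-80:80, n, replace = TRUE)
    len <- sample(seq(10, 52, by = 3), n)
    s <- mkSeeds(rs, pmax(qs, 0), len)
    got <- chainSeeds(s, maxGap = 100, minBlock = 0, overlapTol = 25)
    want <- brutePeelPartition(s, maxGap = 100, overlapTol = 25)
    # compare as partitions of seed weight: every block's seed set must be
    # one of the oracle chains
    gotParts <- lapply(got$seeds, function(cs)
      sort(match(paste(cs$ref_start, cs$qry_start), paste(s$ref_start, s$qry_start))))
    expect_setequal(vapply(gotParts, paste, "", collapse = ","),
                    vapply(want, paste, "", collapse = ","))
  }
})

test_that("whole-genome self-alignment gives one full-identity block per chromosome", {
  g <- generateAncestor(2, c(5000, 4000), gc = 0.4, seed = 31)
  b <- alignGenomes(g, g)
  # self-alignment: full-length blocks at identity 100 on the diagonal
  diag <- b[b$ref_chrom == b$qry_chrom & b$ref_start == 0 &
              b$qry_start == 0, ]
  expect_identical(nrow(diag), 2L)
  expect_true(all(diag$identity == 100))
  expect_identical(diag$ref_end[diag$ref_chrom == "chrI"], 5000L)
  # a genome with zero chromosomes is rejected at construction
  expect_error(Genome("x", setNames(character(), character())), "chromosome")
})

test_that("alignment blocks are symmetric under swapping reference and query", {
  g <- generateAncestor(1, 20000, gc = 0.4, seed = 33)
  d <- applySubstitutions(g, 0.005, seed = 34, strain = "d")$genome
  d <- plantSV(d, "DEL", "chrI", 8000, 500)$genome
  ab <- alignGenomes(g, d)
  ba <- alignGenomes(d, g)
  expect_identical(nrow(ab), nrow(ba))
  o <- order(ab$ref_start); p <- order(ba$qry_start)
  expect_identical(ab$ref_start[o], ba$qry_start[p])
  expect_identical(ab$ref_end[o], ba$qry_end[p])
  expect_identical(ab$qry_start[o], ba$ref_start[p])
  expect_equal(ab$identity[o], ba$identity[p])
})
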