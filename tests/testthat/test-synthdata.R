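# Synthetic-genome primitives: ancestor generation, substitution model,
# and feature planting.

test_that("ancestor generation honors lengths, seed determinism and gc", {
  g <- generateAncestor(2, c(10000, 8000), gc = 0.38, seed = 7)
  expect_identical(unname(chromLengths(g)), c(10000L, 8000L))
  g2 <- generateAncestor(2, c(10000, 8000), gc = 0.38, seed = 7)
  expect_identical(as.character(chromSeqs(g)), as.character(chromSeqs(g2)))
  g3 <- generateAncestor(2, c(10000, 8000), gc = 0.38, seed = 8)
  expect_false(identical(as.character(chromSeqs(g)), as.character(chromSeqs(g3))))
  gcOnly <- generateAncestor(1, 5000, gc = 1.0, seed = 1)
  expect_true(grepl("^[GC]+$", getChrom(gcOnly, "chrI")))
  expect_error(generateAncestor(1, -5, gc = 0.4, seed = 1), "positive")
  expect_error(generateAncestor(1, 100, gc = 1.4, seed = 1), "gc")
})

test_that("substitution model matches its binomial contract", {
  g <- generateAncestor(1, 10000, gc = 0.4, seed = 3)
  z <- applySubstitutions(g, 0, seed = 5)
  expect_identical(getChrom(z$genome, "chrI"), getChrom(g, "chrI"))
  expect_identical(nrow(z$substitutions), 0L)
  # substitution counts across seeds stay inside the central 99.9% binomial
  # interval, and records never report ref == alt
  bounds <- qbinom(c(0.0005, 0.9995), 10000, 0.01)
  for (s in 1:20) {
    z <- applySubstitutions(g, 0.01, seed = s)
    n <- nrow(z$substitutions)
    expect_gte(n, bounds[1]); expect_lte(n, bounds[2])
    expect_true(all(z$substitutions$ref_base != z$substitutions$alt_base))
  }
  # excluded intervals are untouched
  z <- applySubstitutions(g, 0.2, seed = 9,
                          exclude = data.frame(chrom = "chrI", start = 2000,
                                               end = 3000))
  expect_false(any(z$substitutions$pos >= 2000 & z$substitutions$pos < 3000))
  expect_error(applySubstitutions(g, 0.3, seed = 1), "rate")
})

test_that("SV planting follows each type's arithmetic contract", {
  g <- generateAncestor(2, c(10000, 9000), gc = 0.4, seed = 11,
                        chromNames = c("chrXI", "chrXII"))
  d <- plantSV(g, "DEL", "chrXI", 2000, 500)
  expect_identical(unname(chromLengths(d$genome)[["chrXI"]]), 9500L)
  i <- plantSV(g, "INS", "chrXI", 2000, 300, payloadSeed = 2)
  expect_identical(unname(chromLengths(i$genome)[["chrXI"]]), 10300L)
  v <- plantSV(g, "INV", "chrXI", 4000, 300)
  expect_identical(unname(chromLengths(v$genome)[["chrXI"]]), 10000L)
  expect_identical(getChrom(v$genome, "chrXI", 4000, 4300),
                   rc(getChrom(g, "chrXI", 4000, 4300)))
  # involution: inverting twice restores the original
  v2 <- plantSV(v$genome, "INV", "chrXI", 4000, 300)
  expect_identical(getChrom(v2$genome, "chrXI"), getChrom(g, "chrXI"))
  u <- plantSV(g, "DUP", "chrXI", 5000, 400)
  expect_identical(unname(chromLengths(u$genome)[["chrXI"]]), 10400L)
  expect_identical(getChrom(u$genome, "chrXI", 5400, 5800),
                   getChrom(g, "chrXI", 5000, 5400))
})

test_that("a terminal translocation moves the donor tail onto the acceptor", {
  # synthetic analog of an ~80-kb terminal transfer between chromosomes
  g <- generateAncestor(2, c(100000, 90000), gc = 0.4, seed = 13,
                        chromNames = c("chrXI", "chrXII"))
  t <- plantSV(g, "TRA", "chrXI", 20000, 80000, toChrom = "chrXII")
  expect_identical(unname(chromLengths(t$genome)[["chrXI"]]), 20000L)
  expect_identical(unname(chromLengths(t$genome)[["chrXII"]]), 170000L)
  expect_identical(getChrom(t$genome, "chrXII", 90000, 170000),
                   getChrom(g, "chrXI", 20000, 100000))
  expect_identical(t$record$to_pos, 90000L)
  # non-terminal segment is rejected
  expect_error(plantSV(g, "TRA", "chrXI", 20000, 500, toChrom = "chrXII"),
               "terminal")
  expect_error(plantSV(g, "DEL", "chrXI", 99900, 500), "bounds")
})

test_that("Ty planting builds each state from the library parts", {
  lib <- defaultTyLibrary()
  g <- generateAncestor(1, 30000, gc = 0.4, seed = 17)
  ltrLen <- length(lib@classes$Ty1$ltr)
  intLen <- length(lib@classes$Ty1$internal)
  solo <- plantTyElement(g, lib, "Ty1", "solo_LTR", "not_applicable", "chrI", 5000)
  expect_identical(solo$record$end - solo$record$start, ltrLen)
  expect_identical(getChrom(solo$genome, "chrI", 5000, 5000 + ltrLen),
                   as.character(lib@classes$Ty1$ltr))
  comp <- plantTyElement(g, lib, "Ty1", "complete", "functional", "chrI", 5000)
  expect_identical(comp$record$end - comp$record$start, 2L * ltrLen + intLen)
  # premature-stop lesion: translated internal region stops early
  lof <- plantTyElement(g, lib, "Ty2", "complete", "loss_of_function", "chrI",
                        5000)
  cd <- lib@classes$Ty2$coding[1, ]
  int2 <- getChrom(lof$genome, "chrI",
                   5000 + length(lib@classes$Ty2$ltr),
                   5000 + length(lib@classes$Ty2$ltr) + length(lib@classes$Ty2$internal))
  aa <- as.character(suppressWarnings(Biostrings::translate(
    Biostrings::DNAString(substr(int2, cd$start + 1, cd$end)))))
  firstStop <- regexpr("*", aa, fixed = TRUE)[1]
  expect_lt(firstStop, nchar(aa))
  # truncation removes the requested internal block
  tr <- plantTyElement(g, lib, "Ty5", "truncated", "loss_of_function", "chrI",
                       5000)
  expect_identical(tr$record$end - tr$record$start,
                   2L * length(lib@classes$Ty5$ltr) +
                     length(lib@classes$Ty5$internal) - 2000L)
  expect_error(plantTyElement(g, lib, "Ty9", "complete", "functional", "chrI", 1),
               "unknown")
  expect_error(plantTyElement(g, lib, "Ty1", "solo_LTR", "functional", "chrI", 1),
               "not_applicable")
})

test_that("introgressed ORF planting preserves length and shares one origin", {
  set.seed(1)
  orfs <- Biostrings::DNAStringSet(setNames(
    vapply(1:3, function(i) randSeq(900), ""), c("orf1", "orf2", "orf3")))
  cats <- list(F1 = orfs, F2 = orfs, F3 = orfs, O1 = orfs)
  z <- plantIntrogressedORFs(cats, "orf1", 0, c("F1", "F2", "F3"), seed = 5)
  expect_identical(as.character(z$catalogs$F1[["orf1"]]),
                   as.character(z$catalogs$O1[["orf1"]]))
  z <- plantIntrogressedORFs(cats, "orf2", 0.08, c("F1", "F2", "F3"), seed = 5)
  f1 <- as.character(z$catalogs$F1[["orf2"]])
  expect_identical(nchar(f1), 900L)
  expect_identical(f1, as.character(z$catalogs$F2[["orf2"]]))  # single origin
  expect_false(identical(f1, as.character(z$catalogs$O1[["orf2"]])))
  # substitution count within the central 99.9% binomial band
  mism <- sum(strsplit(f1, "")[[1]] !=
                strsplit(as.character(orfs[["orf2"]]), "")[[1]])
  bounds <- qbinom(c(0.0005, 0.9995), 900, 0.08)
  expect_gte(mism, bounds[1]); expect_lte(mism, bounds[2])
  expect_error(plantIntrogressedORFs(cats, "nope", 0.05, "F1", seed = 1),
               "missing")
})

test_that("exact substitution placement controls identity to the base", {
  set.seed(2)
  s <- randSeq(999)
  z <- substituteExact(s, 51, seed = 3)
  expect_identical(nchar(z), 999L)
  expect_identical(sum(strsplit(s, "")[[1]] != strsplit(z, "")[[1]]), 51L)
})
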