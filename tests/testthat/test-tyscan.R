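# Ty annotation: scanning, state classification, viability, flank test,
# composition summaries.

tyLib <- defaultTyLibrary()

test_that("the library writes and reads back identically", {
  fa <- tempfile(fileext = ".fa"); ya <- tempfile(fileext = ".yaml")
  writeTyLibrary(tyLib, fa, ya)
  lib2 <- readTyLibrary(fa, ya)
  expect_identical(names(lib2@classes), names(tyLib@classes))
  for (nm in names(tyLib@classes)) {
    expect_identical(as.character(lib2@classes[[nm]]$ltr),
                     as.character(tyLib@classes[[nm]]$ltr))
    expect_identical(as.character(lib2@classes[[nm]]$internal),
                     as.character(tyLib@classes[[nm]]$internal))
    expect_identical(lib2@classes[[nm]]$coding, tyLib@classes[[nm]]$coding)
  }
})

test_that("scanning finds planted components and nothing in shuffled background", {
  g <- generateAncestor(1, 40000, gc = 0.38, seed = 81, strain = "t")
  gp <- plantTyElement(g, tyLib, "Ty3", "complete", "functional", "chrI", 15000)
  hits <- scanTy(gp$genome, tyLib)
  h3 <- hits[hits$class == "Ty3", ]
  expect_identical(h3$part, c("LTR", "internal", "LTR"))
  expect_true(all(h3$strand == "+"))
  expect_true(all(h3$identity == 100))
  # solo LTR: exactly one LTR hit, no internal
  gs <- plantTyElement(g, tyLib, "Ty2", "solo_LTR", "not_applicable", "chrI", 15000)
  hs <- scanTy(gs$genome, tyLib)
  expect_identical(hs$part[hs$class == "Ty2"], "LTR")
  expect_false(any(hs$part == "internal"))
  # clean random background: zero hits at default thresholds
  expect_identical(nrow(scanTy(g, tyLib)), 0L)
})

test_that("state classification follows the grouping rules", {
  mk <- function(part, start, end, class = "Ty1", frac = 1) {
    data.frame(class = class, part = part, chrom = "chrI", start = start,
               end = end, strand = "+", identity = 99, part_fraction = frac,
               stringsAsFactors = FALSE)
  }
  # LTR - internal - LTR within the window: complete
  els <- classifyElements(rbind(mk("LTR", 0, 330), mk("internal", 340, 5600),
                                mk("LTR", 5610, 5940)))
  expect_identical(els$state, "complete")
  # internal coverage short of the full span: truncated despite both LTRs
  els <- classifyElements(rbind(mk("LTR", 0, 330),
                                mk("internal", 340, 3300, frac = 0.6),
                                mk("LTR", 3310, 3640)))
  expect_identical(els$state, "truncated")
  # two LTRs 50 kb apart, nothing between: two solo elements
  els <- classifyElements(rbind(mk("LTR", 0, 330), mk("LTR", 50000, 50330)))
  expect_identical(els$state, c("solo_LTR", "solo_LTR"))
  expect_identical(els$viability, c("not_applicable", "not_applicable"))
  # each hit is consumed by at most one element
  els <- classifyElements(rbind(mk("LTR", 0, 330), mk("internal", 340, 5600),
                                mk("LTR", 5610, 5940), mk("LTR", 8000, 8330)))
  expect_identical(sort(els$state), c("complete", "solo_LTR"))
  expect_identical(sum(vapply(els$components, nrow, 1L)), 4L)
})

test_that("near-identical LTR classes resolve by identity with joint-label ties", {
  # Ty1-like LTR also present verbatim under another class name
  lib2 <- TyLibrary(list(
    TyA = list(ltr = as.character(tyLib@classes$Ty1$ltr),
               internal = as.character(tyLib@classes$Ty1$internal),
               coding = tyLib@classes$Ty1$coding),
    TyB = list(ltr = as.character(tyLib@classes$Ty1$ltr),
               internal = as.character(tyLib@classes$Ty2$internal),
               coding = tyLib@classes$Ty2$coding)))
  g <- generateAncestor(1, 20000, gc = 0.38, seed = 83, strain = "t")
  gp <- plantTyElement(g, lib2, "TyA", "solo_LTR", "not_applicable", "chrI", 9000)
  hits <- scanTy(gp$genome, lib2)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$class, "TyA/TyB")
})

test_that("viability calls premature stops, frameshifts and truncations", {
  g <- generateAncestor(1, 40000, gc = 0.38, seed = 85, strain = "t")
  check <- function(class, state, viab, lesion = "premature_stop") {
    gp <- plantTyElement(g, tyLib, class, state, viab, "chrI", 15000,
                         lesion = lesion)
    els <- annotateTy(gp$genome, tyLib)
    expect_identical(nrow(els), 1L)
    expect_identical(els$class, class)
    expect_identical(els$state, state)
    expect_identical(els$viability, viab)
  }
  check("Ty1", "complete", "functional")
  check("Ty2", "complete", "loss_of_function", "premature_stop")
  check("Ty3", "complete", "loss_of_function", "frameshift")
  check("Ty5", "truncated", "loss_of_function")
})

test_that("viability is invariant under a synonymous substitution", {
  g <- generateAncestor(1, 40000, gc = 0.38, seed = 87, strain = "t")
  gp <- plantTyElement(g, tyLib, "Ty4", "complete", "functional", "chrI", 15000)
  lib4 <- tyLib@classes$Ty4
  cd <- lib4$coding[1, ]
  intStart <- 15000 + length(lib4$ltr)
  # find a codon whose third-position swap is synonymous (e.g. GGx glycine)
  internal <- as.character(lib4$internal)
  found <- FALSE
  for (codonIdx in seq(10, 200)) {
    at <- cd$start + 3 * codonIdx          # 0-based codon start
    codon <- substr(internal, at + 1, at + 3)
    if (substr(codon, 1, 2) %in% c("GG", "CC", "GC", "CG", "AC", "GT", "TC", "CT")) {
      alt <- ifelse(substr(codon, 3, 3) == "A", "G", "A")
      gseq <- getChrom(gp$genome, "chrI")
      pos <- intStart + at + 2               # third codon base, 0-based
      substr(gseq, pos + 1, pos + 1) <- alt
      g2 <- Genome("t", c(chrI = gseq))
      els <- annotateTy(g2, tyLib)
      expect_identical(els$viability, "functional")
      found <- TRUE
      break
    }
  }
  expect_true(found)
})

test_that("the 10-kb flank test separates duplication from transposition", {
  fx <- simulateFlankBenchmark(seed = 89)
  expect_identical(
    transpositionVsDuplication(fx$dupPair[1, ], fx$dupPair[2, ], fx$genome),
    "segmental_duplication")
  expect_identical(
    transpositionVsDuplication(fx$indepPair[1, ], fx$indepPair[2, ], fx$genome),
    "independent_transposition")
  expect_error(
    transpositionVsDuplication(fx$dupPair[1, ], fx$indepPair[1, ], fx$genome),
    "class")
  bad <- fx$dupPair[1, ]; bad$chrom <- "chrZ"
  expect_error(transpositionVsDuplication(bad, bad, fx$genome), "missing")
})

test_that("composition tables count and normalize per category", {
  els <- data.frame(
    strain = c(rep("A", 4), "B"),
    class = c("Ty1", "Ty1", "Ty1", "Ty5", "Ty1"),
    state = c("solo_LTR", "solo_LTR", "solo_LTR", "complete", "solo_LTR"),
    chrom = "chrI", start = c(0, 1000, 2000, 3000, 0) * 10L,
    end = c(330, 1330, 2330, 9000, 330) * 10L,
    stringsAsFactors = FALSE)
  s <- tySummary(els, normalize = TRUE)
  expect_identical(s$count[s$strain == "A" & s$class == "Ty1"], 3L)
  expect_identical(s$count[s$strain == "A" & s$class == "Ty5"], 1L)
  # normalization: the per-category maximum maps to 1
  expect_equal(s$norm_count[s$strain == "A" & s$class == "Ty1"], 1)
  expect_equal(s$norm_count[s$strain == "B" & s$class == "Ty1"], 1 / 3)
  expect_identical(tySummary(els[0, ])$count, integer())
})
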