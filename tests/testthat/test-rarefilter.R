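# A hand-built population with a planted recombinant mosaic:
# cores 1-3 on one chromosome; hap 3 at core 2 is a singleton carried by
# individual e's paternal gamete, flanked by common haplotypes.
.plantedPopulation <- function() {
  pat <- rbind(c(1L, 1L, 1L),
               c(1L, 1L, 1L),
               c(2L, 2L, 2L),
               c(2L, 2L, 2L),
               c(1L, 3L, 2L))   # mosaic: common left, rare centre, common right
  mat <- rbind(c(1L, 1L, 1L),
               c(2L, 2L, 2L),
               c(1L, 1L, 1L),
               c(2L, 2L, 2L),
               c(1L, 1L, 1L))
  codes <- new("DiplotypeCodes", ids = letters[1:5],
               paternal = pat, maternal = mat)
  haplotypeLibraryFromCodes(codes)
}

test_that("a planted recombinant mosaic passes the flanking filter", {
  lc <- .plantedPopulation()
  # centre core: hap1 count 5, hap2 count 4, hap3 (mosaic) count 1
  expect_identical(lc$library@counts[[2]], c(5L, 4L, 1L))
  m <- applyRareFilter(lc$library, lc$codes, mode = "flanking",
                       rareCountThreshold = 2, flankCount = 2, nComb = 3)
  f <- flatIndex(lc$library, 2, 3)
  expect_true(m[f])   # flanks common (counts 5, 4), pair (1,2) unique
  expect_identical(attr(m, "reason")[f], "rare_kept")
})

test_that("rare haplotypes at chromosome ends are never targeted", {
  lc <- .plantedPopulation()
  # make a rare haplotype at the first core: give gamete a new ID there
  codes <- lc$codes
  codes@paternal[5, 1] <- 4L
  lc2 <- haplotypeLibraryFromCodes(codes)
  m <- applyRareFilter(lc2$library, lc2$codes, mode = "flanking")
  f <- flatIndex(lc2$library, 1, unique(lc2$codes@paternal[5, 1]))
  expect_false(m[f])
  expect_identical(attr(m, "reason")[f], "edge_core")
})

test_that("rare flanks or common flanking pairs disqualify a rare haplotype", {
  lc <- .plantedPopulation()
  codes <- lc$codes
  # rare left flank: the mosaic carrier's core-1 hap becomes a singleton
  codes@paternal[5, 1] <- 5L
  lcA <- haplotypeLibraryFromCodes(codes)
  mA <- applyRareFilter(lcA$library, lcA$codes, mode = "flanking")
  fA <- flatIndex(lcA$library, 2, lcA$codes@paternal[5, 2])
  expect_false(mA[fA])
  expect_identical(attr(mA, "reason")[fA], "flank_fail")
  # common flanking pair: many other gametes share the (1, 2) context
  codes2 <- lc$codes
  codes2@maternal[1:3, 1] <- 1L
  codes2@maternal[1:3, 2] <- 1L
  codes2@maternal[1:3, 3] <- 2L
  lcB <- haplotypeLibraryFromCodes(codes2)
  mB <- applyRareFilter(lcB$library, lcB$codes, mode = "flanking",
                        nComb = 3)
  fB <- flatIndex(lcB$library, 2, lcB$codes@paternal[5, 2])
  expect_false(mB[fB])
  expect_identical(attr(mB, "reason")[fB], "comb_fail")
})

test_that("filter modes nest: exclude within flanking within none", {
  set.seed(116)
  for (rep in 1:5) {
    toy <- randomToyPopulation(15, 6, 8, conc = 0.3)
    mNone <- applyRareFilter(toy$library, toy$codes, "none")
    mFlank <- applyRareFilter(toy$library, toy$codes, "flanking")
    mExcl <- applyRareFilter(toy$library, toy$codes, "exclude")
    expect_true(all(mNone))
    expect_true(all(!mExcl | mFlank))  # exclude subset of flanking
    expect_true(all(!mFlank | mNone))
    common <- hapPopCounts(toy$library) > 2
    expect_true(all(mExcl[common] & mFlank[common]))
  }
})

test_that("flanking mask equals brute-force evaluation of the conditions", {
  set.seed(117)
  for (rep in 1:8) {
    toy <- randomToyPopulation(15, 5, 6, conc = 0.3,
                               missingProb = sample(c(0, 0.05), 1))
    thr <- sample(1:2, 1); fc <- sample(1:3, 1); nc <- sample(2:4, 1)
    got <- applyRareFilter(toy$library, toy$codes, "flanking",
                           rareCountThreshold = thr, flankCount = fc,
                           nComb = nc)
    want <- oracleRareFilter(toy$library, toy$codes, thr, fc, nc)
    expect_identical(as.logical(got), want)
  }
})

test_that("raising flankCount or lowering nComb never grows the targeted set", {
  set.seed(118)
  toy <- randomToyPopulation(20, 6, 6, conc = 0.3)
  base <- applyRareFilter(toy$library, toy$codes, "flanking",
                          flankCount = 2, nComb = 3)
  harderFlank <- applyRareFilter(toy$library, toy$codes, "flanking",
                                 flankCount = 4, nComb = 3)
  harderComb <- applyRareFilter(toy$library, toy$codes, "flanking",
                                flankCount = 2, nComb = 2)
  expect_true(all(!harderFlank | base))
  expect_true(all(!harderComb | base))
})

test_that("single-core chromosomes leave their rare haplotypes untargeted", {
  codes <- new("DiplotypeCodes", ids = c("a", "b"),
               paternal = rbind(1L, 1L), maternal = rbind(1L, 2L))
  lc <- haplotypeLibraryFromCodes(codes)
  m <- applyRareFilter(lc$library, lc$codes, "flanking")
  expect_false(m[flatIndex(lc$library, 1, 2)])  # the singleton
  expect_true(m[flatIndex(lc$library, 1, 1)])   # the common haplotype
})
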