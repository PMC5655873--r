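test_that("slot counts and set costs follow the linear budget model", {
  expect_identical(maxSlots(budgetModel(400000, 40, 80)), 5000L)
  expect_identical(maxSlots(budgetModel(1600000, 40, 80)), 20000L)
  expect_identical(maxSlots(budgetModel(100, 0, 80)), 1L)
  bm <- budgetModel(400000, 40, 80)
  emptySet <- new("SequencingSet", members = NA_character_[0],
                  budget = bm, metadata = list())
  expect_equal(totalCost(emptySet, bm), 0)
  one5x <- new("SequencingSet", members = rep("a", 5), budget = bm,
               metadata = list())
  expect_equal(totalCost(one5x, bm), 440)
  many <- new("SequencingSet", members = sprintf("i%04d", 1:3333),
              budget = bm, metadata = list())
  expect_equal(totalCost(many, bm), 399960)
  # a cost hook replaces the linear formula
  bmHook <- budgetModel(1000, 40, 80,
                        costHook = function(nInd, cov) 100 * nInd + cov)
  expect_equal(totalCost(one5x, bmHook), 105)
})

test_that("prior coverage increments counts per carried copy", {
  codes <- new("DiplotypeCodes", ids = c("a", "b"),
               paternal = rbind(c(1L, 1L), c(2L, 1L)),
               maternal = rbind(c(2L, 1L), c(2L, 2L)))
  lc <- haplotypeLibraryFromCodes(codes)
  st <- newHapCountState(lc$library)
  expect_identical(applyPriorCoverage(st, lc$codes, lc$library,
                                      integer(0)), st)
  # a heterozygous at core 1 (haps 1, 2), homozygous at core 2 (hap 1)
  st2 <- applyPriorCoverage(st, lc$codes, lc$library, c(a = 2L))
  expect_identical(st2@counts, c(2L, 2L, 4L, 0L))
  st3 <- applyPriorCoverage(st, lc$codes, lc$library, c(a = 1L))
  expect_identical(st3@counts[3], 2L)  # homozygous core: +2 per 1x
  expect_error(applyPriorCoverage(st, lc$codes, lc$library, c(zz = 1L)),
               "unknown")
})

test_that("a lone affordable individual fills one slot", {
  codes <- new("DiplotypeCodes", ids = "solo",
               paternal = matrix(1L), maternal = matrix(2L))
  lc <- haplotypeLibraryFromCodes(codes)
  set.seed(1)
  s <- greedySelect(lc$codes, lc$library, budgetModel(120, 40, 80), 10)
  expect_identical(indCoverage(s), c(solo = 1L))
  expect_identical(nSlots(s), 1L)
})

test_that("each greedy addition attains the independently recomputed argmax", {
  set.seed(106)
  for (rep in 1:25) {
    toy <- randomToyPopulation(sample(4:8, 1), 2, 5,
                               missingProb = sample(c(0, 0.1), 1))
    bm <- budgetModel(sample(3:4, 1) * 120, 40, 80)
    s <- greedySelect(toy$codes, toy$library, bm, sample(1:3, 1))
    expect_true(oracleCheckGreedyTrace(s, toy$codes, toy$library, bm,
                                       s@metadata$targetCov))
  }
})

test_that("selection respects coverage caps and budget feasibility", {
  set.seed(107)
  toy <- randomToyPopulation(30, 4, 6)
  bm <- budgetModel(5000, 40, 80)
  for (method in c("hapcov", "iws", "random")) {
    s <- greedySelect(toy$codes, toy$library, bm, 3, method = method,
                      maxIndividualCoverage = 2)
    cov <- indCoverage(s)
    expect_true(all(cov <= 2))
    expect_lte(totalCost(s, bm), bm@totalBudget)
  }
  # without an explicit cap, coverage never exceeds twice the target
  s <- greedySelect(toy$codes, toy$library, budgetModel(100000, 0, 80), 2)
  expect_true(all(indCoverage(s) <= 4))
})

test_that("identical inputs and seed give identical sets for all methods", {
  set.seed(108)
  toy <- randomToyPopulation(25, 4, 8)
  bm <- budgetModel(3000, 40, 80)
  for (method in c("hapcov", "iws", "iws_homozygous", "random")) {
    set.seed(31); s1 <- greedySelect(toy$codes, toy$library, bm, 5,
                                     method = method)
    set.seed(31); s2 <- greedySelect(toy$codes, toy$library, bm, 5,
                                     method = method)
    expect_identical(setMembers(s1), setMembers(s2))
  }
})

test_that("random selection fills every affordable slot up to the cap", {
  codes <- new("DiplotypeCodes", ids = "only",
               paternal = matrix(1L), maternal = matrix(1L))
  lc <- haplotypeLibraryFromCodes(codes)
  set.seed(2)
  s <- selectRandom(lc$codes, lc$library, budgetModel(2000, 40, 80), 10)
  expect_identical(indCoverage(s), c(only = 20L))  # cap = 2 * target
  set.seed(109)
  toy <- randomToyPopulation(200, 2, 5)
  s1 <- selectRandom(toy$codes, toy$library, budgetModel(5000, 40, 80), 10,
                     maxIndividualCoverage = 1)
  expect_true(all(indCoverage(s1) == 1L))
})

test_that("homozygous-only IWS targets nothing in a never-homozygous population", {
  codes <- new("DiplotypeCodes", ids = c("a", "b"),
               paternal = rbind(1L, 1L), maternal = rbind(2L, 2L))
  lc <- haplotypeLibraryFromCodes(codes)
  set.seed(3)
  s <- selectIWSOriginal(lc$codes, lc$library, budgetModel(1000, 40, 80), 5)
  expect_identical(nFilledSlots(s), 0L)
})

test_that("homozygous-only IWS stops with unspent budget once targets cap", {
  # one common haplotype observed homozygous; budget far exceeds its need
  codes <- new("DiplotypeCodes", ids = sprintf("i%02d", 1:5),
               paternal = matrix(c(1L, 1L, 1L, 2L, 3L), 5),
               maternal = matrix(c(1L, 1L, 4L, 5L, 6L), 5))
  lc <- haplotypeLibraryFromCodes(codes)
  set.seed(4)
  s <- selectIWSOriginal(lc$codes, lc$library, budgetModel(10000, 40, 80), 2)
  counts <- s@metadata$counts
  expect_gte(counts[1], 4L)          # hap 1 reached 2 * targetCov
  expect_lt(nFilledSlots(s), nSlots(s))  # slots left empty
  expect_true(all(names(indCoverage(s)) %in% c("i01", "i02", "i03")))
})

test_that("incremental counts match a from-scratch recount after selection", {
  set.seed(110)
  toy <- randomToyPopulation(40, 5, 10, missingProb = 0.05)
  bm <- budgetModel(4000, 40, 80)
  prior <- c(i005 = 2L, i017 = 1L)
  st <- applyPriorCoverage(newHapCountState(toy$library), toy$codes,
                           toy$library, prior)
  s <- greedySelect(toy$codes, toy$library, bm, 4, state = st)
  expect_identical(s@metadata$counts,
                   oracleRecount(s, toy$codes, toy$library, prior))
})

test_that("pre-sequenced individuals contribute counts without consuming budget", {
  set.seed(111)
  toy <- randomToyPopulation(20, 3, 6)
  bm <- budgetModel(1200, 40, 80)
  prior <- c(i001 = 5L)
  st <- applyPriorCoverage(newHapCountState(toy$library), toy$codes,
                           toy$library, prior)
  s <- greedySelect(toy$codes, toy$library, bm, 5, state = st)
  # the full slot allowance is still available for new sequencing
  expect_identical(nSlots(s), 15L)
  expect_lte(totalCost(s, bm), bm@totalBudget)
})

test_that("zero exchange rounds return the set unchanged", {
  set.seed(112)
  toy <- randomToyPopulation(20, 3, 6)
  bm <- budgetModel(2000, 40, 80)
  s <- greedySelect(toy$codes, toy$library, bm, 3)
  r <- refineSet(s, toy$codes, toy$library, bm, 3, exchangeRounds = 0)
  expect_identical(setMembers(r), setMembers(s))
})

test_that("the refinement incumbent metric never decreases", {
  set.seed(113)
  toy <- randomToyPopulation(60, 4, 12)
  bm <- budgetModel(4000, 40, 80)
  s <- greedySelect(toy$codes, toy$library, bm, 4)
  r <- refineSet(s, toy$codes, toy$library, bm, 4, exchangeRounds = 50,
                 exchangesPerRound = 3)
  traj <- r@metadata$trajectory
  expect_true(all(diff(traj) >= 0))
  expect_equal(r@metadata$pctAtTarget, traj[length(traj)])
  expect_identical(r@metadata$counts,
                   oracleRecount(r, toy$codes, toy$library))
})

test_that("oversized exchange requests are clipped with a warning", {
  set.seed(114)
  toy <- randomToyPopulation(10, 2, 4)
  bm <- budgetModel(500, 40, 80)  # 6 slots, few filled
  s <- greedySelect(toy$codes, toy$library, bm, 2)
  expect_warning(
    refineSet(s, toy$codes, toy$library, bm, 2, exchangeRounds = 2,
              exchangesPerRound = 500),
    "clipped")
})

test_that("exchanging the whole set equals best-of fresh selections", {
  set.seed(115)
  toy <- randomToyPopulation(30, 3, 8)
  bm <- budgetModel(1500, 40, 80)
  s <- greedySelect(toy$codes, toy$library, bm, 3)
  r <- refineSet(s, toy$codes, toy$library, bm, 3, exchangeRounds = 10,
                 exchangesPerRound = nFilledSlots(s))
  expect_gte(r@metadata$pctAtTarget, s@metadata$pctAtTarget)
  expect_true(all(diff(r@metadata$trajectory) >= 0))
})
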