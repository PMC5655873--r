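test_that("without recombination and one founder, everyone is identical", {
  pop <- simulatePopulation(nGenerations = 4, nPerGeneration = 20,
                            nSiresSelected = 3, nChromosomes = 2,
                            coresPerChromosome = 3,
                            nFounderHaplotypes = 1, recombProb = 0,
                            mosaicProb = 0, seed = 21)
  expect_true(all(pop@codes@paternal == 1L))
  expect_true(all(pop@codes@maternal == 1L))
})

test_that("without recombination every gamete copies one parental gamete", {
  pop <- simulatePopulation(nGenerations = 5, nPerGeneration = 30,
                            nSiresSelected = 3, nChromosomes = 2,
                            coresPerChromosome = 4,
                            nFounderHaplotypes = 20, recombProb = 0,
                            mosaicProb = 0, seed = 22)
  ped <- pop@pedigree
  kids <- which(!is.na(ped$sire))
  for (i in kids) {
    s <- match(ped$sire[i], ped$id)
    for (ch in unique(pop@chromOfCore)) {
      cols <- which(pop@chromOfCore == ch)
      g <- pop@codes@paternal[i, cols]
      expect_true(identical(g, pop@codes@paternal[s, cols]) ||
                  identical(g, pop@codes@maternal[s, cols]))
    }
  }
})

test_that("between-core switch rate matches the binomial expectation", {
  rates <- replicate(10, {
    pop <- simulatePopulation(nGenerations = 6, nPerGeneration = 100,
                              nSiresSelected = 5, nChromosomes = 2,
                              coresPerChromosome = 10,
                              nFounderHaplotypes = 50, recombProb = 0.1,
                              mosaicProb = 0, selection = "random")
    pop@params$nSwitches / (pop@params$nMeioses * 2)  # per chromosome
  })
  nJunctions <- 9
  expected <- 0.1 * nJunctions
  # binomial SE of the mean switch count per chromosome per meiosis
  nTot <- 10 * 5 * 100 * 2 * 2 * nJunctions
  se <- sqrt(0.1 * 0.9 / nTot) * nJunctions
  expect_lt(abs(mean(rates) - expected), 3 * se)
})

test_that("simulation is deterministic given a seed", {
  p1 <- simulatePopulation(nGenerations = 4, nPerGeneration = 30,
                           nSiresSelected = 3, nChromosomes = 2,
                           coresPerChromosome = 5,
                           nFounderHaplotypes = 30, seed = 23)
  p2 <- simulatePopulation(nGenerations = 4, nPerGeneration = 30,
                           nSiresSelected = 3, nChromosomes = 2,
                           coresPerChromosome = 5,
                           nFounderHaplotypes = 30, seed = 23)
  expect_identical(p1@codes@paternal, p2@codes@paternal)
  expect_identical(p1@pedigree, p2@pedigree)
})

test_that("the default spectrum is right-skewed with many rare haplotypes", {
  pop <- simulatePopulation(seed = 24)
  pc <- hapPopCounts(haplotypeLibraryFromCodes(pop@codes,
                                               pop@chromOfCore)$library)
  expect_gt(mean(pc <= 2), 0.25)
  # few common haplotypes hold most of the mass
  expect_gt(sum(sort(pc, decreasing = TRUE)[1:round(0.1 * length(pc))]) /
              sum(pc), 0.5)
})

test_that("sire selection narrows haplotype diversity relative to random mating", {
  divLast <- function(selection, seed) {
    pop <- simulatePopulation(nGenerations = 10, nPerGeneration = 100,
                              nSiresSelected = 5, nChromosomes = 2,
                              coresPerChromosome = 5,
                              nFounderHaplotypes = 100, mosaicProb = 0,
                              selection = selection, seed = seed)
    last <- pop@pedigree$generation == 10
    length(unique(as.vector(pop@codes@paternal[last, ])))
  }
  sel <- vapply(1:3, function(s) divLast("truncation", s), numeric(1))
  rnd <- vapply(1:3, function(s) divLast("random", 100 + s), numeric(1))
  expect_lt(mean(sel), mean(rnd))
})

test_that("pedigree structure is internally consistent", {
  pop <- simulatePopulation(nGenerations = 5, nPerGeneration = 40,
                            nSiresSelected = 4, nChromosomes = 1,
                            coresPerChromosome = 4,
                            nFounderHaplotypes = 20, seed = 25)
  ped <- pop@pedigree
  kids <- !is.na(ped$sire)
  sireRows <- match(ped$sire[kids], ped$id)
  damRows <- match(ped$dam[kids], ped$id)
  expect_true(all(ped$sex[sireRows] == "M"))
  expect_true(all(ped$sex[damRows] == "F"))
  expect_true(all(ped$generation[sireRows] == ped$generation[kids] - 1L))
  expect_error(simulatePopulation(nGenerations = 2, nPerGeneration = 10,
                                  nSiresSelected = 50),
               "exceeds males")
})

test_that("rendering then rebuilding recovers the simulated haplotype counts", {
  pop <- simulatePopulation(nGenerations = 6, nPerGeneration = 50,
                            nSiresSelected = 4, nChromosomes = 2,
                            coresPerChromosome = 5,
                            nFounderHaplotypes = 40, seed = 26)
  g <- renderMarkerAlleles(pop, markersPerCore = 12, seed = 27)
  res <- buildLibrary(g, attr(g, "coreMap"))
  truth <- haplotypeLibraryFromCodes(pop@codes, pop@chromOfCore)
  expect_identical(nHaplotypes(res$library), nHaplotypes(truth$library))
  for (c in seq_len(nCores(res$library)))
    expect_identical(sort(res$library@counts[[c]]),
                     sort(truth$library@counts[[c]]))
  # assignments agree up to relabelling: same partition of gametes
  expect_true(all((res$codes@paternal == res$codes@maternal) ==
                  (truth$codes@paternal == truth$codes@maternal)))
})

test_that("marker rendering uses distinct strings per haplotype", {
  pop <- simulatePopulation(nGenerations = 3, nPerGeneration = 20,
                            nSiresSelected = 2, nChromosomes = 1,
                            coresPerChromosome = 2,
                            nFounderHaplotypes = 2, mosaicProb = 0,
                            seed = 28)
  g <- renderMarkerAlleles(pop, markersPerCore = 8, seed = 29)
  expect_identical(ncol(g@paternal), 16L)
  lib <- buildLibrary(g, attr(g, "coreMap"))$library
  for (c in 1:2)
    expect_lte(length(lib@haplotypes[[c]]), 2L)
})
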