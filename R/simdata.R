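# one meiosis per row: recombine a parent's two gamete code matrices into
# child gametes. Two recombination processes, both without interference:
# a switch of the source strand between adjacent cores (probability
# recombProb per junction), and a crossover landing inside a core
# (probability mosaicProb per core), which creates a novel mosaic
# haplotype at that core -- left part from the current strand, right part
# from the other -- and switches the strand downstream. Mosaic products of
# the same ordered (left, right) pair at a core are treated as one novel
# haplotype; the registry maps each novel ID to its composition so marker
# rendering can reconstruct its allele string.
.meiose <- function(hapA, hapB, chromOfCore, recombProb, mosaicProb,
                    registry, nextId) {
  n <- nrow(hapA)
  C <- ncol(hapA)
  out <- matrix(NA_integer_, n, C)
  nSwitches <- 0L
  nMosaic <- 0L
  for (ch in unique(chromOfCore)) {
    cols <- which(chromOfCore == ch)
    len <- length(cols)
    swJ <- if (len > 1L)
      matrix(stats::rbinom(n * (len - 1L), 1L, recombProb), n, len - 1L)
    else matrix(0L, n, 0L)
    W <- if (mosaicProb > 0)
      matrix(stats::rbinom(n * len, 1L, mosaicProb), n, len)
    else matrix(0L, n, len)
    nSwitches <- nSwitches + sum(swJ)
    src <- matrix(0L, n, len)
    src[, 1L] <- stats::rbinom(n, 1L, 0.5)
    if (len > 1L)
      for (j in 2L:len)
        src[, j] <- (src[, j - 1L] + swJ[, j - 1L] + W[, j - 1L]) %% 2L
    a <- hapA[, cols, drop = FALSE]
    b <- hapB[, cols, drop = FALSE]
    pick <- src == 1L
    o <- a
    o[pick] <- b[pick]
    ev <- which(W == 1L, arr.ind = TRUE)
    if (nrow(ev)) {
      for (e in seq_len(nrow(ev))) {
        i <- ev[e, 1L]
        j <- ev[e, 2L]
        core <- cols[j]
        l <- if (src[i, j] == 0L) hapA[i, core] else hapB[i, core]
        r <- if (src[i, j] == 0L) hapB[i, core] else hapA[i, core]
        if (is.na(l) || is.na(r) || l == r) next  # invisible crossover
        key <- paste(l, r)
        id <- registry$map[[core]][[key]]
        if (is.null(id)) {
          id <- nextId[core]
          nextId[core] <- id + 1L
          registry$map[[core]][[key]] <- id
          registry$log[[core]] <- rbind(
            registry$log[[core]],
            data.frame(id = id, left = l, right = r))
        }
        o[i, j] <- id
        nMosaic <- nMosaic + 1L
      }
    }
    out[, cols] <- o
  }
  list(out = out, nSwitches = nSwitches, nMosaic = nMosaic,
       registry = registry, nextId = nextId)
}

#' Simulate a multi-generation livestock pedigree with core haplotypes
#'
#' Gene-dropping simulation of phased core-level haplotypes through a
#' structured pedigree under truncation selection of sires. At each core,
#' founder gametes draw a haplotype ID from a pool of distinct founder
#' haplotypes whose frequencies follow a symmetric Dirichlet (small
#' concentration gives the right-skewed spectrum typical of livestock
#' populations: many rare haplotypes, few common ones); draws are
#' independent across cores, so founder chromosomes share a haplotype at
#' one core without necessarily sharing it at the next, as in
#' coalescent-derived data. Descendants inherit one recombined
#' gamete per parent, with an independent switch between adjacent cores
#' per meiosis (no interference), so rare recombinant mosaics of common
#' haplotypes accumulate over generations. Each individual carries a
#' heritable polygenic value (parent average plus Gaussian noise); under
#' truncation selection the top-valued males sire the next generation,
#' while all females are candidate dams.
#'
#' @param nGenerations number of generations (founders included).
#' @param nPerGeneration individuals per generation.
#' @param sexRatio proportion of males per generation.
#' @param nSiresSelected sires selected per generation.
#' @param nChromosomes,coresPerChromosome genome layout.
#' @param nFounderHaplotypes distinct founder haplotypes in each core's
#'   pool.
#' @param founderConcentration symmetric Dirichlet concentration of founder
#'   haplotype frequencies; smaller = more skewed spectrum.
#' @param recombProb probability of a recombination switch between adjacent
#'   cores per meiosis (default 0.1: ~100 cM chromosomes split into 10
#'   cores).
#' @param mosaicProb probability, per core per meiosis, of a crossover
#'   landing inside the core and creating a novel rare haplotype that is a
#'   mosaic of the two parental haplotypes at that core (the recombinant
#'   mosaics the flanking-context filter targets). The default keeps the
#'   singleton/doubleton share of the spectrum in the regime observed in
#'   phased livestock haplotype libraries.
#' @param selection \code{"truncation"} on the polygenic value, or
#'   \code{"random"} (sires drawn uniformly from all males).
#' @param polygenicNoiseSD SD of the within-family polygenic deviation.
#' @param seed optional RNG seed for a reproducible population.
#' @return a \linkS4class{SimulatedPopulation}; its \code{codes} hold
#'   founder-haplotype IDs per core (convert with
#'   \code{\link{haplotypeLibraryFromCodes}} or render marker alleles with
#'   \code{\link{renderMarkerAlleles}}).
#' @export
simulatePopulation <- function(nGenerations = 15L, nPerGeneration = 1000L,
                               sexRatio = 0.5, nSiresSelected = 25L,
                               nChromosomes = 10L, coresPerChromosome = 10L,
                               nFounderHaplotypes = 1000L,
                               founderConcentration = 0.01,
                               recombProb = 0.1, mosaicProb = 0.004,
                               selection = c("truncation", "random"),
                               polygenicNoiseSD = sqrt(0.5), seed = NULL) {
  selection <- match.arg(selection)
  if (!is.null(seed)) set.seed(seed)
  nGenerations <- as.integer(nGenerations)
  n <- as.integer(nPerGeneration)
  if (nGenerations < 1L || n < 2L) stop("invalid population size")
  if (recombProb < 0 || recombProb > 1) stop("recombProb must be in [0, 1]")
  nMale <- as.integer(round(n * sexRatio))
  if (nSiresSelected > nMale)
    stop("nSiresSelected exceeds males per generation")
  C <- as.integer(nChromosomes * coresPerChromosome)
  chromOfCore <- as.character(rep(seq_len(nChromosomes),
                                  each = coresPerChromosome))
  N <- nGenerations * n
  pat <- matrix(NA_integer_, N, C)
  mat <- matrix(NA_integer_, N, C)
  sex <- character(N)
  sire <- rep(NA_integer_, N)
  dam <- rep(NA_integer_, N)
  generation <- rep(seq_len(nGenerations), each = n)
  tbv <- numeric(N)
  # founder generation: per core, founder gametes draw a haplotype ID from
  # the core's pool of nFounderHaplotypes distinct haplotypes, with
  # Dirichlet frequencies. Draws are independent across cores, so
  # haplotype sharing between founder chromosomes decays across cores (as
  # in coalescent-derived data, where the genealogy changes along the
  # chromosome); recombinant mosaics of founder haplotypes then accumulate
  # through the pedigree.
  for (c in seq_len(C)) {
    p <- stats::rgamma(nFounderHaplotypes, shape = founderConcentration)
    if (sum(p) == 0) p <- rep(1, nFounderHaplotypes)
    p <- p / sum(p)
    pat[seq_len(n), c] <- sample.int(nFounderHaplotypes, n, replace = TRUE,
                                     prob = p)
    mat[seq_len(n), c] <- sample.int(nFounderHaplotypes, n, replace = TRUE,
                                     prob = p)
  }
  sex[seq_len(n)] <- sample(c(rep("M", nMale), rep("F", n - nMale)))
  tbv[seq_len(n)] <- stats::rnorm(n)
  nSwitches <- 0L
  nMosaic <- 0L
  nMeioses <- 0L
  registry <- list(map = replicate(C, list(), simplify = FALSE),
                   log = replicate(C, NULL, simplify = FALSE))
  nextId <- rep(as.integer(nFounderHaplotypes) + 1L, C)
  for (g in seq_len(nGenerations)[-1L]) {
    prev <- which(generation == g - 1L)
    rows <- which(generation == g)
    males <- prev[sex[prev] == "M"]
    females <- prev[sex[prev] == "F"]
    sirePool <- if (selection == "truncation")
      males[order(tbv[males], decreasing = TRUE)][seq_len(nSiresSelected)]
    else males
    s <- sirePool[sample.int(length(sirePool), n, replace = TRUE)]
    d <- females[sample.int(length(females), n, replace = TRUE)]
    gp <- .meiose(pat[s, , drop = FALSE], mat[s, , drop = FALSE],
                  chromOfCore, recombProb, mosaicProb, registry, nextId)
    registry <- gp$registry
    nextId <- gp$nextId
    gm <- .meiose(pat[d, , drop = FALSE], mat[d, , drop = FALSE],
                  chromOfCore, recombProb, mosaicProb, registry, nextId)
    registry <- gm$registry
    nextId <- gm$nextId
    nSwitches <- nSwitches + gp$nSwitches + gm$nSwitches
    nMosaic <- nMosaic + gp$nMosaic + gm$nMosaic
    nMeioses <- nMeioses + 2L * n
    pat[rows, ] <- gp$out
    mat[rows, ] <- gm$out
    sire[rows] <- s
    dam[rows] <- d
    sex[rows] <- sample(c(rep("M", nMale), rep("F", n - nMale)))
    tbv[rows] <- (tbv[s] + tbv[d]) / 2 +
      stats::rnorm(n, sd = polygenicNoiseSD)
  }
  ids <- sprintf("ind%06d", seq_len(N))
  ped <- data.frame(
    id = ids,
    sire = ifelse(is.na(sire), NA_character_, ids[sire]),
    dam = ifelse(is.na(dam), NA_character_, ids[dam]),
    sex = sex, generation = generation,
    polygenicValue = tbv)
  codes <- new("DiplotypeCodes", ids = ids, paternal = pat, maternal = mat)
  new("SimulatedPopulation", pedigree = ped, codes = codes,
      chromOfCore = chromOfCore,
      params = list(nGenerations = nGenerations, nPerGeneration = n,
                    sexRatio = sexRatio, nSiresSelected = nSiresSelected,
                    nChromosomes = nChromosomes,
                    coresPerChromosome = coresPerChromosome,
                    nFounderHaplotypes = nFounderHaplotypes,
                    founderConcentration = founderConcentration,
                    recombProb = recombProb, mosaicProb = mosaicProb,
                    selection = selection,
                    polygenicNoiseSD = polygenicNoiseSD,
                    nSwitches = nSwitches, nMosaic = nMosaic,
                    nMeioses = nMeioses,
                    mosaics = registry$log))
}

#' Render marker alleles for a simulated population
#'
#' Assigns each founder core-haplotype a distinct random biallelic string of
#' \code{markersPerCore} markers and emits phased genotypes, so that
#' \code{\link{buildLibrary}} with zero mismatches recovers the simulated
#' haplotype structure exactly (up to ID relabelling). Colliding founder
#' strings within a core are redrawn; the number of retries is recorded in
#' the result's \code{"retries"} attribute.
#'
#' @param pop a \linkS4class{SimulatedPopulation}.
#' @param markersPerCore markers per core (must allow
#'   \code{nFounderHaplotypes} distinct strings).
#' @param seed optional RNG seed.
#' @return a \linkS4class{PhasedGenotypes} (attribute \code{"coreMap"}
#'   holds the matching \linkS4class{CoreMap}).
#' @export
renderMarkerAlleles <- function(pop, markersPerCore, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- as.integer(markersPerCore)
  if (m < 1L) stop("markersPerCore must be >= 1")
  nF <- pop@params$nFounderHaplotypes
  if (2^min(m, 30) < nF)
    stop("markersPerCore too small for ", nF, " distinct founder strings")
  C <- ncol(pop@codes@paternal)
  n <- length(pop@codes@ids)
  patAll <- matrix(NA_integer_, n, C * m)
  matAll <- matrix(NA_integer_, n, C * m)
  retries <- 0L
  mosaics <- pop@params$mosaics
  for (c in seq_len(C)) {
    fnd <- matrix(stats::rbinom(nF * m, 1L, 0.5), nF, m)
    repeat {
      key <- do.call(paste0, as.data.frame(fnd))
      dup <- which(duplicated(key))
      if (!length(dup)) break
      retries <- retries + length(dup)
      fnd[dup, ] <- stats::rbinom(length(dup) * m, 1L, 0.5)
    }
    mos <- mosaics[[c]]
    nMos <- if (is.null(mos)) 0L else nrow(mos)
    M <- rbind(fnd, matrix(NA_integer_, nMos, m))
    keys <- do.call(paste0, as.data.frame(fnd))
    if (nMos > 0L) {
      if (m < 2L)
        stop("markersPerCore must be >= 2 to render mosaic haplotypes")
      mos <- mos[order(mos$id), , drop = FALSE]
      for (j in seq_len(nMos)) {
        # left/right IDs were created earlier, so their rows of M are
        # already materialised
        placed <- FALSE
        for (b in sample.int(m - 1L)) {
          cand <- c(M[mos$left[j], seq_len(b)],
                    M[mos$right[j], (b + 1L):m])
          ck <- paste0(cand, collapse = "")
          if (!(ck %in% keys)) {
            M[mos$id[j], ] <- cand
            keys <- c(keys, ck)
            placed <- TRUE
            break
          }
          retries <- retries + 1L
        }
        if (!placed)
          stop("no breakpoint renders a distinct string for mosaic ",
               "haplotype ", mos$id[j], " at core ", c,
               "; increase markersPerCore")
      }
    }
    cols <- (c - 1L) * m + seq_len(m)
    patAll[, cols] <- M[pop@codes@paternal[, c], ]
    matAll[, cols] <- M[pop@codes@maternal[, c], ]
  }
  if (retries > 0L)
    message("renderMarkerAlleles: redrew ", retries,
            " colliding founder string(s)")
  markerMap <- data.frame(chrom = rep(pop@chromOfCore, each = m))
  g <- phasedGenotypes(pop@codes@ids, patAll, matAll, markerMap)
  attr(g, "coreMap") <- makeCoreMap(markerMap, m)
  attr(g, "retries") <- retries
  g
}
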