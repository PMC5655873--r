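# Independent, deliberately naive reference implementations used as
# oracles. They re-derive quantities from first principles (explicit loops
# over gametes and cores) and share no code with the package internals.

# multiset multiplicities of identical strings, in first-appearance order
oracleStringCounts <- function(strings) {
  u <- unique(strings[!is.na(strings)])
  vapply(u, function(s) sum(strings == s, na.rm = TRUE), integer(1),
         USE.NAMES = FALSE)
}

# per-haplotype score evaluated straight from the printed formulas
oracleHapScore <- function(count, method, targetCov, freq = NULL) {
  if (method == "hapcov") {
    if (count >= 2 * targetCov) 0
    else exp((count / (2 * targetCov - 1))^2)
  } else {
    if (count >= 2 * targetCov) 0 else (1 - freq)^2
  }
}

# individual score: loop over cores and both gametes
oracleIndividualScore <- function(i, codes, library, counts, targeted,
                                  method, targetCov) {
  total <- 0
  for (c in seq_len(ncol(codes@paternal))) {
    for (h in c(codes@paternal[i, c], codes@maternal[i, c])) {
      if (is.na(h)) next
      f <- library@offsets[c] + h
      if (!targeted[f]) next
      total <- total + oracleHapScore(
        counts[f], method, targetCov,
        library@counts[[c]][h] / library@nAssigned[c])
    }
  }
  total
}

# from-scratch haplotype count recount: loop over every individual's
# coverage, core and gamete
oracleRecount <- function(set, codes, library, prior = NULL) {
  K <- nHaplotypes(library)
  counts <- integer(K)
  cov <- indCoverage(set)
  if (!is.null(prior)) {
    for (id in names(prior)) {
      x <- prior[[id]]
      if (id %in% names(cov)) cov[id] <- cov[id] + x
      else cov[id] <- x
    }
  }
  for (id in names(cov)) {
    i <- match(id, codes@ids)
    for (c in seq_len(ncol(codes@paternal))) {
      for (h in c(codes@paternal[i, c], codes@maternal[i, c])) {
        if (is.na(h)) next
        f <- library@offsets[c] + h
        counts[f] <- counts[f] + cov[[id]]
      }
    }
  }
  counts
}

# brute-force evaluation of the three flanking-context conditions for
# every rare haplotype
oracleRareFilter <- function(library, codes, rareThr, flankCount, nComb) {
  K <- nHaplotypes(library)
  keep <- rep(TRUE, K)
  chrom <- as.character(library@cores$chrom)
  C <- length(chrom)
  G <- rbind(codes@paternal, codes@maternal)
  for (c in seq_len(C)) {
    for (h in seq_along(library@counts[[c]])) {
      if (library@counts[[c]][h] > rareThr) next
      f <- library@offsets[c] + h
      if (c == 1L || c == C || chrom[c - 1L] != chrom[c] ||
          chrom[c + 1L] != chrom[c]) {
        keep[f] <- FALSE
        next
      }
      ok <- TRUE
      for (g in seq_len(nrow(G))) {
        if (is.na(G[g, c]) || G[g, c] != h) next
        L <- G[g, c - 1L]; R <- G[g, c + 1L]
        if (is.na(L) || is.na(R) ||
            library@counts[[c - 1L]][L] <= flankCount ||
            library@counts[[c + 1L]][R] <= flankCount) { ok <- FALSE; break }
        nPair <- 0L
        for (g2 in seq_len(nrow(G)))
          if (!is.na(G[g2, c - 1L]) && !is.na(G[g2, c + 1L]) &&
              G[g2, c - 1L] == L && G[g2, c + 1L] == R)
            nPair <- nPair + 1L
        if (nPair >= nComb) { ok <- FALSE; break }
      }
      keep[f] <- ok
    }
  }
  keep
}

# replay a greedy selection: check that each successive addition attains
# the maximum independently recomputed score among affordable, under-cap
# candidates, and that the budget is respected throughout
oracleCheckGreedyTrace <- function(set, codes, library, budget, targetCov,
                                   method = "hapcov", mask = NULL) {
  K <- nHaplotypes(library)
  targeted <- if (is.null(mask)) rep(TRUE, K) else mask
  counts <- integer(K)
  coverage <- integer(length(codes@ids))
  members <- setMembers(set)
  for (s in which(!is.na(members))) {
    filled <- sum(coverage)
    scores <- vapply(seq_along(codes@ids), function(i)
      oracleIndividualScore(i, codes, library, counts, targeted,
                            method, targetCov), numeric(1))
    afford <- vapply(seq_along(codes@ids), function(i) {
      extraLib <- if (coverage[i] == 0L) budget@libraryCost else 0
      cost <- budget@libraryCost * sum(coverage > 0L) + extraLib +
        budget@costPer1x * (filled + 1L)
      cost <= budget@totalBudget + 1e-9
    }, logical(1))
    cand <- afford & coverage < 2 * targetCov & scores > 0
    if (!any(cand)) return(FALSE)
    i <- match(members[s], codes@ids)
    if (!cand[i]) return(FALSE)
    if (scores[i] < max(scores[cand]) - 1e-9) return(FALSE)
    coverage[i] <- coverage[i] + 1L
    for (c in seq_len(ncol(codes@paternal)))
      for (h in c(codes@paternal[i, c], codes@maternal[i, c]))
        if (!is.na(h)) {
          f <- library@offsets[c] + h
          counts[f] <- counts[f] + 1L
        }
  }
  # final cost within budget
  totalCost(set, budget) <= budget@totalBudget + 1e-9
}

# small random population of diplotype codes with a skewed spectrum
randomToyPopulation <- function(n, C, K, conc = 0.4, missingProb = 0) {
  p <- stats::rgamma(K, conc) + 1e-9
  p <- p / sum(p)
  pat <- matrix(sample.int(K, n * C, TRUE, p), n, C)
  mat <- matrix(sample.int(K, n * C, TRUE, p), n, C)
  if (missingProb > 0) {
    pat[stats::runif(n * C) < missingProb] <- NA_integer_
    mat[stats::runif(n * C) < missingProb] <- NA_integer_
  }
  codes <- new("DiplotypeCodes", ids = sprintf("i%03d", seq_len(n)),
               paternal = pat, maternal = mat)
  haplotypeLibraryFromCodes(codes)
}
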