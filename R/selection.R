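#' Maximum number of sequencing slots under a budget
#'
#' The budget divided by the cost of 1x sequencing bounds the total
#' coverage that could be produced; each slot corresponds to 1x sequencing
#' of one individual. Because some resources go to library preparation,
#' some slots will usually be left empty.
#'
#' @param budget a \linkS4class{BudgetModel}.
#' @return integer slot count, \code{floor(totalBudget / costPer1x)}.
#' @examples
#' maxSlots(budgetModel(400000, 40, 80))   # 5000
#' maxSlots(budgetModel(1600000, 40, 80))  # 20000
#' @export
maxSlots <- function(budget) {
  stopifnot(is(budget, "BudgetModel"))
  as.integer(floor(budget@totalBudget / budget@costPer1x))
}

#' Total cost of a sequencing set
#'
#' Library-preparation cost times the number of unique individuals in the
#' set plus the cost of 1x sequencing times the total coverage produced
#' (filled slots); or the budget's \code{costHook} if one is set.
#'
#' @param set a \linkS4class{SequencingSet}.
#' @param budget a \linkS4class{BudgetModel}; defaults to the budget the set
#'   was built under.
#' @param libraryFreeIds individuals whose library already exists and incurs
#'   no cost.
#' @return numeric cost.
#' @export
totalCost <- function(set, budget = set@budget,
                      libraryFreeIds = character(0)) {
  cov <- indCoverage(set)
  filled <- sum(cov)
  if (!is.null(budget@costHook))
    return(budget@costHook(length(cov), filled))
  nLib <- sum(!(names(cov) %in% libraryFreeIds))
  budget@libraryCost * nLib + budget@costPer1x * filled
}

#' Add pre-existing sequencing coverage to a haplotype count state
#'
#' For each individual with prior coverage x, the count of every non-missing
#' haplotype copy it carries is incremented by x per copy (a homozygous core
#' contributes +2x to its haplotype).
#'
#' @param state a \linkS4class{HapCountState}.
#' @param codes a \linkS4class{DiplotypeCodes}.
#' @param library the matching \linkS4class{HaplotypeLibrary}.
#' @param prior named integer vector: pre-existing coverage (x) per
#'   individual ID.
#' @return the updated \linkS4class{HapCountState}.
#' @export
applyPriorCoverage <- function(state, codes, library, prior) {
  if (!length(prior)) return(state)
  if (is.null(names(prior)) || any(!nzchar(names(prior))))
    stop("prior must be a named vector of coverages")
  unknown <- setdiff(names(prior), codes@ids)
  if (length(unknown))
    stop("prior coverage for unknown individual(s): ",
         paste(unknown, collapse = ", "))
  if (any(prior < 0)) stop("prior coverages must be >= 0")
  idx0 <- .flatCodes(codes, library)
  counts <- state@counts
  rows <- match(names(prior), codes@ids)
  for (j in seq_along(rows)) {
    v <- idx0[rows[j], ]
    v <- v[v > 0L]
    for (f in v) counts[f] <- counts[f] + as.integer(prior[j])
  }
  new("HapCountState", counts = counts, targeted = state@targeted)
}

#' Recount haplotype appearances of a sequencing set from scratch
#'
#' @param set a \linkS4class{SequencingSet}.
#' @param codes,library the population the set was selected from.
#' @param prior optional named prior-coverage vector included in the count.
#' @return integer vector over all (core, haplotype) pairs (flat indexing).
#' @export
tallyHapCounts <- function(set, codes, library, prior = NULL) {
  state <- newHapCountState(library)
  if (!is.null(prior))
    state <- applyPriorCoverage(state, codes, library, prior)
  cov <- indCoverage(set)
  if (length(cov))
    state <- applyPriorCoverage(state, codes, library, cov)
  state@counts
}

# percentage of targeted unique haplotypes whose count has reached twice
# the target coverage (the expected-coverage model's "at or above target").
# Single source of truth for the refinement acceptance rule and for
# summarizeCoverage.
.pctAtTarget <- function(counts, targeted, targetCov) {
  nT <- sum(targeted)
  if (nT == 0L) stop("no targeted haplotypes")
  100 * sum(counts[targeted] >= 2 * targetCov) / nT
}

# Build the reusable selection context for one population/problem.
.selectionContext <- function(codes, library, budget, targetCov, method,
                              state, mask, maxIndividualCoverage,
                              priorLibraryFree) {
  n <- length(codes@ids)
  if (n == 0L) stop("empty population")
  if (targetCov < 1) stop("targetCov must be >= 1")
  K <- nHaplotypes(library)
  if (is.null(state)) state <- newHapCountState(library)
  if (length(state@counts) != K)
    stop("state does not match library")
  targeted <- state@targeted
  if (!is.null(mask)) {
    if (length(mask) != K) stop("mask length must equal nHaplotypes(library)")
    targeted <- targeted & mask
  }
  if (method == "iws_homozygous")
    targeted <- targeted & .homozygousMask(codes, library)
  cap <- min(if (is.null(maxIndividualCoverage)) Inf
             else maxIndividualCoverage, 2 * targetCov)
  if (cap < 1) stop("maxIndividualCoverage must be >= 1")
  # haplotypes that cannot reach the target under the coverage cap are
  # pre-excluded from targeting (see minCarriersForTarget)
  if (is.finite(cap) && cap < 2 * targetCov)
    targeted <- targeted & (hapPopCounts(library) >=
                              minCarriersForTarget(targetCov, cap))
  idx0 <- .flatCodes(codes, library)
  list(n = n, ids = codes@ids, idx0 = idx0, carried = .carriedList(idx0),
       targeted = targeted, baseCounts = state@counts,
       method = method, targetCov = targetCov, cap = cap,
       popFreq = if (method %in% c("iws", "iws_homozygous"))
         populationFrequencies(library) else NULL,
       total = budget@totalBudget, libCost = budget@libraryCost,
       per1x = budget@costPer1x, hook = budget@costHook,
       libFree = codes@ids %in% priorLibraryFree)
}

# Greedy (or random) filling of the empty slots of a set.
# members/counts/coverage are the current state; emptyQueue gives the slot
# positions to fill, lowest index first. Ties for the maximum score are
# broken uniformly at random; stops when slots, affordable candidates, or
# positive scores run out.
.fillSet <- function(ctx, members, counts, coverage) {
  emptyQueue <- which(is.na(members))
  qi <- 1L
  repeat {
    if (qi > length(emptyQueue)) break
    nUnique <- sum(coverage > 0L)
    filled <- sum(coverage)
    if (is.null(ctx$hook)) {
      base <- ctx$libCost * sum(coverage > 0L & !ctx$libFree) +
        ctx$per1x * (filled + 1L)
      addLib <- ifelse(coverage > 0L | ctx$libFree, 0, ctx$libCost)
      afford <- (base + addLib) <= ctx$total + 1e-9
    } else {
      costExist <- ctx$hook(nUnique, filled + 1L)
      costNew <- ctx$hook(nUnique + 1L, filled + 1L)
      afford <- ifelse(coverage > 0L, costExist, costNew) <= ctx$total + 1e-9
    }
    cand <- afford & coverage < ctx$cap
    if (!any(cand)) break
    if (ctx$method == "random") {
      w <- which(cand)
      pick <- w[sample.int(length(w), 1L)]
    } else {
      s <- .hapScores(counts, ctx$targeted, ctx$method, ctx$targetCov,
                      ctx$popFreq)
      indScore <- .individualScores(s, ctx$idx0)
      indScore[!cand] <- -Inf
      best <- max(indScore)
      if (best <= 0) break  # all targeted haplotypes capped: stop, leave
                            # remaining slots empty
      w <- which(indScore == best)
      pick <- w[sample.int(length(w), 1L)]
    }
    members[emptyQueue[qi]] <- ctx$ids[pick]
    qi <- qi + 1L
    coverage[pick] <- coverage[pick] + 1L
    cr <- ctx$carried[[pick]]
    counts[cr$index] <- counts[cr$index] + cr$mult
  }
  list(members = members, counts = counts, coverage = coverage)
}

#' Greedy selection of an initial sequencing set
#'
#' Iteratively adds the individual with the maximum total score (the sum of
#' its carried haplotypes' scores under the current set state) to the first
#' available slot, incrementing each carried haplotype's count by one per
#' copy, until the budget is exhausted, all slots are filled, or every
#' candidate's score is zero. Candidates whose marginal cost (1x sequencing,
#' plus library preparation if not yet in the set) exceeds the remaining
#' budget are skipped in favour of the next-best affordable candidate. Ties
#' for the maximum score are broken uniformly at random, so with all counts
#' at zero the first pick is a random individual among those carrying the
#' most non-missing targeted haplotypes.
#'
#' @param codes a \linkS4class{DiplotypeCodes}.
#' @param library the matching \linkS4class{HaplotypeLibrary}.
#' @param budget a \linkS4class{BudgetModel}.
#' @param targetCov target haplotype coverage (x).
#' @param method \code{"hapcov"} (coverage-balancing score, default),
#'   \code{"iws"} (population-frequency score), \code{"iws_homozygous"}
#'   (population-frequency score targeting only haplotypes observed
#'   homozygous in at least one individual), or \code{"random"}.
#' @param state optional \linkS4class{HapCountState} carrying pre-existing
#'   coverage (see \code{\link{applyPriorCoverage}}) and/or targeting.
#' @param mask optional flat logical targeting mask from
#'   \code{\link{applyRareFilter}}; combined (AND) with the state's.
#' @param maxIndividualCoverage optional cap on slots per individual; the
#'   effective cap is never above twice the target coverage. When the cap
#'   binds, haplotypes whose population count cannot reach the target are
#'   pre-excluded from targeting.
#' @param priorLibraryFree IDs of individuals whose sequencing library
#'   already exists, so adding them incurs no library cost.
#' @return a \linkS4class{SequencingSet}; its \code{metadata} records the
#'   method, target, final haplotype counts, targeting mask and cost.
#' @seealso \code{\link{refineSet}}, \code{\link{selectRandom}},
#'   \code{\link{selectIWSOriginal}}
#' @export
greedySelect <- function(codes, library, budget, targetCov,
                         method = c("hapcov", "iws", "iws_homozygous",
                                    "random"),
                         state = NULL, mask = NULL,
                         maxIndividualCoverage = NULL,
                         priorLibraryFree = character(0)) {
  method <- match.arg(method)
  stopifnot(is(codes, "DiplotypeCodes"), is(library, "HaplotypeLibrary"),
            is(budget, "BudgetModel"))
  ctx <- .selectionContext(codes, library, budget, targetCov, method,
                           state, mask, maxIndividualCoverage,
                           priorLibraryFree)
  members <- rep(NA_character_, maxSlots(budget))
  res <- .fillSet(ctx, members, ctx$baseCounts, integer(ctx$n))
  .newSet(res, ctx, budget)
}

.newSet <- function(res, ctx, budget, trajectory = NULL) {
  set <- new("SequencingSet", members = res$members, budget = budget,
             metadata = list())
  set@metadata <- list(
    method = ctx$method, targetCov = ctx$targetCov,
    counts = res$counts, targeted = ctx$targeted,
    cost = totalCost(set, budget,
                     libraryFreeIds = ctx$ids[ctx$libFree]),
    pctAtTarget = if (any(ctx$targeted))
      .pctAtTarget(res$counts, ctx$targeted, ctx$targetCov) else NA_real_,
    trajectory = trajectory)
  set
}

#' Refine a sequencing set through rounds of slot exchanges
#'
#' Each round removes the occupants of a random sample of filled slots
#' (decrementing their haplotype counts; an individual that loses all its
#' slots frees its library cost) and refills the emptied slots by the greedy
#' rule; removed individuals may re-enter. The new set is retained if and
#' only if its percentage of targeted unique haplotypes at (or above) the
#' target coverage is at least the incumbent's, so the incumbent metric is
#' non-decreasing over rounds. With \code{method = "random"} exchanges are
#' random and always accepted. Exchanging all slots each round amounts to
#' drawing independent fresh selections and keeping the best.
#'
#' @param set the \linkS4class{SequencingSet} to refine.
#' @inheritParams greedySelect
#' @param exchangeRounds number of exchange rounds.
#' @param exchangesPerRound slots exchanged per round; clipped (with a
#'   warning) to the number of filled slots.
#' @return the refined \linkS4class{SequencingSet}; \code{metadata$trajectory}
#'   holds the incumbent metric before refinement and after each round.
#' @export
refineSet <- function(set, codes, library, budget = set@budget, targetCov,
                      method = c("hapcov", "iws", "random"),
                      exchangeRounds = 100L, exchangesPerRound = 10L,
                      state = NULL, mask = NULL,
                      maxIndividualCoverage = NULL,
                      priorLibraryFree = character(0)) {
  method <- match.arg(method)
  exchangeRounds <- as.integer(exchangeRounds)
  exchangesPerRound <- as.integer(exchangesPerRound)
  if (exchangesPerRound < 1L) stop("exchangesPerRound must be >= 1")
  ctx <- .selectionContext(codes, library, budget, targetCov, method,
                           state, mask, maxIndividualCoverage,
                           priorLibraryFree)
  members <- set@members
  coverage <- integer(ctx$n)
  cov <- indCoverage(set)
  coverage[match(names(cov), ctx$ids)] <- as.integer(cov)
  counts <- ctx$baseCounts
  for (i in which(coverage > 0L)) {
    cr <- ctx$carried[[i]]
    counts[cr$index] <- counts[cr$index] + cr$mult * coverage[i]
  }
  metric <- .pctAtTarget(counts, ctx$targeted, ctx$targetCov)
  trajectory <- numeric(exchangeRounds + 1L)
  trajectory[1L] <- metric
  clipWarned <- FALSE
  for (r in seq_len(exchangeRounds)) {
    filled <- which(!is.na(members))
    if (!length(filled)) break
    k <- exchangesPerRound
    if (k > length(filled)) {
      if (!clipWarned) {
        warning("exchangesPerRound exceeds filled slots; clipped to ",
                length(filled))
        clipWarned <- TRUE
      }
      k <- length(filled)
    }
    sel <- filled[sample.int(length(filled), k)]
    newMembers <- members
    newCounts <- counts
    newCoverage <- coverage
    for (s in sel) {
      i <- match(newMembers[s], ctx$ids)
      newMembers[s] <- NA_character_
      newCoverage[i] <- newCoverage[i] - 1L
      cr <- ctx$carried[[i]]
      newCounts[cr$index] <- newCounts[cr$index] - cr$mult
    }
    res <- .fillSet(ctx, newMembers, newCounts, newCoverage)
    newMetric <- .pctAtTarget(res$counts, ctx$targeted, ctx$targetCov)
    if (method == "random" || newMetric >= metric) {
      members <- res$members
      counts <- res$counts
      coverage <- res$coverage
      metric <- newMetric
    }
    trajectory[r + 1L] <- metric
  }
  .newSet(list(members = members, counts = counts, coverage = coverage),
          ctx, budget, trajectory = trajectory)
}

#' Random allocation of sequencing slots
#'
#' Fills slots with uniformly random affordable individuals respecting the
#' coverage cap; the comparison baseline for the score-driven methods.
#'
#' @inheritParams greedySelect
#' @return a \linkS4class{SequencingSet}.
#' @export
selectRandom <- function(codes, library, budget, targetCov,
                         state = NULL, mask = NULL,
                         maxIndividualCoverage = NULL,
                         priorLibraryFree = character(0)) {
  greedySelect(codes, library, budget, targetCov, method = "random",
               state = state, mask = mask,
               maxIndividualCoverage = maxIndividualCoverage,
               priorLibraryFree = priorLibraryFree)
}

#' Original inverse weight selection (homozygous-only targeting)
#'
#' The original IWS strategy: only haplotypes observed in homozygous state
#' in at least one individual are targeted, scored by the population
#' frequency inverted parabola, and selection stops after the initial set is
#' constructed with no refinement. It may terminate with unspent budget once
#' every targeted haplotype's count is capped.
#'
#' @inheritParams greedySelect
#' @return a \linkS4class{SequencingSet}.
#' @export
selectIWSOriginal <- function(codes, library, budget, targetCov,
                              state = NULL, mask = NULL,
                              maxIndividualCoverage = NULL,
                              priorLibraryFree = character(0)) {
  greedySelect(codes, library, budget, targetCov, method = "iws_homozygous",
               state = state, mask = mask,
               maxIndividualCoverage = maxIndividualCoverage,
               priorLibraryFree = priorLibraryFree)
}
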