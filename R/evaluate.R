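#' Summarize the haplotype coverage achieved by a sequencing set
#'
#' Expected haplotype coverage is HapCount x 0.5: each 1x of a carrier
#' reads either the paternal or maternal gamete with probability 0.5, so a
#' haplotype needs an appearance count of twice the target coverage to
#' reach the target in expectation. Percentages are over targeted unique
#' haplotypes; the histogram bins coverage at half-x steps (a zero bin,
#' then (0, 0.5], (0.5, 1], ...).
#'
#' @param set a \linkS4class{SequencingSet}.
#' @param codes,library the population the set was selected from.
#' @param targetCov target haplotype coverage (x).
#' @param mask optional flat logical targeting mask (default: mask stored
#'   in the set's metadata, else all haplotypes).
#' @param prior optional named prior-coverage vector counted in addition to
#'   the set.
#' @return a \linkS4class{CoverageSummary}.
#' @export
summarizeCoverage <- function(set, codes, library, targetCov,
                              mask = NULL, prior = NULL) {
  K <- nHaplotypes(library)
  if (is.null(mask)) mask <- set@metadata$targeted
  if (is.null(mask)) mask <- rep(TRUE, K)
  if (length(mask) != K) stop("mask length must equal nHaplotypes(library)")
  if (!any(mask)) stop("empty target mask")
  counts <- tallyHapCounts(set, codes, library, prior)
  tc <- counts[mask]
  nT <- sum(mask)
  pctAt <- .pctAtTarget(counts, mask, targetCov)
  pctZero <- 100 * sum(tc == 0L) / nT
  pctUnder <- 100 * sum(tc > 0L & tc < 2 * targetCov) / nT
  pop <- hapPopCounts(library)
  wAll <- sum(pop[mask])
  wAt <- sum(pop[mask & counts >= 2 * targetCov])
  covX <- tc / 2
  upper <- max(0.5, ceiling(max(covX) * 2) / 2)
  edges <- seq(0.5, upper, by = 0.5)
  hist <- data.frame(
    lower = c(0, 0, edges[-length(edges)]),
    upper = c(0, edges),
    nHaplotypes = c(sum(covX == 0),
                    vapply(seq_along(edges), function(i) {
                      lo <- c(0, edges)[i]
                      sum(covX > lo & covX <= edges[i])
                    }, numeric(1))))
  cov <- indCoverage(set)
  covTab <- if (length(cov)) {
    t <- table(factor(cov, levels = seq_len(max(cov))))
    data.frame(coverage = as.integer(names(t)),
               nIndividuals = as.integer(t))
  } else data.frame(coverage = integer(0), nIndividuals = integer(0))
  new("CoverageSummary",
      pctAtTarget = pctAt, pctZero = pctZero, pctUnderTarget = pctUnder,
      totalPctWeighted = 100 * wAt / wAll,
      histogram = hist, setSize = length(cov), coverageTable = covTab,
      targetCov = as.numeric(targetCov), nTargeted = as.integer(nT))
}

#' Minimum carriers needed for a haplotype to reach the target coverage
#'
#' Under a cap on individual coverage, a haplotype's appearance count can
#' grow by at most the cap per carried gamete copy, so only haplotypes with
#' population count at least \code{ceiling(2 * targetCov /
#' maxIndividualCoverage)} can reach the target in expectation. With a 1x
#' cap this threshold is 10, 20 and 30 carriers for targets of 5x, 10x and
#' 15x; haplotypes below it are pre-excluded from targeting when a cap is
#' active.
#'
#' @param targetCov target haplotype coverage (x).
#' @param maxIndividualCoverage per-individual coverage cap (x), >= 1.
#' @return integer carrier-count threshold.
#' @examples
#' minCarriersForTarget(10, 1)  # 20
#' minCarriersForTarget(10, 4)  # 5
#' @export
minCarriersForTarget <- function(targetCov, maxIndividualCoverage) {
  if (maxIndividualCoverage < 1) stop("maxIndividualCoverage must be >= 1")
  as.integer(ceiling(2 * targetCov / maxIndividualCoverage))
}
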