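#' Coverage-balancing haplotype score
#'
#' The score a haplotype contributes while building the sequencing set,
#' based on its appearance count in the set relative to the target coverage:
#' \deqn{Score = exp((HapCount / (2 TargetCov - 1))^2)} while
#' \eqn{HapCount < 2 TargetCov}, and 0 once the count reaches twice the
#' target coverage (the count needed to produce the target coverage, since
#' each 1x of a carrier reads either gamete with probability 0.5). Scores
#' therefore rise from 1 (unsequenced) to e (one appearance short of
#' target), then drop to 0 to prevent over-sequencing well-covered
#' haplotypes.
#'
#' @param hapCount appearance count(s) in the current sequencing set,
#'   including pre-existing coverage; non-negative integer(s).
#' @param targetCov target haplotype coverage (x), integer >= 1.
#' @return numeric score(s) in \{0\} U [1, e].
#' @examples
#' hapScoreCoverage(0, 10)   # 1
#' hapScoreCoverage(19, 10)  # e
#' hapScoreCoverage(20, 10)  # 0
#' @export
hapScoreCoverage <- function(hapCount, targetCov) {
  if (length(targetCov) != 1L || targetCov < 1)
    stop("targetCov must be a single value >= 1")
  if (any(hapCount < 0)) stop("hapCount must be non-negative")
  ifelse(hapCount < 2 * targetCov,
         exp((hapCount / (2 * targetCov - 1))^2), 0)
}

#' Inverse-weight (IWS) haplotype score
#'
#' The inverted-parabola score of the inverse weight selection method:
#' \eqn{f^2 - 2f + 1 = (1 - f)^2}, where \eqn{f} is the fixed population
#' frequency of the haplotype. Rare haplotypes score near 1, ubiquitous
#' ones 0.
#'
#' @param popFrequency population frequency(ies) in [0, 1].
#' @return numeric score(s) in [0, 1].
#' @examples
#' hapScoreIWS(1)    # 0
#' hapScoreIWS(0.5)  # 0.25
#' @export
hapScoreIWS <- function(popFrequency) {
  if (any(popFrequency < 0 | popFrequency > 1))
    stop("popFrequency must lie in [0, 1]")
  popFrequency^2 - 2 * popFrequency + 1
}

# Flat per-haplotype score vector under the current counts.
# All methods zero a haplotype once its count reaches 2*targetCov, and
# untargeted haplotypes always score 0. method "random" scores everything 0
# (selection is by random draw, not score).
.hapScores <- function(counts, targeted, method, targetCov, popFreq = NULL) {
  s <- switch(method,
    hapcov = hapScoreCoverage(counts, targetCov),
    iws = ,
    iws_homozygous = ifelse(counts >= 2 * targetCov, 0,
                            hapScoreIWS(popFreq)),
    random = numeric(length(counts)),
    stop("unknown method: ", method))
  s[!targeted] <- 0
  s
}

# individual scores = row sums of haplotype scores over carried copies.
# idx0: n x 2C flat-index matrix with 0 for missing assignments.
.individualScores <- function(hapScores, idx0) {
  sc0 <- c(0, hapScores)
  rowSums(matrix(sc0[idx0 + 1L], nrow = nrow(idx0)))
}

#' Total score of each individual under the current sequencing-set state
#'
#' Sum, over all cores and both gametes, of the haplotype score of each
#' non-missing, targeted assignment; a homozygous core contributes its
#' haplotype's score twice.
#'
#' @param codes a \linkS4class{DiplotypeCodes}.
#' @param library the matching \linkS4class{HaplotypeLibrary}.
#' @param state a \linkS4class{HapCountState} (see
#'   \code{\link{newHapCountState}}).
#' @param targetCov target haplotype coverage (x).
#' @param method scoring method: \code{"hapcov"} (coverage-balancing,
#'   default), \code{"iws"}/\code{"iws_homozygous"} (population-frequency
#'   inverted parabola with the same zero cap at twice the target
#'   coverage), or \code{"random"} (all zero; selection is by random draw).
#' @return named numeric vector of individual scores.
#' @export
individualScores <- function(codes, library, state, targetCov,
                             method = c("hapcov", "iws", "iws_homozygous",
                                        "random")) {
  method <- match.arg(method)
  idx0 <- .flatCodes(codes, library)
  popFreq <- if (method %in% c("iws", "iws_homozygous"))
    populationFrequencies(library) else NULL
  s <- .hapScores(state@counts, state@targeted, method, targetCov, popFreq)
  structure(.individualScores(s, idx0), names = codes@ids)
}

#' Create a fresh haplotype count state
#'
#' @param library a \linkS4class{HaplotypeLibrary}.
#' @param targeted optional flat logical targeting mask (from
#'   \code{\link{applyRareFilter}}); default: all haplotypes targeted.
#' @return a \linkS4class{HapCountState} with all counts zero.
#' @export
newHapCountState <- function(library, targeted = NULL) {
  K <- nHaplotypes(library)
  if (is.null(targeted)) targeted <- rep(TRUE, K)
  if (length(targeted) != K)
    stop("targeted mask length must equal nHaplotypes(library)")
  new("HapCountState", counts = integer(K), targeted = as.logical(targeted))
}
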