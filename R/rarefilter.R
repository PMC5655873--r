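#' Decide which rare haplotypes are targeted
#'
#' Haplotypes with a population count at or below \code{rareCountThreshold}
#' (singletons and doubletons by default) are either all targeted
#' (\code{mode = "none"}), all untargeted (\code{mode = "exclude"}), or
#' kept only when their flanking context marks them as a likely recombinant
#' mosaic of common haplotypes (\code{mode = "flanking"}). Under
#' \code{"flanking"}, a rare haplotype stays targeted iff for every gamete
#' carrying it: (1) its core is not the first or last core of the
#' chromosome; (2) both flanking haplotypes (same gamete, adjacent cores)
#' are non-missing with population counts greater than \code{flankCount};
#' and (3) fewer than \code{nComb} gametes in the population carry that
#' exact (left, right) flanking pair. Runs of consecutive rare cores, or a
#' flanking-pair context shared by many gametes, instead suggest an
#' unrelated genome or a phasing error, and such rare haplotypes are
#' dropped. Common haplotypes are always targeted.
#'
#' @param library a \linkS4class{HaplotypeLibrary}.
#' @param codes the matching \linkS4class{DiplotypeCodes}.
#' @param mode one of \code{"none"}, \code{"exclude"}, \code{"flanking"}.
#' @param rareCountThreshold population count at or below which a haplotype
#'   is rare (default 2).
#' @param flankCount flanking haplotypes must have population counts
#'   strictly greater than this (default 2).
#' @param nComb the flanking combination must be carried by strictly fewer
#'   than this many gametes (default 3).
#' @param combUnit whether condition (3) counts carrier \code{"gamete"}s
#'   (phase-consistent default) or distinct \code{"individual"}s.
#' @return logical targeting mask over all (core, haplotype) pairs in flat
#'   indexing, with a \code{"reason"} attribute (character codes:
#'   \code{common}, \code{rare_kept}, \code{rare_excluded},
#'   \code{edge_core}, \code{flank_fail}, \code{comb_fail}).
#' @export
applyRareFilter <- function(library, codes,
                            mode = c("none", "exclude", "flanking"),
                            rareCountThreshold = 2L, flankCount = 2L,
                            nComb = 3L,
                            combUnit = c("gamete", "individual")) {
  mode <- match.arg(mode)
  combUnit <- match.arg(combUnit)
  if (rareCountThreshold < 0L || flankCount < 0L || nComb < 0L)
    stop("thresholds must be non-negative")
  K <- nHaplotypes(library)
  popCounts <- hapPopCounts(library)
  rare <- popCounts <= rareCountThreshold
  mask <- rep(TRUE, K)
  reason <- rep("common", K)
  reason[rare] <- "rare_kept"
  if (mode == "none") {
    attr(mask, "reason") <- reason
    return(mask)
  }
  if (mode == "exclude") {
    mask[rare] <- FALSE
    reason[rare] <- "rare_excluded"
    attr(mask, "reason") <- reason
    return(mask)
  }
  # mode == "flanking"
  C <- nCores(library)
  chrom <- as.character(library@cores$chrom)
  # gamete x core matrix (2n rows: all paternal gametes then all maternal)
  G <- rbind(codes@paternal, codes@maternal)
  gameteInd <- rep(seq_len(length(codes@ids)), 2L)
  for (c in seq_len(C)) {
    rareHere <- which(library@counts[[c]] <= rareCountThreshold)
    if (!length(rareHere)) next
    flat <- library@offsets[c] + rareHere
    edge <- c == 1L || c == C || chrom[c] != chrom[c - 1L] ||
      chrom[c] != chrom[c + 1L]
    if (edge) {
      mask[flat] <- FALSE
      reason[flat] <- "edge_core"
      next
    }
    cntL <- library@counts[[c - 1L]]
    cntR <- library@counts[[c + 1L]]
    for (j in seq_along(rareHere)) {
      h <- rareHere[j]
      carriers <- which(!is.na(G[, c]) & G[, c] == h)
      keep <- TRUE
      why <- "rare_kept"
      for (g in carriers) {
        L <- G[g, c - 1L]
        R <- G[g, c + 1L]
        if (is.na(L) || is.na(R) ||
            cntL[L] <= flankCount || cntR[R] <= flankCount) {
          keep <- FALSE; why <- "flank_fail"; break
        }
        pairCarrier <- !is.na(G[, c - 1L]) & !is.na(G[, c + 1L]) &
          G[, c - 1L] == L & G[, c + 1L] == R
        nPair <- if (combUnit == "gamete") sum(pairCarrier)
                 else length(unique(gameteInd[pairCarrier]))
        if (nPair >= nComb) {
          keep <- FALSE; why <- "comb_fail"; break
        }
      }
      mask[flat[j]] <- keep
      reason[flat[j]] <- why
    }
  }
  attr(mask, "reason") <- reason
  mask
}
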