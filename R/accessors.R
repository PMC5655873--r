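#' Construct a budget model
#'
#' @param totalBudget total sequencing budget (currency units).
#' @param libraryCost library-preparation cost per sequenced individual,
#'   charged once per individual in the set.
#' @param costPer1x cost of 1x sequencing of one individual.
#' @param costHook optional \code{function(nIndividuals, totalCoverage)}
#'   replacing the linear total-cost formula.
#' @return a \linkS4class{BudgetModel}.
#' @examples
#' budgetModel(400000, 40, 80)
#' @export
budgetModel <- function(totalBudget, libraryCost, costPer1x, costHook = NULL) {
  new("BudgetModel", totalBudget = as.numeric(totalBudget),
      libraryCost = as.numeric(libraryCost),
      costPer1x = as.numeric(costPer1x), costHook = costHook)
}

#' Number of cores in a library or core map
#' @param x a \linkS4class{HaplotypeLibrary}, \linkS4class{CoreMap} or
#'   \linkS4class{DiplotypeCodes}.
#' @return integer.
#' @export
nCores <- function(x) {
  if (is(x, "HaplotypeLibrary")) nrow(x@cores)
  else if (is(x, "CoreMap")) nrow(x@cores)
  else if (is(x, "DiplotypeCodes")) ncol(x@paternal)
  else stop("no core count for class ", class(x))
}

#' Total number of distinct (core, haplotype) pairs in a library
#' @param library a \linkS4class{HaplotypeLibrary}.
#' @return integer.
#' @export
nHaplotypes <- function(library) {
  sum(vapply(library@counts, length, integer(1)))
}

#' Flat index of a (core, haplotype) pair
#'
#' The package stores per-(core, haplotype) quantities (counts, targeting
#' masks, scores) in flat vectors over all cores; this maps a core index and
#' within-core haplotype ID to the flat position.
#'
#' @param library a \linkS4class{HaplotypeLibrary}.
#' @param core core index (1-based), recycled against \code{hap}.
#' @param hap haplotype ID within the core.
#' @return integer vector of flat positions.
#' @export
flatIndex <- function(library, core, hap) {
  k <- vapply(library@counts, length, integer(1))
  bad <- hap < 1L | hap > k[core]
  if (any(bad, na.rm = TRUE))
    stop("unknown haplotype ID for core ", core[which(bad)[1L]])
  library@offsets[core] + hap
}

#' Population counts of all haplotypes as a flat vector
#' @param library a \linkS4class{HaplotypeLibrary}.
#' @return integer vector over all (core, haplotype) pairs, in flat-index
#'   order.
#' @export
hapPopCounts <- function(library) {
  unlist(library@counts, use.names = FALSE)
}

#' Population frequency of a haplotype at a core
#'
#' Population count of the haplotype divided by the total number of
#' non-missing gamete assignments at that core.
#'
#' @param library a \linkS4class{HaplotypeLibrary}.
#' @param core core index.
#' @param hap haplotype ID within the core; if missing, frequencies of all
#'   haplotypes of the core are returned.
#' @return numeric in [0, 1].
#' @examples
#' # a singleton among 4 assigned gametes has frequency 0.25
#' @export
populationFrequency <- function(library, core, hap) {
  cnt <- library@counts[[core]]
  if (missing(hap)) return(cnt / library@nAssigned[core])
  if (any(hap < 1L | hap > length(cnt)))
    stop("unknown haplotype ID ", hap, " at core ", core)
  cnt[hap] / library@nAssigned[core]
}

#' Flat population frequencies over all cores
#' @param library a \linkS4class{HaplotypeLibrary}.
#' @return numeric vector in flat-index order.
#' @export
populationFrequencies <- function(library) {
  unlist(lapply(seq_len(nCores(library)), function(c)
    library@counts[[c]] / library@nAssigned[c]), use.names = FALSE)
}

#' Individual IDs
#' @param x a \linkS4class{DiplotypeCodes} or \linkS4class{PhasedGenotypes}.
#' @return character vector.
#' @export
individualIds <- function(x) x@ids

#' Slot assignments of a sequencing set
#' @param set a \linkS4class{SequencingSet}.
#' @return character vector, one individual ID (or NA) per slot.
#' @export
setMembers <- function(set) set@members

#' Per-individual sequencing coverage of a set
#' @param set a \linkS4class{SequencingSet}.
#' @return named integer vector: slots held (x) per individual in the set.
#' @export
indCoverage <- function(set) {
  m <- set@members[!is.na(set@members)]
  if (!length(m)) return(integer(0))
  tab <- table(m)
  structure(as.integer(tab), names = names(tab))
}

#' Unique individuals in a sequencing set
#' @param set a \linkS4class{SequencingSet}.
#' @return character vector of IDs holding at least one slot.
#' @export
uniqueIndividuals <- function(set) unique(set@members[!is.na(set@members)])

#' Number of filled slots (total coverage produced, in x)
#' @param set a \linkS4class{SequencingSet}.
#' @return integer.
#' @export
nFilledSlots <- function(set) sum(!is.na(set@members))

#' @describeIn nFilledSlots total number of slots (filled or empty).
#' @export
nSlots <- function(set) length(set@members)

setMethod("show", "CoreMap", function(object) {
  cat(sprintf("CoreMap: %d cores on %d chromosome(s), %s markers/core\n",
              nrow(object@cores), length(unique(object@cores$chrom)),
              if (object@coreLength > 0L) object@coreLength else "unspecified"))
})

setMethod("show", "PhasedGenotypes", function(object) {
  cat(sprintf("PhasedGenotypes: %d individuals x %d markers (%d chromosome(s))\n",
              length(object@ids), ncol(object@paternal),
              length(unique(object@markerMap$chrom))))
})

setMethod("show", "HaplotypeLibrary", function(object) {
  k <- vapply(object@counts, length, integer(1))
  cat(sprintf("HaplotypeLibrary: %d cores, %d haplotypes (%.1f/core), %d assigned gametes/core (median)\n",
              nrow(object@cores), sum(k), mean(k),
              as.integer(stats::median(object@nAssigned))))
})

setMethod("show", "DiplotypeCodes", function(object) {
  cat(sprintf("DiplotypeCodes: %d individuals x %d cores (%.1f%% missing)\n",
              length(object@ids), ncol(object@paternal),
              100 * mean(is.na(c(object@paternal, object@maternal)))))
})

setMethod("show", "BudgetModel", function(object) {
  cat(sprintf("BudgetModel: total %.0f, library %.0f, per-1x %.0f%s\n",
              object@totalBudget, object@libraryCost, object@costPer1x,
              if (is.null(object@costHook)) " (linear)" else " (custom cost hook)"))
})

setMethod("show", "SequencingSet", function(object) {
  cov <- indCoverage(object)
  cat(sprintf("SequencingSet: %d/%d slots filled, %d unique individuals\n",
              nFilledSlots(object), nSlots(object), length(cov)))
  if (length(cov))
    cat(sprintf("  coverage range %dx-%dx; total cost %.0f\n",
                min(cov), max(cov), totalCost(object, object@budget)))
})

setMethod("show", "HapCountState", function(object) {
  cat(sprintf("HapCountState: %d haplotypes (%d targeted), total count %d\n",
              length(object@counts), sum(object@targeted),
              sum(object@counts)))
})

setMethod("show", "CoverageSummary", function(object) {
  cat(sprintf("CoverageSummary (target %gx, %d targeted haplotypes)\n",
              object@targetCov, object@nTargeted))
  cat(sprintf("  %% at/above target: %.1f\n", object@pctAtTarget))
  cat(sprintf("  %% zero coverage:   %.1f\n", object@pctZero))
  cat(sprintf("  %% under target:    %.1f\n", object@pctUnderTarget))
  cat(sprintf("  %% weighted mass at target: %.1f\n", object@totalPctWeighted))
  cat(sprintf("  set size: %d unique individuals\n", object@setSize))
})

setMethod("show", "SimulatedPopulation", function(object) {
  cat(sprintf("SimulatedPopulation: %d individuals, %d generations, %d cores\n",
              nrow(object@pedigree), max(object@pedigree$generation),
              ncol(object@codes@paternal)))
})
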