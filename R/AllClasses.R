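#' @import methods
NULL

setClassUnion("functionOrNULL", c("function", "NULL"))

#' CoreMap: partition of the marker map into fixed-length cores
#'
#' A core is a window of \code{coreLength} consecutive markers on one
#' chromosome; haplotypes are defined within cores. Cores within a chromosome
#' are contiguous, ordered and non-overlapping; trailing markers that do not
#' fill a complete core are dropped.
#'
#' @slot cores data.frame with columns \code{core} (global 1-based core
#'   index), \code{chrom} (chromosome ID), \code{start}, \code{end}
#'   (1-based inclusive marker indices).
#' @slot coreLength integer, markers per core; 0 for abstract core maps that
#'   carry no marker coordinates (e.g. built directly from simulated codes).
#' @exportClass CoreMap
setClass("CoreMap",
  slots = c(cores = "data.frame", coreLength = "integer"))

setValidity("CoreMap", function(object) {
  df <- object@cores
  need <- c("core", "chrom", "start", "end")
  if (!all(need %in% names(df)))
    return(sprintf("cores must have columns %s", paste(need, collapse = ", ")))
  if (nrow(df) == 0L) return("core map is empty")
  if (!identical(df$core, seq_len(nrow(df))))
    return("core indices must be 1..C in order")
  if (object@coreLength > 0L) {
    if (any(df$end - df$start + 1L != object@coreLength))
      return("every core must span exactly coreLength markers")
    for (ch in unique(df$chrom)) {
      sub <- df[df$chrom == ch, ]
      if (nrow(sub) > 1L &&
          any(sub$start[-1L] != sub$end[-nrow(sub)] + 1L))
        return(sprintf("cores on chromosome %s are not contiguous", ch))
    }
  }
  # a chromosome's cores must form one contiguous run of rows
  r <- rle(as.character(df$chrom))
  if (anyDuplicated(r$values))
    return("cores of one chromosome must be consecutive rows")
  TRUE
})

#' PhasedGenotypes: phased biallelic marker genotypes for a population
#'
#' Two gamete allele vectors (paternal, maternal) per individual over all
#' markers; alleles are 0/1 with \code{NA} for unphased or missing calls.
#'
#' @slot ids character vector of unique individual IDs.
#' @slot paternal,maternal integer matrices (individuals x markers).
#' @slot markerMap data.frame with column \code{chrom}, one row per marker in
#'   marker order.
#' @exportClass PhasedGenotypes
setClass("PhasedGenotypes",
  slots = c(ids = "character", paternal = "matrix", maternal = "matrix",
            markerMap = "data.frame"))

setValidity("PhasedGenotypes", function(object) {
  n <- length(object@ids)
  if (anyDuplicated(object@ids)) return("duplicate individual IDs")
  if (nrow(object@paternal) != n || nrow(object@maternal) != n)
    return("allele matrices must have one row per individual")
  if (ncol(object@paternal) != ncol(object@maternal))
    return("paternal and maternal matrices differ in marker count")
  if (nrow(object@markerMap) != ncol(object@paternal))
    return("markerMap must have one row per marker")
  if (!"chrom" %in% names(object@markerMap))
    return("markerMap must have a 'chrom' column")
  v <- c(object@paternal, object@maternal)
  if (!all(v %in% c(0L, 1L, NA_integer_)))
    return("alleles must be 0, 1 or NA")
  r <- rle(as.character(object@markerMap$chrom))
  if (anyDuplicated(r$values))
    return("markers of one chromosome must be consecutive")
  TRUE
})

#' HaplotypeLibrary: per-core catalogue of distinct haplotypes
#'
#' For each core, the distinct haplotypes observed in the population with
#' their population counts (number of gametes assigned to each) and, when
#' built from marker data, a representative allele string. Haplotype IDs are
#' integers assigned in discovery order within each core.
#'
#' @slot cores data.frame with columns \code{core} and \code{chrom}.
#' @slot haplotypes list (per core) of character vectors of representative
#'   allele strings; may be \code{NA} for code-only libraries.
#' @slot counts list (per core) of integer population counts, indexed by
#'   haplotype ID.
#' @slot nAssigned integer vector (per core): non-missing gamete assignments.
#' @slot offsets integer vector (per core): 0-based offset of the core's
#'   haplotype IDs in the package's flat (core, haplotype) indexing.
#' @exportClass HaplotypeLibrary
setClass("HaplotypeLibrary",
  slots = c(cores = "data.frame", haplotypes = "list", counts = "list",
            nAssigned = "integer", offsets = "integer"))

setValidity("HaplotypeLibrary", function(object) {
  C <- nrow(object@cores)
  if (!all(c("core", "chrom") %in% names(object@cores)))
    return("cores must have columns core, chrom")
  if (length(object@haplotypes) != C || length(object@counts) != C ||
      length(object@nAssigned) != C || length(object@offsets) != C)
    return("per-core slots must all have one element per core")
  for (c in seq_len(C)) {
    if (length(object@haplotypes[[c]]) != length(object@counts[[c]]))
      return("haplotypes and counts differ in length")
    if (any(object@counts[[c]] < 1L))
      return("population counts must be >= 1")
    if (sum(object@counts[[c]]) != object@nAssigned[c])
      return("counts must sum to the non-missing assignments of the core")
  }
  k <- vapply(object@counts, length, integer(1))
  if (!identical(object@offsets, cumsum(c(0L, k))[seq_len(C)]))
    return("offsets inconsistent with per-core haplotype counts")
  TRUE
})

#' DiplotypeCodes: per individual x core haplotype-ID assignments
#'
#' @slot ids character vector of unique individual IDs.
#' @slot paternal,maternal integer matrices (individuals x cores) of
#'   haplotype IDs within each core; \code{NA} = missing assignment.
#' @exportClass DiplotypeCodes
setClass("DiplotypeCodes",
  slots = c(ids = "character", paternal = "matrix", maternal = "matrix"))

setValidity("DiplotypeCodes", function(object) {
  n <- length(object@ids)
  if (anyDuplicated(object@ids)) return("duplicate individual IDs")
  if (nrow(object@paternal) != n || nrow(object@maternal) != n)
    return("code matrices must have one row per individual")
  if (ncol(object@paternal) != ncol(object@maternal))
    return("code matrices differ in core count")
  TRUE
})

#' BudgetModel: sequencing cost structure
#'
#' Linear by default: total cost = libraryCost x unique individuals +
#' costPer1x x total coverage. A \code{costHook} function
#' \code{function(nIndividuals, totalCoverage)} replaces the linear formula
#' for non-linear cost structures.
#'
#' @slot totalBudget,libraryCost,costPer1x numeric, in abstract currency
#'   units.
#' @slot costHook function or NULL.
#' @exportClass BudgetModel
setClass("BudgetModel",
  slots = c(totalBudget = "numeric", libraryCost = "numeric",
            costPer1x = "numeric", costHook = "functionOrNULL"))

setValidity("BudgetModel", function(object) {
  if (object@totalBudget < 0 || object@libraryCost < 0)
    return("costs must be non-negative")
  if (object@costPer1x <= 0) return("costPer1x must be positive")
  TRUE
})

#' SequencingSet: ordered 1x sequencing slots assigned to individuals
#'
#' Each slot is one unit of 1x sequencing; an individual holding n slots is
#' sequenced at nx. Empty slots are \code{NA}.
#'
#' @slot members character vector of length maxSlots; individual ID per slot
#'   or \code{NA}.
#' @slot budget the \linkS4class{BudgetModel} the set was built under.
#' @slot metadata list of run provenance (method, targetCov, cost, metric
#'   trajectory, final haplotype counts, ...).
#' @exportClass SequencingSet
setClass("SequencingSet",
  slots = c(members = "character", budget = "BudgetModel",
            metadata = "list"))

#' HapCountState: per-(core, haplotype) appearance counts and targeting
#'
#' Counts use the package's flat (core, haplotype) indexing (see
#' \code{\link{flatIndex}}); each count is the number of times the haplotype
#' appears in the current sequencing set (one per slot of each carrier, per
#' carried copy) plus any pre-existing coverage. Untargeted haplotypes keep
#' their counts but always score zero.
#'
#' @slot counts integer vector over all (core, haplotype) pairs.
#' @slot targeted logical vector of equal length.
#' @exportClass HapCountState
setClass("HapCountState",
  slots = c(counts = "integer", targeted = "logical"))

setValidity("HapCountState", function(object) {
  if (length(object@counts) != length(object@targeted))
    return("counts and targeted must have equal length")
  if (any(object@counts < 0L)) return("counts must be non-negative")
  TRUE
})

#' CoverageSummary: evaluation of the coverage a sequencing set achieves
#'
#' Expected haplotype coverage is HapCount x 0.5 (each 1x of an individual
#' reads either gamete with probability 0.5).
#'
#' @slot pctAtTarget,pctZero,pctUnderTarget percentages over targeted unique
#'   haplotypes: at/above target, zero coverage, strictly between.
#' @slot totalPctWeighted population-frequency-weighted percentage of
#'   targeted haplotype mass at/above target.
#' @slot histogram data.frame of half-x coverage bins.
#' @slot setSize integer, unique individuals in the set.
#' @slot coverageTable data.frame: individuals per coverage level.
#' @slot targetCov numeric target coverage (x).
#' @slot nTargeted integer, targeted unique haplotypes.
#' @exportClass CoverageSummary
setClass("CoverageSummary",
  slots = c(pctAtTarget = "numeric", pctZero = "numeric",
            pctUnderTarget = "numeric", totalPctWeighted = "numeric",
            histogram = "data.frame", setSize = "integer",
            coverageTable = "data.frame", targetCov = "numeric",
            nTargeted = "integer"))

#' SimulatedPopulation: pedigree gene-dropping simulation output
#'
#' @slot pedigree data.frame: id, sire, dam, sex, generation.
#' @slot codes \linkS4class{DiplotypeCodes} of founder-haplotype IDs per core.
#' @slot chromOfCore character/integer vector: chromosome of each core.
#' @slot params list of the simulation configuration actually used, plus
#'   bookkeeping (total recombination switches, meioses simulated).
#' @exportClass SimulatedPopulation
setClass("SimulatedPopulation",
  slots = c(pedigree = "data.frame", codes = "DiplotypeCodes",
            chromOfCore = "character", params = "list"))
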