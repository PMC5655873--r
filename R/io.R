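#' Read phased genotypes from a plain-text file
#'
#' Two lines per individual (paternal gamete then maternal), each
#' \code{"individualID allele allele ..."}; alleles are 0/1 with 9 for
#' missing. Both lines of a pair must carry the same ID and all rows the
#' same number of markers; malformed input is rejected with the offending
#' line number.
#'
#' @param path file path.
#' @param markerMap optional data.frame with a \code{chrom} column (one row
#'   per marker); default: a single chromosome.
#' @return a \linkS4class{PhasedGenotypes}.
#' @export
readPhasedGenotypes <- function(path, markerMap = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) %% 2L != 0L)
    stop("odd number of genotype lines (", length(lines),
         "); expected two per individual")
  tok <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(tok)
  if (length(unique(nf)) != 1L)
    stop("ragged rows: line ", which(nf != nf[1L])[1L],
         " has ", nf[which(nf != nf[1L])[1L]], " fields, expected ", nf[1L])
  ids <- vapply(tok, `[`, character(1), 1L)
  alleles <- lapply(seq_along(tok), function(i) {
    v <- tok[[i]][-1L]
    bad <- !(v %in% c("0", "1", "9"))
    if (any(bad))
      stop("line ", i, ": unknown allele code '", v[which(bad)[1L]], "'")
    a <- as.integer(v)
    a[a == 9L] <- NA_integer_
    a
  })
  odd <- seq(1L, length(lines), by = 2L)
  if (any(ids[odd] != ids[odd + 1L])) {
    j <- which(ids[odd] != ids[odd + 1L])[1L]
    stop("line ", 2L * j, ": maternal line ID '", ids[odd[j] + 1L],
         "' does not match paternal line ID '", ids[odd[j]], "'")
  }
  phasedGenotypes(ids[odd],
                  do.call(rbind, alleles[odd]),
                  do.call(rbind, alleles[odd + 1L]),
                  markerMap)
}

#' Write phased genotypes to the two-line-per-individual text format
#' @param genotypes a \linkS4class{PhasedGenotypes}.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writePhasedGenotypes <- function(genotypes, path) {
  fmt <- function(mat, i) {
    v <- mat[i, ]
    v[is.na(v)] <- 9L
    paste(c(genotypes@ids[i], v), collapse = " ")
  }
  n <- length(genotypes@ids)
  lines <- character(2L * n)
  for (i in seq_len(n)) {
    lines[2L * i - 1L] <- fmt(genotypes@paternal, i)
    lines[2L * i] <- fmt(genotypes@maternal, i)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a marker-to-chromosome map
#'
#' Text file with rows \code{"markerIndex chromosomeID"}, markers in order.
#'
#' @param path file path.
#' @return data.frame with a \code{chrom} column, one row per marker.
#' @export
readMarkerMap <- function(path) {
  df <- utils::read.table(path, header = FALSE,
                          col.names = c("marker", "chrom"),
                          colClasses = c("integer", "character"))
  if (!identical(df$marker, seq_len(nrow(df))))
    stop("marker indices must be 1..M in order")
  data.frame(chrom = df$chrom)
}

#' Read an explicit core map from a BED-like text file
#'
#' Rows \code{"chrom start end"} with 0-based half-open marker-index
#' ranges; all cores must have equal length.
#'
#' @param path file path.
#' @return a \linkS4class{CoreMap}.
#' @export
readCoreMap <- function(path) {
  df <- utils::read.table(path, header = FALSE,
                          col.names = c("chrom", "start", "end"),
                          colClasses = c("character", "integer", "integer"))
  len <- unique(df$end - df$start)
  if (length(len) != 1L || len < 1L)
    stop("all cores must span the same positive number of markers")
  new("CoreMap",
      cores = data.frame(core = seq_len(nrow(df)), chrom = df$chrom,
                         start = df$start + 1L, end = df$end),
      coreLength = len)
}

#' Read pre-existing per-individual sequencing coverage
#'
#' Rows \code{"individualID coverageX"}.
#'
#' @param path file path.
#' @return named integer vector of coverages.
#' @export
readPriorCoverage <- function(path) {
  df <- utils::read.table(path, header = FALSE,
                          col.names = c("id", "coverage"),
                          colClasses = c("character", "numeric"))
  if (any(df$coverage < 0) || any(df$coverage != round(df$coverage)))
    stop("coverages must be non-negative integers")
  structure(as.integer(df$coverage), names = df$id)
}

#' Write a sequencing set as "individualID coverageX" rows
#' @param set a \linkS4class{SequencingSet}.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeSequencingSet <- function(set, path) {
  cov <- indCoverage(set)
  utils::write.table(data.frame(id = names(cov), coverage = as.integer(cov)),
                     path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write a haplotype library as text
#'
#' One row per haplotype: \code{coreIndex hapID populationCount
#' alleleString} (allele string \code{NA} for code-only libraries).
#'
#' @param library a \linkS4class{HaplotypeLibrary}.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeHaplotypeLibrary <- function(library, path) {
  rows <- lapply(seq_len(nCores(library)), function(c)
    data.frame(core = c, hap = seq_along(library@counts[[c]]),
               count = library@counts[[c]],
               alleles = library@haplotypes[[c]]))
  utils::write.table(do.call(rbind, rows), path, quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# short deterministic hash of a configuration list, for run provenance
.configHash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * seq_along(v)) %% .Machine$integer.max)
}

#' Write a JSON run report for a sequencing set
#'
#' @param set a \linkS4class{SequencingSet} (refined or initial).
#' @param path output path.
#' @param config optional configuration list embedded (with its hash) for
#'   provenance.
#' @param seed the seed used for the run.
#' @return invisibly, the path.
#' @export
writeRunReport <- function(set, path, config = list(), seed = NA) {
  cov <- indCoverage(set)
  report <- list(
    configHash = .configHash(config),
    seed = seed,
    config = config,
    method = set@metadata$method,
    targetCov = set@metadata$targetCov,
    pctAtTarget = set@metadata$pctAtTarget,
    trajectory = set@metadata$trajectory,
    finalCost = set@metadata$cost,
    slotsFilled = nFilledSlots(set),
    slotsEmpty = nSlots(set) - nFilledSlots(set),
    uniqueIndividuals = length(cov))
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' Run a grid of allocation scenarios on one population
#'
#' Executes, for every budget x target x method combination and
#' \code{nReps} repetitions: rare-haplotype filtering, greedy selection,
#' optional exchange refinement, and coverage evaluation. Repetitions rerun
#' the (stochastic) allocation on the same population with child seeds
#' spawned deterministically from \code{seed}.
#'
#' @param codes,library the population (e.g. from
#'   \code{\link{haplotypeLibraryFromCodes}} on a simulated population, or
#'   \code{\link{buildLibrary}} on real genotypes).
#' @param budgets numeric vector of total budgets.
#' @param targetCovs numeric vector of target coverages (x).
#' @param methods subset of \code{c("hapcov", "iws", "iws_homozygous",
#'   "random")}.
#' @param nReps repetitions per scenario.
#' @param libraryCost,costPer1x linear cost model parameters.
#' @param rareFilterMode,rareCountThreshold,flankCount,nComb rare-haplotype
#'   filter configuration (see \code{\link{applyRareFilter}}).
#' @param exchangeRounds,exchangesPerRound refinement configuration; 0
#'   rounds skips refinement. The original homozygous-only IWS method is
#'   never refined.
#' @param maxIndividualCoverage optional per-individual coverage cap.
#' @param seed master seed; per-run child seeds derive from it.
#' @param outFile optional TSV path for the per-repetition results (header
#'   comments carry the seed and config hash).
#' @return list with \code{results} (one row per scenario x repetition),
#'   \code{summary} (means and standard errors per scenario), \code{seed}
#'   and \code{configHash}.
#' @export
runScenario <- function(codes, library, budgets, targetCovs = 10,
                        methods = c("hapcov", "iws", "random"),
                        nReps = 10L, libraryCost = 40, costPer1x = 80,
                        rareFilterMode = "exclude",
                        rareCountThreshold = 2L, flankCount = 2L,
                        nComb = 3L, exchangeRounds = 0L,
                        exchangesPerRound = 10L,
                        maxIndividualCoverage = NULL, seed = 1L,
                        outFile = NULL) {
  methods <- match.arg(methods, c("hapcov", "iws", "iws_homozygous",
                                  "random"), several.ok = TRUE)
  config <- list(budgets = budgets, targetCovs = targetCovs,
                 methods = methods, nReps = nReps,
                 libraryCost = libraryCost, costPer1x = costPer1x,
                 rareFilterMode = rareFilterMode,
                 rareCountThreshold = rareCountThreshold,
                 flankCount = flankCount, nComb = nComb,
                 exchangeRounds = exchangeRounds,
                 exchangesPerRound = exchangesPerRound,
                 maxIndividualCoverage = maxIndividualCoverage,
                 seed = seed)
  mask <- applyRareFilter(library, codes, mode = rareFilterMode,
                          rareCountThreshold = rareCountThreshold,
                          flankCount = flankCount, nComb = nComb)
  grid <- expand.grid(rep = seq_len(nReps), method = methods,
                      targetCov = targetCovs, budget = budgets,
                      stringsAsFactors = FALSE)
  set.seed(seed)
  childSeeds <- sample.int(.Machine$integer.max - 1L, nrow(grid))
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    set.seed(childSeeds[i])
    bm <- budgetModel(g$budget, libraryCost, costPer1x)
    set <- greedySelect(codes, library, bm, g$targetCov,
                        method = g$method, mask = mask,
                        maxIndividualCoverage = maxIndividualCoverage)
    if (exchangeRounds > 0L && g$method != "iws_homozygous")
      set <- refineSet(set, codes, library, bm, g$targetCov,
                       method = if (g$method == "random") "random"
                                else g$method,
                       exchangeRounds = exchangeRounds,
                       exchangesPerRound = exchangesPerRound,
                       mask = mask,
                       maxIndividualCoverage = maxIndividualCoverage)
    sm <- summarizeCoverage(set, codes, library, g$targetCov, mask = mask)
    rows[[i]] <- data.frame(
      budget = g$budget, targetCov = g$targetCov, method = g$method,
      rep = g$rep, seed = childSeeds[i],
      pctAtTarget = sm@pctAtTarget, pctZero = sm@pctZero,
      pctUnderTarget = sm@pctUnderTarget,
      totalPctWeighted = sm@totalPctWeighted,
      setSize = sm@setSize, slotsFilled = nFilledSlots(set),
      slotsEmpty = nSlots(set) - nFilledSlots(set),
      totalCost = set@metadata$cost)
  }
  results <- do.call(rbind, rows)
  se <- function(x) stats::sd(x) / sqrt(length(x))
  agg <- stats::aggregate(
    cbind(pctAtTarget, pctZero, pctUnderTarget, setSize) ~
      budget + targetCov + method,
    data = results, FUN = mean)
  aggSE <- stats::aggregate(
    cbind(pctAtTarget, pctZero, pctUnderTarget, setSize) ~
      budget + targetCov + method,
    data = results, FUN = se)
  names(aggSE)[-(1:3)] <- paste0("se_", names(aggSE)[-(1:3)])
  summary <- merge(agg, aggSE, by = c("budget", "targetCov", "method"))
  hash <- .configHash(config)
  if (!is.null(outFile)) {
    con <- file(outFile, "w")
    writeLines(sprintf("# seed=%s configHash=%s", seed, hash), con)
    utils::write.table(results, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
  }
  list(results = results, summary = summary, seed = seed,
       configHash = hash)
}
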