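#' Construct a PhasedGenotypes object
#'
#' @param ids character vector of individual IDs.
#' @param paternal,maternal integer matrices (individuals x markers),
#'   alleles 0/1, \code{NA} missing.
#' @param markerMap data.frame with a \code{chrom} column, one row per
#'   marker; defaults to a single chromosome.
#' @return a \linkS4class{PhasedGenotypes}.
#' @export
phasedGenotypes <- function(ids, paternal, maternal, markerMap = NULL) {
  storage.mode(paternal) <- "integer"
  storage.mode(maternal) <- "integer"
  if (is.null(markerMap))
    markerMap <- data.frame(chrom = rep("1", ncol(paternal)))
  new("PhasedGenotypes", ids = as.character(ids), paternal = paternal,
      maternal = maternal, markerMap = markerMap)
}

#' Derive a core map from a marker map
#'
#' Splits each chromosome into consecutive cores of \code{coreLength}
#' markers. Trailing markers of a chromosome that do not fill a complete
#' core are dropped from all cores.
#'
#' @param markerMap data.frame with a \code{chrom} column, one row per
#'   marker in marker order.
#' @param coreLength markers per core.
#' @return a \linkS4class{CoreMap}.
#' @examples
#' makeCoreMap(data.frame(chrom = rep(c("1", "2"), each = 250)), 100)
#' @export
makeCoreMap <- function(markerMap, coreLength) {
  coreLength <- as.integer(coreLength)
  if (coreLength < 1L) stop("coreLength must be >= 1")
  ch <- as.character(markerMap$chrom)
  r <- rle(ch)
  if (anyDuplicated(r$values))
    stop("markers of one chromosome must be consecutive")
  starts <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  rows <- list()
  for (i in seq_along(r$values)) {
    nFull <- r$lengths[i] %/% coreLength
    if (nFull == 0L) next
    s <- starts[i] + (seq_len(nFull) - 1L) * coreLength
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = r$values[i], start = s, end = s + coreLength - 1L)
  }
  if (!length(rows)) stop("no chromosome holds a complete core")
  df <- do.call(rbind, rows)
  df <- data.frame(core = seq_len(nrow(df)), df)
  new("CoreMap", cores = df, coreLength = coreLength)
}

# allele-string per gamete for one core; rows with any NA give NA
.coreStrings <- function(mat, cols) {
  sub <- mat[, cols, drop = FALSE]
  s <- do.call(paste0, as.data.frame(sub))
  s[rowSums(is.na(sub)) > 0L] <- NA_character_
  s
}

# greedy first-match clustering of strings within a core.
# Returns list(ids = integer assignment per string (NA kept),
#              reps = representative strings in discovery order)
.clusterCore <- function(strings, maxMismatches) {
  ok <- !is.na(strings)
  if (maxMismatches == 0L) {
    reps <- unique(strings[ok])
    ids <- match(strings, reps)
    return(list(ids = ids, reps = reps))
  }
  ids <- rep(NA_integer_, length(strings))
  repMat <- NULL  # k x m integer matrix of representatives
  reps <- character(0)
  for (g in which(ok)) {
    v <- utf8ToInt(strings[g])
    if (is.null(repMat)) {
      repMat <- matrix(v, nrow = 1L)
      reps <- strings[g]
      ids[g] <- 1L
      next
    }
    d <- rowSums(repMat != matrix(v, nrow(repMat), length(v), byrow = TRUE))
    hit <- which(d <= maxMismatches)
    if (length(hit)) {
      ids[g] <- hit[1L]  # lowest-ID existing haplotype
    } else {
      repMat <- rbind(repMat, v)
      reps <- c(reps, strings[g])
      ids[g] <- length(reps)
    }
  }
  list(ids = ids, reps = reps)
}

#' Build the haplotype library and diplotype codes from phased genotypes
#'
#' Within each core, gamete allele strings are compared; identical strings
#' (or strings within \code{maxMismatches} of an existing haplotype's
#' representative, to absorb genotyping errors) share a haplotype ID. A
#' string joins the lowest-ID haplotype whose founding representative
#' differs at no more than \code{maxMismatches} positions, else founds a new
#' haplotype. Gamete-core strings containing any missing allele get a
#' missing assignment. Gametes are scanned in individual order, paternal
#' before maternal, so IDs are deterministic in discovery order.
#'
#' @param genotypes a \linkS4class{PhasedGenotypes}.
#' @param coreMap a \linkS4class{CoreMap} consistent with the marker map.
#' @param maxMismatches allowed mismatches to an existing representative
#'   (default 0: exact identity).
#' @return list with elements \code{library}
#'   (\linkS4class{HaplotypeLibrary}) and \code{codes}
#'   (\linkS4class{DiplotypeCodes}).
#' @export
buildLibrary <- function(genotypes, coreMap, maxMismatches = 0L) {
  stopifnot(is(genotypes, "PhasedGenotypes"), is(coreMap, "CoreMap"))
  maxMismatches <- as.integer(maxMismatches)
  if (maxMismatches < 0L) stop("maxMismatches must be >= 0")
  nM <- ncol(genotypes@paternal)
  if (max(coreMap@cores$end) > nM)
    stop("core map refers to markers beyond the genotype matrix (",
         max(coreMap@cores$end), " > ", nM, ")")
  gChrom <- as.character(genotypes@markerMap$chrom)
  n <- length(genotypes@ids)
  C <- nrow(coreMap@cores)
  patCodes <- matrix(NA_integer_, n, C)
  matCodes <- matrix(NA_integer_, n, C)
  haplotypes <- vector("list", C)
  counts <- vector("list", C)
  nAssigned <- integer(C)
  for (c in seq_len(C)) {
    cols <- coreMap@cores$start[c]:coreMap@cores$end[c]
    if (!all(gChrom[cols] == as.character(coreMap@cores$chrom[c])))
      stop("core ", c, " spans markers of a different chromosome")
    # gamete order: ind1 pat, ind1 mat, ind2 pat, ...
    sp <- .coreStrings(genotypes@paternal, cols)
    sm <- .coreStrings(genotypes@maternal, cols)
    g <- as.vector(rbind(sp, sm))
    cl <- .clusterCore(g, maxMismatches)
    ids <- matrix(cl$ids, nrow = 2L)
    patCodes[, c] <- ids[1L, ]
    matCodes[, c] <- ids[2L, ]
    counts[[c]] <- tabulate(cl$ids, nbins = length(cl$reps))
    haplotypes[[c]] <- cl$reps
    nAssigned[c] <- sum(!is.na(cl$ids))
    if (!length(cl$reps)) stop("core ", c, " has no non-missing gamete")
  }
  k <- vapply(counts, length, integer(1))
  lib <- new("HaplotypeLibrary",
             cores = data.frame(core = seq_len(C),
                                chrom = as.character(coreMap@cores$chrom)),
             haplotypes = haplotypes, counts = counts,
             nAssigned = nAssigned,
             offsets = cumsum(c(0L, k))[seq_len(C)])
  codes <- new("DiplotypeCodes", ids = genotypes@ids,
               paternal = patCodes, maternal = matCodes)
  list(library = lib, codes = codes)
}

#' Build a code-only haplotype library from existing diplotype codes
#'
#' Relabels arbitrary per-core haplotype IDs (e.g. founder IDs from
#' \code{\link{simulatePopulation}}) into compact discovery-order IDs and
#' tallies population counts. Representative allele strings are \code{NA}.
#'
#' @param codes a \linkS4class{DiplotypeCodes} (any integer IDs per core).
#' @param chromOfCore chromosome of each core (defaults to one chromosome).
#' @return list with elements \code{library} and \code{codes} (relabelled).
#' @export
haplotypeLibraryFromCodes <- function(codes, chromOfCore = NULL) {
  stopifnot(is(codes, "DiplotypeCodes"))
  C <- ncol(codes@paternal)
  if (is.null(chromOfCore)) chromOfCore <- rep("1", C)
  n <- length(codes@ids)
  patCodes <- matrix(NA_integer_, n, C)
  matCodes <- matrix(NA_integer_, n, C)
  counts <- vector("list", C)
  haplotypes <- vector("list", C)
  nAssigned <- integer(C)
  for (c in seq_len(C)) {
    g <- as.vector(rbind(codes@paternal[, c], codes@maternal[, c]))
    u <- unique(g[!is.na(g)])
    ids <- match(g, u)
    m <- matrix(ids, nrow = 2L)
    patCodes[, c] <- m[1L, ]
    matCodes[, c] <- m[2L, ]
    counts[[c]] <- tabulate(ids, nbins = length(u))
    haplotypes[[c]] <- rep(NA_character_, length(u))
    nAssigned[c] <- sum(!is.na(ids))
  }
  k <- vapply(counts, length, integer(1))
  lib <- new("HaplotypeLibrary",
             cores = data.frame(core = seq_len(C),
                                chrom = as.character(chromOfCore)),
             haplotypes = haplotypes, counts = counts,
             nAssigned = nAssigned,
             offsets = cumsum(c(0L, k))[seq_len(C)])
  list(library = lib,
       codes = new("DiplotypeCodes", ids = codes@ids,
                   paternal = patCodes, maternal = matCodes))
}

# n x 2C matrix of flat (core, haplotype) indices; NA -> 0 sentinel
.flatCodes <- function(codes, library) {
  off <- library@offsets
  p <- sweep(codes@paternal, 2L, off, `+`)
  m <- sweep(codes@maternal, 2L, off, `+`)
  idx <- cbind(p, m)
  idx[is.na(idx)] <- 0L
  idx
}

# per-individual carried haplotypes: list of list(index, mult)
.carriedList <- function(idx0) {
  lapply(seq_len(nrow(idx0)), function(i) {
    v <- idx0[i, ]
    v <- v[v > 0L]
    if (!length(v)) return(list(index = integer(0), mult = integer(0)))
    t <- table(v)
    list(index = as.integer(names(t)), mult = as.integer(t))
  })
}

# flat logical mask of haplotypes observed homozygous in >= 1 individual
.homozygousMask <- function(codes, library) {
  K <- nHaplotypes(library)
  mask <- logical(K)
  hom <- !is.na(codes@paternal) & !is.na(codes@maternal) &
    codes@paternal == codes@maternal
  for (c in seq_len(ncol(codes@paternal))) {
    h <- unique(codes@paternal[hom[, c], c])
    if (length(h)) mask[library@offsets[c] + h] <- TRUE
  }
  mask
}
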