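#' Normalize intensities to parts per million
#'
#' Divides each sample's intensities by that sample's total and multiplies by
#' 1e6, removing between-sample differences in total protein amount. Zeros
#' are missing values by label-free convention and stay zero.
#'
#' @param se a `SummarizedExperiment` with an `intensity` assay (or the first
#'   assay), zeros meaning missing.
#' @return the experiment with a `ppm` assay added; each sample's nonmissing
#'   values sum to 1e6.
#' @examples
#' se <- simulateCellCycleDataset(simConfig(nProteins = 100, seed = 1))
#' se <- ppmNormalize(se)
#' colSums(SummarizedExperiment::assay(se, "ppm"))[1:3]
#' @export
ppmNormalize <- function(se) {
  x <- intensityAssay(se)
  tot <- colSums(x)
  if (any(tot == 0))
    stop("sample(s) with no nonzero intensity: ",
         paste(colnames(x)[tot == 0], collapse = ", "))
  ppm <- sweep(x, 2, tot / 1e6, `/`)
  SummarizedExperiment::assays(se)$ppm <- ppm
  se
}

intensityAssay <- function(se) {
  nms <- SummarizedExperiment::assayNames(se)
  nm <- if ("intensity" %in% nms) "intensity" else 1L
  x <- SummarizedExperiment::assay(se, nm)
  if (any(x < 0)) stop("negative intensities are not allowed")
  x
}

ppmAssay <- function(se) {
  if (!"ppm" %in% SummarizedExperiment::assayNames(se))
    stop("run ppmNormalize() first: no 'ppm' assay present")
  SummarizedExperiment::assay(se, "ppm")
}

#' Assemble ordered pseudotimecourses
#'
#' For each technical repeat, orders the samples biological-replicate-major
#' and population-minor (replicate 1: P1..P16, replicate 2: P1..P16, ...) so
#' every protein has one series per repeat — 64 points under the 16 x 4
#' design. Zeros become `NA`. A protein is testable in a repeat only when its
#' series completeness meets `completenessThreshold`.
#'
#' @param se a ppm-normalized experiment (see [ppmNormalize()]) whose
#'   `colData` has `population`, `biorep` and `techrep`.
#' @param completenessThreshold minimum nonmissing fraction for a series to
#'   be periodicity-testable.
#' @return a [PseudotimecourseSet-class].
#' @examples
#' se <- ppmNormalize(simulateCellCycleDataset(simConfig(nProteins = 100)))
#' assemblePseudotimecourses(se)
#' @export
assemblePseudotimecourses <- function(se, completenessThreshold = 0.95) {
  ppm <- ppmAssay(se)
  cd <- SummarizedExperiment::colData(se)
  need <- c("population", "biorep", "techrep")
  if (!all(need %in% colnames(cd)))
    stop("colData must contain: ", paste(need, collapse = ", "))
  pop <- as.integer(factor(cd$population, levels = levels(cd$population)))
  reps <- sort(unique(cd$techrep))
  nPop <- nlevels(cd$population)
  bioreps <- sort(unique(cd$biorep))
  full <- expand.grid(population = seq_len(nPop), biorep = bioreps)
  series <- lapply(reps, function(t) {
    idx <- integer(0)
    missingCells <- character(0)
    for (b in bioreps) for (p in seq_len(nPop)) {
      j <- which(cd$techrep == t & cd$biorep == b & pop == p)
      if (length(j) != 1L)
        missingCells <- c(missingCells, sprintf("P%d_B%d_T%d", p, b, t))
      else idx <- c(idx, j)
    }
    if (length(missingCells))
      stop("incomplete design; absent samples: ",
           paste(missingCells, collapse = ", "))
    m <- ppm[, idx, drop = FALSE]
    m[m == 0] <- NA_real_
    m
  })
  names(series) <- paste0("T", reps)
  completeness <- vapply(series, function(m) rowMeans(!is.na(m)),
                         numeric(nrow(ppm)))
  new("PseudotimecourseSet", series = series,
      completeness = completeness,
      testable = completeness >= completenessThreshold,
      completenessThreshold = completenessThreshold,
      populations = rep(seq_len(nPop), length(bioreps)))
}
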