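#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#'   rowData
NULL

#' Simulation configuration for the synthetic cell-cycle dataset
#'
#' Holds the parameters of the synthetic proteome generator: the sorted-cell
#' design (populations x biological replicates x technical repeats), the
#' fraction and amplitude of periodic proteins, multiplicative noise and
#' per-sample depth variation, and the abundance-dependent missingness curve.
#'
#' @slot nProteins number of protein groups to simulate.
#' @slot fracPeriodic fraction of proteins given a periodic profile, in [0,1].
#' @slot nPopulations number of FACS populations per biological replicate
#'   (the downstream signature stages assume 16).
#' @slot nBiorep number of biological replicates.
#' @slot nTechrep number of technical repeats per sample.
#' @slot amplitudeRange peak-to-trough fold-change interval from which each
#'   periodic protein's amplitude is drawn uniformly; lower bound must exceed 1.
#' @slot noiseCV coefficient of variation of the multiplicative log-normal
#'   measurement noise.
#' @slot depthCV coefficient of variation of the per-sample total-intensity
#'   (depth) factors.
#' @slot missingMidpoint abundance quantile at which the probability of a
#'   value being censored to zero is 0.5.
#' @slot missingSlope steepness of the logistic missingness curve per
#'   natural-log unit of intensity.
#' @slot seed integer seed; identical seeds give bit-identical output.
#'
#' @seealso [simConfig()], [simulateCellCycleDataset()]
#' @export
setClass("SimConfig", representation(
  nProteins = "integer",
  fracPeriodic = "numeric",
  nPopulations = "integer",
  nBiorep = "integer",
  nTechrep = "integer",
  amplitudeRange = "numeric",
  noiseCV = "numeric",
  depthCV = "numeric",
  missingMidpoint = "numeric",
  missingSlope = "numeric",
  seed = "integer"
))

setValidity("SimConfig", function(object) {
  msg <- character()
  counts <- c(nProteins = object@nProteins, nPopulations = object@nPopulations,
              nBiorep = object@nBiorep, nTechrep = object@nTechrep)
  if (any(is.na(counts)) || any(counts < 1L))
    msg <- c(msg, "all design counts must be >= 1")
  if (object@fracPeriodic < 0 || object@fracPeriodic > 1)
    msg <- c(msg, "fracPeriodic must lie in [0, 1]")
  if (length(object@amplitudeRange) != 2L ||
      object@amplitudeRange[1] <= 1 || diff(object@amplitudeRange) < 0)
    msg <- c(msg, "amplitudeRange must be [lo, hi] with lo > 1 and hi >= lo")
  if (object@noiseCV < 0 || object@depthCV < 0)
    msg <- c(msg, "noiseCV and depthCV must be nonnegative")
  if (object@missingMidpoint < 0 || object@missingMidpoint > 1)
    msg <- c(msg, "missingMidpoint is a quantile and must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Paired pseudotimecourse matrices for periodicity testing
#'
#' One matrix per technical repeat, each row a protein and each column one of
#' the ordered samples (biological-replicate-major, population-minor, so with
#' the 16 x 4 design each series has 64 points). Zeros in the source table are
#' treated as missing; `completeness` records the nonmissing fraction per
#' protein and repeat, and `testable` flags series meeting the completeness
#' threshold.
#'
#' @slot series list of numeric matrices (protein x timepoint), one per
#'   technical repeat; missing values are `NA`.
#' @slot completeness matrix (protein x repeat) of nonmissing fractions.
#' @slot testable logical matrix (protein x repeat).
#' @slot completenessThreshold minimum completeness for a series to be tested.
#' @slot populations integer vector giving the population index of each column.
#'
#' @export
setClass("PseudotimecourseSet", representation(
  series = "list",
  completeness = "matrix",
  testable = "matrix",
  completenessThreshold = "numeric",
  populations = "integer"
))

setValidity("PseudotimecourseSet", function(object) {
  msg <- character()
  if (length(object@series) < 1L)
    msg <- c(msg, "at least one technical repeat is required")
  dims <- vapply(object@series, dim, integer(2))
  if (length(unique(dims[1, ])) != 1L || length(unique(dims[2, ])) != 1L)
    msg <- c(msg, "all repeats must share dimensions")
  if (ncol(object@completeness) != length(object@series))
    msg <- c(msg, "completeness must have one column per repeat")
  if (length(msg)) msg else TRUE
})

#' Cell-cycle-state signature model
#'
#' The classification signature built from the pseudoperiodic proteins: their
#' z-scaled abundances over all samples, per-population mean profiles, the
#' k-means aggregation of populations into cell cycle states (CCSs), and the
#' mean scaled profile of each CCS.
#'
#' @slot pspIds character vector of signature protein identifiers.
#' @slot sampleMatrix numeric matrix (sample x protein) of per-protein
#'   z-scaled abundances.
#' @slot popMeans numeric matrix (population x protein) of mean scaled values.
#' @slot ccsProfiles numeric matrix (CCS x protein); each row is the mean of
#'   its member populations' rows of `popMeans`.
#' @slot popToCcs named integer vector mapping each population to its CCS.
#' @slot contiguous logical, whether every CCS is a temporally contiguous
#'   block of populations (reported, not enforced).
#'
#' @export
setClass("SignatureModel", representation(
  pspIds = "character",
  sampleMatrix = "matrix",
  popMeans = "matrix",
  ccsProfiles = "matrix",
  popToCcs = "integer",
  contiguous = "logical"
))

setValidity("SignatureModel", function(object) {
  msg <- character()
  nCcs <- nrow(object@ccsProfiles)
  if (!all(sort(unique(object@popToCcs)) == seq_len(nCcs)))
    msg <- c(msg, "popToCcs must be surjective onto 1..nCcs")
  if (length(object@popToCcs) != nrow(object@popMeans))
    msg <- c(msg, "popToCcs must map every population")
  if (ncol(object@popMeans) != length(object@pspIds) ||
      ncol(object@ccsProfiles) != length(object@pspIds))
    msg <- c(msg, "profile matrices must have one column per signature protein")
  recomputed <- t(vapply(seq_len(nCcs), function(s) {
    colMeans(object@popMeans[object@popToCcs == s, , drop = FALSE])
  }, numeric(length(object@pspIds))))
  if (max(abs(recomputed - object@ccsProfiles)) > 1e-8)
    msg <- c(msg, "ccsProfiles rows must be means of mapped popMeans rows")
  if (length(msg)) msg else TRUE
})

#' Match-filter thresholds for MS1 feature matches
#'
#' Robust location/scale estimates of the three match-error dimensions
#' (retention-time difference in minutes, m/z difference in Da, m/z error in
#' ppm) together with the sigma multipliers applied when filtering.
#'
#' @slot center named numeric: median of each matched-error dimension.
#' @slot sigma named numeric: robust sigma (1.4826 x MAD) per dimension.
#' @slot nSigma named numeric: multipliers, by default 2.5 for retention time
#'   and 3 for both m/z dimensions.
#'
#' @export
setClass("MatchFilter", representation(
  center = "numeric",
  sigma = "numeric",
  nSigma = "numeric"
))

setValidity("MatchFilter", function(object) {
  dims <- c("d_rt", "d_mz", "ppm_err")
  msg <- character()
  if (!all(dims %in% names(object@sigma)) ||
      !all(dims %in% names(object@center)) ||
      !all(dims %in% names(object@nSigma)))
    msg <- c(msg, "center, sigma and nSigma must name d_rt, d_mz and ppm_err")
  if (any(object@nSigma <= 0)) msg <- c(msg, "sigma multipliers must be > 0")
  if (any(object@sigma[dims] <= 0)) msg <- c(msg, "sigmas must be > 0")
  if (length(msg)) msg else TRUE
})

#' Match-between-runs FDR report
#'
#' Target and decoy matched fractions and their ratio, the empirical estimate
#' of the feature-match false discovery rate, before and (when a filter is
#' supplied) after sigma-based match filtering.
#'
#' @slot targetMatchFraction fraction of target features assigned a match.
#' @slot decoyMatchFractions per-decoy matched fractions.
#' @slot fdrEstimate mean over decoys of decoy fraction / target fraction.
#' @slot retention fraction of target matches surviving the filter (NA when
#'   no filter was applied).
#' @slot postFilterFdr the same ratio estimate on the filtered tables (NA
#'   when no filter was applied).
#'
#' @export
setClass("FdrReport", representation(
  targetMatchFraction = "numeric",
  decoyMatchFractions = "numeric",
  fdrEstimate = "numeric",
  retention = "numeric",
  postFilterFdr = "numeric"
))

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nProteins, "proteins,",
      sprintf("%.1f%% periodic,", 100 * object@fracPeriodic),
      object@nPopulations, "populations x", object@nBiorep, "bioreps x",
      object@nTechrep, "tech repeats\n")
  cat(sprintf("  amplitude %g-%g fold, noise CV %g, depth CV %g, seed %d\n",
              object@amplitudeRange[1], object@amplitudeRange[2],
              object@noiseCV, object@depthCV, object@seed))
})

setMethod("show", "PseudotimecourseSet", function(object) {
  cat("PseudotimecourseSet:", nrow(object@series[[1]]), "proteins x",
      ncol(object@series[[1]]), "points in", length(object@series),
      "technical repeats\n")
  cat(sprintf("  testable series: %s (completeness >= %g)\n",
              paste(colSums(object@testable), collapse = " / "),
              object@completenessThreshold))
})

setMethod("show", "SignatureModel", function(object) {
  cat("SignatureModel:", length(object@pspIds), "signature proteins,",
      nrow(object@popMeans), "populations ->", nrow(object@ccsProfiles),
      "CCSs\n")
  map <- split(names(object@popToCcs), object@popToCcs)
  for (s in seq_along(map))
    cat(sprintf("  CCS%d: %s\n", s, paste(map[[s]], collapse = ", ")))
  if (!object@contiguous)
    cat("  note: at least one CCS is not a contiguous population block\n")
})

setMethod("show", "MatchFilter", function(object) {
  cat("MatchFilter thresholds (center +/- n*sigma):\n")
  for (d in c("d_rt", "d_mz", "ppm_err"))
    cat(sprintf("  %-8s %g +/- %.3g * %.4g\n", d, object@center[[d]],
                object@nSigma[[d]], object@sigma[[d]]))
})

setMethod("show", "FdrReport", function(object) {
  cat(sprintf("FdrReport: target matched %.3f, decoy matched %s\n",
              object@targetMatchFraction,
              paste(sprintf("%.4f", object@decoyMatchFractions),
                    collapse = ", ")))
  cat(sprintf("  estimated match FDR %.4f", object@fdrEstimate))
  if (!is.na(object@postFilterFdr))
    cat(sprintf(" -> %.4f after filtering (retention %.3f)",
                object@postFilterFdr, object@retention))
  cat("\n")
})

#' @describeIn SignatureModel-class identifiers of the signature proteins.
#' @param object a `SignatureModel`.
#' @export
setGeneric("pspIds", function(object) standardGeneric("pspIds"))

#' @rdname SignatureModel-class
#' @export
setMethod("pspIds", "SignatureModel", function(object) object@pspIds)

#' @describeIn SignatureModel-class population-to-CCS map.
#' @export
setGeneric("popToCcs", function(object) standardGeneric("popToCcs"))

#' @rdname SignatureModel-class
#' @export
setMethod("popToCcs", "SignatureModel", function(object) object@popToCcs)

#' @describeIn SignatureModel-class CCS mean scaled profiles (CCS x protein).
#' @export
setGeneric("ccsProfiles", function(object) standardGeneric("ccsProfiles"))

#' @rdname SignatureModel-class
#' @export
setMethod("ccsProfiles", "SignatureModel", function(object) object@ccsProfiles)

#' @describeIn SignatureModel-class per-population mean scaled profiles.
#' @export
setGeneric("popMeans", function(object) standardGeneric("popMeans"))

#' @rdname SignatureModel-class
#' @export
setMethod("popMeans", "SignatureModel", function(object) object@popMeans)

#' @describeIn FdrReport-class the estimated match FDR.
#' @param object an `FdrReport`.
#' @export
setGeneric("fdrEstimate", function(object) standardGeneric("fdrEstimate"))

#' @rdname FdrReport-class
#' @export
setMethod("fdrEstimate", "FdrReport", function(object) object@fdrEstimate)
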