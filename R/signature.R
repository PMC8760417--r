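#' Build the cell-cycle-state signature model
#'
#' z-scales each signature protein's ppm abundances across all samples,
#' computes per-population mean profiles, and aggregates the populations
#' into `nCcs` cell cycle states by restarted k-means (see
#' [aggregateCcs()]). The result carries everything needed for PCA, k-NN
#' classification and Spearman assignment of query proteomes.
#'
#' @param se ppm-normalized experiment.
#' @param ids signature protein identifiers (the PsPs).
#' @param nCcs number of aggregated cell cycle states.
#' @param seed seed for the k-means restarts.
#' @return a [SignatureModel-class].
#' @export
buildSignature <- function(se, ids, nCcs = 8L, seed = 1L) {
  ppm <- ppmAssay(se)
  if (nlevels(SummarizedExperiment::colData(se)$population) != 16L)
    stop("the signature stages assume the 16-population design")
  x <- ppm[ids, , drop = FALSE]
  x[x == 0] <- NA_real_
  scaled <- t(scale(t(x)))
  scaled[is.na(scaled)] <- 0    # scaled mean; signature proteins are near-complete
  cd <- SummarizedExperiment::colData(se)
  pops <- levels(cd$population)
  pm <- t(vapply(pops, function(p) {
    rowMeans(scaled[, cd$population == p, drop = FALSE])
  }, numeric(length(ids))))
  rownames(pm) <- pops
  agg <- aggregateCcs(pm, nCcs = nCcs, seed = seed)
  new("SignatureModel", pspIds = ids, sampleMatrix = t(scaled),
      popMeans = pm, ccsProfiles = agg$ccsProfiles,
      popToCcs = agg$popToCcs, contiguous = agg$contiguous)
}

#' PCA of the signature sample matrix (the cell-cycle wheel)
#'
#' Centered, SVD-based principal component analysis of the per-protein
#' scaled sample matrix. Constant features are dropped with a warning. The
#' sign of PC1 is fixed so that the mean score of the interphase samples
#' (populations in the first half of the cycle) is positive; PCA is
#' otherwise sign-ambiguous.
#'
#' @param sampleMatrix numeric matrix (sample x feature).
#' @param populations integer population index per sample; parsed from
#'   rownames of the form `P<pop>_...` when `NULL`.
#' @return list with `scores`, `varExplained` (percentages summing to 100)
#'   and `rotation`.
#' @export
pcaWheel <- function(sampleMatrix, populations = NULL) {
  stopifnot(nrow(sampleMatrix) >= 3)
  sdev <- apply(sampleMatrix, 2, stats::sd)
  if (any(sdev < 1e-12)) {
    warning(sum(sdev < 1e-12), " constant feature(s) dropped")
    sampleMatrix <- sampleMatrix[, sdev >= 1e-12, drop = FALSE]
  }
  pc <- stats::prcomp(sampleMatrix, center = TRUE, scale. = FALSE)
  varExplained <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  if (is.null(populations))
    populations <- suppressWarnings(
      as.integer(sub("^P(\\d+)_.*$", "\\1", rownames(sampleMatrix))))
  if (!anyNA(populations)) {
    interphase <- populations <= max(populations) / 2
    if (any(interphase) && mean(pc$x[interphase, 1]) < 0) {
      pc$x[, 1] <- -pc$x[, 1]
      pc$rotation[, 1] <- -pc$rotation[, 1]
    }
  }
  list(scores = pc$x, varExplained = varExplained, rotation = pc$rotation)
}

#' Euclidean k-NN classification of cell-cycle samples
#'
#' Majority vote among the `k` nearest training samples. Vote ties are
#' broken toward the tied label with the smallest mean neighbor distance,
#' then toward the lowest label index, so classification is deterministic.
#'
#' @param train numeric matrix (sample x feature).
#' @param trainLabels factor of training labels.
#' @param test numeric matrix with the same features.
#' @param k number of neighbors.
#' @return factor of predicted labels for the test rows.
#' @export
knnClassify <- function(train, trainLabels, test, k = 6L) {
  if (ncol(train) != ncol(test)) stop("train and test features differ")
  if (nrow(train) < k) stop("fewer training samples than k")
  trainLabels <- as.factor(trainLabels)
  d2 <- outer(rowSums(test^2), rep(1, nrow(train))) +
        outer(rep(1, nrow(test)), rowSums(train^2)) -
        2 * test %*% t(train)
  pred <- vapply(seq_len(nrow(test)), function(i) {
    nb <- order(d2[i, ])[seq_len(k)]
    votes <- table(trainLabels[nb])
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1L) {
      meanDist <- vapply(top, function(lb) {
        mean(d2[i, nb[trainLabels[nb] == lb]])
      }, numeric(1))
      top <- top[meanDist == min(meanDist)]
      if (length(top) > 1L)
        top <- top[which.min(match(top, levels(trainLabels)))]
    }
    top[1]
  }, character(1))
  factor(pred, levels = levels(trainLabels))
}

#' Aggregate populations into cell cycle states by k-means
#'
#' Runs k-means (Euclidean) on the population mean profiles with many
#' random restarts under a fixed seed, discarding restarts that produce an
#' empty cluster (or duplicate initial centers) and keeping the solution
#' with the lowest total within-cluster sum of squares. The states are then
#' relabeled by the temporal order of their member populations (circular
#' mean position, ties to the earliest member), and each state's profile
#' is the mean of its members' profiles. Temporal contiguity of the member
#' blocks is reported, not enforced.
#'
#' @param popMeans matrix (population x protein) of mean scaled profiles.
#' @param nCcs number of states.
#' @param seed integer seed.
#' @param nRestarts number of random restarts.
#' @return list with `popToCcs`, `ccsProfiles`, `contiguous`, `withinss`.
#' @export
aggregateCcs <- function(popMeans, nCcs = 8L, seed = 1L, nRestarts = 100L) {
  nPop <- nrow(popMeans)
  stopifnot(nCcs >= 2, nCcs <= nPop, nRestarts >= 1)
  withLocalSeed(seed, {
    best <- NULL
    for (r in seq_len(nRestarts)) {
      centers <- popMeans[sample.int(nPop, nCcs), , drop = FALSE]
      km <- tryCatch(
        stats::kmeans(popMeans, centers = centers, iter.max = 100L),
        error = function(e) NULL)   # empty cluster / duplicate centers
      if (is.null(km) || length(unique(km$cluster)) != nCcs) next
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
    if (is.null(best)) stop("no k-means restart produced ", nCcs, " clusters")
    cl <- best$cluster
    ## temporal order on the circle, so a wrap-around state (e.g. P16 + P1,
    ## mitotic exit flowing into G1) sorts at the end rather than mid-cycle
    ang <- 2 * pi * (seq_len(nPop) - 1) / nPop
    circMean <- vapply(seq_len(nCcs), function(s) {
      idx <- which(cl == s)
      a <- atan2(mean(sin(ang[idx])), mean(cos(ang[idx])))
      (a + 2 * pi) %% (2 * pi)
    }, numeric(1))
    firstIdx <- vapply(seq_len(nCcs), function(s) min(which(cl == s)),
                       numeric(1))
    relabel <- match(cl, order(circMean, firstIdx))
    names(relabel) <- rownames(popMeans)
    profiles <- t(vapply(seq_len(nCcs), function(s) {
      colMeans(popMeans[relabel == s, , drop = FALSE])
    }, numeric(ncol(popMeans))))
    rownames(profiles) <- paste0("CCS", seq_len(nCcs))
    contiguous <- all(vapply(seq_len(nCcs), function(s) {
      idx <- sort(which(relabel == s))
      gaps <- diff(c(idx, idx[1] + nPop))      # circular gaps
      sum(gaps > 1) <= 1
    }, logical(1)))
    list(popToCcs = as.integer(relabel) |> setNames(rownames(popMeans)),
         ccsProfiles = profiles, contiguous = contiguous,
         withinss = best$tot.withinss)
  })
}

#' Normalize a query proteome for signature assignment
#'
#' `silac_log_ratio`: values are already log-ratios and are centered to
#' median zero. `lfq_vs_reference`: values are label-free intensities which
#' are divided by the matched reference intensities (an asynchronous
#' control), log2-transformed and centered; nonpositive ratios become
#' missing.
#'
#' @param values named numeric vector (protein -> value), NAs allowed.
#' @param mode normalization mode.
#' @param reference named reference intensities (lfq mode).
#' @return named numeric vector of centered log-ratios.
#' @export
normalizeQuery <- function(values,
                           mode = c("silac_log_ratio", "lfq_vs_reference"),
                           reference = NULL) {
  mode <- match.arg(mode)
  if (mode == "lfq_vs_reference") {
    if (is.null(reference)) stop("lfq_vs_reference requires a reference")
    ref <- reference[names(values)]
    ratio <- values / ref
    ratio[!is.finite(ratio) | ratio <= 0] <- NA_real_
    values <- log2(ratio)
  }
  values - stats::median(values, na.rm = TRUE)
}

#' Assign a cell cycle state to a query proteome
#'
#' Spearman rank correlation of the query values against each CCS profile
#' over the pairwise-complete signature proteins. The best state is the
#' argmax correlation; its significance comes from the large-sample t
#' approximation of Spearman's rho at the overlap size (one-sided, positive
#' association). Queries overlapping fewer than `minOverlap` signature
#' proteins are left unassigned.
#'
#' @param query named numeric vector (protein -> normalized value, NAs
#'   allowed), see [normalizeQuery()].
#' @param model a [SignatureModel-class].
#' @param minOverlap minimum number of nonmissing signature proteins.
#' @return one-row `data.frame`: `rho_CCS*`, `n_overlap`, `best_ccs`, `rho`,
#'   `p`, and `reason` when unassigned.
#' @export
spearmanAssign <- function(query, model, minOverlap = 30L) {
  prof <- ccsProfiles(model)
  common <- intersect(names(query)[!is.na(query)], pspIds(model))
  nCcs <- nrow(prof)
  rho <- setNames(rep(NA_real_, nCcs), paste0("rho_", rownames(prof)))
  out <- data.frame(t(rho), n_overlap = length(common),
                    best_ccs = NA_character_, rho = NA_real_, p = NA_real_,
                    reason = NA_character_, check.names = FALSE)
  if (length(common) < minOverlap) {
    out$reason <- sprintf("overlap %d below minimum %d", length(common),
                          minOverlap)
    return(out)
  }
  q <- query[common]
  rho <- vapply(seq_len(nCcs), function(s) {
    stats::cor(q, prof[s, common], method = "spearman")
  }, numeric(1))
  out[1, seq_len(nCcs)] <- rho
  best <- which.max(rho)
  n <- length(common)
  r <- rho[best]
  tstat <- r * sqrt((n - 2) / max(1 - r^2, 1e-12))
  out$best_ccs <- rownames(prof)[best]
  out$rho <- r
  out$p <- stats::pt(tstat, df = n - 2, lower.tail = FALSE)
  out
}

#' Assign cell cycle states to a batch of query proteomes
#'
#' Runs [spearmanAssign()] on every query and controls the best-state
#' significance across the batch by Benjamini-Hochberg; `assigned` flags
#' experiments with adjusted p below `fdrLevel`.
#'
#' @param queries named list of query vectors, or a numeric matrix
#'   (protein x experiment).
#' @param model a [SignatureModel-class].
#' @param minOverlap minimum overlap per query.
#' @param fdrLevel BH level for the `assigned` flag.
#' @return `data.frame`, one row per experiment, with `padj` and `assigned`.
#' @export
spearmanAssignBatch <- function(queries, model, minOverlap = 30L,
                                fdrLevel = 0.05) {
  if (is.matrix(queries))
    queries <- lapply(setNames(seq_len(ncol(queries)), colnames(queries)),
                      function(j) setNames(queries[, j], rownames(queries)))
  rows <- lapply(queries, spearmanAssign, model = model,
                 minOverlap = minOverlap)
  out <- do.call(rbind, rows)
  out <- cbind(experiment_id = names(queries), out)
  rownames(out) <- NULL
  out$padj <- NA_real_
  ok <- !is.na(out$p)
  out$padj[ok] <- stats::p.adjust(out$p[ok], method = "BH")
  out$assigned <- !is.na(out$padj) & out$padj < fdrLevel
  out
}

#' Circular rank correlation of an angular ordering
#'
#' Measures how well the angular order of points around a circle (e.g.
#' populations in the PC1/PC2 plane) recovers a known cyclic order,
#' maximizing the Spearman correlation over all rotations and both
#' directions — the wheel has no preferred origin or handedness.
#'
#' @param angles numeric angles (radians), one per object.
#' @param trueOrder known cyclic positions (default 1..n).
#' @return maximum Spearman correlation over the 2n alignments.
#' @export
circularRankCor <- function(angles, trueOrder = seq_along(angles)) {
  n <- length(angles)
  stopifnot(length(trueOrder) == n)
  ord <- order(angles)               # counterclockwise ordering
  pos <- match(seq_len(n), ord)      # circular position of each object
  bestCor <- -1
  for (dir in c(1, -1)) {
    p <- if (dir == 1) pos else (n + 1 - pos)
    for (shift in 0:(n - 1)) {
      shifted <- ((p - 1 + shift) %% n) + 1
      bestCor <- max(bestCor,
                     stats::cor(shifted, trueOrder, method = "spearman"))
    }
  }
  bestCor
}
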