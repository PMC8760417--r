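#' Mean population profiles of signature proteins
#'
#' Averages each protein's ppm values over all replicate series per
#' population (8 values per population under the full design, missing values
#' excluded), then z-standardizes the 16-point mean profile. Proteins with a
#' population missing in all replicates, or with a constant (degenerate)
#' profile, are excluded with a warning.
#'
#' @param se ppm-normalized experiment.
#' @param ids proteins to profile (typically the PsPs).
#' @return list with `mean` and `scaled` matrices (protein x population) and
#'   `excluded`, the ids dropped.
#' @export
meanProfiles <- function(se, ids) {
  if (!length(ids)) stop("empty protein set")
  ppm <- ppmAssay(se)
  missingIds <- setdiff(ids, rownames(ppm))
  if (length(missingIds))
    stop("unknown protein id(s): ", paste(head(missingIds, 5), collapse = ", "))
  cd <- SummarizedExperiment::colData(se)
  pops <- levels(cd$population)
  x <- ppm[ids, , drop = FALSE]
  x[x == 0] <- NA_real_
  mp <- vapply(pops, function(p) {
    rowMeans(x[, cd$population == p, drop = FALSE], na.rm = TRUE)
  }, numeric(length(ids)))
  bad <- apply(mp, 1, function(r) any(!is.finite(r)))
  sdev <- apply(mp, 1, stats::sd)
  degen <- !bad & (is.na(sdev) | sdev < 1e-12)
  drop <- bad | degen
  if (any(drop))
    warning(sum(bad), " protein(s) with an all-missing population and ",
            sum(degen), " constant profile(s) excluded")
  mp <- mp[!drop, , drop = FALSE]
  scaled <- t(scale(t(mp)))
  attr(scaled, "scaled:center") <- NULL
  attr(scaled, "scaled:scale") <- NULL
  list(mean = mp, scaled = scaled, excluded = ids[drop])
}

#' Ward clustering of scaled profiles
#'
#' Agglomerative hierarchical clustering with the Ward minimum-variance
#' criterion (squared-Euclidean updates, distances on the Euclidean scale)
#' on the z-scaled mean profiles, cut at `k` clusters.
#'
#' @param scaled matrix (protein x population) of scaled profiles.
#' @param k number of clusters.
#' @return list with `labels` (named integer vector), `k`, and `hclust`,
#'   the linkage record.
#' @export
wardCluster <- function(scaled, k) {
  stopifnot(k >= 2)
  if (k > nrow(scaled)) stop("k exceeds the number of profiles")
  hc <- stats::hclust(stats::dist(scaled), method = "ward.D2")
  list(labels = stats::cutree(hc, k = k), k = k, hclust = hc)
}

wssOfPartition <- function(scaled, labels) {
  sum(vapply(split(seq_len(nrow(scaled)), labels), function(idx) {
    m <- scaled[idx, , drop = FALSE]
    sum(sweep(m, 2, colMeans(m))^2)
  }, numeric(1)))
}

#' Elbow curve of within-cluster sum of squares
#'
#' Within-cluster sum of squares of the Ward partition for each candidate
#' `k`, plus the maximum-curvature (largest discrete second difference) k.
#' A curve is flagged as having a strong elbow when its largest single-step
#' drop exceeds five times the median step drop; structureless data decline
#' smoothly and fail that test, so no elbow is reported for them.
#'
#' @param scaled matrix of scaled profiles.
#' @param kRange candidate cluster numbers.
#' @return list with `k`, `wss`, `elbow` (NA when no strong elbow), and
#'   `strongElbow`.
#' @export
elbowWss <- function(scaled, kRange = 2:10) {
  kRange <- kRange[kRange <= nrow(scaled)]
  hc <- stats::hclust(stats::dist(scaled), method = "ward.D2")
  wss <- vapply(kRange, function(k) {
    wssOfPartition(scaled, stats::cutree(hc, k = k))
  }, numeric(1))
  elbow <- NA_integer_
  strong <- FALSE
  if (length(kRange) >= 3) {
    curv <- diff(diff(wss))                    # at kRange[2:(n-1)]
    elbow <- kRange[which.max(curv) + 1L]
    steps <- -diff(wss)
    strong <- max(steps) > 5 * stats::median(steps)
    if (!strong) elbow <- NA_integer_
  }
  list(k = kRange, wss = wss, elbow = elbow, strongElbow = strong)
}

#' Relabel clusters by temporal peak order
#'
#' Replaces the arbitrary agglomeration labels with labels 1..k ordered by
#' the circular position of each cluster-mean profile's peak population, so
#' cluster 1 peaks earliest in the cycle. Ties on the peak position go to
#' the cluster containing the lexicographically smallest member. The
#' partition itself is unchanged.
#'
#' @param labels integer cluster labels named by protein.
#' @param scaled the matrix the clustering was fit on.
#' @return relabeled integer vector with attribute `peakPopulation`.
#' @export
orderClustersByPeak <- function(labels, scaled) {
  ks <- sort(unique(labels))
  peaks <- vapply(ks, function(cl) {
    which.max(colMeans(scaled[labels == cl, , drop = FALSE]))
  }, integer(1))
  first <- vapply(ks, function(cl) min(which(labels == cl)), integer(1))
  newOrder <- ks[order(peaks, first)]
  relabel <- match(labels, newOrder)
  names(relabel) <- names(labels)
  attr(relabel, "peakPopulation") <- peaks[order(peaks, first)]
  relabel
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same objects;
#' 1 means identical partitions, 0 the expectation under independence.
#'
#' @param a,b label vectors of equal length.
#' @return the adjusted Rand index.
#' @export
adjustedRandIndex <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(length(a), 2)
  expected <- ai * bj / n2
  denom <- (ai + bj) / 2 - expected
  if (denom == 0) return(1)
  (nij - expected) / denom
}
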