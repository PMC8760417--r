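checkMatchTable <- function(tab) {
  need <- c("matched", "d_rt", "d_mz", "ppm_err")
  if (!all(need %in% names(tab)))
    stop("match table must have columns: ", paste(need, collapse = ", "))
  invisible(tab)
}

#' Estimate the feature-match (MBR) FDR from target and decoy runs
#'
#' Matches to a chemically-modified decoy run are false by construction, so
#' the matched fraction of decoy features, normalized by the matched
#' fraction of target features, estimates the false discovery rate of the
#' target matches. With several decoy runs the per-decoy ratios are
#' averaged. When a [MatchFilter-class] is supplied the report also carries
#' the post-filter FDR (same ratio on the filtered tables) and the target
#' match retention.
#'
#' @param target target match table (see [simulateMatchTables()] /
#'   [readMatchTable()]).
#' @param decoys one decoy match table or a list of them.
#' @param filter optional [MatchFilter-class] from [fitMatchSigmas()].
#' @return an [FdrReport-class].
#' @examples
#' sim <- simulateMatchTables(20000, 20000, trueFraction = 0.93, seed = 5)
#' estimateFdr(sim$target, sim$decoy)
#' @export
estimateFdr <- function(target, decoys, filter = NULL) {
  checkMatchTable(target)
  if (is.data.frame(decoys)) decoys <- list(decoys)
  lapply(decoys, checkMatchTable)
  targetFrac <- mean(target$matched)
  if (targetFrac == 0) stop("no matched target features: FDR undefined")
  decoyFracs <- vapply(decoys, function(d) mean(d$matched), numeric(1))
  fdr <- mean(decoyFracs / targetFrac)
  retention <- NA_real_
  postFdr <- NA_real_
  if (!is.null(filter)) {
    ft <- filterMatches(target, filter)
    fdList <- lapply(decoys, filterMatches, filter = filter)
    retention <- ft$retention
    postTargetFrac <- mean(ft$table$matched)
    postFdr <- mean(vapply(fdList, function(fd) mean(fd$table$matched),
                           numeric(1)) / postTargetFrac)
  }
  new("FdrReport", targetMatchFraction = targetFrac,
      decoyMatchFractions = decoyFracs, fdrEstimate = fdr,
      retention = retention, postFilterFdr = postFdr)
}

#' Fit robust sigma thresholds on the match-error dimensions
#'
#' Estimates the spread of each matched-error dimension of the target run
#' (retention-time difference, m/z difference, m/z error) with the robust
#' sigma `1.4826 x MAD` about the median, which resists the wide tail of
#' false matches. Returns the thresholds used by [filterMatches()]:
#' 2.5 sigma for match time and 3 sigma for the two m/z dimensions.
#'
#' @param target target match table with at least 100 matched features.
#' @param nSigma named multipliers per dimension.
#' @return a [MatchFilter-class].
#' @export
fitMatchSigmas <- function(target,
                           nSigma = c(d_rt = 2.5, d_mz = 3, ppm_err = 3)) {
  checkMatchTable(target)
  matched <- target[target$matched, , drop = FALSE]
  if (nrow(matched) < 100L)
    stop("need at least 100 matched features to fit sigmas")
  dims <- c("d_rt", "d_mz", "ppm_err")
  center <- vapply(matched[dims], stats::median, numeric(1))
  sigma <- vapply(matched[dims], function(v) stats::mad(v), numeric(1))
  if (any(sigma <= 0))
    stop("degenerate (zero-spread) dimension: ",
         paste(dims[sigma <= 0], collapse = ", "))
  new("MatchFilter", center = center, sigma = sigma, nSigma = nSigma[dims])
}

#' Apply sigma-based match filtering
#'
#' Keeps a match only when every error dimension lies within its
#' `center +/- nSigma * sigma` window (boundary inclusive); filtered
#' matches become unmatched features, so matched fractions and FDR
#' estimates recompute consistently on the filtered table.
#'
#' @param table a match table.
#' @param filter a [MatchFilter-class].
#' @return list with `table` (filtered), `keep` (logical over input rows:
#'   matched and within all windows), and `retention` (kept / initially
#'   matched).
#' @export
filterMatches <- function(table, filter) {
  checkMatchTable(table)
  stopifnot(is(filter, "MatchFilter"))
  keep <- table$matched
  for (d in c("d_rt", "d_mz", "ppm_err")) {
    lim <- filter@nSigma[[d]] * filter@sigma[[d]]
    keep <- keep & !is.na(table[[d]]) &
      abs(table[[d]] - filter@center[[d]]) <= lim
  }
  nInit <- sum(table$matched)
  out <- table
  drop <- out$matched & !keep
  out$matched[drop] <- FALSE
  out[drop, c("d_rt", "d_mz", "ppm_err")] <- NA_real_
  list(table = out, keep = keep,
       retention = if (nInit > 0) sum(keep) / nInit else NA_real_)
}
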