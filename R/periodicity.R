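#' Periodogram of a pseudotimecourse
#'
#' Classical periodogram of a mean-centered series:
#' `I[k] = |sum_t x_t exp(-2 pi i k t / N)|^2 / N` at the Fourier
#' frequencies `k/N`, `k = 1..floor((N-1)/2)` (31 ordinates for a 64-point
#' series). Constant series are degenerate and flagged untestable.
#'
#' @param x numeric series; `NA`s must have been imputed beforehand.
#' @return list with `I` (spectral power, named by `k`), `m` (number of
#'   ordinates), `N`, and `degenerate`.
#' @examples
#' pg <- periodogram(cos(2 * pi * 4 * (1:64) / 64))
#' which.max(pg$I)  # all power at k = 4
#' @export
periodogram <- function(x) {
  if (any(!is.finite(x))) stop("series must be finite (impute gaps first)")
  N <- length(x)
  m <- (N - 1L) %/% 2L
  xc <- x - mean(x)
  if (all(abs(xc) < 1e-12 * max(1, abs(mean(x)))))
    return(list(I = setNames(rep(0, m), seq_len(m)), m = m, N = N,
                degenerate = TRUE))
  I <- (Mod(stats::fft(xc))^2 / N)[2:(m + 1L)]
  list(I = setNames(I, seq_len(m)), m = m, N = N, degenerate = FALSE)
}

#' Fisher's g statistic
#'
#' Ratio of the maximum periodogram ordinate to the sum of all ordinates;
#' the dominant Fourier index is the argmax, with exact ties broken toward
#' the smaller index (longer period).
#'
#' @param pg a [periodogram()] result.
#' @return list with `g` and `kMax`.
#' @examples
#' fisherG(periodogram(cos(2 * pi * 4 * (1:64) / 64)))
#' @export
fisherG <- function(pg) {
  if (pg$degenerate) stop("degenerate periodogram: constant series")
  kMax <- which.max(pg$I)        # which.max takes the first of tied maxima
  list(g = unname(pg$I[kMax] / sum(pg$I)), kMax = unname(kMax))
}

#' Exact null p-value of Fisher's g
#'
#' Under Gaussian white noise the exact upper-tail probability is
#' `p = sum_{j=1}^{min(m, floor(1/g))} (-1)^(j-1) C(m,j) (1-jg)^(m-1)`.
#' Terms are evaluated in log space and accumulated with their alternating
#' signs to control cancellation; the result is clipped to [0, 1].
#'
#' @param g Fisher's g statistic in (0, 1].
#' @param m number of periodogram ordinates.
#' @return the exact p-value.
#' @examples
#' fisherGPvalue(0.9, 7)  # 7 * 0.1^6
#' @export
fisherGPvalue <- function(g, m) {
  stopifnot(m >= 1, g > 0, g <= 1)
  jMax <- min(m, floor(1 / g))
  if (g <= 1 / m) return(1)
  j <- seq_len(jMax)
  logTerms <- lchoose(m, j) + (m - 1) * log1p(-j * g)
  p <- sum((-1)^(j - 1) * exp(logTerms))
  min(max(p, 0), 1)
}

#' Storey q-values
#'
#' Estimates the null proportion pi0 on the lambda grid 0.05, 0.10, ...,
#' 0.95 with a cubic smoothing spline evaluated at the largest lambda
#' (clipped to (0, 1]), then computes `q_i = pi0 * min_{p_j >= p_i}
#' (n p_j / rank_j)`, which is monotone in p. With fewer than 100 p-values
#' the pi0 estimate is unstable and the function falls back to pi0 = 1
#' (Benjamini-Hochberg) with a warning.
#'
#' @param p vector of p-values in [0, 1].
#' @param lambda grid for the pi0 fit.
#' @return q-values in the input order; attribute `pi0` carries the estimate.
#' @examples
#' storeyQvalues(runif(200))
#' @export
storeyQvalues <- function(p, lambda = seq(0.05, 0.95, 0.05)) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  ok <- !is.na(p)
  pv <- p[ok]
  n <- length(pv)
  if (n == 0L) return(p)
  if (n < 100L) {
    warning("fewer than 100 p-values; using pi0 = 1 (Benjamini-Hochberg)")
    pi0 <- 1
  } else {
    pi0l <- vapply(lambda, function(l) mean(pv > l) / (1 - l), numeric(1))
    fit <- stats::smooth.spline(lambda, pi0l, df = 3)
    pi0 <- stats::predict(fit, x = max(lambda))$y
    pi0 <- min(max(pi0, 1e-8), 1)
  }
  o <- order(pv, decreasing = TRUE)
  ro <- order(o)
  q <- pi0 * pmin(1, cummin(n / rank(pv, ties.method = "max")[o] * pv[o]))[ro]
  out <- rep(NA_real_, length(p))
  out[ok] <- q
  attr(out, "pi0") <- pi0
  out
}

#' Fisher periodicity test over all pseudotimecourses
#'
#' Applies the periodogram / Fisher g / exact p machinery independently to
#' every protein in every technical repeat. Gaps in a testable series (those
#' meeting the completeness threshold) are imputed with the series mean,
#' which is neutral for the periodogram; untestable or constant series get
#' `NA` results. q-values are computed per repeat across testable proteins.
#'
#' @param pts a [PseudotimecourseSet-class].
#' @return `data.frame` with one row per protein per repeat: `protein_id`,
#'   `repeat_id`, `g`, `k_max`, `freq`, `p`, `q`, `testable`.
#' @examples
#' se <- ppmNormalize(simulateCellCycleDataset(simConfig(nProteins = 150)))
#' head(testPeriodicity(assemblePseudotimecourses(se)))
#' @export
testPeriodicity <- function(pts) {
  stopifnot(is(pts, "PseudotimecourseSet"))
  out <- lapply(seq_along(pts@series), function(t) {
    m <- pts@series[[t]]
    res <- data.frame(protein_id = rownames(m),
                      repeat_id = names(pts@series)[t],
                      g = NA_real_, k_max = NA_integer_, freq = NA_real_,
                      p = NA_real_, q = NA_real_,
                      testable = pts@testable[, t])
    N <- ncol(m)
    for (i in which(res$testable)) {
      x <- m[i, ]
      x[is.na(x)] <- mean(x, na.rm = TRUE)
      pg <- periodogram(x)
      if (pg$degenerate) { res$testable[i] <- FALSE; next }
      fg <- fisherG(pg)
      res$g[i] <- fg$g
      res$k_max[i] <- fg$kMax
      res$freq[i] <- fg$kMax / N
      res$p[i] <- fisherGPvalue(fg$g, pg$m)
    }
    res$q[res$testable] <- as.numeric(storeyQvalues(res$p[res$testable]))
    res
  })
  do.call(rbind, out)
}

#' Call pseudoperiodic proteins
#'
#' A protein is a pseudoperiodic protein (PsP) when its q-value is below
#' `qThresh` in both technical repeats and its dominant oscillation
#' frequency lies in `allowedFreqs` (by default 1/16 or 1/8 of the series
#' length: one or two cycles per pass through the populations) in both
#' repeats. Proteins untestable in either repeat are not PsPs.
#'
#' @param results output of [testPeriodicity()].
#' @param qThresh q-value threshold applied in each repeat.
#' @param allowedFreqs admissible dominant frequencies.
#' @return `data.frame` with one row per protein: per-repeat `q` and `freq`
#'   and the logical `is_psp`.
#' @export
callPsps <- function(results, qThresh = 0.10,
                     allowedFreqs = c(1 / 16, 1 / 8)) {
  reps <- sort(unique(results$repeat_id))
  if (length(reps) < 2L)
    stop("PsP calling requires results from both technical repeats")
  wide <- NULL
  for (r in reps) {
    sub <- results[results$repeat_id == r,
                   c("protein_id", "q", "freq", "testable")]
    names(sub)[2:4] <- paste0(c("q_", "freq_", "testable_"), r)
    wide <- if (is.null(wide)) sub else merge(wide, sub, by = "protein_id")
  }
  qCols <- paste0("q_", reps)
  fCols <- paste0("freq_", reps)
  tCols <- paste0("testable_", reps)
  okQ <- Reduce(`&`, lapply(qCols, function(cc) !is.na(wide[[cc]]) &
                                                wide[[cc]] < qThresh))
  okF <- Reduce(`&`, lapply(fCols, function(cc) {
    f <- wide[[cc]]
    !is.na(f) & vapply(f, function(v) any(abs(v - allowedFreqs) < 1e-9),
                       logical(1))
  }))
  okT <- Reduce(`&`, lapply(tCols, function(cc) wide[[cc]]))
  wide$is_psp <- okT & okQ & okF
  wide
}
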