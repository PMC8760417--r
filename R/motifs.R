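#' Default APC/C degron motif definitions
#'
#' Position-restricted patterns over the 20 amino acids for the three short
#' linear motifs (SLiMs) that mediate substrate recognition by the APC/C:
#' the KEN box, the D-box (RxxL) and the ABBA motif (Fx[ILV][FHY]x[DE]).
#' `.` matches any of the 20 residues; `[..]` restricts a position. Users
#' may supply additional named patterns in the same dialect.
#'
#' @return named character vector of patterns.
#' @examples
#' motifDefs()
#' @export
motifDefs <- function() {
  c(KEN = "KEN", DBOX = "R..L", ABBA = "F.[ILV][FHY].[DE]")
}

## Translate the motif dialect into a strict regex in which '.' matches only
## the 20 amino acids (so X/B/Z and other codes never satisfy a wildcard).
motifRegex <- function(pattern) {
  gsub(".", "[ACDEFGHIKLMNPQRSTVWY]", pattern, fixed = TRUE)
}

#' Scan protein sequences for motifs
#'
#' Reports, per protein and motif, whether the motif occurs (and where).
#' Characters outside the 20-amino-acid alphabet trigger a warning and never
#' match, including against wildcard positions.
#'
#' @param seqs an [Biostrings::AAStringSet] (or named character vector).
#' @param defs named patterns, defaulting to [motifDefs()].
#' @return list with `hits`, a logical matrix (protein x motif), and
#'   `positions`, a nested list of match start positions.
#' @examples
#' scanMotifs(Biostrings::AAStringSet(c(p1 = "AKENRTAL")))$hits
#' @export
scanMotifs <- function(seqs, defs = motifDefs()) {
  if (is(seqs, "XStringSet")) seqs <- as.character(seqs)
  if (is.null(names(seqs))) stop("sequences must be named")
  if (!length(defs) || any(!nzchar(defs))) stop("motif patterns must be nonempty")
  stray <- grepl("[^ACDEFGHIKLMNPQRSTVWY]", seqs)
  if (any(stray))
    warning(sum(stray), " sequence(s) contain non-amino-acid characters; ",
            "those positions never match")
  hits <- matrix(FALSE, length(seqs), length(defs),
                 dimnames = list(names(seqs), names(defs)))
  positions <- lapply(seq_along(seqs), function(i) {
    setNames(vector("list", length(defs)), names(defs))
  })
  names(positions) <- names(seqs)
  for (m in seq_along(defs)) {
    rx <- motifRegex(defs[[m]])
    found <- gregexpr(rx, seqs)
    for (i in seq_along(seqs)) {
      st <- found[[i]]
      if (st[1] != -1) {
        hits[i, m] <- TRUE
        positions[[i]][[m]] <- as.integer(st)
      }
    }
  }
  list(hits = hits, positions = positions)
}

#' Per-cluster motif enrichment
#'
#' One-sided exact hypergeometric test of motif enrichment in each cluster
#' against the background set (cluster versus rest of the background), with
#' the fold change of the in-cluster frequency over the background
#' frequency.
#'
#' @param hits logical matrix from [scanMotifs()].
#' @param clusters named integer/character vector of cluster labels; its
#'   names must be a subset of `backgroundIds`.
#' @param backgroundIds the background protein set (defaults to all scanned
#'   proteins).
#' @param alpha significance level for the `significant` flag.
#' @return `data.frame` with columns `cluster`, `motif`, `a` (cluster hits),
#'   `n` (cluster size), `A` (background hits), `Nbg`, `frequency`, `fold`,
#'   `p`, `significant`.
#' @export
enrichmentTest <- function(hits, clusters, backgroundIds = rownames(hits),
                           alpha = 0.01) {
  if (!length(clusters)) stop("empty cluster assignment")
  if (!all(names(clusters) %in% backgroundIds))
    stop("clusters must be a subset of the background")
  if (!all(backgroundIds %in% rownames(hits)))
    stop("background proteins missing from the scan")
  bg <- hits[backgroundIds, , drop = FALSE]
  Nbg <- nrow(bg)
  out <- list()
  for (cl in sort(unique(clusters))) {
    ids <- names(clusters)[clusters == cl]
    if (!length(ids)) stop("empty cluster: ", cl)
    n <- length(ids)
    for (m in colnames(hits)) {
      a <- sum(bg[ids, m])
      A <- sum(bg[, m])
      p <- stats::phyper(a - 1, A, Nbg - A, n, lower.tail = FALSE)
      out[[length(out) + 1L]] <- data.frame(
        cluster = cl, motif = m, a = a, n = n, A = A, Nbg = Nbg,
        frequency = a / n,
        fold = if (A > 0) (a / n) / (A / Nbg) else NA_real_,
        p = p, significant = p < alpha)
    }
  }
  do.call(rbind, out)
}

#' Multi-SLiM tally per cluster
#'
#' Counts, per protein, the number of distinct motif types present, and
#' tallies per cluster how many proteins carry two or more, and exactly
#' three, SLiMs.
#'
#' @param hits logical matrix from [scanMotifs()].
#' @param clusters named cluster labels.
#' @return list with `perProtein` (named integer vector) and `perCluster`
#'   (`data.frame` with `cluster`, `n`, `multi` (>= 2 SLiMs), `triple`).
#' @export
multiSlimSummary <- function(hits, clusters) {
  counts <- rowSums(hits)
  perCluster <- do.call(rbind, lapply(sort(unique(clusters)), function(cl) {
    ids <- names(clusters)[clusters == cl]
    data.frame(cluster = cl, n = length(ids),
               multi = sum(counts[ids] >= 2),
               triple = sum(counts[ids] == 3))
  }))
  list(perProtein = counts, perCluster = perCluster)
}
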