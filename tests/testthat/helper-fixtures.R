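## Shared fixtures, generated once per test run and memoized.

.fixtureCache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtureCache))
    assign(name, builder(), envir = .fixtureCache)
  get(name, envir = .fixtureCache)
}

## Small normalized dataset with a generous periodic fraction, for
## clustering / signature tests where per-protein power matters more than
## realistic prevalence.
smallDataset <- function() {
  fixture("smallDataset", function() {
    se <- simulateCellCycleDataset(
      simConfig(nProteins = 800, fracPeriodic = 0.15,
                amplitudeRange = c(2, 4), seed = 101L))
    ppmNormalize(se)
  })
}

smallCalls <- function() {
  fixture("smallCalls", function() {
    se <- smallDataset()
    callPsps(testPeriodicity(assemblePseudotimecourses(se)))
  })
}

smallSignature <- function() {
  fixture("smallSignature", function() {
    se <- smallDataset()
    calls <- smallCalls()
    buildSignature(se, calls$protein_id[calls$is_psp], seed = 7L)
  })
}

## Brute-force DFT periodogram, the independent oracle for periodogram().
bruteForcePeriodogram <- function(x) {
  N <- length(x)
  xc <- x - mean(x)
  m <- (N - 1) %/% 2
  vapply(seq_len(m), function(k) {
    re <- sum(xc * cos(-2 * pi * k * seq_len(N) / N))
    im <- sum(xc * sin(-2 * pi * k * seq_len(N) / N))
    (re^2 + im^2) / N
  }, numeric(1))
}

## Brute-force sliding-window motif scan over an explicit per-position
## allowed-residue list; independent of the regex path.
bruteForceScan <- function(seq, pattern) {
  allowed <- CellCycleSig:::parseMotifPattern(pattern)
  L <- nchar(seq)
  w <- length(allowed)
  if (L < w) return(integer(0))
  chars <- strsplit(seq, "")[[1]]
  hits <- integer(0)
  for (s in seq_len(L - w + 1)) {
    ok <- TRUE
    for (j in seq_len(w)) {
      if (!chars[s + j - 1] %in% allowed[[j]]) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, s)
  }
  hits
}

## Monte-Carlo sample of Fisher's g under Gaussian white noise.
mcFisherG <- function(N, R, seed) {
  set.seed(seed)
  m <- (N - 1) %/% 2
  out <- numeric(R)
  chunk <- 10000L
  done <- 0L
  while (done < R) {
    nc <- min(chunk, R - done)
    X <- matrix(rnorm(N * nc), nrow = N)
    Xc <- sweep(X, 2, colMeans(X))
    I <- (Mod(stats::mvfft(Xc))^2 / N)[2:(m + 1), , drop = FALSE]
    out[done + seq_len(nc)] <- apply(I, 2, max) / colSums(I)
    done <- done + nc
  }
  out
}
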