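#' @importFrom stats rlnorm runif rbinom rnorm quantile plogis median mad
#'   setNames
NULL

## Run expr under a fixed seed without disturbing the caller's RNG stream.
withLocalSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

## Deterministic fan-out of one pipeline seed into independent stage seeds;
## kept below 2^31 so the result is a valid R integer.
stageSeed <- function(seed, stage) {
  offs <- c(simulate = 11L, periodicity = 29L, clustering = 47L,
            motifs = 61L, signature = 83L, matchfdr = 101L, query = 131L)
  if (!stage %in% names(offs)) stop("unknown stage: ", stage)
  as.integer((as.numeric(seed) * 7919 + offs[[stage]]) %% 2147483647)
}

#' Construct a simulation configuration
#'
#' Defaults emulate the sorted-cell study design this package targets: 16
#' FACS populations spanning one cell cycle, four biological replicates each
#' measured in technical duplicate (128 samples), a small minority of
#' periodic proteins following one of five cluster-shaped templates, 20%
#' multiplicative noise, 15% sample-depth variation, and left-censored
#' (abundance-dependent) missingness.
#'
#' @param nProteins number of protein groups.
#' @param fracPeriodic fraction of proteins made periodic (one cycle per 16
#'   populations).
#' @param nPopulations,nBiorep,nTechrep design counts.
#' @param amplitudeRange fold-change interval for periodic amplitudes.
#' @param noiseCV multiplicative noise coefficient of variation.
#' @param depthCV per-sample depth-factor coefficient of variation.
#' @param missingMidpoint intensity quantile at which missingness is 50%.
#' @param missingSlope logistic steepness per natural-log intensity unit.
#' @param seed integer seed.
#' @return a validated [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(nProteins = 500, seed = 1)
#' cfg
#' @export
simConfig <- function(nProteins = 5000L, fracPeriodic = 0.02,
                      nPopulations = 16L, nBiorep = 4L, nTechrep = 2L,
                      amplitudeRange = c(1.5, 4), noiseCV = 0.2,
                      depthCV = 0.15, missingMidpoint = 0.02,
                      missingSlope = 3, seed = 1L) {
  new("SimConfig", nProteins = as.integer(nProteins),
      fracPeriodic = fracPeriodic, nPopulations = as.integer(nPopulations),
      nBiorep = as.integer(nBiorep), nTechrep = as.integer(nTechrep),
      amplitudeRange = as.numeric(amplitudeRange), noiseCV = noiseCV,
      depthCV = depthCV, missingMidpoint = missingMidpoint,
      missingSlope = missingSlope, seed = as.integer(seed))
}

#' Periodic profile templates
#'
#' Five raised-cosine templates over one cell cycle, peaking in early
#' interphase, at G1/S, in S/G2, in mid-mitosis and in late mitosis. The
#' template value is the exponent applied to a protein's amplitude, so in
#' log-abundance each template is a pure tone at one cycle per
#' `nPopulations` populations (Fourier index 4 on a 64-point series).
#'
#' @param nPopulations populations per cycle.
#' @return matrix (5 x nPopulations) of exponents in [0, 1]; rownames name
#'   the peak phase, attribute `peak` gives the peak population.
#' @examples
#' profileTemplates()[, 1:4]
#' @export
profileTemplates <- function(nPopulations = 16L) {
  peaks <- c(earlyInterphase = 2, G1S = 5, SG2 = 8,
             midMitosis = 11, lateMitosis = 14)
  peaks <- 1 + (peaks - 1) * nPopulations / 16  # keep phases if design varies
  p <- seq_len(nPopulations)
  tmpl <- t(vapply(peaks, function(pk) {
    (1 + cos(2 * pi * (p - pk) / nPopulations)) / 2
  }, numeric(nPopulations)))
  attr(tmpl, "peak") <- peaks
  tmpl
}

#' Simulate a FACS-resolved cell-cycle proteome dataset
#'
#' Generates a protein x sample intensity matrix following the configured
#' design, with ground-truth labels in `rowData`. Periodic proteins follow
#' one of the five [profileTemplates()] shapes with exactly one cycle per
#' pass through the populations; non-periodic proteins are flat. Intensities
#' carry multiplicative log-normal noise and per-sample depth factors, and
#' values falling under a logistic missingness curve in log-intensity are
#' censored to zero (missing-not-at-random, as in label-free MS data).
#'
#' @param config a [SimConfig-class], see [simConfig()].
#' @return a [SummarizedExperiment::SummarizedExperiment] with assay
#'   `intensity` (zeros are missing), `colData` columns `population`,
#'   `biorep`, `techrep`, and ground truth in `rowData` (`isPeriodic`,
#'   `templateId`, `amplitude`, `phase`, `peakPopulation`, `baseline`).
#' @examples
#' se <- simulateCellCycleDataset(simConfig(nProteins = 200, seed = 7))
#' table(SummarizedExperiment::rowData(se)$isPeriodic)
#' @export
simulateCellCycleDataset <- function(config = simConfig()) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  withLocalSeed(config@seed, {
    nP <- config@nProteins
    nPop <- config@nPopulations
    nSamp <- nPop * config@nBiorep * config@nTechrep
    design <- expand.grid(population = seq_len(nPop),
                          biorep = seq_len(config@nBiorep),
                          techrep = seq_len(config@nTechrep))
    sampleNames <- sprintf("P%d_B%d_T%d", design$population, design$biorep,
                           design$techrep)

    baseline <- rlnorm(nP, meanlog = log(1e4), sdlog = 1.5)
    nPer <- round(config@fracPeriodic * nP)
    isPeriodic <- logical(nP)
    isPeriodic[sample.int(nP, nPer)] <- TRUE
    tmpl <- profileTemplates(nPop)
    templateId <- rep(NA_integer_, nP)
    templateId[isPeriodic] <- sample.int(nrow(tmpl), nPer, replace = TRUE)
    amplitude <- rep(NA_real_, nP)
    amplitude[isPeriodic] <- runif(nPer, config@amplitudeRange[1],
                                   config@amplitudeRange[2])
    peakPop <- attr(tmpl, "peak")[templateId]

    ## expected intensity: baseline * amplitude^template(population)
    shape <- matrix(0, nP, nPop)
    if (nPer > 0)
      shape[isPeriodic, ] <- tmpl[templateId[isPeriodic], , drop = FALSE]
    logA <- ifelse(isPeriodic, log(amplitude), 0)
    mu <- baseline * exp(logA * shape)            # nP x nPop
    expected <- mu[, design$population, drop = FALSE]

    sdlog <- sqrt(log(1 + config@noiseCV^2))
    noise <- matrix(rlnorm(nP * nSamp, -sdlog^2 / 2, sdlog), nP, nSamp)
    depthSd <- sqrt(log(1 + config@depthCV^2))
    depth <- rlnorm(nSamp, -depthSd^2 / 2, depthSd)
    x <- expected * noise
    x <- sweep(x, 2, depth, `*`)

    ## MNAR censoring: logistic in log intensity, midpoint at the configured
    ## abundance quantile of the observed values; a zero midpoint disables
    ## censoring entirely
    if (config@missingMidpoint > 0) {
      x50 <- quantile(x, config@missingMidpoint, names = FALSE)
      pMiss <- plogis(-(log(x) - log(x50)) * config@missingSlope)
      x[matrix(runif(nP * nSamp), nP, nSamp) < pMiss] <- 0
    }

    dimnames(x) <- list(sprintf("prot_%05d", seq_len(nP)), sampleNames)
    cd <- S4Vectors::DataFrame(
      population = factor(sprintf("P%d", design$population),
                          levels = sprintf("P%d", seq_len(nPop))),
      biorep = as.integer(design$biorep),
      techrep = as.integer(design$techrep),
      row.names = sampleNames)
    rd <- S4Vectors::DataFrame(
      isPeriodic = isPeriodic, templateId = templateId,
      amplitude = amplitude, phase = (peakPop - 1) / nPop,
      peakPopulation = peakPop, baseline = baseline,
      row.names = rownames(x))
    se <- SummarizedExperiment::SummarizedExperiment(
      assays = list(intensity = x), colData = cd, rowData = rd)
    S4Vectors::metadata(se)$simConfig <- config
    se
  })
}

#' Simulate target and decoy MS1 feature-match tables
#'
#' Emulates the empirical target/decoy design for estimating the
#' match-between-runs FDR: a target run in which a controllable fraction of
#' features receive a match (a mixture of true matches, with Gaussian errors
#' in retention time, m/z and mass accuracy, and false matches with errors
#' uniform over a wide window), and a chemically-modified decoy run whose
#' matches are false by construction.
#'
#' @param nTarget,nDecoy feature counts in the target and decoy runs.
#' @param trueFraction fraction of target matches that are true.
#' @param matchedFractionTarget fraction of target features matched.
#' @param matchedFractionDecoy fraction of decoy features matched; the
#'   default gives the decoy the same false-match propensity as the target,
#'   `(1 - trueFraction) * matchedFractionTarget`.
#' @param rtSigma,mzSigma,ppmSigma Gaussian error sigmas of true matches
#'   (minutes, Da, ppm).
#' @param falseWindow named half-widths (`d_rt`, `d_mz`, `ppm_err`) of the
#'   uniform error distribution of false matches.
#' @param seed integer seed.
#' @return list with `target` and `decoy` match data frames (columns
#'   `feature_id`, `matched`, `d_rt`, `d_mz`, `ppm_err`, `is_decoy`; error
#'   columns are `NA` for unmatched features) and `truth`, the per-feature
#'   `isFalseMatch` labels of the target run.
#' @examples
#' sim <- simulateMatchTables(5000, 5000, trueFraction = 0.9, seed = 3)
#' mean(sim$target$matched)
#' @export
simulateMatchTables <- function(nTarget, nDecoy, trueFraction,
                                matchedFractionTarget = 0.32,
                                matchedFractionDecoy = NULL,
                                rtSigma = 0.05, mzSigma = 0.0015,
                                ppmSigma = 2,
                                falseWindow = c(d_rt = 1, d_mz = 0.01,
                                                ppm_err = 10),
                                seed = 1L) {
  stopifnot(trueFraction >= 0, trueFraction <= 1,
            matchedFractionTarget >= 0, matchedFractionTarget <= 1)
  if (any(c(rtSigma, mzSigma, ppmSigma) <= 0))
    stop("error sigmas must be positive")
  if (is.null(matchedFractionDecoy))
    matchedFractionDecoy <- (1 - trueFraction) * matchedFractionTarget
  withLocalSeed(seed, {
    drawRun <- function(n, matchedFrac, trueFrac, isDecoy, prefix) {
      matched <- runif(n) < matchedFrac
      isTrue <- matched & (runif(n) < trueFrac)
      isFalse <- matched & !isTrue
      d <- data.frame(
        feature_id = sprintf("%s_%06d", prefix, seq_len(n)),
        matched = matched,
        d_rt = NA_real_, d_mz = NA_real_, ppm_err = NA_real_,
        is_decoy = isDecoy)
      nT <- sum(isTrue); nF <- sum(isFalse)
      d$d_rt[isTrue] <- rnorm(nT, 0, rtSigma)
      d$d_mz[isTrue] <- rnorm(nT, 0, mzSigma)
      d$ppm_err[isTrue] <- rnorm(nT, 0, ppmSigma)
      d$d_rt[isFalse] <- runif(nF, -falseWindow[["d_rt"]],
                               falseWindow[["d_rt"]])
      d$d_mz[isFalse] <- runif(nF, -falseWindow[["d_mz"]],
                               falseWindow[["d_mz"]])
      d$ppm_err[isFalse] <- runif(nF, -falseWindow[["ppm_err"]],
                                  falseWindow[["ppm_err"]])
      list(table = d, isFalse = isFalse)
    }
    target <- drawRun(nTarget, matchedFractionTarget, trueFraction, FALSE,
                      "feat")
    decoy <- drawRun(nDecoy, matchedFractionDecoy, 0, TRUE, "decoy")
    list(target = target$table, decoy = decoy$table,
         truth = data.frame(feature_id = target$table$feature_id,
                            matched = target$table$matched,
                            isFalseMatch = target$isFalse))
  })
}

## Expand a motif pattern (literals, '.', and [..] classes over the 20 amino
## acids) into a list of allowed residues per position.
parseMotifPattern <- function(pattern) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  out <- list()
  i <- 1L
  chars <- strsplit(pattern, "")[[1]]
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == ".") {
      out[[length(out) + 1L]] <- aa
      i <- i + 1L
    } else if (ch == "[") {
      j <- i + 1L
      while (j <= length(chars) && chars[j] != "]") j <- j + 1L
      if (j > length(chars)) stop("unterminated character class in: ", pattern)
      out[[length(out) + 1L]] <- chars[(i + 1L):(j - 1L)]
      i <- j + 1L
    } else {
      if (!ch %in% aa) stop("non-amino-acid literal '", ch, "' in: ", pattern)
      out[[length(out) + 1L]] <- ch
      i <- i + 1L
    }
  }
  out
}

sampleMotifInstance <- function(parsed) {
  paste(vapply(parsed, function(ch) ch[sample.int(length(ch), 1L)],
               character(1)), collapse = "")
}

#' Simulate a proteome FASTA with motifs planted at known frequencies
#'
#' Background sequences are uniform over the 20 amino acids; each sequence
#' independently receives each motif with its stated probability, planted at
#' a random position. Background draws that contain a chance occurrence of
#' any planted motif are re-rolled, so the planted frequency is the true
#' occurrence frequency.
#'
#' @param nSeqs number of sequences.
#' @param motifFreqs named numeric vector, motif name -> planting
#'   probability; names must be motifs known to [motifDefs()] or the
#'   patterns themselves.
#' @param lengthRange integer range of sequence lengths (residues).
#' @param seed integer seed.
#' @return a [Biostrings::AAStringSet]; `mcols()` holds one logical column
#'   `planted_<motif>` per motif.
#' @examples
#' aa <- simulateProteomeFasta(50, c(KEN = 0.2), seed = 2)
#' sum(S4Vectors::mcols(aa)$planted_KEN)
#' @export
simulateProteomeFasta <- function(nSeqs, motifFreqs = c(KEN = 0.08),
                                  lengthRange = c(100L, 400L), seed = 1L) {
  stopifnot(all(motifFreqs >= 0), all(motifFreqs <= 1))
  defs <- motifDefs()
  patterns <- vapply(names(motifFreqs), function(nm) {
    if (nm %in% names(defs)) defs[[nm]] else nm
  }, character(1))
  parsed <- lapply(patterns, parseMotifPattern)
  if (length(parsed) &&
      max(vapply(parsed, length, integer(1))) > min(lengthRange))
    stop("motif longer than the minimum sequence length")
  regexes <- vapply(patterns, motifRegex, character(1))
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  withLocalSeed(seed, {
    lens <- if (lengthRange[1] == lengthRange[2]) rep(lengthRange[1], nSeqs)
            else sample(seq(lengthRange[1], lengthRange[2]), nSeqs,
                        replace = TRUE)
    planted <- matrix(FALSE, nSeqs, length(motifFreqs),
                      dimnames = list(NULL, names(motifFreqs)))
    seqs <- character(nSeqs)
    for (i in seq_len(nSeqs)) {
      for (attempt in seq_len(1000L)) {
        s <- paste(sample(aa, lens[i], replace = TRUE), collapse = "")
        if (!length(regexes) ||
            !any(vapply(regexes, function(r) grepl(r, s), logical(1))))
          break
      }
      for (m in seq_along(motifFreqs)) {
        if (runif(1) < motifFreqs[m]) {
          inst <- sampleMotifInstance(parsed[[m]])
          start <- sample.int(lens[i] - nchar(inst) + 1L, 1L)
          substr(s, start, start + nchar(inst) - 1L) <- inst
          planted[i, m] <- TRUE
        }
      }
      seqs[i] <- s
    }
    out <- Biostrings::AAStringSet(setNames(seqs, sprintf("seq_%05d",
                                                          seq_len(nSeqs))))
    mc <- S4Vectors::DataFrame(planted)
    if (ncol(mc)) colnames(mc) <- paste0("planted_", colnames(planted))
    S4Vectors::mcols(out) <- mc
    out
  })
}
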