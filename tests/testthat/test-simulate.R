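test_that("the dataset generator is deterministic under a fixed seed", {
  cfg <- simConfig(nProteins = 300, seed = 1L)
  a <- simulateCellCycleDataset(cfg)
  b <- simulateCellCycleDataset(cfg)
  expect_identical(SummarizedExperiment::assay(a, "intensity"),
                   SummarizedExperiment::assay(b, "intensity"))
  c <- simulateCellCycleDataset(simConfig(nProteins = 300, seed = 2L))
  expect_false(identical(SummarizedExperiment::assay(a, "intensity"),
                         SummarizedExperiment::assay(c, "intensity")))
})

test_that("the design and ground-truth labels follow the configuration", {
  cfg <- simConfig(nProteins = 1000, fracPeriodic = 0.1, seed = 3L)
  se <- simulateCellCycleDataset(cfg)
  expect_equal(dim(se), c(1000L, 16L * 4L * 2L))
  cd <- SummarizedExperiment::colData(se)
  expect_equal(nrow(unique(as.data.frame(cd))), 128L)
  rd <- SummarizedExperiment::rowData(se)
  expect_equal(sum(rd$isPeriodic), 100L)  # round(frac * n)
  expect_true(all(rd$templateId[rd$isPeriodic] %in% 1:5))
  expect_true(all(is.na(rd$templateId[!rd$isPeriodic])))
  expect_true(all(rd$amplitude[rd$isPeriodic] >= 1.5 &
                  rd$amplitude[rd$isPeriodic] <= 4))
})

test_that("periodic templates are one pure cycle and flat proteins are flat", {
  tmpl <- profileTemplates()
  expect_equal(dim(tmpl), c(5L, 16L))
  ## in log-abundance each template is a single tone at 1 cycle / 16 pops
  for (r in seq_len(5)) {
    I <- bruteForcePeriodogram(tmpl[r, ])
    expect_equal(which.max(I), 1L)
    expect_lt(sum(I[-1]) / sum(I), 1e-20)
  }
  ## a noise-free simulation: non-periodic proteins constant across samples
  cfg <- simConfig(nProteins = 50, fracPeriodic = 0.2, noiseCV = 1e-12,
                   depthCV = 1e-12, missingMidpoint = 0, seed = 4L)
  se <- simulateCellCycleDataset(cfg)
  x <- SummarizedExperiment::assay(se)
  rd <- SummarizedExperiment::rowData(se)
  flat <- x[!rd$isPeriodic, , drop = FALSE]
  expect_lt(max(apply(flat, 1, function(r) diff(range(r)) / mean(r))), 1e-6)
})

test_that("sample depths vary and missingness decreases with abundance", {
  se <- simulateCellCycleDataset(simConfig(nProteins = 3000, seed = 5L))
  x <- SummarizedExperiment::assay(se)
  tot <- colSums(x)
  expect_gt(stats::sd(tot) / mean(tot), 0.05)
  ## logistic fit of missingness on log baseline must slope downward
  rd <- SummarizedExperiment::rowData(se)
  missFrac <- rowMeans(x == 0)
  fit <- stats::glm(missFrac ~ log(rd$baseline), family = stats::quasibinomial())
  expect_lt(stats::coef(fit)[2], 0)
  ## and be monotone across abundance bins
  bins <- cut(log(rd$baseline), stats::quantile(log(rd$baseline), 0:5 / 5),
              include.lowest = TRUE)
  byBin <- tapply(missFrac, bins, mean)
  expect_true(all(diff(byBin) <= 0.005))
})

test_that("match-table generator honours fractions, sigmas and seeds", {
  sim <- simulateMatchTables(40000, 40000, trueFraction = 0.9,
                             matchedFractionTarget = 0.3, seed = 6L)
  expect_equal(mean(sim$target$matched), 0.3, tolerance = 0.02)
  ## decoy defaults to the target's false-match propensity
  expect_equal(mean(sim$decoy$matched), 0.1 * 0.3, tolerance = 0.15)
  expect_true(all(sim$decoy$is_decoy))
  expect_true(all(is.na(sim$target$d_rt[!sim$target$matched])))
  expect_true(all(!is.na(sim$target$d_rt[sim$target$matched])))
  trueM <- sim$target$matched & !sim$truth$isFalseMatch
  expect_equal(stats::sd(sim$target$d_rt[trueM]), 0.05, tolerance = 0.02)
  sim2 <- simulateMatchTables(40000, 40000, trueFraction = 0.9,
                              matchedFractionTarget = 0.3, seed = 6L)
  expect_identical(sim$target, sim2$target)
  sim3 <- simulateMatchTables(40000, 40000, trueFraction = 0.9,
                              matchedFractionTarget = 0.3, seed = 7L)
  expect_false(identical(sim$target, sim3$target))
  expect_error(simulateMatchTables(100, 100, 0.5, rtSigma = 0),
               "sigmas")
})

test_that("FASTA generator plants motifs at the stated frequency", {
  aa <- simulateProteomeFasta(2000, c(KEN = 0.08), lengthRange = c(80, 200),
                              seed = 8L)
  planted <- S4Vectors::mcols(aa)$planted_KEN
  expect_equal(mean(planted), 0.08, tolerance = 0.02)
  scan <- scanMotifs(aa, motifDefs()["KEN"])
  ## collisions are re-rolled, so scan hits == planted labels exactly
  expect_equal(unname(scan$hits[, "KEN"]), planted)
  ## no motifs requested -> mcols empty, scanner finds only chance matches
  bg <- simulateProteomeFasta(200, c(), lengthRange = c(50, 100), seed = 9L)
  expect_equal(ncol(S4Vectors::mcols(bg)), 0L)
  ## minimal-length sequences still carry the motif
  tiny <- simulateProteomeFasta(50, c(KEN = 1), lengthRange = c(3, 3),
                                seed = 10L)
  expect_true(all(as.character(tiny) == "KEN"))
  expect_error(simulateProteomeFasta(10, c(KEN = 1), lengthRange = c(2, 2)),
               "longer than")
})
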