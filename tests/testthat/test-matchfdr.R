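mkMatchTable <- function(matched, d_rt = NULL, d_mz = NULL, ppm_err = NULL,
                         isDecoy = FALSE) {
  n <- length(matched)
  fill <- function(v) {
    out <- rep(NA_real_, n)
    if (!is.null(v)) out[matched] <- v
    out
  }
  data.frame(feature_id = sprintf("f%05d", seq_len(n)), matched = matched,
             d_rt = fill(d_rt), d_mz = fill(d_mz), ppm_err = fill(ppm_err),
             is_decoy = isDecoy)
}

test_that("the FDR estimate is the decoy/target matched-fraction ratio", {
  target <- mkMatchTable(rep(c(TRUE, FALSE), c(32, 68)),
                         d_rt = rnorm(32, 0, 0.05),
                         d_mz = rnorm(32, 0, 0.001),
                         ppm_err = rnorm(32, 0, 2))
  decoy <- mkMatchTable(rep(c(TRUE, FALSE), c(2, 98)), d_rt = rnorm(2),
                        d_mz = rnorm(2), ppm_err = rnorm(2), isDecoy = TRUE)
  rep1 <- estimateFdr(target, decoy)
  expect_equal(fdrEstimate(rep1), 0.02 / 0.32)  # 0.0625 by hand
  ## empty decoy matches -> FDR 0
  decoy0 <- mkMatchTable(rep(FALSE, 100), isDecoy = TRUE)
  expect_equal(fdrEstimate(estimateFdr(target, decoy0)), 0)
  ## several decoys: mean of per-decoy ratios
  decoy2 <- mkMatchTable(rep(c(TRUE, FALSE), c(4, 96)), d_rt = rnorm(4),
                         d_mz = rnorm(4), ppm_err = rnorm(4), isDecoy = TRUE)
  expect_equal(fdrEstimate(estimateFdr(target, list(decoy, decoy2))),
               mean(c(0.02, 0.04)) / 0.32)
  ## no target matches -> undefined
  none <- mkMatchTable(rep(FALSE, 10))
  expect_error(estimateFdr(none, decoy), "undefined")
})

test_that("FDR recovery is unbiased across planted false-match rates", {
  for (f in c(0.03, 0.10)) {
    sim <- simulateMatchTables(30000, 30000, trueFraction = 1 - f,
                               seed = 51L + round(100 * f))
    est <- fdrEstimate(estimateFdr(sim$target, sim$decoy))
    expect_lt(abs(est - f), 0.02)
  }
})

test_that("MAD sigmas are consistent and resist contamination", {
  set.seed(52)
  target <- mkMatchTable(rep(TRUE, 20000),
                         d_rt = rnorm(20000, 0.01, 0.05),
                         d_mz = rnorm(20000, 0, 0.0015),
                         ppm_err = rnorm(20000, 0, 2))
  th <- fitMatchSigmas(target)
  expect_lt(abs(th@sigma[["d_rt"]] - 0.05) / 0.05, 0.05)
  expect_lt(abs(th@center[["d_rt"]] - 0.01), 0.002)
  expect_equal(unname(th@nSigma), c(2.5, 3, 3))
  ## uniform contamination at the false-match rate the filter targets
  ## moves sigma by < 10%
  contam <- runif(1500, -1, 1)
  target2 <- mkMatchTable(rep(TRUE, 21500),
                          d_rt = c(rnorm(20000, 0, 0.05), contam),
                          d_mz = rnorm(21500, 0, 0.0015),
                          ppm_err = rnorm(21500, 0, 2))
  th2 <- fitMatchSigmas(target2)
  expect_lt(abs(th2@sigma[["d_rt"]] - 0.05) / 0.05, 0.1)
  ## degenerate dimension errors
  bad <- mkMatchTable(rep(TRUE, 200), d_rt = rep(0.1, 200),
                      d_mz = rnorm(200), ppm_err = rnorm(200))
  expect_error(fitMatchSigmas(bad), "degenerate")
  expect_error(fitMatchSigmas(target[1:50, ]), "at least 100")
})

test_that("filtering keeps the boundary and hits the Gaussian retention", {
  ## a match exactly on the threshold is retained
  th <- new("MatchFilter", center = c(d_rt = 0, d_mz = 0, ppm_err = 0),
            sigma = c(d_rt = 0.1, d_mz = 0.001, ppm_err = 1),
            nSigma = c(d_rt = 2.5, d_mz = 3, ppm_err = 3))
  edge <- mkMatchTable(c(TRUE, TRUE), d_rt = c(0.25, 0.2500001),
                       d_mz = c(0, 0), ppm_err = c(0, 0))
  fm <- filterMatches(edge, th)
  expect_equal(fm$keep, c(TRUE, FALSE))
  expect_equal(fm$retention, 0.5)
  ## single 2.5-sigma cut on one Gaussian dimension: 2*Phi(2.5) - 1
  set.seed(53)
  n <- 200000
  one <- mkMatchTable(rep(TRUE, n), d_rt = rnorm(n, 0, 0.1),
                      d_mz = rep(c(-1e-7, 1e-7), n / 2),
                      ppm_err = rep(c(-1e-6, 1e-6), n / 2))
  fm1 <- filterMatches(one, th)
  expect_equal(fm1$retention, 2 * stats::pnorm(2.5) - 1, tolerance = 0.003)
  ## all three independent Gaussian dimensions: product of tail masses
  three <- mkMatchTable(rep(TRUE, n), d_rt = rnorm(n, 0, 0.1),
                        d_mz = rnorm(n, 0, 0.001),
                        ppm_err = rnorm(n, 0, 1))
  fm3 <- filterMatches(three, th)
  expect_equal(fm3$retention,
               (2 * stats::pnorm(2.5) - 1) * (2 * stats::pnorm(3) - 1)^2,
               tolerance = 0.003)
})

test_that("filtering lowers the estimated FDR when false matches are broad", {
  sim <- simulateMatchTables(40000, 40000, trueFraction = 0.9, seed = 54L)
  th <- fitMatchSigmas(sim$target)
  pre <- estimateFdr(sim$target, sim$decoy)
  post <- estimateFdr(sim$target, sim$decoy, filter = th)
  expect_false(is.na(post@postFilterFdr))
  expect_lt(post@postFilterFdr, fdrEstimate(pre))
  ## true matches survive almost entirely; overall retention also loses the
  ## (wide-window) false matches the filter is designed to remove
  fm <- filterMatches(sim$target, th)
  trueM <- sim$target$matched & !sim$truth$isFalseMatch
  expect_gte(sum(fm$keep & trueM) / sum(trueM), 0.97)
  expect_gt(post@retention, 0.85)
  expect_true(all(is.na(fm$table$d_rt[!fm$table$matched])))
  expect_equal(sum(fm$table$matched), sum(fm$keep))
})
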