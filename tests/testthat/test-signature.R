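test_that("the signature model satisfies its structural invariants", {
  model <- smallSignature()
  expect_true(validObject(model))
  expect_equal(sort(unique(unname(popToCcs(model)))), 1:8)
  expect_length(popToCcs(model), 16L)
  ## per-protein scaling of the sample matrix
  sm <- model@sampleMatrix
  expect_lt(max(abs(colMeans(sm))), 1e-9)
  ## CCS profiles are means of member population profiles (validity already
  ## checks this; spot-check one state)
  s <- popToCcs(model)[["P1"]]
  members <- names(popToCcs(model))[popToCcs(model) == s]
  expect_equal(unname(ccsProfiles(model)[s, ]),
               unname(colMeans(popMeans(model)[members, , drop = FALSE])))
})

test_that("PCA separates variance correctly and matches an eigen oracle", {
  set.seed(41)
  ## rank-1 matrix: first component carries all variance
  u <- rnorm(30); v <- rnorm(10)
  r1 <- outer(u, v)
  rownames(r1) <- sprintf("P%d_B1_T1", rep(1:15, each = 2))
  p1 <- suppressWarnings(pcaWheel(r1))
  expect_equal(p1$varExplained[1], 100, tolerance = 1e-8)
  ## variance percentages always sum to 100
  x <- matrix(rnorm(200), 20, 10,
              dimnames = list(sprintf("P%d_B1_T1", 1:20), NULL))
  px <- pcaWheel(x)
  expect_equal(sum(px$varExplained), 100)
  ## scores match a covariance eigendecomposition up to sign
  xc <- sweep(x, 2, colMeans(x))
  ev <- eigen(stats::cov(xc))
  oracle <- xc %*% ev$vectors
  for (j in 1:3) {
    agree <- max(abs(px$scores[, j] - oracle[, j]),
                 abs(px$scores[, j] + oracle[, j]))
    mismatch <- min(max(abs(px$scores[, j] - oracle[, j])),
                    max(abs(px$scores[, j] + oracle[, j])))
    expect_lt(mismatch, 1e-8)
    expect_gt(agree, 0)  # nondegenerate
  }
  ## constant features are dropped with a warning
  xconst <- cbind(x, 5)
  expect_warning(pcaWheel(xconst), "constant")
})

test_that("PC1 sign convention puts interphase samples positive", {
  model <- smallSignature()
  pca <- pcaWheel(model@sampleMatrix)
  pops <- as.integer(sub("^P(\\d+)_.*$", "\\1",
                         rownames(model@sampleMatrix)))
  expect_gt(mean(pca$scores[pops <= 8, 1]), 0)
})

test_that("the PC1/PC2 wheel recovers the cyclic population order", {
  model <- smallSignature()
  pca <- pcaWheel(model@sampleMatrix)
  pops <- as.integer(sub("^P(\\d+)_.*$", "\\1",
                         rownames(model@sampleMatrix)))
  popScores <- vapply(1:16, function(p) {
    colMeans(pca$scores[pops == p, 1:2, drop = FALSE])
  }, numeric(2))
  ang <- atan2(popScores[2, ], popScores[1, ])
  expect_gte(circularRankCor(ang), 0.9)
})

test_that("k-NN votes deterministically and agrees with class::knn", {
  ## duplicated training point: unanimous vote
  train <- matrix(rep(c(0, 10), each = 6), 12, 1)
  labels <- factor(rep(c("P1", "P2"), each = 6))
  test <- matrix(c(0, 10), 2, 1)
  expect_equal(as.character(knnClassify(train, labels, test, k = 6)),
               c("P1", "P2"))
  ## k = 1 is nearest neighbor
  expect_equal(as.character(knnClassify(train, labels, test, k = 1)),
               c("P1", "P2"))
  ## vote tie: label with the smaller mean neighbor distance wins
  train2 <- matrix(c(1, 2, -1.5, -2.5), 4, 1)
  labels2 <- factor(c("P1", "P1", "P2", "P2"))
  expect_equal(as.character(knnClassify(train2, labels2,
                                        matrix(0, 1, 1), k = 4)), "P1")
  expect_error(knnClassify(train, labels, matrix(0, 1, 2)), "features")
  ## cross-check against the reference implementation on tie-free data
  skip_if_not_installed("class")
  set.seed(42)
  tr <- matrix(rnorm(600), 100, 6)
  lb <- factor(sample(sprintf("P%d", 1:4), 100, replace = TRUE))
  te <- matrix(rnorm(120), 20, 6)
  ours <- knnClassify(tr, lb, te, k = 1)
  ref <- class::knn(tr, te, lb, k = 1)
  expect_equal(as.character(ours), as.character(ref))
})

test_that("leave-one-biorep-out k-NN beats chance comfortably", {
  model <- smallSignature()
  se <- smallDataset()
  cd <- SummarizedExperiment::colData(se)
  isTest <- cd$biorep == 4
  pred <- knnClassify(model@sampleMatrix[!isTest, , drop = FALSE],
                      cd$population[!isTest],
                      model@sampleMatrix[isTest, , drop = FALSE], k = 6)
  expect_gte(mean(pred == cd$population[isTest]), 0.5)
})

test_that("k-means aggregation pairs well-separated populations", {
  set.seed(43)
  centers <- matrix(rnorm(8 * 20, sd = 4), 8, 20)
  pm <- centers[rep(1:8, each = 2), ] + matrix(rnorm(16 * 20, sd = 0.05),
                                               16, 20)
  rownames(pm) <- sprintf("P%d", 1:16)
  agg <- aggregateCcs(pm, nCcs = 8, seed = 5)
  expect_equal(sort(unique(unname(agg$popToCcs))), 1:8)
  ## each CCS is exactly one adjacent pair, labeled in temporal order
  expect_equal(unname(agg$popToCcs), rep(1:8, each = 2))
  expect_true(agg$contiguous)
  ## determinism under the seed
  agg2 <- aggregateCcs(pm, nCcs = 8, seed = 5)
  expect_identical(agg$popToCcs, agg2$popToCcs)
})

test_that("Spearman assignment is exact on profiles and guards overlap", {
  model <- smallSignature()
  prof <- ccsProfiles(model)
  sub <- sample(colnames(prof), 60)
  q <- stats::setNames(prof[3, sub], sub)
  a <- spearmanAssign(q, model)
  expect_equal(a$rho_CCS3, 1)
  expect_equal(a$best_ccs, "CCS3")
  expect_equal(a$n_overlap, 60L)
  ## negated profile anti-correlates perfectly
  an <- spearmanAssign(-q, model)
  expect_equal(an$rho_CCS3, -1)
  ## monotone transforms leave every rho unchanged
  at <- spearmanAssign(exp(2 * q) + 5, model)
  expect_equal(unlist(at[1, 1:8]), unlist(a[1, 1:8]))
  ## too few proteins -> unassigned with a reason
  small <- spearmanAssign(q[1:10], model)
  expect_true(is.na(small$best_ccs))
  expect_match(small$reason, "overlap")
})

test_that("batch assignment controls significance across experiments", {
  model <- smallSignature()
  prof <- ccsProfiles(model)
  set.seed(44)
  queries <- c(
    lapply(1:4, function(s) prof[s, ] + rnorm(ncol(prof), 0, 0.3)),
    lapply(1:4, function(i) stats::setNames(rnorm(ncol(prof)),
                                            colnames(prof))))
  names(queries) <- c(sprintf("signal%d", 1:4), sprintf("noise%d", 1:4))
  res <- spearmanAssignBatch(queries, model)
  expect_equal(nrow(res), 8L)
  expect_true(all(res$assigned[1:4]))
  expect_equal(res$best_ccs[1:4], sprintf("CCS%d", 1:4))
  expect_true(all(res$padj >= res$p, na.rm = TRUE))
})

test_that("query normalization centers log-ratios and drops bad ratios", {
  v <- stats::setNames(c(2, 2, 2), c("a", "b", "c"))
  ref <- stats::setNames(c(2, 2, 2), c("a", "b", "c"))
  expect_equal(unname(normalizeQuery(v, "lfq_vs_reference", ref)),
               c(0, 0, 0))
  v2 <- stats::setNames(c(4, 1, -3), c("a", "b", "c"))
  ref2 <- stats::setNames(c(1, 1, 1), c("a", "b", "c"))
  out <- normalizeQuery(v2, "lfq_vs_reference", ref2)
  expect_true(is.na(out[["c"]]))
  expect_equal(out[["a"]] - out[["b"]], 2)  # log2(4) - log2(1)
  sil <- normalizeQuery(stats::setNames(rnorm(11), letters[1:11]))
  expect_equal(stats::median(sil), 0)
  expect_error(normalizeQuery(v, "lfq_vs_reference"), "reference")
})

test_that("assignment is robust to removing a couple of signature proteins", {
  model <- smallSignature()
  se <- smallDataset()
  cd <- SummarizedExperiment::colData(se)
  isTest <- cd$biorep == 4
  full <- knnClassify(model@sampleMatrix[!isTest, , drop = FALSE],
                      cd$population[!isTest],
                      model@sampleMatrix[isTest, , drop = FALSE], k = 6)
  set.seed(45)
  stable <- vapply(1:20, function(i) {
    keep <- sample(ncol(model@sampleMatrix),
                   ncol(model@sampleMatrix) - 2)
    pred <- knnClassify(model@sampleMatrix[!isTest, keep, drop = FALSE],
                        cd$population[!isTest],
                        model@sampleMatrix[isTest, keep, drop = FALSE],
                        k = 6)
    mean(pred == full)
  }, numeric(1))
  expect_gte(mean(stable), 0.95)
})
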