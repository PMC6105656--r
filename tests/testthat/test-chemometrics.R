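# PCA ------------------------------------------------------------------

test_that("PCA matches the eigendecomposition oracle on a known cloud", {
  set.seed(13)
  n <- 400
  S <- matrix(c(4, 1.5, 1.5, 1), 2, 2)
  X <- matrix(rnorm(n * 2), n, 2) %*% chol(S)
  d <- SpectralDataset(t(X), c(600, 700))
  pc <- fitPCA(d, 2, recipe = preprocessRecipe())
  ev <- eigen(stats::cov(X))
  for (i in 1:2) {
    v <- ev$vectors[, i]
    v <- v * sign(v[which.max(abs(v))])
    expect_all_equal(pc@loadings[i, ], v, 1e-8)
  }
  expect_equal(pc@explainedVariance,
               ev$values / sum(ev$values), tolerance = 1e-8)
  # scores are centred and loadings orthonormal
  expect_lt(max(abs(colMeans(pc@scores))), 1e-10)
  expect_all_equal(pc@loadings %*% t(pc@loadings), diag(2), 1e-8)
})

test_that("PCA flags rank-1 structure and argument errors", {
  w <- shortAxis(10)
  base <- rexp(length(w))
  y <- vapply(c(1, 2, 5, 9), function(s) s * base, numeric(length(w)))
  pc <- fitPCA(SpectralDataset(y, w), 2, recipe = preprocessRecipe())
  expect_equal(pc@explainedVariance[1L], 1, tolerance = 1e-12)
  expect_error(fitPCA(SpectralDataset(y, w), 5), "nComponents")
  # explained fractions are non-increasing for a generic dataset
  d <- separableDataset(8, noiseSD = 1)
  pc3 <- fitPCA(d, 3)
  expect_true(all(diff(pc3@explainedVariance) <= 0))
})

# calibration/validation split -----------------------------------------

test_that("every-fourth split removes rows 4, 8, ... into validation", {
  d <- separableDataset(4)                       # 8 spectra
  sp <- splitEveryFourth(d)
  nm <- colnames(intensities(d))
  expect_equal(colnames(intensities(sp$validation)), nm[c(4, 8)])
  expect_equal(ncol(sp$calibration), 6L)
  expect_setequal(c(colnames(intensities(sp$calibration)),
                    colnames(intensities(sp$validation))), nm)
  expect_error(splitEveryFourth(d[, 1:3]), "at least 4")
  d100 <- separableDataset(50)
  sp100 <- splitEveryFourth(d100)
  expect_equal(ncol(sp100$validation), 25L)
})

# PLS-DA ----------------------------------------------------------------

test_that("a separable two-class problem is perfect with one LV", {
  d <- separableDataset(10, delta = 50)
  m <- fitPLSDA(d, 1, recipe = preprocessRecipe())
  pr <- predict(m, d)
  expect_equal(pr$class, classLabels(d))
  rep <- classificationReport(m, d, d, "spectrum")
  expect_true(all(rep@perClass$sensitivity == 1))
  expect_true(all(rep@perClass$specificity == 1))
  expect_true(all(rep@perClass$auc == 1))
  expect_error(fitPLSDA(d[, 1:10], 1), "two classes")
})

test_that("full-rank PLS predictions equal the least-squares oracle", {
  set.seed(17)
  n <- 30; p <- 6
  w <- seq(600, 700, length.out = p)
  X <- matrix(rnorm(n * p), n, p)
  labels <- rep(c("a", "b", "c"), each = 10)
  d <- SpectralDataset(t(X), w,
                       data.frame(cell_line = labels,
                                  cell_id = paste0("c", 1:n),
                                  point_index = 0L, scan_index = 0L))
  m <- fitPLSDA(d, p, recipe = preprocessRecipe())     # nLV = rank(X)
  got <- predict(m, d)$scores
  # normal-equations oracle on centred data
  Y <- outer(labels, c("a", "b", "c"), `==`) + 0
  Xc <- scale(X, scale = FALSE); Yc <- scale(Y, scale = FALSE)
  oracle <- Xc %*% solve(crossprod(Xc), crossprod(Xc, Yc)) +
    rep(1, n) %*% t(colMeans(Y))
  expect_all_equal(got, oracle, 1e-8)
  expect_error(fitPLSDA(d, 25, recipe = preprocessRecipe()),
               "exceeds min")
})

test_that("duplicating every calibration row leaves coefficients alone", {
  d <- separableDataset(8, noiseSD = 2)
  m1 <- fitPLSDA(d, 3, recipe = preprocessRecipe())
  dd <- SpectralDataset(cbind(intensities(d), intensities(d)),
                        wavenumbers(d),
                        rbind(as.data.frame(colData(d)),
                              as.data.frame(colData(d))))
  m2 <- fitPLSDA(dd, 3, recipe = preprocessRecipe())
  expect_all_equal(m1@coefficients, m2@coefficients, 1e-8)
})

test_that("prediction ties resolve to the first class deterministically", {
  d <- separableDataset(6, delta = 0)   # identical classes -> flat model
  m <- fitPLSDA(d, 1, recipe = preprocessRecipe())
  pr <- predict(m, d[, 1:2])
  expect_true(all(pr$class == m@classOrder[1L]))
})

# venetian blinds --------------------------------------------------------

test_that("venetian CV is deterministic and zero for separable data", {
  d <- separableDataset(15, delta = 50)
  cv1 <- venetianCV(d, 3, 5, recipe = preprocessRecipe())
  cv2 <- venetianCV(d, 3, 5, recipe = preprocessRecipe())
  expect_identical(cv1, cv2)
  expect_true(all(cv1$cv_error == 0))
  expect_true(all(cv1$cal_error == 0))
})

test_that("venetian CV warns when a class is thinner than the blinds", {
  d <- separableDataset(6)
  expect_warning(venetianCV(d, 2, 10, recipe = preprocessRecipe()),
                 "fewer members than splits")
})

test_that("latent-variable selection follows the 5% target rule", {
  curve <- data.frame(n_lv = 1:3, cal_error = c(.30, .10, .04),
                      cv_error = c(.31, .12, .045))
  sel <- selectNLV(curve, 0.05)
  expect_equal(sel$nLV, 3L)
  expect_true(sel$metTarget)
  # no size meets the target: CV-minimising size with a flag
  curve2 <- data.frame(n_lv = 1:3, cal_error = c(.30, .10, .08),
                       cv_error = c(.31, .12, .15))
  sel2 <- selectNLV(curve2, 0.05)
  expect_equal(sel2$nLV, 2L)
  expect_false(sel2$metTarget)
})

# VIP --------------------------------------------------------------------

test_that("VIP scores satisfy their normalization identity", {
  d <- separableDataset(10, delta = 30, noiseSD = 1)
  for (nlv in 1:3) {
    v <- vipScores(fitPLSDA(d, nlv, recipe = preprocessRecipe()))
    expect_equal(mean(v@vip^2), 1, tolerance = 1e-8)
  }
})

test_that("VIP singles out the informative variable", {
  set.seed(23)
  n <- 60; p <- 11
  X <- matrix(rnorm(n * p), n, p)
  labels <- rep(c("a", "b"), each = n / 2)
  X[, 4] <- X[, 4] + (labels == "b") * 3       # one informative variable
  d <- SpectralDataset(t(X), seq(600, 700, length.out = p),
                       data.frame(cell_line = labels,
                                  cell_id = paste0("c", 1:n),
                                  point_index = 0L, scan_index = 0L))
  m <- fitPLSDA(d, 1, recipe = preprocessRecipe())
  v <- vipScores(m)
  expect_equal(which.max(v@vip), 4L)
  expect_gt(v@vip[4], 1)
  # direct-formula oracle on the fitted weights
  Wn <- m@weights[, 1] / sqrt(sum(m@weights[, 1]^2))
  oracle <- sqrt(p * (Wn^2 * m@ssY[1]) / m@ssY[1])
  expect_all_equal(v@vip, oracle, 1e-10)
  expect_equal(v@wavenumber[v@vip > 1], v@discriminatoryBands)
})

test_that("equally loaded variables all score VIP 1", {
  n <- 40; p <- 8
  labels <- rep(c("a", "b"), each = n / 2)
  base <- (labels == "b") * 2
  X <- vapply(seq_len(p), function(j) base, numeric(n))  # identical columns
  d <- SpectralDataset(t(X), seq(600, 700, length.out = p),
                       data.frame(cell_line = labels,
                                  cell_id = paste0("c", 1:n),
                                  point_index = 0L, scan_index = 0L))
  v <- vipScores(fitPLSDA(d, 1, recipe = preprocessRecipe()))
  expect_all_equal(v@vip, rep(1, p), 1e-6)
})

# ROC/AUC ----------------------------------------------------------------

test_that("AUC equals exhaustive pair counting with half ties", {
  expect_equal(rocAUC(c(TRUE, TRUE, FALSE), c(2, 3, 1)), 1)
  expect_equal(rocAUC(c(TRUE, FALSE, TRUE, FALSE), rep(1, 4)), 0.5)
  set.seed(31)
  truth <- c(rep(TRUE, 7), rep(FALSE, 9))
  scores <- sample(1:8, 16, replace = TRUE)    # ties guaranteed
  pairSum <- 0
  for (i in which(truth)) for (j in which(!truth))
    pairSum <- pairSum + (scores[i] > scores[j]) +
      0.5 * (scores[i] == scores[j])
  expect_equal(rocAUC(truth, scores), pairSum / (7 * 9))
  expect_error(rocAUC(rep(TRUE, 5), rnorm(5)), "both classes")
})

test_that("AUC agrees with an independent ROC implementation", {
  set.seed(37)
  truth <- rep(c(TRUE, FALSE), each = 50)
  scores <- rnorm(100) + truth
  expect_equal(rocAUC(truth, scores),
               as.numeric(pROC::auc(pROC::roc(truth, scores,
                                              quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-12)
})

# report arithmetic ------------------------------------------------------

test_that("report metrics follow their confusion-matrix definitions", {
  set.seed(41)
  d <- separableDataset(20, delta = 40, noiseSD = 8)
  sp <- splitEveryFourth(d)
  m <- fitPLSDA(sp$calibration, 2, recipe = preprocessRecipe())
  rep <- classificationReport(m, sp$calibration, sp$validation, "spectrum",
                              nSplits = 5)
  conf <- rep@confusion
  expect_equal(sum(conf), ncol(sp$validation))
  for (i in seq_len(2)) {
    expect_equal(rep@perClass$sensitivity[i],
                 conf[i, i] / sum(conf[i, ]))
    expect_equal(rep@perClass$specificity[i],
                 sum(conf[-i, -i]) / sum(conf[-i, ]))
  }
  expect_true(all(rep@perClass$rmsec >= 0 & rep@perClass$rmsep >= 0))
})

test_that("cell-level reports average the line-scan points first", {
  cfg <- smallSimConfig(seed = 19)
  sim <- simulateDataset(cfg)
  d <- applyRecipe(sim$dataset, recipeConditioning())
  sp <- splitEveryFourth(d)
  m <- fitPLSDA(sp$calibration, 4)
  rep <- classificationReport(m, sp$calibration, sp$validation, "cell",
                              nSplits = 5)
  # one prediction per cell in the validation set
  nCells <- length(unique(paste(classLabels(sp$validation),
                                colData(sp$validation)$cell_id)))
  expect_equal(sum(rep@confusion), nCells)
  expect_equal(rep@level, "cell")
})

test_that("label permutation drops accuracy to chance", {
  set.seed(43)
  cfg <- smallSimConfig(seed = 29)
  sim <- simulateDataset(cfg)
  d <- applyRecipe(sim$dataset, recipeConditioning())
  perm <- d
  SummarizedExperiment::colData(perm)$cell_line <-
    sample(classLabels(d))
  sp <- splitEveryFourth(perm)
  m <- fitPLSDA(sp$calibration, 4)
  acc <- mean(predict(m, sp$validation)$class ==
                classLabels(sp$validation))
  n <- ncol(sp$validation)
  expect_lt(abs(acc - 0.2), 3 * sqrt(0.2 * 0.8 / n) + 1e-9)
})
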