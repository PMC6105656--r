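# SIMPLS partial least squares discriminant analysis with
# venetian-blinds cross-validation, latent-variable selection, VIP
# scores, and per-class performance reporting.

# one indicator column per class, in classOrder
.indicatorMatrix <- function(labels, classOrder) {
  Y <- matrix(0, length(labels), length(classOrder),
              dimnames = list(NULL, classOrder))
  Y[cbind(seq_along(labels), match(labels, classOrder))] <- 1
  Y
}

# recipe applied inside the model: row-wise steps only; centring is the
# model's own xMean/yMean (the mean_center step)
.rowwiseRecipe <- function(recipe) {
  new("PreprocessRecipe",
      steps = Filter(function(st) st$name != "mean_center", recipe@steps))
}

# SIMPLS (de Jong 1993): deterministic PLS2 on centred X (n x p) and
# Y (n x q).  Scores are normalised to unit Euclidean norm.
.simpls <- function(Xc, Yc, A) {
  p <- ncol(Xc); q <- ncol(Yc)
  R <- matrix(0, p, A); P <- matrix(0, p, A)
  Q <- matrix(0, q, A); V <- matrix(0, p, A)
  TT <- matrix(0, nrow(Xc), A)
  S <- crossprod(Xc, Yc)
  s0 <- max(1, sqrt(sum(S^2)))
  for (a in seq_len(A)) {
    # once the covariance is exhausted (numerical rank reached) the
    # remaining components stay zero: a deterministic degenerate model
    if (sqrt(sum(S^2)) < 1e-12 * s0) break
    sv <- svd(S, nu = 1L, nv = 0L)
    r <- sv$u[, 1L]
    t <- drop(Xc %*% r)
    nt <- sqrt(sum(t^2))
    if (nt < 1e-12) break
    t <- t / nt; r <- r / nt
    pa <- drop(crossprod(Xc, t))
    qa <- drop(crossprod(Yc, t))
    # deterministic sign: largest-|element| X-loading positive
    sgn <- sign(pa[which.max(abs(pa))]); if (sgn == 0) sgn <- 1
    r <- r * sgn; t <- t * sgn; pa <- pa * sgn; qa <- qa * sgn
    v <- pa
    if (a > 1L) {                      # re-orthogonalise deflation basis
      Vp <- V[, seq_len(a - 1L), drop = FALSE]
      v <- v - Vp %*% crossprod(Vp, v)
      v <- v - Vp %*% crossprod(Vp, v)
    }
    v <- v / sqrt(sum(v^2))
    S <- S - v %*% crossprod(v, S)
    R[, a] <- r; TT[, a] <- t; P[, a] <- pa; Q[, a] <- qa; V[, a] <- v
  }
  list(R = R, TT = TT, P = P, Q = Q)
}

#' Fit a PLS-DA model (SIMPLS)
#'
#' Class labels are encoded as one indicator column per class and
#' regressed on the preprocessed, mean-centred spectra with the SIMPLS
#' algorithm.  Deterministic: identical input gives identical models,
#' with a fixed sign convention (largest-magnitude X-loading element
#' positive per latent variable).
#'
#' @param calibration a [SpectralDataset-class] with >= 2 classes.
#' @param nLV number of latent variables (>= 1, at most the rank of the
#'   preprocessed calibration matrix).
#' @param recipe preprocessing chain (default [recipePLSDA()]); any
#'   `mean_center` step is realised as the model's stored centring
#'   vectors so predictions centre new spectra identically.
#' @return A [PLSDAModel-class].
#' @export
fitPLSDA <- function(calibration, nLV = 6L, recipe = recipePLSDA()) {
  classOrder <- sort(unique(classLabels(calibration)))
  if (length(classOrder) < 2L)
    stop("PLS-DA needs at least two classes", call. = FALSE)
  if (nLV < 1L) stop("nLV must be >= 1", call. = FALSE)
  prep <- applyRecipe(calibration, .rowwiseRecipe(recipe))
  X <- t(intensities(prep))
  if (nLV > min(nrow(X) - 1L, ncol(X)))
    stop("nLV exceeds min(n_spectra - 1, n_wavenumbers) of the ",
         "calibration set", call. = FALSE)
  Y <- .indicatorMatrix(classLabels(calibration), classOrder)
  xMean <- colMeans(X); yMean <- colMeans(Y)
  fit <- .simpls(sweep(X, 2L, xMean), sweep(Y, 2L, yMean), as.integer(nLV))
  new("PLSDAModel", nLV = as.integer(nLV), weights = fit$R,
      xLoadings = fit$P, yLoadings = fit$Q,
      coefficients = fit$R %*% t(fit$Q), classOrder = classOrder,
      xMean = xMean, yMean = yMean, ssY = colSums(fit$Q^2),
      wavenumber = wavenumbers(prep), recipe = recipe)
}

setMethod("show", "PLSDAModel", function(object)
  cat(sprintf("PLSDAModel: %d latent variables, %d classes (%s), %d wavenumbers\n",
              object@nLV, length(object@classOrder),
              paste(object@classOrder, collapse = ", "),
              length(object@wavenumber))))

.predictScores <- function(model, d, nLV = model@nLV) {
  prep <- applyRecipe(d, .rowwiseRecipe(model@recipe))
  if (!isTRUE(all.equal(wavenumbers(prep), model@wavenumber)))
    stop("dataset axis does not match the model's calibration axis",
         call. = FALSE)
  Xc <- sweep(t(intensities(prep)), 2L, model@xMean)
  B <- model@weights[, seq_len(nLV), drop = FALSE] %*%
    t(model@yLoadings[, seq_len(nLV), drop = FALSE])
  sweep(Xc %*% B, 2L, model@yMean, `+`)
}

#' Predict class membership from a PLS-DA model
#'
#' Continuous indicator scores are the preprocessed, centred spectra
#' times the regression coefficients plus the intercepts; the assigned
#' class is the argmax score, with ties broken toward the first class in
#' `classOrder` (deterministic).
#'
#' @param object a [PLSDAModel-class].
#' @param newdata a [SpectralDataset-class] on the model's axis.
#' @param nLV number of latent variables to use (default: the model's).
#' @return `list(scores = n x class matrix, class = character vector)`.
#' @export
setMethod("predict", "PLSDAModel", function(object, newdata,
                                            nLV = object@nLV) {
  scores <- .predictScores(object, newdata, nLV)
  cls <- object@classOrder[max.col(scores, ties.method = "first")]
  list(scores = scores, class = cls)
})

# mean over classes of (false-negative rate + false-positive rate)/2
.errorAverage <- function(truth, assigned, classOrder) {
  per <- vapply(classOrder, function(cl) {
    isC <- truth == cl
    fnr <- if (any(isC)) mean(assigned[isC] != cl) else NA_real_
    fpr <- if (any(!isC)) mean(assigned[!isC] == cl) else NA_real_
    (fnr + fpr) / 2
  }, 0)
  mean(per, na.rm = TRUE)
}

#' Split a dataset by removing every fourth spectrum
#'
#' Spectra with 1-based position divisible by 4 (acquisition order) form
#' the validation set; the rest form the calibration set.
#'
#' @param d a [SpectralDataset-class] with >= 4 spectra.
#' @return `list(calibration, validation)` — an exact partition.
#' @export
splitEveryFourth <- function(d) {
  n <- ncol(d)
  if (n < 4L) stop("need at least 4 spectra to split", call. = FALSE)
  val <- which(seq_len(n) %% 4L == 0L)
  list(calibration = d[, -val], validation = d[, val])
}

#' Venetian-blinds cross-validation error curves
#'
#' Fold `j` holds out the spectra whose 1-based position is congruent to
#' `j` modulo `nSplits` (by row order — no randomness, so curves are
#' bit-reproducible).  For each number of latent variables the model is
#' refitted on the remaining folds and the held-out predictions pooled;
#' reported alongside is the calibration (resubstitution) error.  Errors
#' are classification error averages: mean over classes of
#' (FNR + FPR)/2.
#'
#' @param calibration a [SpectralDataset-class].
#' @param nLVMax largest number of latent variables to evaluate.
#' @param nSplits number of blinds (default 10).
#' @param recipe preprocessing chain.
#' @return data.frame with columns `n_lv`, `cal_error`, `cv_error`.
#' @export
venetianCV <- function(calibration, nLVMax = 10L, nSplits = 10L,
                       recipe = recipePLSDA()) {
  n <- ncol(calibration)
  if (nSplits < 2L) stop("nSplits must be >= 2", call. = FALSE)
  truth <- classLabels(calibration)
  classOrder <- sort(unique(truth))
  counts <- table(truth)
  if (any(counts < nSplits))
    warning("class(es) with fewer members than splits: ",
            paste(names(counts)[counts < nSplits], collapse = ", "),
            "; venetian blinds may leave folds without them")
  fold <- (seq_len(n) - 1L) %% nSplits + 1L
  # the per-spectrum recipe steps are fold-independent; apply them once
  # (centring is refitted inside each fold's model)
  prep <- applyRecipe(calibration, .rowwiseRecipe(recipe))
  none <- preprocessRecipe()
  full <- fitPLSDA(prep, nLVMax, none)
  calScores <- lapply(seq_len(nLVMax), function(a)
    .predictScores(full, prep, a))
  cvAssigned <- matrix(NA_character_, n, nLVMax)
  for (j in seq_len(nSplits)) {
    hold <- fold == j
    mj <- fitPLSDA(prep[, !hold], nLVMax, none)
    for (a in seq_len(nLVMax)) {
      sc <- .predictScores(mj, prep[, hold], a)
      cvAssigned[hold, a] <- mj@classOrder[max.col(sc,
                                                   ties.method = "first")]
    }
  }
  data.frame(
    n_lv = seq_len(nLVMax),
    cal_error = vapply(seq_len(nLVMax), function(a)
      .errorAverage(truth,
                    classOrder[max.col(calScores[[a]],
                                       ties.method = "first")],
                    classOrder), 0),
    cv_error = vapply(seq_len(nLVMax), function(a)
      .errorAverage(truth, cvAssigned[, a], classOrder), 0))
}

#' Select the number of latent variables from an error curve
#'
#' Returns the smallest number of latent variables whose calibration and
#' cross-validation classification error averages are both at or below
#' `targetError` (the "set the error average at 5%" rule).  If no size
#' meets the target, the CV-minimising size is returned with
#' `metTarget = FALSE`.
#'
#' @param cvCurve data.frame from [venetianCV()].
#' @param targetError error-average target (default 0.05).
#' @return `list(nLV, metTarget)`.
#' @export
selectNLV <- function(cvCurve, targetError = 0.05) {
  stopifnot(nrow(cvCurve) >= 1L)
  ok <- which(cvCurve$cal_error <= targetError &
                cvCurve$cv_error <= targetError)
  if (length(ok))
    list(nLV = cvCurve$n_lv[ok[1L]], metTarget = TRUE)
  else
    list(nLV = cvCurve$n_lv[which.min(cvCurve$cv_error)],
         metTarget = FALSE)
}

#' Variable importance in projection (VIP) scores
#'
#' `VIP_j = sqrt(p * sum_a ssY_a (w_ja / ||w_a||)^2 / sum_a ssY_a)` over
#' the model's latent variables, where `ssY_a` is the Y sum of squares
#' captured by latent variable a.  The squared scores average exactly 1,
#' so wavenumbers with VIP > 1 are the discriminatory spectral regions.
#'
#' @param m a fitted [PLSDAModel-class].
#' @return A [VIPResult-class].
#' @export
vipScores <- function(m) {
  W <- sweep(m@weights, 2L, sqrt(colSums(m@weights^2)), `/`)
  p <- nrow(W)
  vip <- sqrt(p * drop(W^2 %*% m@ssY) / sum(m@ssY))
  new("VIPResult", vip = vip, wavenumber = m@wavenumber,
      discriminatoryBands = m@wavenumber[vip > 1])
}

setMethod("show", "VIPResult", function(object)
  cat(sprintf("VIPResult: %d/%d wavenumbers with VIP > 1 (max %.2f at %g cm^-1)\n",
              length(object@discriminatoryBands), length(object@vip),
              max(object@vip),
              object@wavenumber[which.max(object@vip)])))

#' One-vs-rest ROC area under the curve
#'
#' AUC as the probability that a random positive outscores a random
#' negative, with ties counted one half (the Mann-Whitney convention),
#' computed from rank statistics.
#'
#' @param truth logical (or 0/1) vector; TRUE = positive class.
#' @param scores continuous classifier scores.
#' @return AUC in \[0, 1\].
#' @export
rocAUC <- function(truth, scores) {
  truth <- as.logical(truth)
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0L || n0 == 0L)
    stop("rocAUC needs both classes present", call. = FALSE)
  r <- rank(scores)                       # midranks handle ties as 1/2
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Average the line-scan spectra of every cell
#'
#' Collapses a dataset to one pointwise-mean spectrum per
#' (cell line, cell id) group — the "averaged line-scan spectrum" level.
#'
#' @param d a [SpectralDataset-class].
#' @return A [SpectralDataset-class] with one column per cell.
#' @export
averageByCell <- function(d) {
  key <- paste(colData(d)$cell_line, colData(d)$cell_id, sep = "\r")
  groups <- split(seq_len(ncol(d)), factor(key, levels = unique(key)))
  y <- vapply(groups, function(i)
    rowMeans(intensities(d)[, i, drop = FALSE]),
    numeric(nrow(d)))
  first <- vapply(groups, `[`, 0L, 1L)
  meta <- data.frame(cell_line = colData(d)$cell_line[first],
                     cell_id = colData(d)$cell_id[first],
                     point_index = 0L,
                     scan_index = colData(d)$scan_index[first])
  SpectralDataset(y, wavenumbers(d), meta)
}

#' Per-class classification report
#'
#' Computes, per class: sensitivity and specificity of the validation
#' assignments (one-vs-rest), AUC from the continuous one-vs-rest
#' validation scores, and RMSEC / RMSECV / RMSEP — the root-mean-square
#' of (indicator - predicted score) for that class over the calibration,
#' pooled cross-validation, and validation predictions respectively —
#' plus the validation confusion matrix.  At `level = "cell"` the point
#' spectra of each cell are averaged first and the averaged spectra
#' predicted.
#'
#' @param m a fitted [PLSDAModel-class].
#' @param calibration,validation the [splitEveryFourth()] datasets.
#' @param level `"spectrum"` or `"cell"`.
#' @param nSplits venetian blinds used for the RMSECV pooling.
#' @return A [ClassificationReport-class].
#' @export
classificationReport <- function(m, calibration, validation,
                                 level = c("spectrum", "cell"),
                                 nSplits = 10L) {
  level <- match.arg(level)
  if (level == "cell") {
    calibration <- averageByCell(calibration)
    validation <- averageByCell(validation)
  }
  classOrder <- m@classOrder
  calTruth <- classLabels(calibration)
  valTruth <- classLabels(validation)
  calScores <- .predictScores(m, calibration)
  valPred <- predict(m, validation)
  # pooled venetian-blinds CV predictions at the model's size
  n <- ncol(calibration)
  fold <- (seq_len(n) - 1L) %% nSplits + 1L
  prep <- applyRecipe(calibration, .rowwiseRecipe(m@recipe))
  none <- preprocessRecipe()
  cvScores <- matrix(NA_real_, n, length(classOrder))
  for (j in unique(fold)) {
    hold <- fold == j
    mj <- fitPLSDA(prep[, !hold], m@nLV, none)
    cvScores[hold, ] <- .predictScores(mj, prep[, hold])
  }
  Ycal <- .indicatorMatrix(calTruth, classOrder)
  Yval <- .indicatorMatrix(valTruth, classOrder)
  per <- lapply(classOrder, function(cl) {
    ci <- match(cl, classOrder)
    isC <- valTruth == cl
    sens <- if (any(isC)) mean(valPred$class[isC] == cl) else NA_real_
    spec <- if (any(!isC)) mean(valPred$class[!isC] != cl) else NA_real_
    auc <- if (any(isC) && any(!isC))
      rocAUC(isC, valPred$scores[, ci]) else NA_real_
    data.frame(class = cl, sensitivity = sens, specificity = spec,
               auc = auc,
               rmsec = sqrt(mean((Ycal[, ci] - calScores[, ci])^2)),
               rmsecv = sqrt(mean((Ycal[, ci] - cvScores[, ci])^2)),
               rmsep = sqrt(mean((Yval[, ci] - valPred$scores[, ci])^2)))
  })
  conf <- table(factor(valTruth, classOrder),
                factor(valPred$class, classOrder))
  new("ClassificationReport", perClass = do.call(rbind, per),
      confusion = unclass(as.matrix(conf)), level = level,
      errorAverage = .errorAverage(valTruth, valPred$class, classOrder))
}

setMethod("show", "ClassificationReport", function(object) {
  cat(sprintf("ClassificationReport (%s level), validation error average %.3f\n",
              object@level, object@errorAverage))
  df <- object@perClass
  df$sensitivity <- sprintf("%.1f%%", 100 * df$sensitivity)
  df$specificity <- sprintf("%.1f%%", 100 * df$specificity)
  for (cc in c("auc", "rmsec", "rmsecv", "rmsep"))
    df[[cc]] <- sprintf("%.4f", df[[cc]])
  print(df, row.names = FALSE)
})
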