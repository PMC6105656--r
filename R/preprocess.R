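#' Build a preprocessing recipe
#'
#' Each argument is either a step name (`"vector_norm"`) or a list whose
#' first element is the step name followed by named parameters, e.g.
#' `list("savgol", width = 11, polyorder = 3)`.  Steps run in the order
#' given.
#'
#' @param ... steps (see Details in [PreprocessRecipe-class]).
#' @return A [PreprocessRecipe-class].
#' @examples
#' preprocessRecipe("vector_norm",
#'                  list("derivative", order = 2, width = 15, polyorder = 3),
#'                  "mean_center")
#' @export
preprocessRecipe <- function(...) {
  steps <- lapply(list(...), function(s) {
    if (is.character(s)) return(list(name = s))
    stopifnot(is.list(s))
    nm <- if (!is.null(s$name)) s$name else s[[1L]]
    prm <- s[setdiff(names(s) %||% character(0), c("", "name"))]
    c(list(name = nm), prm)
  })
  new("PreprocessRecipe", steps = steps)
}

#' @rdname preprocessRecipe
#' @param r a recipe.
#' @export
recipeSummary <- function(r) {
  if (!length(r@steps)) return("<identity>")
  paste(vapply(r@steps, function(st) {
    prm <- st[setdiff(names(st), "name")]
    if (!length(prm)) return(st$name)
    sprintf("%s(%s)", st$name,
            paste(names(prm), unlist(prm), sep = "=", collapse = ","))
  }, ""), collapse = " -> ")
}

setMethod("show", "PreprocessRecipe", function(object)
  cat("PreprocessRecipe:", recipeSummary(object), "\n"))

#' Canned recipes
#'
#' `recipeConditioning()` is the raw-data conditioning chain (cosmic-ray
#' despiking, order-5 iterative polynomial baseline subtraction,
#' Savitzky-Golay smoothing width 11 / order 3).  `recipePCA()` normalises
#' to unit area under the curve.  `recipePLSDA()` is the classification
#' chain: vector normalisation, a joint Savitzky-Golay second-derivative
#' step (width 15, order 3 by default; differentiation and smoothing in
#' one filter), and mean centring.
#'
#' @param width,polyorder Savitzky-Golay window length (odd) and
#'   polynomial order for the derivative step.
#' @return A [PreprocessRecipe-class].
#' @export
recipeConditioning <- function()
  preprocessRecipe("despike", list("baseline", order = 5),
                   list("savgol", width = 11, polyorder = 3))

#' @rdname recipeConditioning
#' @export
recipePCA <- function() preprocessRecipe("area_norm")

#' @rdname recipeConditioning
#' @export
recipePLSDA <- function(width = 15, polyorder = 3)
  preprocessRecipe("vector_norm",
                   list("derivative", order = 2, width = width,
                        polyorder = polyorder),
                   "mean_center")

# ---- per-spectrum primitives (vector level) ----

.despikeVec <- function(y, zThreshold = 8, maxWidth = 3L) {
  n <- length(y)
  if (n < 5L) stop("despike needs at least 5 points", call. = FALSE)
  d2 <- diff(y, differences = 2L)           # centred at points 2..n-1
  med <- stats::median(d2)
  madv <- stats::median(abs(d2 - med))
  score <- if (madv > 0) 0.6745 * abs(d2 - med) / madv else rep(0, n - 2L)
  z <- c(score[1L], score, score[n - 2L])   # pad ends with nearest score
  flagged <- z > zThreshold
  spikes <- integer(0)
  if (any(flagged)) {
    r <- rle(flagged)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values & r$lengths <= maxWidth)) {
      idx <- starts[j]:ends[j]
      lo <- starts[j] - 1L; hi <- ends[j] + 1L
      y[idx] <- if (lo < 1L && hi > n) stats::median(y)
      else if (lo < 1L) y[hi]                  # nearest-neighbour at edge
      else if (hi > n) y[lo]
      else y[lo] + (y[hi] - y[lo]) * (idx - lo) / (hi - lo)
      spikes <- c(spikes, idx)
    }
  }
  list(y = y, spikes = spikes)
}

.baselineVec <- function(w, y, order = 5L, maxIter = 100L, tol = 1e-6) {
  fit <- .baselineMat(w, matrix(y, ncol = 1L), order, maxIter, tol)[, 1L]
  list(corrected = y - fit, baseline = fit)
}

# ModPoly-style on all spectra at once: fit, clip the working signal to
# min(signal, fit), refit; each column iterates until its fit moves by
# less than tol x its own range.
.baselineMat <- function(w, Y, order = 5L, maxIter = 100L, tol = 1e-6) {
  if (any(!is.finite(Y))) stop("baseline: non-finite input", call. = FALSE)
  if (length(w) <= order + 1L)
    stop("baseline: axis shorter than order + 2", call. = FALSE)
  basis <- .polyBasis(w, order)
  rng <- apply(Y, 2L, function(y) max(diff(range(y)), .Machine$double.xmin))
  rng[rng == 0] <- 1
  FIT <- basis %*% crossprod(basis, Y)
  active <- rep(TRUE, ncol(Y))
  for (i in seq_len(maxIter)) {
    sub <- which(active)
    if (!length(sub)) break
    fsub <- FIT[, sub, drop = FALSE]
    work <- pmin(Y[, sub, drop = FALSE], fsub)
    new <- basis %*% crossprod(basis, work)
    moved <- colSums(sweep(abs(new - fsub), 2L, tol * rng[sub], `>`)) > 0L
    FIT[, sub] <- new
    active[sub] <- moved
  }
  FIT
}

# orthonormal polynomial basis columns on the axis (QR of Vandermonde)
.polyBasis <- function(w, order) {
  u <- (w - mean(w)) / (diff(range(w)) / 2)
  V <- outer(u, 0:order, `^`)
  qr.Q(qr(V))
}

.savgolVec <- function(y, width = 11L, polyorder = 3L, deriv = 0L, h = 1) {
  if (width %% 2L == 0L) stop("Savitzky-Golay width must be odd",
                              call. = FALSE)
  if (width <= polyorder) stop("Savitzky-Golay width must exceed polyorder",
                               call. = FALSE)
  if (length(y) < width)
    stop("spectrum shorter than the Savitzky-Golay window", call. = FALSE)
  as.numeric(signal::sgolayfilt(y, p = polyorder, n = width, m = deriv,
                                ts = h))
}

.gridStep <- function(w) {
  dw <- diff(w)
  if (diff(range(dw)) > 1e-6 * mean(dw))
    stop("this operation requires a (near-)uniform wavenumber grid",
         call. = FALSE)
  mean(dw)
}

.areaNormVec <- function(w, y) {
  a <- pracma::trapz(w, abs(y))
  if (a <= 0) stop("area normalization: zero-area spectrum", call. = FALSE)
  y / a
}

.vectorNormVec <- function(y) {
  nrm <- sqrt(sum(y^2))
  if (nrm == 0) stop("vector normalization: zero spectrum", call. = FALSE)
  y / nrm
}

# ---- dataset-level operations ----

.mapSpectra <- function(d, f) {
  y <- intensities(d)
  for (j in seq_len(ncol(y))) y[, j] <- f(y[, j])
  SummarizedExperiment::assay(d, "intensity") <- y
  d
}

#' Remove cosmic-ray spikes
#'
#' Points whose modified z-score of the second difference exceeds
#' `zThreshold`, in runs of at most `maxWidth` consecutive points, are
#' replaced by linear interpolation of the flanking points
#' (nearest-neighbour at the spectrum ends).  Wider excursions — real
#' Raman bands — are left untouched, as are all unflagged points.
#'
#' @param d a [SpectralDataset-class].
#' @param zThreshold modified z-score threshold (> 0), default 8.
#' @param maxWidth maximum spike width in points (1..3).
#' @return The despiked dataset; `metadata(x)$spikes` holds the flagged
#'   index vector per spectrum.
#' @export
despike <- function(d, zThreshold = 8, maxWidth = 3L) {
  stopifnot(zThreshold > 0, maxWidth %in% 1:3)
  spikes <- vector("list", ncol(d))
  y <- intensities(d)
  for (j in seq_len(ncol(y))) {
    r <- .despikeVec(y[, j], zThreshold, maxWidth)
    y[, j] <- r$y
    spikes[[j]] <- r$spikes
  }
  SummarizedExperiment::assay(d, "intensity") <- y
  metadata(d)$spikes <- spikes
  d
}

#' Subtract an iterative polynomial baseline
#'
#' ModPoly-style fluorescence background removal: an order-`order`
#' polynomial is fitted to the spectrum, the working signal is clipped to
#' the pointwise minimum of signal and fit, and the fit is repeated until
#' it changes by less than `tol` (relative to the signal range) or
#' `maxIter` passes.  The corrected spectrum plus the returned baseline
#' reconstruct the input exactly.
#'
#' @param d a [SpectralDataset-class].
#' @param order polynomial order (default 5).
#' @param maxIter,tol iteration controls.
#' @return The corrected dataset; `metadata(x)$baseline` holds the fitted
#'   baseline matrix (wavenumbers x spectra).
#' @export
subtractBaseline <- function(d, order = 5L, maxIter = 100L, tol = 1e-6) {
  w <- wavenumbers(d)
  y <- intensities(d)
  bl <- .baselineMat(w, y, order, maxIter, tol)
  SummarizedExperiment::assay(d, "intensity") <- y - bl
  metadata(d)$baseline <- bl
  d
}

#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial smoothing (default width 11, order 3).
#' Edges are handled by evaluating the edge-window polynomial fit, not by
#' reflection padding.
#'
#' @param d a [SpectralDataset-class].
#' @param width odd window length.
#' @param polyorder polynomial order, `< width`.
#' @return Smoothed dataset.
#' @export
savgolSmooth <- function(d, width = 11L, polyorder = 3L)
  .mapSpectra(d, function(y) .savgolVec(y, width, polyorder))

#' Savitzky-Golay second derivative
#'
#' Joint smoothing and differentiation with respect to the wavenumber
#' coordinate (the grid step is accounted for, so results are per
#' cm^-2).  A Gaussian or Lorentzian band maps to a negative extremum at
#' the band centre.
#'
#' @inheritParams savgolSmooth
#' @param order derivative order (default 2).
#' @return Differentiated dataset.
#' @export
secondDerivative <- function(d, width = 11L, polyorder = 3L, order = 2L) {
  h <- .gridStep(wavenumbers(d))
  .mapSpectra(d, function(y) .savgolVec(y, width, polyorder, order, h))
}

#' Normalise each spectrum to unit area under the curve
#'
#' Divides by the trapezoidal integral of `|intensity|` over the axis.
#' Idempotent and scale-invariant.
#'
#' @param d a [SpectralDataset-class].
#' @return Normalised dataset.
#' @export
normalizeArea <- function(d) {
  w <- wavenumbers(d)
  .mapSpectra(d, function(y) .areaNormVec(w, y))
}

#' Normalise each spectrum to unit Euclidean norm
#'
#' @param d a [SpectralDataset-class].
#' @return Normalised dataset.  Idempotent and scale-invariant.
#' @export
normalizeVector <- function(d) .mapSpectra(d, .vectorNormVec)

#' Mean-centre a dataset per wavenumber
#'
#' Subtracts the across-spectra mean at every wavenumber.  Only defined at
#' dataset level (>= 2 spectra).
#'
#' @param d a [SpectralDataset-class].
#' @return Centred dataset.
#' @export
meanCenter <- function(d) {
  if (ncol(d) < 2L)
    stop("mean_center is a dataset-level step (needs >= 2 spectra)",
         call. = FALSE)
  y <- intensities(d)
  SummarizedExperiment::assay(d, "intensity") <- y - rowMeans(y)
  d
}

#' Apply a preprocessing recipe to a dataset
#'
#' Steps run in listed order; all steps are per-spectrum except
#' `mean_center`, which centres per wavenumber across the dataset.  The
#' applied recipe is appended to `metadata(d)$recipe` for provenance.
#'
#' @param d a [SpectralDataset-class].
#' @param recipe a [PreprocessRecipe-class].
#' @return The preprocessed dataset.
#' @export
applyRecipe <- function(d, recipe) {
  stopifnot(is(recipe, "PreprocessRecipe"))
  validObject(recipe)
  for (st in recipe@steps) {
    d <- switch(st$name,
      despike = despike(d, st$zThreshold %||% 8, st$maxWidth %||% 3L),
      baseline = subtractBaseline(d, st$order %||% 5L,
                                  st$maxIter %||% 100L, st$tol %||% 1e-6),
      savgol = savgolSmooth(d, st$width %||% 11L, st$polyorder %||% 3L),
      area_norm = normalizeArea(d),
      vector_norm = normalizeVector(d),
      derivative = secondDerivative(d, st$width %||% 15L,
                                    st$polyorder %||% 3L,
                                    st$order %||% 2L),
      mean_center = meanCenter(d),
      stop("unknown recipe step: ", st$name, call. = FALSE))
  }
  prev <- metadata(d)$recipe
  metadata(d)$recipe <- if (is.null(prev)) recipe else
    new("PreprocessRecipe", steps = c(prev@steps, recipe@steps))
  d
}
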