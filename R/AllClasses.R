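#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom stats predict
#' @exportMethod show
NULL

.validWavenumber <- function(w) {
  if (!is.numeric(w) || length(w) < 1L)
    return("wavenumber axis must be numeric and non-empty")
  if (anyNA(w) || any(!is.finite(w)))
    return("wavenumber axis must be finite")
  if (any(diff(w) <= 0))
    return("wavenumber axis must be strictly increasing")
  NULL
}

#' SpectralDataset: labelled Raman spectra on a shared wavenumber axis
#'
#' An S4 container for a collection of Raman spectra that share one
#' wavenumber axis, built on [SummarizedExperiment::SummarizedExperiment].
#' Wavenumbers (cm^-1) are rows; spectra are columns.  Per-spectrum
#' acquisition metadata (cell line, cell id, line-scan point index, repeat
#' scan index, excitation wavelength, exposure, accumulations) live in
#' `colData`.
#'
#' @slot .. inherits all slots from `SummarizedExperiment`; the single assay
#'   is named `"intensity"` and `rowData(x)$wavenumber` holds the axis.
#' @export
setClass("SpectralDataset", contains = "SummarizedExperiment")

setValidity("SpectralDataset", function(object) {
  w <- rowData(object)$wavenumber
  if (is.null(w)) return("rowData must contain a 'wavenumber' column")
  msg <- .validWavenumber(w)
  if (!is.null(msg)) return(msg)
  if (!"intensity" %in% SummarizedExperiment::assayNames(object))
    return("assay 'intensity' is required")
  y <- assay(object, "intensity")
  if (nrow(y) != length(w)) return("intensity rows must match axis length")
  if (ncol(object) > 0L && any(!is.finite(y)))
    return("intensities must be finite (no NA/NaN/Inf)")
  cd <- colData(object)
  need <- c("cell_line", "cell_id", "point_index", "scan_index")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    return(paste0("colData missing required column(s): ",
                  paste(miss, collapse = ", ")))
  if (ncol(object) > 0L) {
    if (any(cd$point_index < 0L) || any(cd$scan_index < 0L))
      return("point_index and scan_index must be >= 0")
    if ("excitation_nm" %in% colnames(cd) &&
        !all(cd$excitation_nm %in% c(488, 785)))
      return("excitation_nm must be 488 or 785")
  }
  TRUE
})

#' HyperspectralMap: a raster area scan of Raman spectra
#'
#' Extends [SpectralDataset-class]; columns are pixels stored in row-major
#' order with the x index varying fastest.  `colData` gains integer pixel
#' coordinates `x` (1..nx) and `y` (1..ny).
#'
#' @slot gridShape integer(2), `(nx, ny)` pixels.
#' @slot stepUm positive numeric, spatial step between pixels in micrometres.
#' @export
setClass("HyperspectralMap",
         contains = "SpectralDataset",
         representation(gridShape = "integer", stepUm = "numeric"))

setValidity("HyperspectralMap", function(object) {
  gs <- object@gridShape
  if (length(gs) != 2L || any(gs < 1L))
    return("gridShape must be two positive integers (nx, ny)")
  if (ncol(object) != prod(gs))
    return("pixel count must equal nx * ny")
  if (length(object@stepUm) != 1L || !is.finite(object@stepUm) ||
      object@stepUm <= 0)
    return("stepUm must be a single positive number")
  TRUE
})

#' PreprocessRecipe: an ordered spectral preprocessing chain
#'
#' Steps are applied in order by [applyRecipe()].  Allowed step names:
#' `despike`, `baseline`, `savgol`, `area_norm`, `vector_norm`,
#' `derivative`, `mean_center`.  `mean_center` operates column-wise over a
#' dataset (per wavenumber) and is only valid with >= 2 spectra; all other
#' steps are per-spectrum.
#'
#' @slot steps list of steps; each step is a named list with `name` and
#'   step parameters.
#' @export
setClass("PreprocessRecipe", representation(steps = "list"))

.recipeStepNames <- c("despike", "baseline", "savgol", "area_norm",
                      "vector_norm", "derivative", "mean_center")

setValidity("PreprocessRecipe", function(object) {
  for (st in object@steps) {
    if (is.null(st$name) || !st$name %in% .recipeStepNames)
      return(paste0("unknown recipe step: ",
                    if (is.null(st$name)) "<missing>" else st$name))
    if (st$name %in% c("savgol", "derivative")) {
      w <- st$width %||% 11L; p <- st$polyorder %||% 3L
      if (w %% 2L == 0L) return("Savitzky-Golay width must be odd")
      if (w <= p) return("Savitzky-Golay width must exceed polyorder")
    }
  }
  TRUE
})

#' PCAResult: principal component decomposition of a spectral dataset
#'
#' @slot loadings component x wavenumber matrix with orthonormal rows.
#' @slot scores spectrum x component matrix of centred scores.
#' @slot explainedVariance fraction of total variance per retained
#'   component (non-increasing, sums to <= 1).
#' @slot wavenumber the axis the loadings refer to.
#' @slot recipe the [PreprocessRecipe-class] applied before the fit.
#' @export
setClass("PCAResult",
         representation(loadings = "matrix", scores = "matrix",
                        explainedVariance = "numeric",
                        wavenumber = "numeric",
                        recipe = "PreprocessRecipe"))

#' PLSDAModel: SIMPLS partial least squares discriminant model
#'
#' Classes are encoded as one indicator column per class; a PLS2 regression
#' of the indicator matrix on preprocessed, mean-centred spectra is fitted
#' with the SIMPLS algorithm.  Scores are normalised to unit Euclidean
#' norm, so the Y sum of squares captured by latent variable a equals
#' `sum(yLoadings[, a]^2)`.
#'
#' @slot nLV number of latent variables retained.
#' @slot weights wavenumber x LV matrix R with scores `T = Xc %*% R`.
#' @slot xLoadings wavenumber x LV matrix P.
#' @slot yLoadings class x LV matrix Q.
#' @slot coefficients wavenumber x class regression matrix at `nLV`.
#' @slot classOrder class labels in indicator-column order.
#' @slot xMean,yMean centring vectors from the calibration set.
#' @slot ssY Y sum of squares captured per LV.
#' @slot wavenumber calibration axis (after any axis-changing recipe step).
#' @slot recipe preprocessing applied before centring.
#' @export
setClass("PLSDAModel",
         representation(nLV = "integer", weights = "matrix",
                        xLoadings = "matrix", yLoadings = "matrix",
                        coefficients = "matrix", classOrder = "character",
                        xMean = "numeric", yMean = "numeric",
                        ssY = "numeric", wavenumber = "numeric",
                        recipe = "PreprocessRecipe"))

#' VIPResult: variable importance in projection scores
#'
#' @slot vip per-wavenumber VIP score; `mean(vip^2) == 1`.
#' @slot wavenumber the axis.
#' @slot discriminatoryBands wavenumbers with VIP > 1.
#' @export
setClass("VIPResult",
         representation(vip = "numeric", wavenumber = "numeric",
                        discriminatoryBands = "numeric"))

setValidity("VIPResult", function(object) {
  if (length(object@vip) != length(object@wavenumber))
    return("vip and wavenumber lengths differ")
  if (abs(mean(object@vip^2) - 1) > 1e-6)
    return("mean squared VIP must equal 1")
  TRUE
})

#' ClusterResult: L1 (Manhattan) k-medians segmentation of a map
#'
#' @slot k number of clusters.
#' @slot pixelLabels integer cluster label per pixel, 1..k, renumbered by
#'   descending cluster size.
#' @slot clusterSpectra wavenumber x k matrix of mean raw spectra.
#' @slot objective total within-cluster L1 distance in preprocessed space.
#' @slot sizes pixels per cluster.
#' @export
setClass("ClusterResult",
         representation(k = "integer", pixelLabels = "integer",
                        clusterSpectra = "matrix", objective = "numeric",
                        sizes = "integer"))

setValidity("ClusterResult", function(object) {
  if (!all(object@pixelLabels %in% seq_len(object@k)))
    return("labels must lie in 1..k")
  if (any(tabulate(object@pixelLabels, object@k) == 0L))
    return("every cluster must be non-empty")
  TRUE
})

#' SumFilterImage: per-pixel band integral of a hyperspectral map
#'
#' @slot values numeric per pixel (same ordering as the map columns).
#' @slot gridShape integer(2) `(nx, ny)`.
#' @slot band numeric(2), the integrated `(lo, hi)` window in cm^-1.
#' @export
setClass("SumFilterImage",
         representation(values = "numeric", gridShape = "integer",
                        band = "numeric"))

#' ClassificationReport: per-class PLS-DA performance metrics
#'
#' The machine-readable twin of a classification results table: one row per
#' class with sensitivity, specificity, AUC, RMSEC, RMSECV and RMSEP, plus
#' the validation confusion matrix.
#'
#' @slot perClass data.frame with columns `class`, `sensitivity`,
#'   `specificity`, `auc`, `rmsec`, `rmsecv`, `rmsep`.
#' @slot confusion true-class x assigned-class count matrix (validation).
#' @slot level `"spectrum"` or `"cell"`.
#' @slot errorAverage classification error average on the validation set.
#' @export
setClass("ClassificationReport",
         representation(perClass = "data.frame", confusion = "matrix",
                        level = "character", errorAverage = "numeric"))

#' ClassTemplate: the forward model for one simulated cell class
#'
#' @slot classLabel class name.
#' @slot bands data.frame of fingerprint bands with columns `center`,
#'   `fwhm`, `amplitude`, `shape` (`"gaussian"`/`"lorentzian"`),
#'   `assignment`.
#' @slot baselineCoeffs polynomial coefficients (ascending, order <= 5) on
#'   the axis rescaled to \[-1, 1\].
#' @slot quartzHump amplitude of the broad substrate hump near 1450 cm^-1
#'   added to the baseline (0 disables it).
#' @slot highBands data.frame like `bands` for the high-wavenumber region
#'   (CH stretches, O-H water stretches); rendered only when the axis
#'   extends beyond 2700 cm^-1.
#' @export
setClass("ClassTemplate",
         representation(classLabel = "character", bands = "data.frame",
                        baselineCoeffs = "numeric", quartzHump = "numeric",
                        highBands = "data.frame"))

.validBandTable <- function(b, what) {
  need <- c("center", "fwhm", "amplitude", "shape", "assignment")
  if (!all(need %in% colnames(b)))
    return(paste0(what, " must have columns ", paste(need, collapse = ", ")))
  if (nrow(b)) {
    if (any(b$fwhm < 3))
      return("band FWHM must be >= 3 cm^-1 (instrument resolution floor)")
    if (any(b$amplitude < 0)) return("band amplitudes must be >= 0")
    if (!all(b$shape %in% c("gaussian", "lorentzian")))
      return("band shape must be gaussian or lorentzian")
  }
  NULL
}

setValidity("ClassTemplate", function(object) {
  msg <- .validBandTable(object@bands, "bands")
  if (!is.null(msg)) return(msg)
  msg <- .validBandTable(object@highBands, "highBands")
  if (!is.null(msg)) return(msg)
  if (length(object@baselineCoeffs) > 6L)
    return("baseline polynomial order must be <= 5")
  TRUE
})

#' TrendFit: ordinary least-squares line through a peak-ratio time series
#'
#' @slot slope,slopeSE,intercept,interceptSE OLS estimates and standard
#'   errors.
#' @slot rSquared coefficient of determination; `NA` (with
#'   `degenerate = TRUE`) for a zero-variance series.
#' @slot n number of points fitted.
#' @slot degenerate TRUE when the response had zero variance.
#' @export
setClass("TrendFit",
         representation(slope = "numeric", slopeSE = "numeric",
                        intercept = "numeric", interceptSE = "numeric",
                        rSquared = "numeric", n = "integer",
                        degenerate = "logical"))

`%||%` <- function(a, b) if (is.null(a)) b else a
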