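# Area-scan imaging analytics: band sum filters, Manhattan (L1) k-medians
# segmentation, cluster spectra, and line-vs-area equivalence.

#' Band sum filter
#'
#' Per-pixel trapezoidal integral of intensity over `[lo, hi]` cm^-1,
#' producing a chemical image (e.g. lipid distribution from the CH
#' stretch around 2838-2938 cm^-1, or 1420-1460 cm^-1 in the
#' fingerprint).
#'
#' @param m a [HyperspectralMap-class].
#' @param lo,hi integration bounds, cm^-1 (grid points within the closed
#'   window are used).
#' @return A [SumFilterImage-class].
#' @export
sumFilter <- function(m, lo, hi) {
  if (lo >= hi) stop("sumFilter: lo must be < hi", call. = FALSE)
  w <- wavenumbers(m)
  sel <- which(w >= lo & w <= hi)
  if (length(sel) < 2L)
    stop(sprintf("sumFilter: band [%g, %g] covers < 2 axis points", lo, hi),
         call. = FALSE)
  ww <- w[sel]
  vals <- apply(intensities(m)[sel, , drop = FALSE], 2L,
                function(y) pracma::trapz(ww, y))
  new("SumFilterImage", values = unname(vals), gridShape = m@gridShape,
      band = c(lo, hi))
}

#' @rdname sumFilter
#' @param x a SumFilterImage.
#' @param ... ignored.
#' @export
setMethod("as.matrix", "SumFilterImage", function(x, ...)
  matrix(x@values, nrow = x@gridShape[1L]))

setMethod("show", "SumFilterImage", function(object)
  cat(sprintf("SumFilterImage %d x %d, band [%g, %g] cm^-1, range [%.3g, %.3g]\n",
              object@gridShape[1L], object@gridShape[2L], object@band[1L],
              object@band[2L], min(object@values), max(object@values))))

# ---- L1 k-medians ----

.l1DistToCenters <- function(X, centers) {
  # X: n x p, centers: k x p -> n x k
  k <- nrow(centers)
  D <- matrix(0, nrow(X), k)
  for (j in seq_len(k))
    D[, j] <- rowSums(abs(sweep(X, 2L, centers[j, ], `-`)))
  D
}

.kmediansOnce <- function(X, k, maxIter = 100L) {
  n <- nrow(X)
  # L1-distance-weighted seeding (k-means++ adapted to L1)
  centers <- matrix(0, k, ncol(X))
  centers[1L, ] <- X[sample.int(n, 1L), ]
  if (k > 1L) {
    d <- rowSums(abs(sweep(X, 2L, centers[1L, ], `-`)))
    for (j in 2:k) {
      p <- if (sum(d) > 0) d / sum(d) else rep(1 / n, n)
      centers[j, ] <- X[sample.int(n, 1L, prob = p), ]
      d <- pmin(d, rowSums(abs(sweep(X, 2L, centers[j, ], `-`))))
    }
  }
  labels <- rep(1L, n)
  prevObj <- Inf
  for (it in seq_len(maxIter)) {
    D <- .l1DistToCenters(X, centers)
    labels <- max.col(-D, ties.method = "first")   # ties -> lowest index
    for (j in seq_len(k)) {
      if (!any(labels == j)) {      # re-seed an empty cluster at the
        far <- which.max(D[cbind(seq_len(n), labels)])  # worst-fit point
        labels[far] <- j
      }
      centers[j, ] <- apply(X[labels == j, , drop = FALSE], 2L,
                            stats::median)
    }
    obj <- sum(.l1DistToCenters(X, centers)[cbind(seq_len(n), labels)])
    if (obj > prevObj + 1e-8 * max(1, abs(prevObj)))
      stop("internal error: k-medians objective increased", call. = FALSE)
    if (prevObj - obj < 1e-10 * max(1, obj)) break
    prevObj <- obj
  }
  list(labels = labels, centers = centers, objective = obj)
}

#' Manhattan k-medians segmentation of a hyperspectral map
#'
#' Pixels are preprocessed by `premode` (default: a Savitzky-Golay first
#' derivative, width 21, order 3 — the "derivative pre-mode" of
#' hyperspectral cluster imaging, which cancels smooth baselines; the
#' wide window suppresses pixel noise that otherwise traps the seeding
#' in the background field), then clustered by L1 distance with
#' coordinate-wise median centroid updates — the centroid that minimises
#' within-cluster L1 cost.  The best of `nRestarts` seeded
#' initialisations is kept; the objective is checked to be non-increasing
#' across iterations; labels are renumbered by descending cluster size
#' (so the large background field is typically cluster 1).
#'
#' @param m a [HyperspectralMap-class].
#' @param k number of clusters, `1 <= k <=` number of pixels.
#' @param premode a [PreprocessRecipe-class] applied before clustering,
#'   or NULL for the default derivative pre-mode.
#' @param nRestarts number of seeded restarts (default 10).
#' @param seed RNG seed for the restarts.
#' @return A [ClusterResult-class]; `clusterSpectra` are mean raw (not
#'   preprocessed) spectra per cluster.
#' @export
kmeansManhattan <- function(m, k, premode = NULL, nRestarts = 10L,
                            seed = 1L) {
  npix <- ncol(m)
  if (k < 1L || k > npix)
    stop("k must lie in 1..", npix, call. = FALSE)
  if (is.null(premode))
    premode <- preprocessRecipe(
      list("derivative", order = 1, width = 21, polyorder = 3))
  X <- t(intensities(applyRecipe(m, premode)))
  set.seed(seed)
  best <- NULL
  for (r in seq_len(nRestarts)) {
    res <- .kmediansOnce(X, k)
    if (is.null(best) || res$objective < best$objective) best <- res
  }
  sizes <- tabulate(best$labels, k)
  ord <- order(sizes, decreasing = TRUE)
  relabel <- integer(k); relabel[ord] <- seq_len(k)
  labels <- relabel[best$labels]
  raw <- intensities(m)
  spec <- vapply(seq_len(k),
                 function(j) rowMeans(raw[, labels == j, drop = FALSE]),
                 numeric(nrow(raw)))
  colnames(spec) <- paste0("cluster", seq_len(k))
  new("ClusterResult", k = as.integer(k), pixelLabels = labels,
      clusterSpectra = spec, objective = best$objective,
      sizes = tabulate(labels, k))
}

setMethod("show", "ClusterResult", function(object)
  cat(sprintf("ClusterResult: k = %d, sizes = %s, L1 objective = %.4g\n",
              object@k, paste(object@sizes, collapse = "/"),
              object@objective)))

#' Subtract the background cluster's mean spectrum
#'
#' Returns each non-background cluster's mean raw spectrum minus the
#' background cluster's mean raw spectrum, removing the shared
#' substrate/media/baseline contribution.
#'
#' @param cr a [ClusterResult-class].
#' @param m the clustered [HyperspectralMap-class] (for the axis).
#' @param bgLabel background cluster label (default 1, the largest
#'   cluster).
#' @return Wavenumber x (k-1) matrix of background-subtracted cluster
#'   spectra.
#' @export
subtractBackgroundCluster <- function(cr, m, bgLabel = 1L) {
  if (!bgLabel %in% seq_len(cr@k))
    stop("background label ", bgLabel, " not present", call. = FALSE)
  bg <- cr@clusterSpectra[, bgLabel]
  out <- cr@clusterSpectra[, -bgLabel, drop = FALSE] - bg
  rownames(out) <- NULL
  out
}

#' Average the line-scan spectra of one cell
#'
#' Pointwise mean of the point spectra belonging to one cell.
#'
#' @param d a [SpectralDataset-class].
#' @param cellId the cell identifier.
#' @param cellLine optional class restriction (needed if cell ids repeat
#'   across classes).
#' @return A one-spectrum [SpectralDataset-class].
#' @export
lineScanAverage <- function(d, cellId, cellLine = NULL) {
  keep <- colData(d)$cell_id == cellId
  if (!is.null(cellLine)) keep <- keep & colData(d)$cell_line == cellLine
  if (!any(keep))
    stop("no spectra for cell '", cellId, "'", call. = FALSE)
  sub <- d[, keep]
  Spectrum(wavenumbers(sub), rowMeans(intensities(sub)),
           cell_line = colData(sub)$cell_line[1L], cell_id = cellId)
}

#' Compare a line-scan average with an area-scan average
#'
#' Both spectra are area-normalised, then subtracted; a small maximum
#' absolute difference indicates that the line scan recapitulates the
#' area average (about 10 sample points along a line through the cell
#' centre suffice).
#'
#' @param lineAvg,areaAvg one-spectrum [SpectralDataset-class] objects on
#'   a shared axis.
#' @return `list(difference = Spectrum, maxAbs = numeric)`.
#' @export
compareLineVsArea <- function(lineAvg, areaAvg) {
  if (!isTRUE(all.equal(wavenumbers(lineAvg), wavenumbers(areaAvg))))
    stop("line and area spectra must share the wavenumber axis",
         call. = FALSE)
  dl <- intensities(normalizeArea(lineAvg))[, 1L]
  da <- intensities(normalizeArea(areaAvg))[, 1L]
  diffv <- dl - da
  list(difference = Spectrum(wavenumbers(lineAvg), diffv),
       maxAbs = max(abs(diffv)))
}
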