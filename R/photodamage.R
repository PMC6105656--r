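# Photodamage monitoring: peak-intensity ratios across repeated scans and
# ordinary least-squares trend assessment.

#' Windowed peak intensity
#'
#' Maximum intensity within `center +/- halfWindow` cm^-1, robust to a
#' few cm^-1 of calibration drift.  Spectra are expected to be
#' baseline-corrected.
#'
#' @param s a [SpectralDataset-class] (one value is returned per spectrum).
#' @param center band centre, cm^-1.
#' @param halfWindow half-width of the search window, cm^-1 (default 8).
#' @return Numeric vector, one peak intensity per spectrum.
#' @export
peakIntensity <- function(s, center, halfWindow = 8) {
  w <- wavenumbers(s)
  sel <- which(w >= center - halfWindow & w <= center + halfWindow)
  if (!length(sel))
    stop(sprintf(
      "peak window %g +/- %g cm^-1 lies outside the axis [%g, %g]",
      center, halfWindow, min(w), max(w)), call. = FALSE)
  unname(apply(intensities(s)[sel, , drop = FALSE], 2L, max))
}

#' Peak intensity ratio I(a/b)
#'
#' @param s a [SpectralDataset-class].
#' @param a,b band centres, cm^-1.  Requesting a band outside the axis
#'   (e.g. I(2854/2930) on a 785 nm fingerprint-only spectrum) is a range
#'   error.
#' @param halfWindow search half-width, cm^-1.
#' @return Numeric vector of ratios, one per spectrum.
#' @export
intensityRatio <- function(s, a, b, halfWindow = 8) {
  num <- peakIntensity(s, a, halfWindow)
  den <- peakIntensity(s, b, halfWindow)
  if (any(den <= 0))
    stop("intensity ratio: non-positive denominator peak at ", b,
         " cm^-1", call. = FALSE)
  num / den
}

#' Peak-ratio time series over repeated scans
#'
#' Groups a dataset by `scan_index`, averages the point spectra within
#' each scan (the averaged line-scan spectrum), and computes the named
#' intensity ratio per scan.
#'
#' @param d a [SpectralDataset-class] with `scan_index` metadata.
#' @param ratioName text of the form `"I(a/b)"`.
#' @param halfWindow search half-width, cm^-1.
#' @return data.frame with columns `scan_index` and `value`, carrying the
#'   ratio name as the `"ratio"` attribute.
#' @export
ratioSeries <- function(d, ratioName, halfWindow = 8) {
  ab <- .parseRatioName(ratioName)
  si <- colData(d)$scan_index
  scans <- sort(unique(si))
  y <- intensities(d)
  avg <- vapply(scans, function(k)
    rowMeans(y[, si == k, drop = FALSE]), numeric(nrow(y)))
  vals <- intensityRatio(SpectralDataset(avg, wavenumbers(d)),
                         ab["a"], ab["b"], halfWindow)
  structure(data.frame(scan_index = scans, value = vals),
            ratio = ratioName)
}

#' Ordinary least-squares trend through a ratio series
#'
#' Fits `value ~ time` by OLS and reports slope and intercept with their
#' standard errors and R^2.  A zero-variance response is flagged as
#' degenerate (slope 0, SE 0, R^2 undefined) rather than fitted; zero
#' time variance is an error.
#'
#' @param values ratio values per scan, or a data.frame from
#'   [ratioSeries()] (columns `scan_index`/`value`).
#' @param times regressor (scan indices by default, minutes accepted).
#' @return A [TrendFit-class].
#' @examples
#' fitTrend(2 * (1:4) + 1)   # slope 2, intercept 3, R^2 = 1
#' @export
fitTrend <- function(values, times = NULL) {
  if (is.data.frame(values)) {
    if (is.null(times)) times <- values$scan_index
    values <- values$value
  }
  if (is.null(times)) times <- seq_along(values)
  n <- length(values)
  if (n < 3L)
    stop("trend fit needs >= 3 points for standard errors", call. = FALSE)
  if (stats::var(times) == 0)
    stop("trend fit: zero variance in the time axis", call. = FALSE)
  if (stats::var(values) == 0)
    return(new("TrendFit", slope = 0, slopeSE = 0,
               intercept = values[1L], interceptSE = 0,
               rSquared = NA_real_, n = as.integer(n), degenerate = TRUE))
  fit <- stats::lm(values ~ times)
  cf <- stats::coef(fit)
  ssRes <- sum(stats::residuals(fit)^2)
  ssTot <- sum((values - mean(values))^2)
  # standard errors from the residual variance (closed form; avoids
  # summary.lm's near-perfect-fit warning on exact lines)
  s2 <- ssRes / (n - 2L)
  sxx <- sum((times - mean(times))^2)
  new("TrendFit",
      slope = unname(cf["times"]), slopeSE = sqrt(s2 / sxx),
      intercept = unname(cf["(Intercept)"]),
      interceptSE = sqrt(s2 * (1 / n + mean(times)^2 / sxx)),
      rSquared = 1 - ssRes / ssTot, n = as.integer(n), degenerate = FALSE)
}

setMethod("show", "TrendFit", function(object) {
  if (object@degenerate) {
    cat(sprintf("TrendFit (degenerate): constant %.4g over %d points\n",
                object@intercept, object@n))
  } else {
    cat(sprintf("TrendFit: y = %.4g (SE %.2g) x + %.4g (SE %.2g), R2 = %.3f, n = %d\n",
                object@slope, object@slopeSE, object@intercept,
                object@interceptSE, object@rSquared, object@n))
  }
})

#' Trend fits for a set of ratios
#'
#' @param d a [SpectralDataset-class] of repeated scans.
#' @param ratioNames character vector of `"I(a/b)"` names.
#' @param halfWindow search half-width, cm^-1.
#' @return data.frame with one row per ratio: slope, slope SE, intercept,
#'   intercept SE, R^2, n.
#' @export
photodamageReport <- function(d, ratioNames, halfWindow = 8) {
  rows <- lapply(ratioNames, function(nm) {
    f <- fitTrend(ratioSeries(d, nm, halfWindow))
    data.frame(ratio = nm, slope = f@slope, slope_se = f@slopeSE,
               intercept = f@intercept, intercept_se = f@interceptSE,
               r_squared = f@rSquared, n = f@n)
  })
  do.call(rbind, rows)
}
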