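#' Principal component analysis of a spectral dataset
#'
#' Applies the preprocessing recipe (default: normalisation to area under
#' the curve), mean-centres per wavenumber, and decomposes the sample
#' covariance.  Loadings rows are orthonormal; explained-variance
#' fractions are non-increasing; the sign convention is deterministic
#' (the largest-magnitude loading element of each component is positive).
#'
#' @param d a [SpectralDataset-class].
#' @param nComponents number of components to retain,
#'   `<= min(nSpectra, nWavenumbers)`.
#' @param recipe preprocessing chain (default [recipePCA()]).
#' @return A [PCAResult-class].
#' @export
fitPCA <- function(d, nComponents = 3L, recipe = recipePCA()) {
  if (nComponents > min(ncol(d), nrow(d)))
    stop("nComponents exceeds min(nSpectra, nWavenumbers)", call. = FALSE)
  prep <- applyRecipe(d, .rowwiseRecipe(recipe))
  X <- t(intensities(prep))                       # spectra x wavenumbers
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  k <- seq_len(nComponents)
  load <- t(pc$rotation[, k, drop = FALSE])       # component x wavenumber
  scores <- pc$x[, k, drop = FALSE]
  for (i in k) {                                  # deterministic signs
    s <- sign(load[i, which.max(abs(load[i, ]))])
    if (s < 0) { load[i, ] <- -load[i, ]; scores[, i] <- -scores[, i] }
  }
  rownames(load) <- colnames(scores) <- paste0("PC", k)
  new("PCAResult", loadings = load, scores = scores,
      explainedVariance = pc$sdev[k]^2 / sum(pc$sdev^2),
      wavenumber = wavenumbers(prep), recipe = recipe)
}

setMethod("show", "PCAResult", function(object)
  cat(sprintf("PCAResult: %d components, explained variance %s\n",
              nrow(object@loadings),
              paste(sprintf("%.1f%%", 100 * object@explainedVariance),
                    collapse = " / "))))
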