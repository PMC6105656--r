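# Small in-code fixtures shared across test files.

# short uniform fingerprint axis for fast tests
shortAxis <- function(step = 2) seq(600, 1100, by = step)

# a template with three well-separated Lorentzian bands and no baseline
isolatedTemplate <- function(label = "toy", baseline = numeric(0)) {
  classTemplate(label, data.frame(
    center = c(700, 850, 1003),
    fwhm = 12,
    amplitude = c(100, 60, 200),
    shape = "lorentzian",
    assignment = c("lipid", "nucleic_acid", "protein")))
}

# tiny deterministic labelled dataset: two classes separated on one band
separableDataset <- function(nPerClass = 12, delta = 50, noiseSD = 0,
                             seed = 42) {
  set.seed(seed)
  w <- shortAxis()
  band1 <- 100 / (1 + (2 * (w - 700) / 12)^2)
  band2 <- 100 / (1 + (2 * (w - 1003) / 12)^2)
  mk <- function(amp) band1 * amp + band2 +
    if (noiseSD > 0) rnorm(length(w), 0, noiseSD) else 0
  y <- vapply(seq_len(2 * nPerClass), function(i)
    mk(1 + (i > nPerClass) * delta / 100), numeric(length(w)))
  meta <- data.frame(
    cell_line = rep(c("classA", "classB"), each = nPerClass),
    cell_id = paste0("c", rep(seq_len(2 * nPerClass))),
    point_index = 0L, scan_index = 0L)
  SpectralDataset(y, w, meta)
}

# small simulation config for pipeline-ish tests
smallSimConfig <- function(seed = 1, ...) {
  simulationConfig(nCellsPerClass = 4L, nPointsPerCell = 4L,
                   axisLo = 600, axisHi = 1400, axisStep = 2,
                   seed = seed, ...)
}

expect_all_equal <- function(a, b, tol = 1e-12)
  expect_true(max(abs(a - b)) <= tol)
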