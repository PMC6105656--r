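# Synthetic live-cell Raman spectra with planted ground truth.
#
# Forward model: each class is a template of Lorentzian/Gaussian bands on
# a smooth polynomial fluorescence baseline (optionally with a broad
# quartz-substrate hump).  Between-cell and within-cell variability are
# multiplicative lognormal factors on band amplitudes; noise is
# shot-like (Gaussian with variance proportional to signal plus a dark
# floor) or additive; cosmic-ray hits are narrow positive excursions at
# Poisson-distributed counts per spectrum.

#' Construct a class template
#'
#' @param classLabel class name.
#' @param bands data.frame with columns `center`, `fwhm`, `amplitude`,
#'   `shape`, `assignment`.
#' @param baselineCoeffs polynomial coefficients (ascending powers) on the
#'   axis rescaled to \[-1, 1\].
#' @param quartzHump amplitude of a broad Gaussian substrate hump at
#'   1450 cm^-1 (FWHM 300); 0 disables.
#' @param highBands band table for the high-wavenumber region (used only
#'   when the rendering axis extends beyond 2700 cm^-1).
#' @return A [ClassTemplate-class].
#' @export
classTemplate <- function(classLabel, bands,
                          baselineCoeffs = numeric(0), quartzHump = 0,
                          highBands = .emptyBands()) {
  new("ClassTemplate", classLabel = classLabel,
      bands = as.data.frame(bands),
      baselineCoeffs = as.numeric(baselineCoeffs),
      quartzHump = as.numeric(quartzHump),
      highBands = as.data.frame(highBands))
}

.emptyBands <- function()
  data.frame(center = numeric(0), fwhm = numeric(0), amplitude = numeric(0),
             shape = character(0), assignment = character(0))

# The 19 fingerprint band centres used for discrimination of human lung
# cells, with their biochemical assignments.
.baseBandTable <- function() {
  data.frame(
    center = c(641, 718, 784, 828, 881, 944, 1003, 1043, 1085, 1166,
               1239, 1264, 1301, 1316, 1440, 1458, 1580, 1658, 1674),
    fwhm = 12,
    amplitude = c(90, 120, 180, 105, 90, 105, 360, 135, 165, 120,
                  180, 210, 255, 165, 330, 210, 135, 390, 180),
    shape = "lorentzian",
    assignment = c("protein", "lipid", "nucleic_acid", "nucleic_acid",
                   "carbohydrate", "carbohydrate", "protein",
                   "carbohydrate", "carbohydrate", "protein", "protein",
                   "lipid", "lipid", "nucleic_acid", "lipid",
                   "nucleic_acid", "protein", "protein", "protein"))
}

.highBandTable <- function() {
  data.frame(
    center = c(2854, 2930, 3250, 3430),
    fwhm = c(30, 35, 180, 200),
    amplitude = c(450, 540, 180, 300),
    shape = c("lorentzian", "lorentzian", "gaussian", "gaussian"),
    assignment = c("lipid", "protein", "water", "water"))
}

.defaultBaselineCoeffs <- function() c(900, -150, 240, 0, 60, 0)

# per-class amplitude multipliers at selected centres (all others 1)
.classEffects <- function() {
  list(
    A549 = c("718" = 1.50, "1264" = 1.50, "1301" = 1.50, "1440" = 1.50,
             "1658" = 1.50, "784" = 0.90),
    MRC5 = c("784" = 1.60, "718" = 0.84, "1264" = 0.84, "1301" = 0.84,
             "1440" = 0.84, "1658" = 0.90, "1003" = 1.10),
    ATCC = c("641" = 1.20, "1003" = 1.20, "1166" = 1.20, "1239" = 1.20,
             "1580" = 1.20, "1674" = 1.20, "881" = 0.90, "944" = 0.90,
             "1043" = 0.90, "1085" = 0.90),
    LONZA = c("881" = 1.24, "944" = 1.24, "1043" = 1.24, "1085" = 1.24,
              "641" = 0.92, "1003" = 0.92, "1166" = 0.92, "1239" = 0.92,
              "1580" = 0.92, "1674" = 0.92),
    PAP243 = c("784" = 1.24, "828" = 1.20, "1316" = 1.20, "1458" = 1.16,
               "881" = 1.10, "944" = 1.10, "1043" = 1.10, "1085" = 1.10,
               "1239" = 1.12))
}

#' Default five-class cell templates
#'
#' Five templates (A549, MRC5, ATCC, LONZA, PAP243) sharing the same 19
#' fingerprint band centres; classes differ only in band amplitudes.  The
#' cancer-like A549 template has elevated lipid bands (718, 1264, 1301,
#' 1440, 1658 cm^-1), the fibroblast-like MRC5 template an elevated
#' DNA/pyrimidine band (784 cm^-1), and the three bronchial-epithelial
#' templates differ pairwise by smaller offsets at protein and
#' carbohydrate bands.
#'
#' @return Named list of five [ClassTemplate-class] objects.
#' @export
defaultTemplates <- function() {
  base <- .baseBandTable()
  hi <- .highBandTable()
  eff <- .classEffects()
  out <- lapply(names(eff), function(cl) {
    b <- base
    e <- eff[[cl]]
    i <- match(as.numeric(names(e)), b$center)
    b$amplitude[i] <- b$amplitude[i] * e
    classTemplate(cl, b, .defaultBaselineCoeffs(), quartzHump = 0,
                  highBands = hi)
  })
  names(out) <- names(eff)
  out
}

# ---- rendering ----

.bandBasis <- function(bands, w) {
  if (!nrow(bands)) return(matrix(0, 0L, length(w)))
  m <- matrix(0, nrow(bands), length(w))
  for (i in seq_len(nrow(bands))) {
    x <- w - bands$center[i]
    f <- bands$fwhm[i]
    m[i, ] <- if (bands$shape[i] == "gaussian")
      exp(-4 * log(2) * x^2 / f^2) else 1 / (1 + (2 * x / f)^2)
  }
  m
}

.templateBands <- function(t, w) {
  b <- t@bands
  if (max(w) > 2700 && nrow(t@highBands)) b <- rbind(b, t@highBands)
  b
}

.baselineEval <- function(t, w) {
  bl <- numeric(length(w))
  if (length(t@baselineCoeffs)) {
    u <- (w - mean(range(w))) / (diff(range(w)) / 2)
    bl <- drop(outer(u, seq_along(t@baselineCoeffs) - 1L, `^`) %*%
                 t@baselineCoeffs)
  }
  if (t@quartzHump > 0)
    bl <- bl + t@quartzHump * exp(-4 * log(2) * (w - 1450)^2 / 300^2)
  bl
}

#' Render a noise-free spectrum from a template
#'
#' Sum of the template's band profiles (Gaussian/Lorentzian closed forms,
#' peak value = amplitude) scaled per band, plus the polynomial baseline,
#' evaluated on the axis.  High-wavenumber bands are included only when
#' the axis extends beyond 2700 cm^-1.  Deterministic.
#'
#' @param t a [ClassTemplate-class].
#' @param wavenumber the rendering axis.
#' @param bandScale per-band multipliers (>= 0), one per row of the active
#'   band table; default all 1.
#' @param baseline include the baseline (default TRUE).
#' @return A one-spectrum [SpectralDataset-class].
#' @export
renderCleanSpectrum <- function(t, wavenumber, bandScale = NULL,
                                baseline = TRUE) {
  bands <- .templateBands(t, wavenumber)
  if (is.null(bandScale)) bandScale <- rep(1, nrow(bands))
  if (length(bandScale) == 1L) bandScale <- rep(bandScale, nrow(bands))
  if (length(bandScale) != nrow(bands))
    stop(sprintf("bandScale has %d values for %d bands",
                 length(bandScale), nrow(bands)), call. = FALSE)
  if (any(bandScale < 0)) stop("bandScale must be >= 0", call. = FALSE)
  y <- drop(crossprod(.bandBasis(bands, wavenumber),
                      bands$amplitude * bandScale))
  if (baseline) y <- y + .baselineEval(t, wavenumber)
  Spectrum(wavenumber, y, cell_line = t@classLabel,
           excitation_nm = if (max(wavenumber) > 1800) 488 else 785)
}

# lognormal multipliers with mean 1 and coefficient of variation cv
.lognormMult <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  exp(stats::rnorm(n, -s2 / 2, sqrt(s2)))
}

.noiseSD <- function(clean, noiseModel, noiseScale, darkFloor) {
  if (noiseScale <= 0) return(array(0, dim(clean)))
  if (noiseModel == "shot")
    noiseScale * sqrt(pmax(clean, 0) + darkFloor)
  else array(noiseScale, dim(clean))
}

.injectCosmicRays <- function(y, sd, rate, ampRange) {
  # y, sd: wavenumber x spectra; returns list(y, spikes per spectrum)
  spikes <- vector("list", ncol(y))
  if (rate <= 0) return(list(y = y, spikes = spikes))
  p <- nrow(y)
  for (j in seq_len(ncol(y))) {
    ns <- stats::rpois(1L, rate)
    idx <- integer(0)
    for (s in seq_len(ns)) {
      width <- sample(1:3, 1L)
      start <- sample(seq_len(p - width + 1L), 1L)
      localSD <- max(sd[start, j], 1)
      amp <- stats::runif(1L, ampRange[1L], ampRange[2L]) * localSD
      pts <- start:(start + width - 1L)
      y[pts, j] <- y[pts, j] + amp * 0.5^(seq_len(width) - 1L)
      idx <- c(idx, pts)
    }
    spikes[[j]] <- sort(unique(idx))
  }
  list(y = y, spikes = spikes)
}

#' Simulation configuration
#'
#' Defaults reproduce the study conditions: five classes, 30 cells per
#' class, 10 line-scan points per cell (1500 spectra), fingerprint axis
#' 600-1800 cm^-1 at 1 cm^-1 spacing, lognormal between-cell (CV 0.06)
#' and within-cell (CV 0.08) band-amplitude variability, shot-like noise
#' and sparse cosmic-ray spikes.
#'
#' @param axisLo,axisHi,axisStep wavenumber grid specification (cm^-1).
#' @param templates list of [ClassTemplate-class] objects.
#' @param nCellsPerClass,nPointsPerCell replicate structure.
#' @param cellAmplitudeCV,pointAmplitudeCV lognormal coefficients of
#'   variation of the between-cell and within-cell per-band amplitude
#'   multipliers.
#' @param noiseModel `"shot"` (sd = scale * sqrt(signal + dark)) or
#'   `"additive"` (constant sd = scale).
#' @param noiseScale,darkFloor noise parameters (counts).
#' @param cosmicRayRate expected spikes per spectrum (Poisson).
#' @param cosmicRayAmplitudeRange spike amplitude range in multiples of
#'   the local noise sd.
#' @param seed RNG seed; the seed fully determines the output.
#' @return A validated config list of class `"SimulationConfig"`.
#' @export
simulationConfig <- function(axisLo = 600, axisHi = 1800, axisStep = 1,
                             templates = defaultTemplates(),
                             nCellsPerClass = 30L, nPointsPerCell = 10L,
                             cellAmplitudeCV = 0.06,
                             pointAmplitudeCV = 0.08,
                             noiseModel = c("shot", "additive"),
                             noiseScale = 0.5, darkFloor = 50,
                             cosmicRayRate = 0.2,
                             cosmicRayAmplitudeRange = c(10, 40),
                             seed = 0L) {
  noiseModel <- match.arg(noiseModel)
  stopifnot(axisLo < axisHi, axisStep > 0, length(templates) >= 1L,
            nCellsPerClass >= 1L, nPointsPerCell >= 1L,
            cellAmplitudeCV >= 0, pointAmplitudeCV >= 0, noiseScale >= 0,
            darkFloor >= 0, cosmicRayRate >= 0,
            cosmicRayAmplitudeRange[1L] <= cosmicRayAmplitudeRange[2L])
  structure(list(axisLo = axisLo, axisHi = axisHi, axisStep = axisStep,
                 templates = templates,
                 nCellsPerClass = as.integer(nCellsPerClass),
                 nPointsPerCell = as.integer(nPointsPerCell),
                 cellAmplitudeCV = cellAmplitudeCV,
                 pointAmplitudeCV = pointAmplitudeCV,
                 noiseModel = noiseModel, noiseScale = noiseScale,
                 darkFloor = darkFloor, cosmicRayRate = cosmicRayRate,
                 cosmicRayAmplitudeRange = cosmicRayAmplitudeRange,
                 seed = as.integer(seed)),
            class = "SimulationConfig")
}

#' Simulate a labelled multi-class line-scan dataset
#'
#' For every class and cell, a per-cell band-amplitude multiplier vector
#' is drawn once (lognormal, CV `cellAmplitudeCV`); each line-scan point
#' additionally draws per-band within-cell multipliers (CV
#' `pointAmplitudeCV`).  Spectra are band sums plus baseline plus noise,
#' with cosmic-ray spikes injected as 1-3 point positive excursions.
#' Identical seeds give identical output.
#'
#' @param cfg a [simulationConfig()].
#' @return `list(dataset, truth)`; `truth` carries the per-spectrum class,
#'   cell id and planted band amplitudes, per-spectrum spike positions,
#'   and (when spikes are active) the pre-spike intensity matrix.
#' @export
simulateDataset <- function(cfg = simulationConfig()) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  set.seed(cfg$seed)
  w <- seq(cfg$axisLo, cfg$axisHi, by = cfg$axisStep)
  perClass <- cfg$nCellsPerClass * cfg$nPointsPerCell
  exc <- if (max(w) > 1800) 488 else 785
  mats <- list(); metas <- list(); amps <- list(); spikes <- list()
  for (t in cfg$templates) {
    bands <- .templateBands(t, w)
    basis <- .bandBasis(bands, w)                      # nb x p
    bl <- .baselineEval(t, w)
    nb <- nrow(bands)
    A <- matrix(0, perClass, nb)
    cellIds <- sprintf("%s_c%02d", t@classLabel, seq_len(cfg$nCellsPerClass))
    for (ci in seq_len(cfg$nCellsPerClass)) {
      cellMult <- .lognormMult(nb, cfg$cellAmplitudeCV)
      for (pi in seq_len(cfg$nPointsPerCell)) {
        row <- (ci - 1L) * cfg$nPointsPerCell + pi
        A[row, ] <- bands$amplitude * cellMult *
          .lognormMult(nb, cfg$pointAmplitudeCV)
      }
    }
    clean <- t(A %*% basis) + bl                       # p x perClass
    sd <- .noiseSD(clean, cfg$noiseModel, cfg$noiseScale, cfg$darkFloor)
    noisy <- clean + if (cfg$noiseScale > 0)
      matrix(stats::rnorm(length(clean), 0, sd), nrow(clean)) else 0
    cr <- .injectCosmicRays(noisy, sd, cfg$cosmicRayRate,
                            cfg$cosmicRayAmplitudeRange)
    mats[[t@classLabel]] <- list(final = cr$y, prespike = noisy)
    spikes[[t@classLabel]] <- cr$spikes
    amps[[t@classLabel]] <- A
    metas[[t@classLabel]] <- data.frame(
      cell_line = t@classLabel,
      cell_id = rep(cellIds, each = cfg$nPointsPerCell),
      point_index = rep(seq_len(cfg$nPointsPerCell) - 1L,
                        cfg$nCellsPerClass),
      scan_index = 0L, excitation_nm = exc, exposure_s = 1,
      accumulations = 30L)
  }
  y <- do.call(cbind, lapply(mats, `[[`, "final"))
  meta <- do.call(rbind, metas)
  rownames(meta) <- NULL
  d <- SpectralDataset(y, w, meta)
  truth <- list(
    spectra = meta[, c("cell_line", "cell_id", "point_index")],
    bandAmplitudes = do.call(rbind, amps),
    centers = .templateBands(cfg$templates[[1L]], w)$center,
    spikes = do.call(c, unname(spikes)))
  if (cfg$cosmicRayRate > 0)
    truth$prespike <- do.call(cbind, lapply(mats, `[[`, "prespike"))
  list(dataset = d, truth = truth)
}

# ---- hyperspectral map simulation ----

#' Default cell region layout for simulated area scans
#'
#' An elliptical cell with an elliptical nucleus and two circular lipid
#' droplets (one on the horizontal midline so a line scan through the
#' cell centre crosses it) on a background field.
#'
#' @param nx,ny grid size in pixels.
#' @return Character vector of length `nx * ny` (x varying fastest) with
#'   values in `background`, `cytoplasm`, `nucleus`, `lipid_droplet`.
#' @export
defaultRegionLayout <- function(nx, ny) {
  ix <- rep(seq_len(nx), ny); iy <- rep(seq_len(ny), each = nx)
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  inEll <- function(x0, y0, rx, ry) ((ix - x0) / rx)^2 + ((iy - y0) / ry)^2 <= 1
  lay <- rep("background", nx * ny)
  lay[inEll(cx, cy, 0.40 * nx, 0.36 * ny)] <- "cytoplasm"
  lay[inEll(cx - 0.12 * nx, cy, 0.16 * nx, 0.15 * ny)] <- "nucleus"
  rd <- max(1.5, 0.07 * nx)
  lay[(ix - (cx + 0.24 * nx))^2 + (iy - cy)^2 <= rd^2 &
        lay != "background"] <- "lipid_droplet"
  lay[(ix - (cx + 0.10 * nx))^2 + (iy - (cy - 0.22 * ny))^2 <= rd^2 &
        lay != "background"] <- "lipid_droplet"
  lay
}

.regionMultipliers <- function() list(
  background = c(lipid = 0, protein = 0, nucleic_acid = 0,
                 carbohydrate = 0, water = 0),
  cytoplasm = c(lipid = 1, protein = 1, nucleic_acid = 1,
                carbohydrate = 1, water = 1),
  nucleus = c(lipid = 0.5, protein = 1.1, nucleic_acid = 2.5,
              carbohydrate = 1, water = 1),
  lipid_droplet = c(lipid = 4, protein = 0.8, nucleic_acid = 0.5,
                    carbohydrate = 0.8, water = 0.6))

#' Simulate a hyperspectral area scan of one cell
#'
#' Pixels are rendered from region-specific band multipliers (lipid
#' droplets: lipid bands strongly elevated; nucleus: nucleic-acid bands
#' elevated; background: baseline only) plus noise; the ground truth
#' stores the region label per pixel.
#'
#' @param t a [ClassTemplate-class].
#' @param gridShape integer(2) `(nx, ny)`.
#' @param stepUm spatial step, micrometres.
#' @param regionLayout per-pixel region labels (default
#'   [defaultRegionLayout()]).
#' @param axisLo,axisHi,axisStep rendering axis.
#' @param noiseModel,noiseScale,darkFloor noise controls as in
#'   [simulationConfig()].
#' @param pixelCV lognormal per-pixel, per-band amplitude CV.
#' @param seed RNG seed.
#' @param regionMultipliers optional named list overriding the per-region,
#'   per-assignment multipliers.
#' @return `list(map, truth)` with `truth$region` the planted label per
#'   pixel.
#' @export
simulateMap <- function(t, gridShape = c(20L, 20L), stepUm = 0.5,
                        regionLayout = NULL,
                        axisLo = 600, axisHi = 1800, axisStep = 1,
                        noiseModel = c("shot", "additive"),
                        noiseScale = 0.5, darkFloor = 50, pixelCV = 0.05,
                        seed = 0L, regionMultipliers = NULL) {
  noiseModel <- match.arg(noiseModel)
  set.seed(seed)
  nx <- as.integer(gridShape[1L]); ny <- as.integer(gridShape[2L])
  if (is.null(regionLayout)) regionLayout <- defaultRegionLayout(nx, ny)
  stopifnot(length(regionLayout) == nx * ny)
  mult <- regionMultipliers %||% .regionMultipliers()
  bad <- setdiff(unique(regionLayout), names(mult))
  if (length(bad))
    stop("unknown region label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  w <- seq(axisLo, axisHi, by = axisStep)
  bands <- .templateBands(t, w)
  basis <- .bandBasis(bands, w)
  bl <- .baselineEval(t, w)
  nb <- nrow(bands)
  A <- matrix(0, nx * ny, nb)
  for (j in seq_len(nx * ny)) {
    m <- mult[[regionLayout[j]]]
    A[j, ] <- bands$amplitude * unname(m[bands$assignment]) *
      .lognormMult(nb, pixelCV)
  }
  clean <- t(A %*% basis) + bl
  sd <- .noiseSD(clean, noiseModel, noiseScale, darkFloor)
  y <- clean + if (noiseScale > 0)
    matrix(stats::rnorm(length(clean), 0, sd), nrow(clean)) else 0
  map <- HyperspectralMap(y, w, c(nx, ny), stepUm)
  truth <- list(region = regionLayout,
                x = rep(seq_len(nx), ny), y = rep(seq_len(ny), each = nx),
                bandAmplitudes = A, centers = bands$center,
                assignments = bands$assignment)
  list(map = map, truth = truth)
}

# ---- photodamage time series ----

.parseRatioName <- function(nm) {
  m <- regmatches(nm, regexec("^I\\((\\d+(?:\\.\\d+)?)/(\\d+(?:\\.\\d+)?)\\)$",
                              nm))[[1L]]
  if (length(m) != 3L)
    stop("cannot parse ratio name '", nm, "' (expected I(a/b))",
         call. = FALSE)
  c(a = as.numeric(m[2L]), b = as.numeric(m[3L]))
}

.cleanPeak <- function(t, w, center, bandScale, halfWindow = 8) {
  sel <- which(w >= center - halfWindow & w <= center + halfWindow)
  bands <- .templateBands(t, w)
  max(drop(crossprod(.bandBasis(bands, w[sel]),
                     bands$amplitude * bandScale)))
}

#' Simulate repeated line scans with planted intensity-ratio trends
#'
#' Emulates photodamage monitoring: one averaged line-scan spectrum per
#' repeat scan, where each named peak-intensity ratio I(a/b) changes
#' linearly with the scan index by adjusting the numerator band's
#' amplitude (other bands held fixed).  Eight scans mirror the 785 nm
#' protocol, four the 488 nm protocol.
#'
#' @param t a [ClassTemplate-class].
#' @param nScans number of repeat scans (>= 2).
#' @param plantedSlopes named numeric vector; names like `"I(1003/1301)"`,
#'   values the per-scan-index slope of the ratio.
#' @param axisLo,axisHi,axisStep rendering axis; extend beyond 2700 to
#'   reach CH-stretch ratios such as I(2854/2930).
#' @param noiseModel,noiseScale,darkFloor noise controls.
#' @param includeBaseline add the template baseline (spectra then need
#'   baseline subtraction before ratio analysis).
#' @param seed RNG seed.
#' @return `list(dataset, truth)`; `truth$slopes` are the planted slopes,
#'   `truth$intercepts` the scan-1 ratio values.
#' @export
simulatePhotodamageSeries <- function(t, nScans = 8L,
                                      plantedSlopes = c("I(1003/1301)" = 0),
                                      axisLo = 600, axisHi = 1800,
                                      axisStep = 1,
                                      noiseModel = c("additive", "shot"),
                                      noiseScale = 0.01, darkFloor = 50,
                                      includeBaseline = FALSE, seed = 0L) {
  noiseModel <- match.arg(noiseModel)
  stopifnot(nScans >= 2L)
  set.seed(seed)
  w <- seq(axisLo, axisHi, by = axisStep)
  bands <- .templateBands(t, w)
  ratios <- lapply(names(plantedSlopes), .parseRatioName)
  numIdx <- vapply(ratios, function(r) {
    i <- which(abs(bands$center - r["a"]) < 2)
    if (!length(i))
      stop("no template band at ", r["a"], " cm^-1", call. = FALSE)
    i[1L]
  }, 0L)
  denIdx <- vapply(ratios, function(r) {
    i <- which(abs(bands$center - r["b"]) < 2)
    if (!length(i))
      stop("no template band at ", r["b"], " cm^-1", call. = FALSE)
    i[1L]
  }, 0L)
  if (length(intersect(numIdx, denIdx)))
    stop("a planted ratio's numerator band is another's denominator",
         call. = FALSE)
  ones <- rep(1, nrow(bands))
  r0 <- vapply(seq_along(ratios), function(i)
    .cleanPeak(t, w, ratios[[i]]["a"], ones) /
      .cleanPeak(t, w, ratios[[i]]["b"], ones), 0)
  names(r0) <- names(plantedSlopes)
  mats <- vector("list", nScans)
  for (k in seq_len(nScans)) {
    sc <- ones
    # secant solve: band tails couple the peak windows weakly, so a few
    # passes pin every planted windowed-max ratio to its target
    for (pass in 1:8) for (i in seq_along(ratios)) {
      target <- r0[i] + plantedSlopes[i] * (k - 1L)
      den <- .cleanPeak(t, w, ratios[[i]]["b"], sc)
      num <- .cleanPeak(t, w, ratios[[i]]["a"], sc)
      zero <- sc; zero[numIdx[i]] <- 0
      unit <- (num - .cleanPeak(t, w, ratios[[i]]["a"], zero)) /
        max(sc[numIdx[i]], 1e-9)
      s <- sc[numIdx[i]] + (target * den - num) / unit
      if (s < 0)
        stop("planted slope drives band ", bands$center[numIdx[i]],
             " negative by scan ", k, call. = FALSE)
      sc[numIdx[i]] <- s
    }
    clean <- drop(crossprod(.bandBasis(bands, w), bands$amplitude * sc))
    if (includeBaseline) clean <- clean + .baselineEval(t, w)
    sd <- .noiseSD(matrix(clean), noiseModel, noiseScale, darkFloor)
    mats[[k]] <- clean + if (noiseScale > 0)
      stats::rnorm(length(clean), 0, sd) else 0
  }
  y <- do.call(cbind, mats)
  meta <- data.frame(cell_line = t@classLabel, cell_id = "cell1",
                     point_index = 0L, scan_index = seq_len(nScans),
                     excitation_nm = if (max(w) > 1800) 488 else 785,
                     exposure_s = 1, accumulations = 30L)
  list(dataset = SpectralDataset(y, w, meta),
       truth = list(slopes = plantedSlopes, intercepts = r0))
}
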