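test_that("default templates share the 19 discriminatory band centres", {
  tms <- defaultTemplates()
  expect_length(tms, 5L)
  centers <- c(641, 718, 784, 828, 881, 944, 1003, 1043, 1085, 1166,
               1239, 1264, 1301, 1316, 1440, 1458, 1580, 1658, 1674)
  for (t in tms) expect_equal(t@bands$center, centers)
  # class structure: cancer-like template lipid-rich, fibroblast-like
  # DNA-rich
  amp <- function(t, ctr) t@bands$amplitude[t@bands$center == ctr]
  expect_gt(amp(tms$A549, 1301), amp(tms$MRC5, 1301))
  expect_gt(amp(tms$MRC5, 784), amp(tms$A549, 784))
  # the three bronchial-epithelial templates differ pairwise but by
  # smaller offsets than the A549/MRC5 lipid contrast
  hb <- c("ATCC", "LONZA", "PAP243")
  for (i in 1:2) for (j in (i + 1):3) {
    a <- tms[[hb[i]]]@bands$amplitude; b <- tms[[hb[j]]]@bands$amplitude
    expect_true(any(a != b))
    expect_lt(max(abs(a / b - 1)), amp(tms$A549, 1301) /
                amp(tms$MRC5, 1301) - 1)
  }
})

test_that("clean rendering obeys the closed-form band model", {
  w <- shortAxis(1)
  t <- classTemplate("g", data.frame(center = 850, fwhm = 20,
                                     amplitude = 5, shape = "gaussian",
                                     assignment = "protein"))
  y <- intensities(renderCleanSpectrum(t, w))[, 1L]
  expect_equal(max(y), 5)                       # peak = amplitude
  expect_equal(w[which.max(y)], 850)
  expect_equal(y[w == 860], 5 * 2^(-(10 / 10)^2))  # gaussian closed form
  # zero multipliers and no baseline -> all-zero spectrum
  y0 <- intensities(renderCleanSpectrum(t, w, bandScale = 0))[, 1L]
  expect_true(all(y0 == 0))
  # linearity: doubling the multiplier doubles the band
  y2 <- intensities(renderCleanSpectrum(t, w, bandScale = 2))[, 1L]
  expect_all_equal(y2, 2 * y)
  expect_error(renderCleanSpectrum(t, w, bandScale = c(1, 1)), "1 bands")
})

test_that("simulateDataset honours replicate structure and determinism", {
  cfg <- smallSimConfig(seed = 11)
  sim <- simulateDataset(cfg)
  expect_equal(nSpectra(sim$dataset), 5L * 4L * 4L)
  expect_equal(unname(table(classLabels(sim$dataset))[["A549"]]), 16L)
  # grouping by (cell_line, cell_id) partitions rows into cells of 4
  grp <- table(paste(colData(sim$dataset)$cell_line,
                     colData(sim$dataset)$cell_id))
  expect_true(all(grp == 4L))
  sim2 <- simulateDataset(smallSimConfig(seed = 11))
  expect_identical(intensities(sim$dataset), intensities(sim2$dataset))
  sim3 <- simulateDataset(smallSimConfig(seed = 12))
  expect_false(identical(intensities(sim$dataset),
                         intensities(sim3$dataset)))
})

test_that("degenerate config collapses each class to one spectrum", {
  cfg <- smallSimConfig(seed = 1, cellAmplitudeCV = 0,
                        pointAmplitudeCV = 0, noiseScale = 0,
                        cosmicRayRate = 0)
  y <- intensities(simulateDataset(cfg)$dataset)
  for (cl in unique(classLabels(simulateDataset(cfg)$dataset))) {
    cols <- which(classLabels(simulateDataset(cfg)$dataset) == cl)
    expect_all_equal(y[, cols[1L]], y[, cols[length(cols)]])
  }
})

test_that("noise- and spike-free simulation survives conditioning to 1%", {
  # despike + baseline subtraction leave the planted band shapes intact
  # (bands separated enough that the polynomial baseline is identifiable)
  b <- isolatedTemplate()@bands
  b$shape <- "gaussian"        # compact tails keep the baseline identifiable
  t <- classTemplate("toy", b, baselineCoeffs = c(900, -150, 240, 0, 60, 0))
  cfg <- simulationConfig(templates = list(t), nCellsPerClass = 2,
                          nPointsPerCell = 2, axisLo = 600, axisHi = 1800,
                          axisStep = 2, cellAmplitudeCV = 0,
                          pointAmplitudeCV = 0, noiseScale = 0,
                          cosmicRayRate = 0, seed = 3)
  sim <- simulateDataset(cfg)
  cond <- subtractBaseline(despike(sim$dataset))
  w <- wavenumbers(sim$dataset)
  clean <- intensities(renderCleanSpectrum(t, w, baseline = FALSE))[, 1L]
  got <- intensities(cond)[, 1L]
  expect_lt(max(abs(got - clean)), 0.01 * max(clean))
})

test_that("simulated maps have the documented region structure", {
  t <- defaultTemplates()$A549
  out <- simulateMap(t, gridShape = c(20, 20), noiseScale = 0,
                     pixelCV = 0, seed = 5)
  expect_equal(nSpectra(out$map), 400L)
  expect_s4_class(out$map, "HyperspectralMap")
  expect_setequal(unique(out$truth$region),
                  c("background", "cytoplasm", "nucleus", "lipid_droplet"))
  # droplet pixels carry more lipid CH2-bend signal than cytoplasm
  img <- sumFilter(out$map, 1420, 1460)
  expect_gt(min(img@values[out$truth$region == "lipid_droplet"]),
            max(img@values[out$truth$region == "cytoplasm"]))
  expect_error(simulateMap(t, regionLayout = rep("blob", 400)),
               "unknown region")
})

test_that("background-only maps contain baseline and noise only", {
  t <- defaultTemplates()$A549
  out <- simulateMap(t, gridShape = c(5, 5), noiseScale = 0.5,
                     regionLayout = rep("background", 25), seed = 2)
  w <- wavenumbers(out$map)
  bl <- intensities(renderCleanSpectrum(t, w, bandScale = 0))[, 1L]
  resid <- intensities(out$map) - bl
  sd <- 0.5 * sqrt(pmax(bl, 0) + 50)
  expect_lt(max(abs(resid) / sd), 5)    # no band exceeds noise 5 sigma
})

test_that("photodamage series plant linear ratio trends exactly", {
  t <- isolatedTemplate()
  # zero slope, zero noise: ratios constant across scans
  s0 <- simulatePhotodamageSeries(t, nScans = 8,
                                  plantedSlopes = c("I(1003/850)" = 0),
                                  noiseScale = 0, seed = 1)
  r0 <- ratioSeries(s0$dataset, "I(1003/850)")
  expect_lt(diff(range(r0$value)), 1e-9)
  # planted slope, zero noise: ratios exactly linear in scan index
  s1 <- simulatePhotodamageSeries(t, nScans = 8,
                                  plantedSlopes = c("I(1003/850)" = 0.03),
                                  noiseScale = 0, seed = 1)
  r1 <- ratioSeries(s1$dataset, "I(1003/850)")
  f <- fitTrend(r1)
  expect_equal(f@slope, 0.03, tolerance = 1e-6)
  expect_equal(f@rSquared, 1, tolerance = 1e-9)
  # scan-count presets: 4 mirrors 488 nm, 8 mirrors 785 nm
  expect_equal(nSpectra(simulatePhotodamageSeries(t, nScans = 4,
    plantedSlopes = c("I(1003/850)" = 0), noiseScale = 0)$dataset), 4L)
  expect_error(simulatePhotodamageSeries(t, plantedSlopes = c(oops = 0.1)),
               "parse")
  expect_error(simulatePhotodamageSeries(t,
    plantedSlopes = c("I(999/850)" = 0.1)), "no template band")
})

test_that("noisy planted slopes are recovered within 2 standard errors", {
  t <- isolatedTemplate()
  s <- simulatePhotodamageSeries(t, nScans = 8,
                                 plantedSlopes = c("I(1003/850)" = 0.03),
                                 noiseScale = 0.01, seed = 1)
  f <- fitTrend(ratioSeries(s$dataset, "I(1003/850)"))
  expect_lt(abs(f@slope - 0.03), 2 * f@slopeSE + 1e-12)
})

test_that("larger planted class offsets cannot hurt recovery on average", {
  mkTemplates <- function(delta) {
    base <- data.frame(center = c(700, 784, 850, 1003, 1050),
                       fwhm = 12, amplitude = c(120, 150, 90, 300, 100),
                       shape = "lorentzian",
                       assignment = c("lipid", "nucleic_acid", "lipid",
                                      "protein", "carbohydrate"))
    up <- base
    up$amplitude <- up$amplitude * c(1 + delta, 1 - delta, 1, 1, 1)
    list(classTemplate("low", base), classTemplate("high", up))
  }
  accFor <- function(delta, seed) {
    cfg <- simulationConfig(templates = mkTemplates(delta),
                            nCellsPerClass = 6, nPointsPerCell = 4,
                            axisLo = 600, axisHi = 1200, axisStep = 2,
                            noiseModel = "additive", noiseScale = 4,
                            cosmicRayRate = 0, seed = seed)
    sp <- splitEveryFourth(simulateDataset(cfg)$dataset)
    m <- fitPLSDA(sp$calibration, 2)
    pr <- predict(m, averageByCell(sp$validation))
    mean(pr$class == classLabels(averageByCell(sp$validation)))
  }
  seeds <- 1:10
  weak <- vapply(seeds, function(s) accFor(0.05, s), 0)
  strong <- vapply(seeds, function(s) accFor(0.25, s), 0)
  expect_gte(mean(strong), mean(weak))
})
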