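# End-to-end orchestration: config -> simulate (or load) -> condition ->
# crop -> split -> cross-validate -> fit -> report.

.stageSeed <- function(seed, stage) {
  (as.integer(seed) +
     sum(utf8ToInt(stage) * seq_len(nchar(stage))) * 131L) %% 2147483647L
}

.readRunConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  hasSim <- !is.null(config$simulate)
  hasInput <- !is.null(config$input)
  if (hasSim == hasInput)
    stop("config must contain exactly one of 'simulate' or 'input'",
         call. = FALSE)
  config$seed <- as.integer(config$seed %||% 0L)
  config
}

.logStage <- function(stage, ...)
  message(sprintf("[%s] %s", stage, sprintf(...)))

# deterministic fingerprint of the run configuration (provenance only)
.configHash <- function(config) {
  chars <- utf8ToInt(paste(deparse(config), collapse = "\n"))
  sprintf("%08x", sum(chars * (seq_along(chars) %% 991 + 1)) %% 4294967291)
}

.writeCSV <- function(x, path) {
  utils::write.csv(format(as.data.frame(x), digits = 12, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  path
}

.loadOrSimulate <- function(config) {
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    args <- sim[intersect(names(sim), names(formals(simulationConfig)))]
    args$seed <- .stageSeed(config$seed, "simulate")
    out <- simulateDataset(do.call(simulationConfig, args))
    .logStage("simulate", "%d spectra, %d classes, seed %d",
              ncol(out$dataset), length(unique(classLabels(out$dataset))),
              args$seed)
    out
  } else {
    d <- readSpectralDataset(config$input$matrix, config$input$meta)
    .logStage("load", "%d spectra from %s", ncol(d), config$input$matrix)
    list(dataset = d, truth = NULL)
  }
}

#' Run the full identification analysis
#'
#' Executes the complete pipeline: simulate (or load) -> despike ->
#' baseline subtraction -> Savitzky-Golay smoothing -> crop to the
#' fingerprint window -> every-fourth calibration/validation split ->
#' venetian-blinds cross-validation -> latent-variable selection ->
#' PLS-DA fit -> classification reports at the spectrum and cell level
#' plus VIP scores, writing every artifact (CSV/JSON) with provenance.
#' Fully deterministic for a fixed config.
#'
#' @param config a run configuration: a YAML file path or a list with
#'   exactly one of `simulate` (arguments of [simulationConfig()]) or
#'   `input` (`matrix`/`meta` file paths), plus optional `seed`, `crop`
#'   (`lo`, `hi`), `plsda` (`nLVMax`, `nSplits`, `targetError`,
#'   `derivWidth`) and `level` (`"spectrum"`, `"cell"` or `"both"`).
#' @param outDir output directory (created if needed).
#' @return Invisibly, a list with the written file paths and the fitted
#'   objects (`model`, `cvCurve`, `selection`, `reports`, `vip`).
#' @export
runFullAnalysis <- function(config, outDir) {
  config <- .readRunConfig(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  failed <- TRUE
  on.exit(if (failed) unlink(written), add = TRUE)  # drop partial outputs
  sim <- .loadOrSimulate(config)
  d <- sim$dataset
  n0 <- ncol(d)
  d <- applyRecipe(d, recipeConditioning())
  stopifnot(ncol(d) == n0)          # conditioning never drops spectra
  .logStage("condition", "despike + baseline + smooth on %d spectra",
            ncol(d))
  crop <- config$crop %||% list(lo = 600, hi = 1800)
  d <- cropAxis(d, crop$lo, crop$hi)
  .logStage("crop", "axis restricted to [%g, %g] cm^-1, %d points",
            crop$lo, crop$hi, nrow(d))
  sp <- splitEveryFourth(d)
  .logStage("split", "calibration %d / validation %d spectra",
            ncol(sp$calibration), ncol(sp$validation))
  pl <- config$plsda %||% list()
  recipe <- recipePLSDA(width = pl$derivWidth %||% 15L)
  nSplits <- pl$nSplits %||% 10L
  cvCurve <- venetianCV(sp$calibration, pl$nLVMax %||% 10L, nSplits,
                        recipe)
  sel <- selectNLV(cvCurve, pl$targetError %||% 0.05)
  .logStage("select", "%d latent variables (target met: %s)", sel$nLV,
            sel$metTarget)
  model <- fitPLSDA(sp$calibration, sel$nLV, recipe)
  levels <- switch(config$level %||% "both",
                   both = c("spectrum", "cell"),
                   spectrum = "spectrum", cell = "cell")
  reports <- lapply(levels, function(lv)
    classificationReport(model, sp$calibration, sp$validation, lv,
                         nSplits))
  names(reports) <- levels
  vip <- vipScores(model)
  written <- c(written, .writeCSV(cvCurve, file.path(outDir,
                                                     "error_curve.csv")))
  for (lv in levels) {
    rp <- reports[[lv]]
    written <- c(written,
      .writeCSV(rp@perClass,
                file.path(outDir, sprintf("report_%s.csv", lv))),
      .writeCSV(cbind(true_class = rownames(rp@confusion),
                      as.data.frame(rp@confusion)),
                file.path(outDir, sprintf("confusion_%s.csv", lv))))
    .logStage("report", "%s level: error average %.3f", lv,
              rp@errorAverage)
  }
  written <- c(written,
    .writeCSV(data.frame(wavenumber = vip@wavenumber, vip = vip@vip),
              file.path(outDir, "vip.csv")))
  prov <- list(config_hash = .configHash(config), seed = config$seed,
               n_spectra = n0, n_lv = sel$nLV,
               met_target = sel$metTarget,
               crop = unlist(crop), recipe = recipeSummary(recipe),
               package_version = as.character(
                 utils::packageVersion("RamanCellID")))
  provPath <- file.path(outDir, "provenance.json")
  jsonlite::write_json(prov, provPath, auto_unbox = TRUE, digits = NA)
  written <- c(written, provPath)
  failed <- FALSE
  invisible(list(files = written, model = model, cvCurve = cvCurve,
                 selection = sel, reports = reports, vip = vip,
                 split = sp, truth = sim$truth))
}

#' Run the hyperspectral map analysis
#'
#' Simulates (or loads) an area scan, writes band sum-filter images,
#' segments the map with Manhattan k-medians under the derivative
#' pre-mode, and writes the label image, per-cluster mean spectra and
#' background-subtracted cluster spectra.
#'
#' @param config a YAML path or list with exactly one of `simulate`
#'   (arguments of [simulateMap()]; a `template` name from
#'   [defaultTemplates()] may be given) or `input` (`matrix` path), plus
#'   optional `seed`, `k` (default 4), and `sumFilterBands` (list of
#'   `(lo, hi)` pairs, default `list(c(1420, 1460))`).
#' @param outDir output directory.
#' @return Invisibly, a list with file paths, the
#'   [ClusterResult-class], the map, and the simulation truth.
#' @export
runMapAnalysis <- function(config, outDir) {
  config <- .readRunConfig(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    tmpl <- sim$template %||% "A549"
    if (is.character(tmpl)) tmpl <- defaultTemplates()[[tmpl]]
    args <- sim[intersect(names(sim), names(formals(simulateMap)))]
    args$t <- tmpl
    args$seed <- .stageSeed(config$seed, "map")
    out <- do.call(simulateMap, args)
    m <- out$map; truth <- out$truth
    .logStage("simulate", "map %d x %d pixels", m@gridShape[1L],
              m@gridShape[2L])
  } else {
    m <- readSpectralDataset(config$input$matrix, config$input$meta)
    if (!is(m, "HyperspectralMap"))
      stop("input matrix is not a flattened map (no grid_shape comment)",
           call. = FALSE)
    truth <- NULL
  }
  k <- config$k %||% 4L
  written <- character(0)
  bands <- config$sumFilterBands %||% list(c(1420, 1460))
  for (b in bands) {
    img <- sumFilter(m, b[[1L]], b[[2L]])
    written <- c(written, .writeCSV(
      as.data.frame(as.matrix(img)),
      file.path(outDir, sprintf("sum_filter_%g_%g.csv", b[[1L]],
                                b[[2L]]))))
  }
  cr <- kmeansManhattan(m, k, seed = .stageSeed(config$seed, "kmedians"))
  .logStage("segment", "k = %d, sizes %s", k,
            paste(cr@sizes, collapse = "/"))
  written <- c(written,
    .writeCSV(as.data.frame(matrix(cr@pixelLabels,
                                   nrow = m@gridShape[1L])),
              file.path(outDir, "labels.csv")),
    .writeCSV(cbind(wavenumber = wavenumbers(m), cr@clusterSpectra),
              file.path(outDir, "cluster_spectra.csv")))
  if (k > 1L)
    written <- c(written, .writeCSV(
      cbind(wavenumber = wavenumbers(m),
            subtractBackgroundCluster(cr, m, 1L)),
      file.path(outDir, "cluster_spectra_bg_subtracted.csv")))
  invisible(list(files = written, clusters = cr, map = m, truth = truth))
}
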