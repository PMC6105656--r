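#' Construct a SpectralDataset
#'
#' @param intensity numeric matrix, wavenumbers x spectra (one column per
#'   spectrum).  A plain vector is treated as a single spectrum.
#' @param wavenumber strictly increasing numeric axis in cm^-1, one value
#'   per intensity row.
#' @param meta `data.frame` (or `DataFrame`) with one row per spectrum.
#'   Missing required columns (`cell_line`, `cell_id`, `point_index`,
#'   `scan_index`) are filled with defaults; `excitation_nm`,
#'   `exposure_s` and `accumulations` are optional acquisition fields.
#'
#' @return A [SpectralDataset-class].
#' @examples
#' w <- seq(600, 1800, by = 5)
#' d <- SpectralDataset(matrix(rexp(length(w) * 3), ncol = 3), w)
#' nSpectra(d)
#' @export
SpectralDataset <- function(intensity, wavenumber, meta = NULL) {
  if (is.vector(intensity)) intensity <- matrix(intensity, ncol = 1L)
  intensity <- as.matrix(intensity)
  n <- ncol(intensity)
  meta <- .completeMeta(meta, n)
  colnames(intensity) <- rownames(meta) <- .spectrumNames(meta, n)
  se <- SummarizedExperiment(
    assays = list(intensity = intensity),
    rowData = DataFrame(wavenumber = as.numeric(wavenumber)),
    colData = meta)
  new("SpectralDataset", se)
}

.completeMeta <- function(meta, n) {
  if (is.null(meta)) meta <- data.frame(row.names = seq_len(max(n, 0L)))
  meta <- as(meta, "DataFrame")
  if (nrow(meta) != n)
    stop("metadata has ", nrow(meta), " rows for ", n, " spectra",
         call. = FALSE)
  if (is.null(meta$cell_line)) meta$cell_line <- rep("unknown", n)
  if (is.null(meta$cell_id)) meta$cell_id <- rep("cell1", n)
  if (is.null(meta$point_index)) meta$point_index <- seq_len(n) - 1L
  if (is.null(meta$scan_index)) meta$scan_index <- rep(0L, n)
  meta$cell_line <- as.character(meta$cell_line)
  meta$cell_id <- as.character(meta$cell_id)
  meta$point_index <- as.integer(meta$point_index)
  meta$scan_index <- as.integer(meta$scan_index)
  meta
}

.spectrumNames <- function(meta, n) {
  if (n == 0L) return(NULL)
  make.unique(paste(meta$cell_line, meta$cell_id, meta$point_index,
                    meta$scan_index, sep = "."))
}

#' Construct a single spectrum
#'
#' Convenience wrapper returning a one-column [SpectralDataset-class].
#'
#' @param wavenumber axis in cm^-1.
#' @param intensity intensity vector, one value per axis point.
#' @param ... metadata fields (e.g. `cell_line`, `excitation_nm`).
#' @return A one-spectrum [SpectralDataset-class].
#' @export
Spectrum <- function(wavenumber, intensity, ...) {
  meta <- list(...)
  meta <- if (length(meta)) do.call(data.frame, meta) else NULL
  SpectralDataset(matrix(as.numeric(intensity), ncol = 1L), wavenumber, meta)
}

#' Construct a HyperspectralMap
#'
#' @param cube numeric matrix, wavenumbers x pixels; pixels ordered with
#'   the x index varying fastest (row-major over the grid).
#' @param wavenumber axis in cm^-1.
#' @param gridShape integer(2) `(nx, ny)`.
#' @param stepUm spatial step between adjacent pixels, micrometres.
#' @param meta optional per-pixel metadata.
#' @return A [HyperspectralMap-class].
#' @export
HyperspectralMap <- function(cube, wavenumber, gridShape, stepUm = 0.5,
                             meta = NULL) {
  gridShape <- as.integer(gridShape)
  d <- SpectralDataset(cube, wavenumber, meta)
  cd <- colData(d)
  npix <- ncol(d)
  cd$x <- rep_len(seq_len(gridShape[1L]), npix)
  cd$y <- rep(seq_len(gridShape[2L]), each = gridShape[1L])[seq_len(npix)]
  SummarizedExperiment::colData(d) <- cd
  new("HyperspectralMap", d, gridShape = gridShape,
      stepUm = as.numeric(stepUm))
}

# ---- accessors ----

#' @rdname SpectralDataset
#' @param x a SpectralDataset.
#' @export
wavenumbers <- function(x) rowData(x)$wavenumber

#' @rdname SpectralDataset
#' @export
intensities <- function(x) assay(x, "intensity")

#' @rdname SpectralDataset
#' @export
nSpectra <- function(x) ncol(x)

#' @rdname SpectralDataset
#' @export
classLabels <- function(x) colData(x)$cell_line

#' @rdname HyperspectralMap
#' @param x a HyperspectralMap.
#' @export
gridShape <- function(x) x@gridShape

#' @rdname HyperspectralMap
#' @export
stepUm <- function(x) x@stepUm

setMethod("show", "SpectralDataset", function(object) {
  w <- wavenumbers(object)
  cat(class(object), "with", ncol(object), "spectra on",
      length(w), "wavenumbers",
      sprintf("[%.1f, %.1f] cm^-1\n", min(w), max(w)))
  if (ncol(object)) {
    tb <- table(classLabels(object))
    cat("  classes:", paste(sprintf("%s(%d)", names(tb), tb),
                            collapse = " "), "\n")
  }
  if (!is.null(metadata(object)$recipe))
    cat("  preprocessing:",
        recipeSummary(metadata(object)$recipe), "\n")
})

setMethod("show", "HyperspectralMap", function(object) {
  gs <- object@gridShape
  cat("HyperspectralMap", sprintf("%d x %d pixels, step %.2f um,",
      gs[1L], gs[2L], object@stepUm),
      length(wavenumbers(object)), "wavenumbers\n")
})

# ---- axis cropping ----

#' Crop a dataset to a wavenumber window
#'
#' Retains the axis points with `lo <= wavenumber <= hi`, e.g. to restrict
#' 785 nm acquisitions to the biological fingerprint region
#' (600-1800 cm^-1).
#'
#' @param d a [SpectralDataset-class] (or map).
#' @param lo,hi window bounds in cm^-1, `lo < hi`.
#' @return The cropped dataset (same class as the input).  Idempotent.
#' @export
cropAxis <- function(d, lo, hi) {
  if (lo >= hi) stop("cropAxis: lo must be < hi", call. = FALSE)
  keep <- which(wavenumbers(d) >= lo & wavenumbers(d) <= hi)
  if (!length(keep))
    stop(sprintf("cropAxis: window [%g, %g] does not overlap axis [%g, %g]",
                 lo, hi, min(wavenumbers(d)), max(wavenumbers(d))),
         call. = FALSE)
  d[keep, ]
}

# ---- plain-text I/O ----
# Dialect: comma-separated text; '#'-prefixed comment lines are ignored
# (maps store "# grid_shape: nx ny" and "# step_um: s" there); the first
# data row is the wavenumber axis and each subsequent row is one spectrum.
# Metadata travels in a sidecar CSV with one row per spectrum in file
# order.

#' Read a spectral dataset (or map) from delimited text
#'
#' @param path matrix file: first non-comment row is the axis, each later
#'   row one spectrum.  `# grid_shape:`/`# step_um:` comments mark a
#'   flattened [HyperspectralMap-class].
#' @param metaPath sidecar metadata CSV, one row per spectrum (optional;
#'   defaults filled when absent).
#' @return A [SpectralDataset-class] or [HyperspectralMap-class].
#' @export
readSpectralDataset <- function(path, metaPath = NULL) {
  lines <- readLines(path)
  isComment <- grepl("^\\s*#", lines)
  comments <- lines[isComment]
  dataIdx <- which(!isComment & nzchar(trimws(lines)))
  if (!length(dataIdx)) stop("no data rows in ", path, call. = FALSE)
  parseRow <- function(i) {
    fields <- strsplit(lines[i], ",", fixed = TRUE)[[1L]]
    vals <- suppressWarnings(as.numeric(fields))
    if (anyNA(vals))
      stop(sprintf("malformed numeric field on line %d of %s ('%s')",
                   i, path, trimws(fields[which(is.na(vals))[1L]])),
           call. = FALSE)
    vals
  }
  axis <- parseRow(dataIdx[1L])
  rows <- lapply(dataIdx[-1L], function(i) {
    v <- parseRow(i)
    if (length(v) != length(axis))
      stop(sprintf(
        "line %d of %s has %d values but the axis has %d points",
        i, path, length(v), length(axis)), call. = FALSE)
    v
  })
  mat <- if (length(rows)) do.call(cbind, rows) else
    matrix(numeric(0), nrow = length(axis), ncol = 0L)
  meta <- NULL
  if (!is.null(metaPath)) {
    meta <- utils::read.csv(metaPath, stringsAsFactors = FALSE)
    if (nrow(meta) != ncol(mat))
      stop(sprintf(
        "metadata has %d rows but matrix file has %d spectra",
        nrow(meta), ncol(mat)), call. = FALSE)
    if (ncol(mat) == 0L) meta <- NULL
  }
  gsLine <- grep("grid_shape:", comments, value = TRUE)
  if (length(gsLine)) {
    gs <- as.integer(strsplit(sub(".*grid_shape:\\s*", "", gsLine[1L]),
                              "\\s+")[[1L]][1:2])
    stLine <- grep("step_um:", comments, value = TRUE)
    st <- if (length(stLine))
      as.numeric(sub(".*step_um:\\s*", "", stLine[1L])) else 0.5
    return(HyperspectralMap(mat, axis, gs, st, meta))
  }
  SpectralDataset(mat, axis, meta)
}

#' Write a spectral dataset (or map) to delimited text
#'
#' Numbers are printed with 15 significant digits so that
#' `readSpectralDataset(writeSpectralDataset(d))` round-trips losslessly
#' for all practical spectra.
#'
#' @param d a [SpectralDataset-class] or [HyperspectralMap-class].
#' @param path matrix file to write.
#' @param metaPath metadata CSV to write (optional).
#' @return Invisibly, `path`.
#' @export
writeSpectralDataset <- function(d, path, metaPath = NULL) {
  fmt <- function(v) paste(format(v, digits = 15, scientific = TRUE,
                                  trim = TRUE), collapse = ",")
  hdr <- character(0)
  if (is(d, "HyperspectralMap"))
    hdr <- c(sprintf("# grid_shape: %d %d", d@gridShape[1L],
                     d@gridShape[2L]),
             sprintf("# step_um: %.6g", d@stepUm))
  y <- intensities(d)
  rows <- c(hdr, fmt(wavenumbers(d)),
            vapply(seq_len(ncol(y)), function(j) fmt(y[, j]), ""))
  ok <- tryCatch({ writeLines(rows, path); TRUE },
                 error = function(e) stop("cannot write ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  if (!is.null(metaPath)) {
    md <- as.data.frame(colData(d))
    utils::write.csv(md, metaPath, row.names = FALSE)
  }
  invisible(path)
}
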