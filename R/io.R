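#' @include AllClasses.R grid.R chain.R discrimination.R estimators.R
NULL

.sidecarPath <- function(path) paste0(path, ".json")

.writeSidecar <- function(path, meta) {
  jsonlite::write_json(meta, .sidecarPath(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
}

.readSidecar <- function(path) {
  sp <- .sidecarPath(path)
  if (!file.exists(sp)) stop("format error: missing sidecar file ", sp)
  jsonlite::read_json(sp, simplifyVector = TRUE)
}

#' Read and write density fields
#'
#' A density field is stored as a plain-text whitespace-delimited matrix
#' (rows = first axis) plus a JSON sidecar `<path>.json` holding the grid
#' shape and dimensionality. Round trips are lossless to full double
#' precision.
#'
#' @param field a [DensityField-class].
#' @param path file path for the matrix (sidecar written alongside).
#' @return `readDensityField` returns a [DensityField-class].
#' @export
writeDensityField <- function(field, path) {
  M <- fieldMatrix(field)
  utils::write.table(format(M, digits = 17, scientific = TRUE, trim = TRUE),
                     path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  .writeSidecar(path, list(type = "DensityField",
                           ndim = field@grid@ndim,
                           shape = field@grid@shape))
  invisible(path)
}

#' @rdname writeDensityField
#' @export
readDensityField <- function(path) {
  meta <- .readSidecar(path)
  if (is.null(meta$type) || meta$type != "DensityField")
    stop("format error: sidecar type is not 'DensityField'")
  M <- as.matrix(utils::read.table(path, header = FALSE))
  shape <- as.integer(meta$shape)
  if (!identical(dim(M), c(shape[1], if (length(shape) == 2) shape[2] else 1L)))
    stop("format error: matrix dimensions do not match sidecar shape")
  densityField(as.numeric(M), spatialGrid(shape))
}

#' Read and write chain datasets
#'
#' CSV with columns `chain_id`, `iteration`, `x`, `y`, `is_dummy`
#' (iteration 0 = seed) plus a JSON sidecar with stimulus id, provenance
#' and metadata.
#'
#' @param dataset a [ChainDataset-class].
#' @param path CSV path (sidecar written alongside).
#' @return `readChainDataset` returns a [ChainDataset-class].
#' @export
writeChainDataset <- function(dataset, path) {
  utils::write.csv(dataset@records, path, row.names = FALSE, quote = FALSE)
  .writeSidecar(path, list(type = "ChainDataset", stimulus = dataset@stimulus,
                           provenance = dataset@provenance,
                           meta = dataset@meta))
  invisible(path)
}

#' @rdname writeChainDataset
#' @export
readChainDataset <- function(path) {
  meta <- .readSidecar(path)
  if (is.null(meta$type) || meta$type != "ChainDataset")
    stop("format error: sidecar type is not 'ChainDataset'")
  r <- utils::read.csv(path)
  need <- c("chain_id", "iteration", "x", "y", "is_dummy")
  missing <- setdiff(need, names(r))
  if (length(missing))
    stop("format error: CSV is missing column(s): ",
         paste(missing, collapse = ", "))
  chainDataset(r, stimulus = meta$stimulus %||% "unnamed",
               provenance = meta$provenance %||% "observed",
               meta = as.list(meta$meta))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and write d' maps
#'
#' Plain-text table of probe coordinates and d' values plus a JSON sidecar
#' with radius, smoothing metadata and probe-grid shape.
#'
#' @param map a [DPrimeMap-class].
#' @param path file path.
#' @return `readDPrimeMap` returns a [DPrimeMap-class].
#' @export
writeDPrimeMap <- function(map, path) {
  df <- data.frame(map@points, value = map@values, retained = map@retained)
  names(df)[seq_len(ncol(map@points))] <- c("x", "y")[seq_len(ncol(map@points))]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  .writeSidecar(path, list(type = "DPrimeMap", radius = map@radius,
                           kernelSd = map@kernelSd,
                           interpolated = map@interpolated,
                           shape = map@shape))
  invisible(path)
}

#' @rdname writeDPrimeMap
#' @export
readDPrimeMap <- function(path) {
  meta <- .readSidecar(path)
  if (is.null(meta$type) || meta$type != "DPrimeMap")
    stop("format error: sidecar type is not 'DPrimeMap'")
  df <- utils::read.csv(path)
  cols <- intersect(c("x", "y"), names(df))
  new("DPrimeMap", points = as.matrix(df[cols]), values = df$value,
      shape = as.integer(meta$shape), radius = meta$radius,
      kernelSd = meta$kernelSd, interpolated = isTRUE(meta$interpolated),
      retained = as.logical(df$retained))
}

#' Read and write 2AFC datasets
#'
#' CSV with columns `probe_x`, `probe_y`, `condition`, `response` plus a
#' JSON sidecar (offset radius, trials per point).
#'
#' @param dataset a [TwoAFCDataset-class].
#' @param path CSV path.
#' @return `read2afc` returns a [TwoAFCDataset-class].
#' @export
write2afc <- function(dataset, path) {
  utils::write.csv(dataset@data, path, row.names = FALSE, quote = FALSE)
  meta <- dataset@meta
  meta$generatingMap <- NULL  # not serialized in the sidecar
  .writeSidecar(path, c(list(type = "TwoAFCDataset", radius = dataset@radius),
                        meta))
  invisible(path)
}

#' @rdname write2afc
#' @export
read2afc <- function(path) {
  meta <- .readSidecar(path)
  if (is.null(meta$type) || meta$type != "TwoAFCDataset")
    stop("format error: sidecar type is not 'TwoAFCDataset'")
  df <- utils::read.csv(path)
  need <- c("probe_x", "probe_y", "condition", "response")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("format error: CSV is missing column(s): ",
         paste(missing, collapse = ", "))
  extra <- meta[setdiff(names(meta), c("type", "radius"))]
  new("TwoAFCDataset", data = df, radius = meta$radius, meta = extra)
}

#' Read and write CAM parameters as JSON
#'
#' @param params a [CAMParams-class].
#' @param path JSON path.
#' @return `readCamParams` returns a [CAMParams-class].
#' @export
writeCamParams <- function(params, path) {
  jsonlite::write_json(
    list(type = "CAMParams", w = params@w, c = params@c,
         prototypes = params@prototypes, noiseSd = params@noiseSd),
    path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor", pretty = TRUE)
  invisible(path)
}

#' @rdname writeCamParams
#' @export
readCamParams <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(j$type) || j$type != "CAMParams")
    stop("format error: JSON type is not 'CAMParams'")
  P <- j$prototypes
  if (is.null(dim(P))) P <- matrix(P, nrow = 1)
  camParams(j$w, j$c, P, j$noiseSd %||% NA_real_)
}

#' Read and write grayscale PGM (P2, ASCII) images
#'
#' Minimal plain-PGM support for grayscale rasters used as display stimuli
#' or synthetic-prior sources. Values are scaled to \[0,1\] intensities.
#'
#' @param img numeric matrix in \[0,1\], indexed (x, y).
#' @param path file path.
#' @param maxval integer gray-level maximum (default 255).
#' @return `readPGM` returns a numeric matrix in \[0,1\].
#' @export
writePGM <- function(img, path, maxval = 255L) {
  vals <- round(t(img) * maxval)  # PGM is row-major: rows = y
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(nrow(img), ncol(img)), as.character(maxval)), con)
  utils::write.table(vals, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writePGM
#' @export
readPGM <- function(path) {
  toks <- scan(path, what = character(), comment.char = "#", quiet = TRUE)
  if (toks[1] != "P2") stop("format error: only ASCII PGM (P2) is supported")
  w <- as.integer(toks[2]); h <- as.integer(toks[3])
  maxval <- as.numeric(toks[4])
  vals <- as.numeric(toks[-(1:4)])
  if (length(vals) != w * h) stop("format error: PGM pixel count mismatch")
  matrix(vals, nrow = w, ncol = h) / maxval
}

#' Read a grayscale image (PNG or PGM) as a \[0,1\] intensity raster
#'
#' PNG files are read through the `png` package (color images are averaged
#' to grayscale); PGM through [readPGM()].
#'
#' @param path image path (.png or .pgm).
#' @return numeric matrix in \[0,1\], indexed (x, y) with y increasing
#'   upward in normalized coordinates.
#' @export
readImage <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "pgm") return(readPGM(path))
  if (ext != "png") stop("format error: expected a .png or .pgm file")
  if (!requireNamespace("png", quietly = TRUE))
    stop("reading PNG requires the 'png' package")
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) a <- apply(a[, , 1:3, drop = FALSE], c(1, 2), mean)
  # png rows run top-to-bottom; convert to (x, y) with y upward
  t(a)[, nrow(a):1, drop = FALSE]
}
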