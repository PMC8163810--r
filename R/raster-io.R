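#' @include raster-grid.R
NULL

## On-disk raster convention: ESRI ASCII grid (.asc), one band per file,
## nodata -9999, row 1 = northernmost row. The CRS label, when present, is
## stored in a one-line sidecar "<file>.crs" (the .asc format itself carries
## no CRS). All files are plain text and readable by standard GIS software.

#' Write a raster layer to an ESRI ASCII grid
#'
#' @param layer a [GridLayer-class] (or subclass).
#' @param file output path (conventionally `.asc`).
#' @param nodata value written for `NA` pixels (default -9999).
#' @return the file path, invisibly.
#' @seealso [readAsciiGrid()]
#' @export
writeAsciiGrid <- function(layer, file, nodata = -9999) {
  v <- gridValues(layer)
  res <- gridResolution(layer)
  org <- gridOrigin(layer)
  gt <- sp::GridTopology(cellcentre.offset = org + res / 2,
                         cellsize = c(res, res),
                         cells.dim = c(ncol(v), nrow(v)))
  sgdf <- sp::SpatialGridDataFrame(sp::SpatialGrid(gt),
                                   data.frame(z = as.vector(t(v))))
  sp::write.asciigrid(sgdf, file, na.value = nodata)
  crs <- gridCRS(layer)
  if (!is.na(crs)) writeLines(crs, paste0(file, ".crs"))
  invisible(file)
}

#' Read an ESRI ASCII grid into a raster layer
#'
#' @param file path to a `.asc` file; if a `<file>.crs` sidecar exists its
#'   first line is attached as the CRS label.
#' @param class the S4 class to construct (`"GridLayer"`, `"HeightRaster"`
#'   or `"HeightChangeRaster"`).
#' @return an object of the requested class; nodata pixels are `NA`.
#' @export
readAsciiGrid <- function(file, class = "GridLayer") {
  if (!file.exists(file)) stop("no such raster file: ", file, call. = FALSE)
  g <- sp::read.asciigrid(file, colname = "z")
  v <- t(as.matrix(g))          # -> rows = y (north first), cols = x
  gp <- g@grid
  if (abs(gp@cellsize[1] - gp@cellsize[2]) > 1e-9)
    stop("only square pixels are supported", call. = FALSE)
  crsFile <- paste0(file, ".crs")
  crs <- if (file.exists(crsFile)) readLines(crsFile, n = 1L) else NA_character_
  new(class, values = v, resolution = gp@cellsize[1],
      origin = as.numeric(gp@cellcentre.offset - gp@cellsize / 2), crs = crs)
}

#' Read a canopy height raster from an ESRI ASCII grid
#'
#' Convenience wrapper around [readAsciiGrid()] returning a
#' [HeightRaster-class].
#'
#' @inheritParams readAsciiGrid
#' @export
readHeightRaster <- function(file) readAsciiGrid(file, class = "HeightRaster")

#' Write a multi-band raster as one ASCII grid per band
#'
#' Bands are written as `<prefix>_<band>.asc` so that each file remains a
#' standard single-band grid.
#'
#' @param x a [BandRaster-class].
#' @param prefix path prefix for the per-band files.
#' @return character vector of written paths, invisibly.
#' @export
writeBandRaster <- function(x, prefix) {
  paths <- character(0)
  for (i in seq_along(x@bandNames)) {
    lay <- gridLayer(x@values[, , i], resolution = x@resolution,
                     origin = x@origin, crs = x@crs)
    p <- paste0(prefix, "_", x@bandNames[i], ".asc")
    writeAsciiGrid(lay, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read a multi-band raster written by [writeBandRaster()]
#'
#' @param prefix path prefix used at write time.
#' @param bands character vector of band names to read.
#' @return a [BandRaster-class].
#' @export
readBandRaster <- function(prefix, bands) {
  layers <- lapply(bands, function(b)
    readAsciiGrid(paste0(prefix, "_", b, ".asc")))
  v0 <- gridValues(layers[[1]])
  arr <- array(NA_real_, c(dim(v0), length(bands)))
  for (i in seq_along(layers)) arr[, , i] <- gridValues(layers[[i]])
  new("BandRaster", values = arr, bandNames = bands,
      resolution = gridResolution(layers[[1]]),
      origin = gridOrigin(layers[[1]]), crs = gridCRS(layers[[1]]))
}

## ---------------------------------------------------------------------------
## Point tables
## ---------------------------------------------------------------------------

## internal: validate a lidar-style point table
checkPoints <- function(points, requireNonEmpty = TRUE) {
  need <- c("x", "y", "z", "return_number", "scan_angle")
  if (!is.data.frame(points) || !all(need %in% names(points)))
    stop("points must be a data.frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (requireNonEmpty && nrow(points) == 0L)
    stop("points table is empty", call. = FALSE)
  if (nrow(points)) {
    if (any(!is.finite(points$x)) || any(!is.finite(points$y)) ||
        any(!is.finite(points$z)))
      stop("point coordinates must be finite", call. = FALSE)
    if (any(points$return_number < 1))
      stop("return_number must be >= 1", call. = FALSE)
  }
  invisible(points)
}

#' Read a lidar-style point table from CSV
#'
#' Expects the header `x,y,z,return_number,scan_angle`: planar coordinates
#' and elevation in metres, positive integer return number, and signed scan
#' angle in degrees from nadir.
#'
#' @param file CSV path.
#' @return a validated data.frame of points.
#' @seealso [filterReturns()], [writePointCsv()]
#' @export
readPointCsv <- function(file) {
  if (!file.exists(file)) stop("no such point file: ", file, call. = FALSE)
  checkPoints(utils::read.csv(file))
}

#' Write a lidar-style point table to CSV
#'
#' @param points data.frame with columns `x,y,z,return_number,scan_angle`.
#' @param file output CSV path.
#' @return the file path, invisibly.
#' @export
writePointCsv <- function(points, file) {
  checkPoints(points, requireNonEmpty = FALSE)
  utils::write.csv(points[c("x", "y", "z", "return_number", "scan_angle")],
                   file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

## ---------------------------------------------------------------------------
## Endmember tables
## ---------------------------------------------------------------------------

#' Write endmember spectra to CSV
#'
#' Long format with header `endmember,band,reflectance`.
#'
#' @param endmembers an [EndmemberSet-class].
#' @param file output CSV path.
#' @return the file path, invisibly.
#' @export
writeEndmemberCsv <- function(endmembers, file) {
  sp <- endmemberSpectra(endmembers)
  df <- data.frame(endmember = rep(colnames(sp), each = nrow(sp)),
                   band = rep(endmembers@bands, times = ncol(sp)),
                   reflectance = as.vector(sp))
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Read endmember spectra from CSV
#'
#' @param file CSV with columns `endmember,band,reflectance`; band and
#'   endmember order follow first appearance in the file.
#' @return an [EndmemberSet-class].
#' @export
readEndmemberCsv <- function(file) {
  if (!file.exists(file)) stop("no such endmember file: ", file, call. = FALSE)
  df <- utils::read.csv(file)
  need <- c("endmember", "band", "reflectance")
  if (!all(need %in% names(df)))
    stop("endmember CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  ems <- unique(df$endmember)
  bands <- unique(df$band)
  sp <- matrix(NA_real_, length(bands), length(ems),
               dimnames = list(bands, ems))
  for (i in seq_len(nrow(df)))
    sp[as.character(df$band[i]), as.character(df$endmember[i])] <-
      df$reflectance[i]
  if (any(is.na(sp)))
    stop("endmember CSV is missing band/endmember combinations", call. = FALSE)
  new("EndmemberSet", spectra = sp, bands = as.character(bands))
}
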