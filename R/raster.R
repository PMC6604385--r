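# Gridded layers (land cover, NDVI, chronic pollutant surfaces) as plain
# ESRI ASCII grids: a text header carrying the geotransform followed by rows
# of cell values, northernmost row first.

#' Construct a raster layer
#'
#' A minimal in-memory raster: a numeric matrix (row 1 = northern edge) plus
#' the geotransform of an ESRI ASCII grid (lower-left corner and square cell
#' size, in decimal degrees).
#'
#' @param values Numeric matrix of cell values, row 1 northernmost.
#' @param xll,yll Longitude/latitude of the lower-left corner of the grid.
#' @param cellsize Cell size in degrees (square cells).
#' @param nodata Value encoding missing cells in files (default -9999).
#' @param classes Optional named integer vector mapping land-class names to
#'   cell codes (categorical rasters only).
#' @return An object of class `elf_raster`.
#' @export
elf_raster <- function(values, xll, yll, cellsize, nodata = -9999, classes = NULL) {
  stopifnot(is.matrix(values), is.numeric(cellsize), cellsize > 0)
  structure(
    list(values = values, xll = xll, yll = yll, cellsize = cellsize,
         nodata = nodata, classes = classes),
    class = "elf_raster"
  )
}

#' @export
print.elf_raster <- function(x, ...) {
  cat(sprintf("<elf_raster %d x %d, cell %g deg, origin (%g, %g)>\n",
              nrow(x$values), ncol(x$values), x$cellsize, x$xll, x$yll))
  invisible(x)
}

#' @rdname elf_raster
#' @param x An `elf_raster`.
#' @param lon,lat Query coordinates (degrees).
#' @return `raster_extract()`: the value of the cell containing the point
#'   (half-open pixel convention: floor of the fractional row/column index),
#'   or `NA` outside the extent.
#' @export
raster_extract <- function(x, lon, lat) {
  nr <- nrow(x$values); nc <- ncol(x$values)
  col <- floor((lon - x$xll) / x$cellsize) + 1
  row_from_s <- floor((lat - x$yll) / x$cellsize) # 0-based from south
  row <- nr - row_from_s
  out <- rep(NA_real_, length(lon))
  ok <- !is.na(col) & !is.na(row) & col >= 1 & col <= nc & row >= 1 & row <= nr
  out[ok] <- x$values[cbind(row[ok], col[ok])]
  out[!is.na(out) & out == x$nodata] <- NA_real_
  out
}

# Centre coordinates of cell (row, col); row 1 is the northern edge.
raster_cell_centre <- function(x, row, col) {
  nr <- nrow(x$values)
  cbind(lon = x$xll + (col - 0.5) * x$cellsize,
        lat = x$yll + (nr - row + 0.5) * x$cellsize)
}

#' Read / write ESRI ASCII grid rasters
#'
#' @param path File path (`.asc`).
#' @return `read_ascii_grid()` returns an `elf_raster`.
#' @export
read_ascii_grid <- function(path) {
  hdr_lines <- readLines(path, n = 6L)
  hdr <- list()
  for (ln in hdr_lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  miss <- setdiff(need, names(hdr))
  if (length(miss)) stop("ASCII grid header missing: ", paste(miss, collapse = ", "), call. = FALSE)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  n_hdr <- if (is.null(hdr$nodata_value)) 5L else 6L
  vals <- scan(path, skip = n_hdr, quiet = TRUE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  elf_raster(m, hdr$xllcorner, hdr$yllcorner, hdr$cellsize, nodata = nodata)
}

#' @rdname read_ascii_grid
#' @param x An `elf_raster` to write.
#' @export
write_ascii_grid <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(x$values)),
    paste("nrows", nrow(x$values)),
    paste("xllcorner", format(x$xll, digits = 15)),
    paste("yllcorner", format(x$yll, digits = 15)),
    paste("cellsize", format(x$cellsize, digits = 15)),
    paste("NODATA_value", x$nodata)
  ), con)
  v <- x$values
  v[is.na(v)] <- x$nodata
  apply(v, 1L, function(r) writeLines(paste(format(r, digits = 15, trim = TRUE, scientific = FALSE), collapse = " "), con))
  invisible(path)
}
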