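#' Gridded raster layers
#'
#' The spatial container used throughout the package is a lightweight
#' in-memory raster: a numeric matrix (rows from the top of the map down, as
#' in ESRI ASCII grids) plus an affine georeference given by the top-left
#' corner and a square cell size.  `NA` cells are NODATA and are excluded
#' from every analysis.  Coordinates are abstract map units; no projection
#' math is performed.
#'
#' @param values numeric matrix, `NA` = NODATA.
#' @param x0,y0 map coordinates of the top-left corner of the grid.
#' @param cellsize edge length of a (square) cell in map units.
#' @return an object of class `grid_raster`.
#' @export
grid_raster <- function(values, x0 = 0, y0 = nrow(values), cellsize = 1) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!any(is.finite(values)))
    stop("grid_raster: no valid (non-NODATA) cells")
  structure(list(values = values, x0 = x0, y0 = y0, cellsize = cellsize),
            class = "grid_raster")
}

#' @export
print.grid_raster <- function(x, ...) {
  v <- x$values
  cat(sprintf("grid_raster: %d x %d cells (size %g), %d valid\n",
              nrow(v), ncol(v), x$cellsize, sum(is.finite(v))))
  cat(sprintf("  origin (top-left): (%g, %g)  value range: [%g, %g]\n",
              x$x0, x$y0, suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE))))
  invisible(x)
}

#' @export
dim.grid_raster <- function(x) dim(x$values)

grid_is <- function(x) inherits(x, "grid_raster")

#' Check that two rasters share the same grid
#'
#' @param a,b `grid_raster` objects.
#' @return `TRUE` or `FALSE`.
#' @export
same_grid <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(c(a$x0, a$y0, a$cellsize), c(b$x0, b$y0, b$cellsize)))
}

stop_unless_aligned <- function(a, b, what = "rasters") {
  if (!same_grid(a, b)) stop(what, " are not on the same grid")
  invisible(TRUE)
}

#' Cell-centre coordinates
#'
#' @param g a `grid_raster`.
#' @param cells optional integer vector of cell indices (column-major, as
#'   produced by `which()` on the value matrix); default all cells.
#' @return data frame with `cell`, `row`, `col`, `lon`, `lat`.
#' @export
cell_centers <- function(g, cells = seq_along(g$values)) {
  nr <- nrow(g$values)
  row <- ((cells - 1L) %% nr) + 1L
  col <- ((cells - 1L) %/% nr) + 1L
  data.frame(cell = cells, row = row, col = col,
             lon = g$x0 + (col - 0.5) * g$cellsize,
             lat = g$y0 - (row - 0.5) * g$cellsize)
}

#' Cell index containing each coordinate
#'
#' Coordinates outside the grid extent give `NA`.
#'
#' @param g a `grid_raster`.
#' @param lon,lat numeric coordinate vectors.
#' @return integer vector of column-major cell indices.
#' @export
cell_at <- function(g, lon, lat) {
  nr <- nrow(g$values); nc <- ncol(g$values)
  col <- floor((lon - g$x0) / g$cellsize) + 1L
  row <- floor((g$y0 - lat) / g$cellsize) + 1L
  out <- (col - 1L) * nr + row
  bad <- col < 1L | col > nc | row < 1L | row > nr
  out[bad] <- NA_integer_
  as.integer(out)
}

#' Indices of valid (non-NODATA) cells
#' @param g a `grid_raster`.
#' @return integer vector of column-major cell indices.
#' @export
valid_cells <- function(g) which(is.finite(g$values))

#' Write / read ESRI ASCII grids
#'
#' Plain-text raster exchange format; the NODATA value used on disk is
#' `-9999`.
#'
#' @param g a `grid_raster`.
#' @param path file path.
#' @return `read_asc` returns a `grid_raster`; `write_asc` returns `path`
#'   invisibly.
#' @export
write_asc <- function(g, path) {
  v <- g$values
  nr <- nrow(v); nc <- ncol(v)
  hdr <- c(
    sprintf("ncols %d", nc),
    sprintf("nrows %d", nr),
    sprintf("xllcorner %.10g", g$x0),
    sprintf("yllcorner %.10g", g$y0 - nr * g$cellsize),
    sprintf("cellsize %.10g", g$cellsize),
    "NODATA_value -9999")
  v[!is.finite(v)] <- -9999
  lines <- apply(v, 1L, function(r) paste(formatC(r, format = "g", digits = 10),
                                          collapse = " "))
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' @rdname write_asc
#' @export
read_asc <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(tolower(lines[1:6]), "\\s+")
  key <- vapply(hdr, `[`, "", 1L)
  val <- as.numeric(vapply(hdr, `[`, "", 2L))
  names(val) <- key
  nc <- as.integer(val["ncols"]); nr <- as.integer(val["nrows"])
  body <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  v <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  v[v == val["nodata_value"]] <- NA_real_
  grid_raster(v, x0 = unname(val["xllcorner"]),
              y0 = unname(val["yllcorner"] + nr * val["cellsize"]),
              cellsize = unname(val["cellsize"]))
}

## Internal: clone a raster with new values, preserving georeference + mask.
with_values <- function(g, values, keep_mask = TRUE) {
  v <- matrix(values, nrow = nrow(g$values), ncol = ncol(g$values))
  if (keep_mask) v[!is.finite(g$values)] <- NA_real_
  grid_raster(v, g$x0, g$y0, g$cellsize)
}
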