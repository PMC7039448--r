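#' Planar grid rasters
#'
#' A minimal matrix-backed raster: row 1 is the northernmost row, coordinates
#' are planar meters, and `origin_xy` is the top-left *corner* of the grid.
#' Land-cover rasters carry an integer class-code grid plus a code-to-name
#' map; suitability, resistance and path-density rasters carry numeric grids
#' with a declared value range or role. `NA` cells are nodata.
#'
#' @param grid numeric or integer matrix (row 1 = north).
#' @param cell_size_m cell edge length in meters (> 0).
#' @param origin_xy numeric length-2, x/y of the top-left corner.
#' @param class_names named character vector mapping code (as name) to class
#'   name; required for land-cover rasters.
#' @param scale declared value range tag for suitability rasters, one of
#'   `"0-1000"` or `"0-1"`.
#' @param provenance free-text origin tag (model/area) carried along.
#' @return an object of class `grid_raster` (and a role subclass).
#' @name rasters
NULL

new_grid_raster <- function(grid, cell_size_m, origin_xy, subclass,
                            extra = list()) {
  if (!is.matrix(grid) || nrow(grid) < 1L || ncol(grid) < 1L) {
    fail("grid must be a non-empty matrix")
  }
  if (!is.numeric(cell_size_m) || length(cell_size_m) != 1L ||
      is.na(cell_size_m) || cell_size_m <= 0) {
    fail("cell_size_m must be a single positive number")
  }
  if (length(origin_xy) != 2L || any(!is.finite(origin_xy))) {
    fail("origin_xy must be two finite coordinates (top-left corner)")
  }
  r <- c(list(grid = grid, cell_size_m = as.numeric(cell_size_m),
              origin_xy = as.numeric(origin_xy)), extra)
  class(r) <- c(subclass, "grid_raster")
  r
}

#' @rdname rasters
#' @export
landcover_raster <- function(grid, class_names, cell_size_m,
                             origin_xy = c(0, nrow(grid) * cell_size_m)) {
  storage.mode(grid) <- "integer"
  codes <- sort(unique(as.vector(grid[!is.na(grid)])))
  if (!all(as.character(codes) %in% names(class_names))) {
    fail("every code in grid needs an entry in class_names")
  }
  new_grid_raster(grid, cell_size_m, origin_xy, "landcover_raster",
                  list(class_names = class_names))
}

#' @rdname rasters
#' @export
suitability_raster <- function(grid, cell_size_m,
                               origin_xy = c(0, nrow(grid) * cell_size_m),
                               scale = c("0-1000", "0-1"),
                               provenance = NULL) {
  scale <- match.arg(scale)
  hi <- if (scale == "0-1000") 1000 else 1
  v <- grid[!is.na(grid)]
  if (length(v) && (min(v) < 0 || max(v) > hi)) {
    fail("suitability values outside declared %s range", scale)
  }
  new_grid_raster(grid, cell_size_m, origin_xy, "suitability_raster",
                  list(scale = scale, provenance = provenance))
}

#' @rdname rasters
#' @export
resistance_raster <- function(grid, cell_size_m,
                              origin_xy = c(0, nrow(grid) * cell_size_m)) {
  v <- grid[!is.na(grid)]
  if (length(v) && min(v) < 1) fail("resistance values must be >= 1")
  new_grid_raster(grid, cell_size_m, origin_xy, "resistance_raster")
}

#' @rdname rasters
#' @export
density_raster <- function(grid, cell_size_m,
                           origin_xy = c(0, nrow(grid) * cell_size_m),
                           scenario = NULL) {
  v <- grid[!is.na(grid)]
  if (length(v) && min(v) < 0) fail("path density values must be >= 0")
  new_grid_raster(grid, cell_size_m, origin_xy, "density_raster",
                  list(scenario = scenario))
}

#' @export
print.grid_raster <- function(x, ...) {
  v <- x$grid[!is.na(x$grid)]
  cat(sprintf("<%s> %d x %d cells @ %g m, origin (%g, %g)\n",
              class(x)[1L], nrow(x$grid), ncol(x$grid), x$cell_size_m,
              x$origin_xy[1L], x$origin_xy[2L]))
  if (!is.null(x$scale)) cat(" declared scale:", x$scale, "\n")
  if (length(v)) cat(sprintf(" values: [%g, %g], %d nodata\n", min(v), max(v),
                             sum(is.na(x$grid))))
  invisible(x)
}

#' @export
dim.grid_raster <- function(x) dim(x$grid)

# ---- geometry helpers --------------------------------------------------

#' Cell center coordinates and point-to-cell lookup
#'
#' @param raster a `grid_raster`.
#' @param row,col cell indices (row 1 = north).
#' @param x,y planar coordinates in meters.
#' @return `cell_center` returns a matrix with columns x, y; `cell_at` a
#'   matrix with columns row, col (NA when off-raster).
#' @export
cell_center <- function(raster, row, col) {
  cs <- raster$cell_size_m
  cbind(x = raster$origin_xy[1L] + (col - 0.5) * cs,
        y = raster$origin_xy[2L] - (row - 0.5) * cs)
}

#' @rdname cell_center
#' @export
cell_at <- function(raster, x, y) {
  cs <- raster$cell_size_m
  col <- floor((x - raster$origin_xy[1L]) / cs) + 1
  row <- floor((raster$origin_xy[2L] - y) / cs) + 1
  bad <- row < 1 | row > nrow(raster$grid) | col < 1 | col > ncol(raster$grid)
  row[bad] <- NA_integer_
  col[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

same_geometry <- function(a, b) {
  identical(dim(a$grid), dim(b$grid)) &&
    isTRUE(all.equal(a$cell_size_m, b$cell_size_m)) &&
    isTRUE(all.equal(a$origin_xy, b$origin_xy))
}

# ---- ESRI ASCII grid I/O ----------------------------------------------

#' Read and write ESRI ASCII grids
#'
#' The plain-text `.asc` interchange format: a six-line header (ncols, nrows,
#' xllcorner, yllcorner, cellsize, NODATA_value) followed by rows north to
#' south. `NA` cells are written as the nodata value.
#'
#' @param raster a `grid_raster`.
#' @param path file path.
#' @param nodata nodata sentinel written for `NA` cells.
#' @return `read_ascii_grid` returns a bare `grid_raster`; wrap it with a
#'   role constructor to restore class metadata.
#' @export
write_ascii_grid <- function(raster, path, nodata = -9999) {
  g <- raster$grid
  yll <- raster$origin_xy[2L] - nrow(g) * raster$cell_size_m
  hdr <- c(sprintf("ncols %d", ncol(g)), sprintf("nrows %d", nrow(g)),
           sprintf("xllcorner %.10g", raster$origin_xy[1L]),
           sprintf("yllcorner %.10g", yll),
           sprintf("cellsize %.10g", raster$cell_size_m),
           sprintf("NODATA_value %g", nodata))
  g[is.na(g)] <- nodata
  lines <- apply(g, 1L, function(r) paste(formatC(r, format = "g", digits = 15),
                                          collapse = " "))
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  keys <- tolower(vapply(hdr, `[`, "", 1L))
  vals <- as.numeric(vapply(hdr, `[`, "", 2L))
  names(vals) <- keys
  for (k in c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")) {
    if (!k %in% keys) fail("ASCII grid header missing '%s'", k)
  }
  nr <- as.integer(vals[["nrows"]])
  nc <- as.integer(vals[["ncols"]])
  body <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  if (length(body) != nr * nc) fail("ASCII grid body has %d values, expected %d",
                                    length(body), nr * nc)
  g <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  if ("nodata_value" %in% keys) g[g == vals[["nodata_value"]]] <- NA
  origin <- c(vals[["xllcorner"]], vals[["yllcorner"]] + nr * vals[["cellsize"]])
  new_grid_raster(g, vals[["cellsize"]], origin, "grid_raster"[0])
}
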