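#' Regular lon/lat raster grid
#'
#' A minimal in-memory raster: a regular grid of square cells in decimal
#' degrees (WGS84 lon/lat), stored as a numeric matrix whose first row is the
#' northernmost row of cells (north-west origin). Cell centres sit at
#' \code{origin + (index + 0.5) * cell_size}; this centre convention is shared
#' by every function in the package. \code{NA} encodes no-data.
#'
#' @param xmin,ymin west and south edges of the grid (degrees).
#' @param cell_size cell edge length in degrees (default 0.16, roughly a
#'   315 km^2 cell at mid latitudes).
#' @param nrow,ncol grid shape; both must be positive.
#' @param values optional numeric matrix (\code{nrow} x \code{ncol}) or a
#'   single number recycled to the full grid. Row 1 is the northern row.
#' @return an object of class \code{raster_grid}.
#' @export
raster_grid <- function(xmin, ymin, cell_size = 0.16, nrow, ncol, values = NA_real_) {
  if (!is.finite(cell_size) || cell_size <= 0)
    stop("cell_size must be a positive number of degrees")
  if (nrow < 1 || ncol < 1) stop("grid shape must be positive (n_rows * n_cols > 0)")
  if (is.matrix(values)) {
    if (!identical(dim(values), c(as.integer(nrow), as.integer(ncol))))
      stop("values matrix must be nrow x ncol")
    vals <- values
  } else {
    vals <- matrix(as.numeric(values), nrow = nrow, ncol = ncol)
  }
  structure(list(
    xmin = as.numeric(xmin), ymin = as.numeric(ymin),
    cell_size = as.numeric(cell_size),
    nrow = as.integer(nrow), ncol = as.integer(ncol),
    values = vals
  ), class = "raster_grid")
}

#' Build an empty grid covering a bounding box
#'
#' The box is expanded northwards/eastwards to a whole number of cells.
#'
#' @param xmin,xmax,ymin,ymax bounding box in degrees; must be non-degenerate.
#' @param cell_size cell edge in degrees.
#' @return an all-\code{NA} \code{raster_grid}.
#' @export
grid_from_extent <- function(xmin, xmax, ymin, ymax, cell_size = 0.16) {
  if (!(xmax > xmin) || !(ymax > ymin))
    stop("degenerate extent: need xmax > xmin and ymax > ymin")
  ncol <- max(1L, as.integer(ceiling((xmax - xmin) / cell_size - 1e-9)))
  nrow <- max(1L, as.integer(ceiling((ymax - ymin) / cell_size - 1e-9)))
  raster_grid(xmin, ymin, cell_size, nrow, ncol)
}

#' @export
print.raster_grid <- function(x, ...) {
  cat(sprintf("raster_grid: %d x %d cells of %g deg, x [%g, %g], y [%g, %g]\n",
              x$nrow, x$ncol, x$cell_size, x$xmin, grid_xmax(x), x$ymin, grid_ymax(x)))
  cat(sprintf("  values: %d finite, %d no-data\n",
              sum(is.finite(x$values)), sum(!is.finite(x$values))))
  invisible(x)
}

#' @rdname raster_grid
#' @param x object to test.
#' @export
is_raster_grid <- function(x) inherits(x, "raster_grid")

#' @export
grid_xmax <- function(grid) grid$xmin + grid$ncol * grid$cell_size

#' @export
grid_ymax <- function(grid) grid$ymin + grid$nrow * grid$cell_size

#' Do two grids share extent, cell size and shape?
#' @export
same_grid <- function(a, b, tol = 1e-9) {
  is_raster_grid(a) && is_raster_grid(b) &&
    a$nrow == b$nrow && a$ncol == b$ncol &&
    abs(a$xmin - b$xmin) < tol && abs(a$ymin - b$ymin) < tol &&
    abs(a$cell_size - b$cell_size) < tol
}

#' Cell containing a location
#'
#' Vectorized lon/lat to (row, col) lookup. Points on the extreme north/east
#' edges are clamped into the adjacent cell so the closed extent maps cleanly.
#'
#' @param grid a \code{raster_grid}.
#' @param lon,lat coordinates in degrees.
#' @return data.frame with columns \code{row}, \code{col}; \code{NA} rows for
#'   out-of-extent points.
#' @export
cell_of <- function(grid, lon, lat) {
  ymax <- grid_ymax(grid); xmax <- grid_xmax(grid)
  col <- floor((lon - grid$xmin) / grid$cell_size) + 1
  row <- floor((ymax - lat) / grid$cell_size) + 1
  col[lon == xmax] <- grid$ncol
  row[lat == grid$ymin] <- grid$nrow
  bad <- lon < grid$xmin | lon > xmax | lat < grid$ymin | lat > ymax
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Centre coordinates of cells
#'
#' @param grid a \code{raster_grid}.
#' @param row,col cell indices (vectorized). Omit both to get every cell in
#'   matrix order (column-major, as \code{grid$values} vectorizes).
#' @return data.frame with \code{lon}, \code{lat}.
#' @export
cell_center <- function(grid, row = NULL, col = NULL) {
  if (is.null(row) != is.null(col)) stop("give both row and col, or neither")
  if (is.null(row)) {
    row <- rep(seq_len(grid$nrow), times = grid$ncol)
    col <- rep(seq_len(grid$ncol), each = grid$nrow)
  }
  data.frame(
    lon = grid$xmin + (col - 0.5) * grid$cell_size,
    lat = grid_ymax(grid) - (row - 0.5) * grid$cell_size
  )
}

#' Grid value at point locations
#'
#' @param grid a \code{raster_grid}.
#' @param lon,lat coordinates (degrees).
#' @return numeric vector of cell values; errors on out-of-extent points.
#' @export
value_at <- function(grid, lon, lat) {
  rc <- cell_of(grid, lon, lat)
  if (anyNA(rc$row))
    stop("location(s) outside grid extent: index ", paste(which(is.na(rc$row)), collapse = ", "))
  grid$values[cbind(rc$row, rc$col)]
}

#' Latitude-corrected cell areas
#'
#' Approximates each cell's area as \code{(cell * 111.195 km)^2 * cos(lat)}
#' at the cell-centre latitude, so degree cells shrink towards the poles.
#'
#' @param grid a \code{raster_grid}.
#' @return matrix of areas in km^2, same shape as \code{grid$values}.
#' @export
cell_area_km2 <- function(grid) {
  km_per_deg <- pi * 6371.0088 / 180
  lat <- grid_ymax(grid) - (seq_len(grid$nrow) - 0.5) * grid$cell_size
  row_area <- (grid$cell_size * km_per_deg)^2 * cos(lat * pi / 180)
  matrix(rep(row_area, times = grid$ncol), nrow = grid$nrow)
}

#' Read / write ESRI ASCII grid rasters
#'
#' Plain-text single-band raster IO (the \code{.asc} format: a six-line
#' header then rows of values north to south). Values, extent, cell size and
#' no-data cells round-trip exactly; coordinates are taken to be WGS84
#' lon/lat degrees, the package's fixed CRS.
#'
#' @param path file path.
#' @return \code{read_ascii_grid}: a \code{raster_grid}.
#' @export
read_ascii_grid <- function(path) {
  if (!file.exists(path)) stop("raster file not found: ", path)
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (i <= length(lines) && grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("not an ESRI ASCII grid (missing header keys): ", path)
  if (is.null(hdr$xllcorner) || is.null(hdr$yllcorner)) {
    # centre-referenced variant
    if (is.null(hdr$xllcenter) || is.null(hdr$yllcenter))
      stop("ASCII grid header lacks corner/centre reference: ", path)
    hdr$xllcorner <- hdr$xllcenter - hdr$cellsize / 2
    hdr$yllcorner <- hdr$yllcenter - hdr$cellsize / 2
  }
  nodata <- if (is.null(hdr$nodata_value)) -9999 else hdr$nodata_value
  body <- scan(text = paste(lines[i:length(lines)], collapse = "\n"), quiet = TRUE)
  if (length(body) != hdr$nrows * hdr$ncols)
    stop("ASCII grid body has ", length(body), " values, expected ",
         hdr$nrows * hdr$ncols)
  vals <- matrix(body, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  vals[vals == nodata] <- NA_real_
  raster_grid(hdr$xllcorner, hdr$yllcorner, hdr$cellsize,
              hdr$nrows, hdr$ncols, vals)
}

#' @rdname read_ascii_grid
#' @param grid a \code{raster_grid} to write.
#' @param nodata numeric code used for \code{NA} cells on disk.
#' @export
write_ascii_grid <- function(grid, path, nodata = -9999) {
  stopifnot(is_raster_grid(grid))
  vals <- grid$values
  vals[!is.finite(vals)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", grid$ncol),
    sprintf("nrows %d", grid$nrow),
    sprintf("xllcorner %.12g", grid$xmin),
    sprintf("yllcorner %.12g", grid$ymin),
    sprintf("cellsize %.12g", grid$cell_size),
    sprintf("NODATA_value %.12g", nodata)
  ), con)
  writeLines(apply(vals, 1, function(r) paste(sprintf("%.17g", r), collapse = " ")), con)
  invisible(path)
}
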