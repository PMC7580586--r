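#' Read polygons from a GeoJSON file or string
#'
#' Accepts Polygon / MultiPolygon geometries, bare or wrapped in Feature /
#' FeatureCollection / GeometryCollection objects, in WGS84 lon/lat.
#'
#' @param x path to a GeoJSON file, or a GeoJSON string.
#' @return a list of polygons; each polygon is a list of rings, each ring a
#'   two-column (lon, lat) matrix. The first ring is the outer boundary,
#'   later rings are holes (even-odd rule).
#' @export
read_geojson_polygons <- function(x) {
  g <- jsonlite::fromJSON(x, simplifyVector = FALSE)
  polys <- list()
  collect <- function(obj) {
    if (is.null(obj$type)) return()
    switch(obj$type,
      FeatureCollection = for (f in obj$features) collect(f),
      GeometryCollection = for (gm in obj$geometries) collect(gm),
      Feature = collect(obj$geometry),
      Polygon = polys[[length(polys) + 1]] <<- lapply(obj$coordinates, ring_matrix),
      MultiPolygon = for (p in obj$coordinates)
        polys[[length(polys) + 1]] <<- lapply(p, ring_matrix),
      stop("unsupported GeoJSON geometry type: ", obj$type)
    )
  }
  collect(g)
  if (!length(polys)) stop("empty geometry: no polygons found")
  polys
}

ring_matrix <- function(ring) {
  m <- do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
  storage.mode(m) <- "double"
  m
}

#' Point-in-polygon test (even-odd ray casting)
#'
#' @param lon,lat point coordinates (vectorized).
#' @param polygons polygons as returned by \code{\link{read_geojson_polygons}}.
#' @return logical vector: inside any polygon (holes excluded by the
#'   even-odd rule within each polygon).
#' @keywords internal
#' @export
point_in_polygons <- function(lon, lat, polygons) {
  inside_any <- rep(FALSE, length(lon))
  for (poly in polygons) {
    crossings <- rep(0L, length(lon))
    for (ring in poly) {
      x <- ring[, 1]; y <- ring[, 2]
      n <- length(x)
      if (n < 3) next
      j <- c(n, seq_len(n - 1))  # previous vertex
      for (k in seq_len(n)) {
        xi <- x[k]; yi <- y[k]; xj <- x[j[k]]; yj <- y[j[k]]
        hits <- ((yi > lat) != (yj > lat)) &
          (lon < (xj - xi) * (lat - yi) / (yj - yi) + xi)
        crossings <- crossings + hits
      }
    }
    inside_any <- inside_any | (crossings %% 2L == 1L)
  }
  inside_any
}

#' Rasterize a range polygon onto a template grid
#'
#' A cell is inside the range mask iff its centre lies within any polygon
#' (even-odd rule, so holes are excluded).
#'
#' @param polygons a GeoJSON path/string or a polygon list from
#'   \code{\link{read_geojson_polygons}}.
#' @param template a \code{raster_grid} defining the output geometry.
#' @return a \code{range_mask}: a \code{raster_grid} whose values are 1
#'   (inside) / 0 (outside), with class \code{c("range_mask","raster_grid")}.
#' @export
rasterize_range <- function(polygons, template) {
  stopifnot(is_raster_grid(template))
  if (is.character(polygons)) polygons <- read_geojson_polygons(polygons)
  if (!length(polygons)) stop("empty geometry")
  ctr <- cell_center(template)
  inside <- point_in_polygons(ctr$lon, ctr$lat, polygons)
  mask <- raster_grid(template$xmin, template$ymin, template$cell_size,
                      template$nrow, template$ncol,
                      matrix(as.numeric(inside), template$nrow, template$ncol))
  class(mask) <- c("range_mask", class(mask))
  mask
}

#' All-inside mask on a template grid
#'
#' Convenience mask used when no species-range polygon is supplied: every
#' cell of the template counts as in-range.
#'
#' @param template a \code{raster_grid}.
#' @return a \code{range_mask}.
#' @export
full_range_mask <- function(template) {
  mask <- raster_grid(template$xmin, template$ymin, template$cell_size,
                      template$nrow, template$ncol, 1)
  class(mask) <- c("range_mask", class(mask))
  mask
}

#' @rdname rasterize_range
#' @param mask object to query.
#' @return \code{mask_matrix}: logical matrix of in-range cells.
#' @export
mask_matrix <- function(mask) {
  stopifnot(is_raster_grid(mask))
  is.finite(mask$values) & mask$values != 0
}
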