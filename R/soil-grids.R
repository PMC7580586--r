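#' Soil grid sets
#'
#' A soil grid set maps each element to a \code{raster_grid} of soil
#' concentrations (ppb); all member grids share one common geometry.
#'
#' @param grids named list of \code{raster_grid}s, one per element.
#' @return an object of class \code{soil_grid_set}.
#' @export
soil_grid_set <- function(grids) {
  if (!length(grids) || is.null(names(grids)) || any(names(grids) == ""))
    stop("grids must be a named list, one raster per element")
  if (anyDuplicated(names(grids))) stop("duplicate element names in grid set")
  template <- grids[[1]]
  for (nm in names(grids)) {
    if (!is_raster_grid(grids[[nm]])) stop("grid for ", nm, " is not a raster_grid")
    if (!same_grid(template, grids[[nm]]))
      stop("grid for ", nm, " does not share the common geometry")
  }
  structure(list(grids = grids, template = template), class = "soil_grid_set")
}

#' @rdname soil_grid_set
#' @param x object to query/test.
#' @export
is_soil_grid_set <- function(x) inherits(x, "soil_grid_set")

#' @rdname soil_grid_set
#' @export
soil_elements <- function(x) names(x$grids)

#' @export
print.soil_grid_set <- function(x, ...) {
  cat(sprintf("soil_grid_set: %d elements (%s) on a %d x %d grid\n",
              length(x$grids), paste(soil_elements(x), collapse = ", "),
              x$template$nrow, x$template$ncol))
  invisible(x)
}

#' Write / read a soil grid set as one ASCII raster per element
#'
#' @param soil a \code{soil_grid_set}.
#' @param dir directory; files are named \code{soil_<element>.asc}.
#' @param elements elements to read (order preserved).
#' @return the directory (write) or a \code{soil_grid_set} (read).
#' @export
write_soil_grids <- function(soil, dir) {
  stopifnot(is_soil_grid_set(soil))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (el in soil_elements(soil))
    write_ascii_grid(soil$grids[[el]], file.path(dir, paste0("soil_", el, ".asc")))
  invisible(dir)
}

#' @rdname write_soil_grids
#' @export
read_soil_grids <- function(dir, elements = canonical_elements()) {
  paths <- file.path(dir, paste0("soil_", elements, ".asc"))
  missing <- elements[!file.exists(paths)]
  if (length(missing))
    stop("no soil raster for element(s): ", paste(missing, collapse = ", "))
  grids <- lapply(paths, read_ascii_grid)
  names(grids) <- elements
  soil_grid_set(grids)
}
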