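#' Likelihood-of-origin surface for one individual
#'
#' Evaluates, for every in-range cell \code{i}, the normal density comparing
#' the individual's component score \code{y*} to the cell's predicted value
#' \code{mu_i}:
#' \deqn{f(y^* | \mu_i, \sigma) = \frac{1}{\sigma\sqrt{2\pi}}
#'   e^{-(y^*-\mu_i)^2 / (2\sigma^2)}}
#' By default the density is normalized by its theoretical maximum
#' \code{1/(sigma*sqrt(2*pi))}, giving
#' \code{f_i = exp(-(y*-mu_i)^2/(2 sigma^2))} on the 0-1 scale, which equals
#' 1 exactly where \code{mu_i = y*}. \code{normalize = FALSE} returns the raw
#' density instead.
#'
#' @param y_star the individual's component score (finite).
#' @param basemap a \code{basemap} with finite \code{sigma > 0}.
#' @param normalize return the 0-1 normalized value (default TRUE)?
#' @return an \code{assignment_surface}: list with \code{f} (a
#'   \code{raster_grid}; NA outside range), \code{y_star}, \code{sigma},
#'   \code{normalized}.
#' @export
likelihood_surface <- function(y_star, basemap, normalize = TRUE) {
  stopifnot(inherits(basemap, "basemap"))
  if (!is.finite(y_star)) stop("non-finite score y*")
  sigma <- basemap$sigma
  if (!is.finite(sigma) || sigma <= 0) stop("basemap sigma must be finite and > 0")
  f <- exp(-(y_star - basemap$mu$values)^2 / (2 * sigma^2))
  if (!normalize) f <- f / (sigma * sqrt(2 * pi))
  g <- basemap$mu
  structure(list(
    f = raster_grid(g$xmin, g$ymin, g$cell_size, g$nrow, g$ncol, f),
    y_star = y_star, sigma = sigma, normalized = normalize
  ), class = "assignment_surface")
}

#' Likelihood value at a location
#'
#' @param surface an \code{assignment_surface}.
#' @param lon,lat query location (degrees); must fall on an in-range cell.
#' @return the value of the cell containing the location.
#' @export
probability_at <- function(surface, lon, lat) {
  stopifnot(inherits(surface, "assignment_surface"))
  v <- value_at(surface$f, lon, lat)
  if (anyNA(v)) stop("location is outside the assignable range")
  v
}

#' Classify an assignment against the true location
#'
#' An individual is assigned correctly when the surface value at the cell
#' containing its true (sampling) location reaches the threshold; failing
#' that, it is rescued when any cell whose centre lies within
#' \code{buffer_km} of the true location (great-circle, the nightly travel
#' allowance) reaches the threshold.
#'
#' @param surface an \code{assignment_surface}.
#' @param lon,lat true/sampling location.
#' @param threshold probability threshold in (0, 1); default 0.5. The
#'   comparison is \code{>=}, so a cell exactly at the threshold counts.
#' @param buffer_km rescue radius in km (default 10); 0 disables rescue.
#' @return an \code{assignment_result}: one-row data.frame with
#'   \code{probability}, \code{correct}, \code{rescued}, \code{threshold},
#'   \code{buffer_km}.
#' @export
classify_assignment <- function(surface, lon, lat, threshold = 0.5, buffer_km = 10) {
  if (!(threshold > 0 && threshold < 1)) stop("threshold must be in (0, 1)")
  if (buffer_km < 0) stop("buffer_km must be >= 0")
  p <- probability_at(surface, lon, lat)
  correct <- p >= threshold
  rescued <- FALSE
  if (!correct && buffer_km > 0) {
    g <- surface$f
    ctr <- cell_center(g)
    near <- haversine_km(ctr$lon, ctr$lat, lon, lat) <= buffer_km
    vals <- as.vector(g$values)[near]
    rescued <- any(is.finite(vals) & vals >= threshold)
    correct <- rescued
  }
  data.frame(probability = p, correct = correct, rescued = rescued,
             threshold = threshold, buffer_km = buffer_km)
}

#' Range fraction above threshold (assignment precision)
#'
#' The share of the species range predicted as a possible origin: the area
#' of in-range cells whose surface value reaches the threshold, divided by
#' the total in-range area. Cell areas are latitude-corrected
#' (\code{\link{cell_area_km2}}), so a nominal-degree cell counts less
#' towards the fraction at high latitude. Smaller fractions mean more
#' precise assignments.
#'
#' @param surface an \code{assignment_surface}.
#' @param range a \code{range_mask} on the surface grid.
#' @param threshold probability threshold (default 0.5), compared with
#'   \code{>=}.
#' @return fraction in [0, 1].
#' @export
range_fraction <- function(surface, range, threshold = 0.5) {
  stopifnot(inherits(surface, "assignment_surface"))
  g <- surface$f
  if (!same_grid(g, range)) stop("range mask must share the surface grid")
  inr <- mask_matrix(range) & is.finite(g$values)
  if (!any(inr)) stop("empty range: no in-range cell with a finite value")
  area <- cell_area_km2(g)
  above <- inr & g$values >= threshold
  sum(area[above]) / sum(area[inr])
}
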