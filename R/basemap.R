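#' Inverse-distance-weighted interpolation of component scores
#'
#' Interpolates sample scores to every cell of a template grid:
#' \code{value(cell) = sum(w_j y_j) / sum(w_j)} with
#' \code{w_j = d_j^(-power)} and \code{d_j} the haversine distance (km) from
#' the cell centre to sample \code{j}, over the global neighbourhood (all
#' samples). A cell containing one or more samples takes the mean of those
#' samples' scores exactly, so the surface honours its nodes.
#'
#' @param scores a \code{score_set} (or data.frame with \code{lon},
#'   \code{lat} and a score column).
#' @param template a \code{raster_grid} defining the output geometry.
#' @param power IDW power (> 0), default 2.
#' @param column score column name, default \code{"PC1"}.
#' @return a \code{raster_grid} of interpolated values.
#' @export
idw_interpolate <- function(scores, template, power = 2, column = "PC1") {
  stopifnot(is_raster_grid(template))
  if (!nrow(scores)) stop("no samples to interpolate")
  if (!(power > 0)) stop("power must be > 0")
  y <- scores[[column]]
  if (is.null(y)) stop("no score column '", column, "'")
  ctr <- cell_center(template)
  d <- dist_matrix_km(ctr$lon, ctr$lat, scores$lon, scores$lat)
  w <- pmax(d, 1e-9)^(-power)
  vals <- as.vector(w %*% y) / rowSums(w)
  # exactness at nodes: mean of samples within the owning cell
  rc <- cell_of(template, scores$lon, scores$lat)
  own <- !is.na(rc$row)
  if (any(own)) {
    lin <- rc$row[own] + (rc$col[own] - 1L) * template$nrow
    agg <- tapply(y[own], lin, mean)
    vals[as.integer(names(agg))] <- agg
  }
  raster_grid(template$xmin, template$ymin, template$cell_size,
              template$nrow, template$ncol,
              matrix(vals, template$nrow, template$ncol))
}

#' Direct-portion extent: convex hull of the sampled locations
#'
#' The directly mapped portion of the basemap reaches only to the limit of
#' the sampled points: the convex hull of the sample locations, rasterized by
#' the cell-centre-in-hull test, optionally padded by a buffer in degrees.
#'
#' @param profiles an \code{element_profile_set} (or any data.frame with
#'   \code{lon}, \code{lat}) with at least 3 non-collinear samples.
#' @param template a \code{raster_grid}.
#' @param buffer_deg padding distance in degrees (planar), default 0.
#' @return a \code{range_mask}-style grid: 1 inside the (buffered) hull.
#' @export
direct_extent <- function(profiles, template, buffer_deg = 0) {
  stopifnot(is_raster_grid(template))
  pts <- unique(data.frame(lon = profiles$lon, lat = profiles$lat))
  if (nrow(pts) < 3) stop("need at least 3 distinct sample locations")
  h <- grDevices::chull(pts$lon, pts$lat)
  hull <- as.matrix(pts[h, c("lon", "lat")])
  # shoelace area; zero means collinear samples
  xs <- hull[, 1]; ys <- hull[, 2]
  area <- abs(sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys)) / 2
  if (length(h) < 3 || area < 1e-12)
    stop("degenerate (collinear) sample hull; supply a positive buffer_deg ",
         "around a wider sample set")
  ctr <- cell_center(template)
  inside <- point_in_polygons(ctr$lon, ctr$lat, list(list(hull)))
  if (buffer_deg > 0) {
    near <- dist_to_polygon_deg(ctr$lon, ctr$lat, hull) <= buffer_deg
    inside <- inside | near
  }
  mask <- raster_grid(template$xmin, template$ymin, template$cell_size,
                      template$nrow, template$ncol,
                      matrix(as.numeric(inside), template$nrow, template$ncol))
  class(mask) <- c("range_mask", class(mask))
  mask
}

# Planar degree distance from points to a closed polygon's boundary.
dist_to_polygon_deg <- function(lon, lat, hull) {
  n <- nrow(hull)
  dmin <- rep(Inf, length(lon))
  for (k in seq_len(n)) {
    a <- hull[k, ]; b <- hull[if (k == n) 1 else k + 1, ]
    ab <- b - a
    len2 <- sum(ab^2)
    t <- if (len2 == 0) rep(0, length(lon)) else
      pmin(1, pmax(0, ((lon - a[1]) * ab[1] + (lat - a[2]) * ab[2]) / len2))
    dmin <- pmin(dmin, sqrt((lon - (a[1] + t * ab[1]))^2 +
                            (lat - (a[2] + t * ab[2]))^2))
  }
  dmin
}

#' Indirect basemap portion from soil grids
#'
#' Where no samples exist, the basemap is extended indirectly: each cell's
#' soil concentrations are passed through the per-element transfer
#' regressions to a hypothetical fur profile (truncated at zero), which is
#' then scored with the summary loadings exactly as real profiles are.
#'
#' @param soil a \code{soil_grid_set}.
#' @param regressions an \code{element_regression_set} covering every element.
#' @param object a \code{gwpca_model} or a PC1 loading vector in the soil
#'   element order.
#' @param mode scoring mode, as in \code{\link{score_samples}}.
#' @return a \code{raster_grid} of predicted PC1 values.
#' @export
indirect_surface <- function(soil, regressions, object, mode = c("raw", "standardized")) {
  mode <- match.arg(mode)
  stopifnot(is_soil_grid_set(soil))
  els <- soil_elements(soil)
  if (inherits(object, "gwpca_model")) {
    if (!identical(object$elements, els))
      stop("element order mismatch between model and soil grids")
    v <- object$summary_loadings[, 1]
  } else {
    v <- as.numeric(object)
    if (length(v) != length(els)) stop("loading length mismatch")
    if (mode == "standardized") stop("standardized scoring needs a gwpca_model")
  }
  miss <- setdiff(els, rownames(regressions))
  if (length(miss)) stop("missing regression for element(s): ", paste(miss, collapse = ", "))
  template <- soil$template
  fur <- sapply(els, function(el) {
    pmax(regressions[el, "intercept"] +
           regressions[el, "slope"] * as.vector(soil$grids[[el]]$values), 0)
  })
  fur <- matrix(fur, ncol = length(els), dimnames = list(NULL, els))
  if (mode == "standardized")
    fur <- sweep(sweep(fur, 2, object$means), 2, object$sds, "/")
  vals <- as.vector(fur %*% v)
  raster_grid(template$xmin, template$ymin, template$cell_size,
              template$nrow, template$ncol,
              matrix(vals, template$nrow, template$ncol))
}

#' Merge the direct and indirect portions into one basemap
#'
#' In-range cells take the direct (IDW) value where the direct mask is true
#' and the indirect value elsewhere, with no blending or seam smoothing: any
#' misalignment between the portions is left in place so the directly mapped
#' part stays exact. Out-of-range cells are no-data.
#'
#' @param direct,indirect \code{raster_grid}s on the same template.
#' @param direct_mask mask of the directly mapped portion.
#' @param range a \code{range_mask} of the species range.
#' @param sigma assignment standard deviation (> 0); see
#'   \code{\link{estimate_sigma}} and \code{\link{reference_sigma}}.
#' @param meta optional list of provenance metadata carried on the object.
#' @return a \code{basemap}: list with \code{mu} (predicted-PC1
#'   \code{raster_grid}), \code{region} (\code{raster_grid}; 1 = direct,
#'   2 = indirect, NA = outside range), \code{sigma} and \code{meta}.
#' @export
merge_basemap <- function(direct, direct_mask, indirect, range, sigma, meta = list()) {
  if (!same_grid(direct, indirect) || !same_grid(direct, direct_mask) ||
      !same_grid(direct, range))
    stop("direct, indirect, masks and range must share one grid")
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be > 0")
  inr <- mask_matrix(range)
  dm <- mask_matrix(direct_mask)
  mu <- ifelse(inr, ifelse(dm, direct$values, indirect$values), NA_real_)
  if (any(inr & !is.finite(mu)))
    stop("non-finite predicted value inside the range")
  region <- ifelse(inr, ifelse(dm, 1, 2), NA_real_)
  g <- function(v) raster_grid(direct$xmin, direct$ymin, direct$cell_size,
                               direct$nrow, direct$ncol, v)
  structure(list(mu = g(mu), region = g(region), sigma = sigma, meta = meta),
            class = "basemap")
}

#' @export
print.basemap <- function(x, ...) {
  reg <- x$region$values
  cat(sprintf("basemap: %d x %d cells; %d direct, %d indirect, %d outside range; sigma = %.4g\n",
              x$mu$nrow, x$mu$ncol, sum(reg == 1, na.rm = TRUE),
              sum(reg == 2, na.rm = TRUE), sum(is.na(reg)), x$sigma))
  invisible(x)
}

#' Assignment standard deviation from calibration residuals
#'
#' Regresses actual scores on basemap-predicted scores (OLS) and returns the
#' residual standard deviation (n - 2 denominator), the sigma of the
#' assignment density.
#'
#' @param predicted basemap values at the calibration sample cells.
#' @param actual the samples' observed scores.
#' @return sigma (> 0); a perfect fit is an error because it degenerates the
#'   assignment model.
#' @export
estimate_sigma <- function(predicted, actual) {
  ok <- is.finite(predicted) & is.finite(actual)
  if (sum(ok) < 3) stop("need at least 3 finite predicted/actual pairs")
  if (stats::var(predicted[ok]) == 0)
    stop("predicted scores are constant; cannot calibrate sigma")
  fit <- stats::lm(actual[ok] ~ predicted[ok])
  s <- summary(fit)$sigma
  if (!is.finite(s) || s <= 1e-8 * max(stats::sd(actual[ok]), .Machine$double.eps))
    stop("all calibration residuals are zero: degenerate assignment model")
  s
}

#' Reference assignment sigma
#'
#' The published calibration of the assignment density for eastern red bat
#' fur reports a residual variance of 9.696 on the PC1 scale; by default the
#' value is interpreted as sigma^2, giving sigma = sqrt(9.696) ~ 3.114. Set
#' \code{mode = "sd"} to treat the value as sigma itself.
#'
#' @param value the published dispersion value (default 9.696).
#' @param mode \code{"variance"} (default) or \code{"sd"}.
#' @return sigma.
#' @export
reference_sigma <- function(value = 9.696, mode = c("variance", "sd")) {
  mode <- match.arg(mode)
  if (value <= 0) stop("dispersion must be positive")
  if (mode == "variance") sqrt(value) else value
}

#' Correlation between two surfaces at random locations
#'
#' Pearson correlation of the two maps' values at \code{n_points} cells
#' drawn uniformly among the cells where both maps are finite.
#'
#' @param map_a,map_b \code{basemap}s or \code{raster_grid}s on one grid.
#' @param n_points number of random locations (default 150).
#' @param seed integer seed for the draw.
#' @return Pearson correlation coefficient.
#' @export
surface_correlation <- function(map_a, map_b, n_points = 150, seed = 1) {
  ga <- if (inherits(map_a, "basemap")) map_a$mu else map_a
  gb <- if (inherits(map_b, "basemap")) map_b$mu else map_b
  if (!same_grid(ga, gb)) stop("maps must share one grid")
  if (n_points < 3) stop("n_points must be at least 3")
  ok <- which(is.finite(ga$values) & is.finite(gb$values))
  if (length(ok) < 3) stop("fewer than 3 overlapping in-range cells")
  idx <- with_seed(seed, sample(ok, n_points, replace = length(ok) < n_points))
  stats::cor(ga$values[idx], gb$values[idx])
}

#' Build a full basemap from profiles and soil grids
#'
#' Convenience orchestration of the basemap stage: score the samples with
#' the model, IDW-interpolate the direct portion, extend indirectly through
#' the transfer regressions, merge within the range mask, and calibrate
#' sigma by regressing the samples' actual scores on the merged map's
#' predictions at their cells (unless a fixed sigma is supplied).
#'
#' @param profiles training \code{element_profile_set}.
#' @param model fitted \code{gwpca_model}.
#' @param soil \code{soil_grid_set} on the template grid.
#' @param regressions \code{element_regression_set} for the indirect portion.
#' @param range \code{range_mask}; defaults to the full soil grid.
#' @param power IDW power.
#' @param buffer_deg hull buffer for the direct extent.
#' @param sigma fixed sigma; \code{NULL} (default) calibrates it from the
#'   training samples.
#' @param mode scoring mode passed through to scoring and the indirect
#'   surface.
#' @return a \code{basemap}.
#' @export
build_basemap <- function(profiles, model, soil, regressions, range = NULL,
                          power = 2, buffer_deg = 0, sigma = NULL,
                          mode = "raw") {
  template <- soil$template
  if (is.null(range)) range <- full_range_mask(template)
  scores <- score_samples(model, profiles, mode = mode)
  direct <- idw_interpolate(scores, template, power = power)
  dmask <- direct_extent(profiles, template, buffer_deg = buffer_deg)
  indirect <- indirect_surface(soil, regressions, model, mode = mode)
  bm <- merge_basemap(direct, dmask, indirect, range, sigma = 1,
                      meta = list(power = power, buffer_deg = buffer_deg,
                                  bandwidth = model$bandwidth,
                                  kernel = model$kernel, mode = mode))
  if (is.null(sigma)) {
    # IDW honours its nodes exactly, so map values at the training cells are
    # (near-)identical to the training scores; calibrate sigma on
    # leave-one-out IDW predictions instead, so residuals reflect real
    # interpolation error.
    predicted <- loo_idw_predict(scores, power = power)
    sigma <- estimate_sigma(predicted, scores$PC1)
  }
  bm$sigma <- sigma
  if (!is.finite(bm$sigma) || bm$sigma <= 0) stop("sigma must be > 0")
  bm
}

# Leave-one-out IDW prediction of each sample's score from the others.
loo_idw_predict <- function(scores, power = 2, column = "PC1") {
  n <- nrow(scores)
  if (n < 4) stop("need at least 4 samples for leave-one-out calibration")
  y <- scores[[column]]
  d <- dist_matrix_km(scores$lon, scores$lat, scores$lon, scores$lat)
  vapply(seq_len(n), function(j) {
    w <- pmax(d[j, -j], 1e-9)^(-power)
    sum(w * y[-j]) / sum(w)
  }, numeric(1))
}
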