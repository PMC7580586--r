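#' Reference fur concentration scales (ppb)
#'
#' Published mean fur concentrations for the 14-element panel in eastern red
#' bats, used as the realistic concentration scale of the synthetic
#' landscape. See also \code{\link{reference_element_table}}.
#' @keywords internal
fur_mean_scales <- function() {
  c(Al = 18.814, Ni = 2.254, Cu = 6.237, Rb = 0.652, Y = 0.378,
    Mo = 1.585, Sn = 4.225, Ba = 5.415, Cs = 0.914, Ce = 0.325,
    Hg = 4.777, Mg = 51.891, Mn = 1.297, Fe = 65.486)
}

#' Configure a synthetic trace-element landscape
#'
#' Defines the study conditions emulated by the generator: spatially
#' autocorrelated soil element fields (baseline + linear gradient + Gaussian
#' bumps, truncated at zero), a weak linear soil-to-fur transfer
#' (\code{fur = a + b * soil + noise}, truncated at zero), high
#' inter-individual dispersion (fur SD above half the mean), and per-element
#' fur-soil R-squared under 0.16 for the default signal level.
#'
#' @param seed integer seed; the whole landscape (fields and individuals) is
#'   reproducible from it.
#' @param extent named vector \code{c(xmin, xmax, ymin, ymax)} in degrees.
#'   The default is an abstract region with the aspect of eastern North
#'   America.
#' @param cell_size cell edge in degrees (default 0.16).
#' @param elements element panel (no duplicates).
#' @param n_individuals number of known-origin individuals to simulate.
#' @param signal \code{"default"} (weak coupling, the study-like condition),
#'   \code{"strong"} (high transfer R-squared, strong spatial structure) or
#'   \code{"none"} (flat soil, fur is pure noise); presets set the
#'   per-element field and transfer parameters below.
#' @param field optional data.frame overriding the per-element parameters:
#'   one row per element with columns \code{baseline}, \code{n_bumps},
#'   \code{bump_amplitude}, \code{bump_scale}, \code{gradient_lon},
#'   \code{gradient_lat} (ppb per degree), \code{intercept}, \code{slope},
#'   \code{noise_sd}.
#' @return a \code{landscape_config} list.
#' @export
landscape_config <- function(seed = 1,
                             extent = c(xmin = -96, xmax = -72, ymin = 30, ymax = 46),
                             cell_size = 0.16,
                             elements = canonical_elements(),
                             n_individuals = 126,
                             signal = c("default", "strong", "none"),
                             field = NULL) {
  signal <- match.arg(signal)
  extent <- as.numeric(extent[c("xmin", "xmax", "ymin", "ymax")])
  names(extent) <- c("xmin", "xmax", "ymin", "ymax")
  if (anyNA(extent) || extent["xmax"] <= extent["xmin"] || extent["ymax"] <= extent["ymin"])
    stop("degenerate extent")
  if (cell_size <= 0) stop("cell_size must be positive")
  if (n_individuals < 0) stop("n_individuals must be >= 0")
  if (anyDuplicated(elements)) stop("element list has duplicates")

  if (is.null(field)) {
    m <- fur_mean_scales()[elements]
    m[is.na(m)] <- 1  # non-canonical elements default to unit scale
    s0 <- 20 * m      # soil richer than fur by roughly an order of magnitude
    field <- switch(signal,
      default = data.frame(
        baseline = s0, n_bumps = 6, bump_amplitude = 0.6 * s0, bump_scale = 3,
        gradient_lon = 0.02 * s0 * rep_len(c(1, -1), length(m)),
        gradient_lat = 0.02 * s0 * rep_len(c(-1, 1), length(m)),
        intercept = 0.2 * m, slope = 0.8 * m / s0, noise_sd = 0.72 * m),
      strong = data.frame(
        baseline = s0, n_bumps = 8, bump_amplitude = 1.2 * s0, bump_scale = 4,
        gradient_lon = 0.04 * s0 * rep_len(c(1, -1), length(m)),
        gradient_lat = 0.04 * s0 * rep_len(c(-1, 1), length(m)),
        intercept = 0.1 * m, slope = 0.9 * m / s0, noise_sd = 0.08 * m),
      none = data.frame(
        # soil essentially flat (the whisper of a gradient keeps the transfer
        # regressions well-posed) and zero transfer slope: fur is pure noise
        baseline = s0, n_bumps = 0, bump_amplitude = 0, bump_scale = 3,
        gradient_lon = 1e-6 * s0, gradient_lat = 0,
        intercept = m, slope = 0, noise_sd = 0.75 * m)
    )
    rownames(field) <- elements
  } else {
    need <- c("baseline", "n_bumps", "bump_amplitude", "bump_scale",
              "gradient_lon", "gradient_lat", "intercept", "slope", "noise_sd")
    miss <- setdiff(need, names(field))
    if (length(miss)) stop("field is missing column(s): ", paste(miss, collapse = ", "))
    if (nrow(field) != length(elements)) stop("field needs one row per element")
    rownames(field) <- elements
  }
  if (any(field$baseline < 0) || any(field$noise_sd < 0))
    stop("baselines and noise SDs must be >= 0")

  structure(list(seed = as.integer(seed), extent = extent,
                 cell_size = cell_size, elements = elements,
                 n_individuals = as.integer(n_individuals),
                 signal = signal, field = field),
            class = "landscape_config")
}

#' Generate synthetic soil element grids
#'
#' Each element's surface is \code{baseline + linear gradient + sum of
#' Gaussian bumps}, truncated at zero. Bump centres are drawn uniformly over
#' the extent from the config seed, so regeneration from the same config is
#' bit-identical. Gradients are measured from the extent centre so they do
#' not shift the regional mean.
#'
#' @param config a \code{\link{landscape_config}}.
#' @return a \code{soil_grid_set} on the config grid.
#' @export
generate_soil_grids <- function(config) {
  stopifnot(inherits(config, "landscape_config"))
  e <- config$extent
  template <- grid_from_extent(e["xmin"], e["xmax"], e["ymin"], e["ymax"],
                               config$cell_size)
  ctr <- cell_center(template)
  lon0 <- mean(c(e["xmin"], e["xmax"])); lat0 <- mean(c(e["ymin"], e["ymax"]))
  grids <- with_seed(config$seed, {
    out <- list()
    for (el in config$elements) {
      p <- config$field[el, ]
      v <- p$baseline +
        p$gradient_lon * (ctr$lon - lon0) + p$gradient_lat * (ctr$lat - lat0)
      if (p$n_bumps > 0) {
        bx <- stats::runif(p$n_bumps, e["xmin"], e["xmax"])
        by <- stats::runif(p$n_bumps, e["ymin"], e["ymax"])
        bs <- stats::runif(p$n_bumps, -1, 1) * p$bump_amplitude
        for (k in seq_len(p$n_bumps)) {
          d2 <- (ctr$lon - bx[k])^2 + (ctr$lat - by[k])^2
          v <- v + bs[k] * exp(-d2 / (2 * p$bump_scale^2))
        }
      }
      v <- pmax(v, 0)
      out[[el]] <- raster_grid(template$xmin, template$ymin, template$cell_size,
                               template$nrow, template$ncol,
                               matrix(v, template$nrow, template$ncol))
    }
    out
  })
  soil_grid_set(grids)
}

#' Simulate known-origin fur profiles from a soil landscape
#'
#' Individuals get uniform-random origins inside the range mask (or the full
#' extent); each element's fur concentration is the linear transfer of the
#' soil value at the origin cell plus Gaussian noise, truncated at zero:
#' \code{fur_e = a_e + b_e * soil_e(origin) + N(0, noise_e)}.
#'
#' @param soil a \code{soil_grid_set} covering the sampling extent.
#' @param config the \code{\link{landscape_config}} used to generate it.
#' @param mask optional \code{range_mask} on the soil grid restricting
#'   origins.
#' @return list with \code{profiles} (an \code{element_profile_set}) and
#'   \code{truth} (true origins, the soil set, and the transfer parameters).
#' @export
sample_fur_profiles <- function(soil, config, mask = NULL) {
  stopifnot(is_soil_grid_set(soil), inherits(config, "landscape_config"))
  template <- soil$template
  if (!is.null(mask) && !same_grid(mask, template))
    stop("mask must share the soil grid geometry")
  n <- config$n_individuals
  e <- config$extent
  if (!is.null(mask) && n > 0 && !any(mask_matrix(mask)))
    stop("range mask is empty: no cell available for sampling origins")

  origins <- with_seed(config$seed + 1L, {
    lon <- numeric(0); lat <- numeric(0)
    while (length(lon) < n) {
      m <- max(2L * (n - length(lon)), 16L)
      cand_lon <- stats::runif(m, e["xmin"], e["xmax"])
      cand_lat <- stats::runif(m, e["ymin"], e["ymax"])
      keep <- rep(TRUE, m)
      if (!is.null(mask))
        keep <- as.logical(mask_matrix(mask)[as.matrix(cell_of(mask, cand_lon, cand_lat))])
      lon <- c(lon, cand_lon[keep]); lat <- c(lat, cand_lat[keep])
    }
    data.frame(lon = lon[seq_len(n)], lat = lat[seq_len(n)])
  })

  conc <- with_seed(config$seed + 2L, {
    out <- matrix(0, nrow = n, ncol = length(config$elements),
                  dimnames = list(NULL, config$elements))
    for (el in config$elements) {
      p <- config$field[el, ]
      soil_val <- if (n > 0) value_at(soil$grids[[el]], origins$lon, origins$lat) else numeric(0)
      out[, el] <- pmax(p$intercept + p$slope * soil_val +
                          stats::rnorm(n, 0, p$noise_sd), 0)
    }
    out
  })

  ids <- if (n > 0) sprintf("SYN%03d", seq_len(n)) else character(0)
  profiles <- element_profile_set(
    data.frame(sample_id = ids, lon = origins$lon, lat = origins$lat,
               as.data.frame(conc), check.names = FALSE),
    elements = config$elements)
  truth <- structure(list(origins = data.frame(sample_id = ids, origins),
                          soil = soil,
                          transfer = config$field[, c("intercept", "slope", "noise_sd")],
                          config = config),
                     class = "synthetic_truth")
  list(profiles = profiles, truth = truth)
}

#' One-call synthetic dataset
#'
#' Convenience wrapper: generate the soil grids and sample the individuals
#' from one config.
#'
#' @inheritParams sample_fur_profiles
#' @param config a \code{\link{landscape_config}}.
#' @return list with \code{soil}, \code{profiles}, \code{truth}.
#' @export
simulate_landscape <- function(config, mask = NULL) {
  soil <- generate_soil_grids(config)
  smp <- sample_fur_profiles(soil, config, mask)
  list(soil = soil, profiles = smp$profiles, truth = smp$truth)
}
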