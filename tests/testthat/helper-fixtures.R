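# Shared fixture builders. Everything is generated in code; no binary data.

# A small profile set with arbitrary (reproducible) concentrations.
make_profiles <- function(n = 20, elements = c("Al", "Cu", "Ba"), seed = 42,
                          lon_range = c(-90, -80), lat_range = c(32, 40)) {
  withr_seed(seed)
  conc <- matrix(abs(rnorm(n * length(elements), mean = 10, sd = 4)),
                 nrow = n, dimnames = list(NULL, elements))
  element_profile_set(
    data.frame(sample_id = sprintf("B%03d", seq_len(n)),
               lon = runif(n, lon_range[1], lon_range[2]),
               lat = runif(n, lat_range[1], lat_range[2]),
               conc, check.names = FALSE),
    elements = elements)
}

# set.seed without clobbering test reproducibility elsewhere
withr_seed <- function(seed) set.seed(seed)

# A tiny weak-signal landscape config for fast end-to-end runs.
small_config <- function(seed = 5, n = 30, signal = "default", cell_size = 0.8) {
  landscape_config(seed = seed, cell_size = cell_size, n_individuals = n,
                   signal = signal)
}

# A constant-mu basemap on a small grid, for assignment tests.
make_flat_basemap <- function(mu_values, nrow = 1, ncol = length(mu_values),
                              sigma = 1, xmin = 0, ymin = 0, cell = 0.16) {
  g <- raster_grid(xmin, ymin, cell, nrow, ncol,
                   matrix(mu_values, nrow, ncol))
  reg <- raster_grid(xmin, ymin, cell, nrow, ncol, 1)
  structure(list(mu = g, region = reg, sigma = sigma, meta = list()),
            class = "basemap")
}

# Independent haversine (great-circle) distance in km, written from the
# formula so package distance code can be checked against it.
oracle_haversine_km <- function(lon1, lat1, lon2, lat2) {
  r <- 6378137 / 1000  # geosphere's default radius, km
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad / 2
  dlon <- (lon2 - lon1) * to_rad / 2
  a <- sin(dlat)^2 + cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

# Brute-force global Moran's I with rook neighbours on a grid matrix.
oracle_moran_rook <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  x <- as.vector(m)
  xbar <- mean(x)
  num <- 0; wsum <- 0
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    i <- r + (c - 1) * nr
    for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      r2 <- r + d[1]; c2 <- c + d[2]
      if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc) {
        j <- r2 + (c2 - 1) * nr
        num <- num + (x[i] - xbar) * (x[j] - xbar)
        wsum <- wsum + 1
      }
    }
  }
  (length(x) / wsum) * num / sum((x - xbar)^2)
}

# Winding-number point-in-polygon, independent of the package's ray casting.
oracle_point_in_poly <- function(px, py, ring) {
  n <- nrow(ring)
  wn <- 0
  for (k in seq_len(n)) {
    a <- ring[k, ]; b <- ring[if (k == n) 1 else k + 1, ]
    is_left <- (b[1] - a[1]) * (py - a[2]) - (px - a[1]) * (b[2] - a[2])
    if (a[2] <= py) {
      if (b[2] > py && is_left > 0) wn <- wn + 1
    } else {
      if (b[2] <= py && is_left < 0) wn <- wn - 1
    }
  }
  wn != 0
}
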