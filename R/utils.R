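#' Great-circle distance in km
#'
#' Haversine distance on the WGS84 mean sphere, via \pkg{geosphere}. All
#' physical distances in the package (kernel bandwidths, IDW weights, travel
#' buffers) are computed this way; degrees are used only for grid geometry.
#'
#' @param lon1,lat1,lon2,lat2 coordinates in decimal degrees; vectors are
#'   recycled pairwise.
#' @return distances in kilometres.
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2)) / 1000
}

# Pairwise km distance matrix between two coordinate sets.
dist_matrix_km <- function(lon1, lat1, lon2, lat2) {
  geosphere::distm(cbind(lon1, lat1), cbind(lon2, lat2),
                   fun = geosphere::distHaversine) / 1000
}

# Run code under a fixed seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}
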