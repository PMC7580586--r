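score_df <- function(lon, lat, pc1, ids = NULL) {
  d <- data.frame(sample_id = ids %||% sprintf("s%02d", seq_along(lon)),
                  lon = lon, lat = lat, PC1 = pc1)
  class(d) <- c("score_set", "data.frame")
  d
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("IDW honours nodes, symmetry and the closed-form weighting", {
  g <- raster_grid(0, 0, 1, 3, 5)

  # a cell containing a sample takes the sample's score exactly
  ctr <- cell_center(g, 2, 2)
  sc <- score_df(c(ctr$lon, 4.5), c(ctr$lat, 0.5), c(42, 7))
  surf <- idw_interpolate(sc, g)
  expect_equal(surf$values[2, 2], 42)
  expect_equal(surf$values[3, 5], 7)
  # coincident samples in one cell: their mean
  sc2 <- score_df(c(ctr$lon, ctr$lon + 0.01), c(ctr$lat, ctr$lat), c(0, 10))
  expect_equal(idw_interpolate(sc2, g)$values[2, 2], 5)

  # two samples equidistant from a cell centre with values 0 and 10 -> 5
  mid <- cell_center(g, 2, 3)
  sc3 <- score_df(c(mid$lon - 1.4, mid$lon + 1.4), c(mid$lat, mid$lat), c(0, 10))
  for (p in c(1, 2, 4))
    expect_equal(idw_interpolate(sc3, g, power = p)$values[2, 3], 5)

  # closed form: w_j = d_j^-power on haversine distances
  sc4 <- score_df(c(1.2, 3.7), c(0.4, 2.1), c(0, 9))
  surf4 <- idw_interpolate(sc4, g, power = 2)
  target <- cell_center(g, 1, 5)
  d <- oracle_haversine_km(target$lon, target$lat, sc4$lon, sc4$lat)
  expect_equal(surf4$values[1, 5], sum(d^-2 * sc4$PC1) / sum(d^-2))

  # output bounded by the input score range everywhere
  expect_true(all(surf4$values >= 0 & surf4$values <= 9))
  expect_error(idw_interpolate(sc4[0, ], g), "no samples")
  expect_error(idw_interpolate(sc4, g, power = 0), "power")
})

test_that("the hand-worked two-node IDW example gives 1.8", {
  # values 0 and 9 at distances 1 and 2, power 2: (0*1 + 9*0.25)/1.25 = 1.8
  w <- c(1, 2)^-2
  expect_equal(sum(w * c(0, 9)) / sum(w), 1.8)
  # same ratio realized spatially: equator placement, node distances 1:2
  g <- raster_grid(0, -0.5, 1, 1, 7)
  ctr <- cell_center(g, 1, 3)
  deg <- 1.4  # both nodes outside the target cell, distances in ratio 1:2
  sc <- score_df(c(ctr$lon - deg, ctr$lon + 2 * deg), c(0, 0), c(0, 9))
  expect_equal(idw_interpolate(sc, g)$values[1, 3], 1.8, tolerance = 1e-6)
})

test_that("direct extent is the rasterized convex hull of the samples", {
  g <- raster_grid(0, 0, 1, 4, 4)
  corners <- data.frame(lon = c(-0.5, 4.5, 4.5, -0.5), lat = c(-0.5, -0.5, 4.5, 4.5))
  expect_true(all(mask_matrix(direct_extent(corners, g))))

  tri <- data.frame(lon = c(0.2, 3.8, 2), lat = c(0.2, 0.2, 3.8))
  mask <- direct_extent(tri, g)
  ctr <- cell_center(g)
  # barycentric point-in-triangle oracle
  a <- c(0.2, 0.2); b <- c(3.8, 0.2); cc <- c(2, 3.8)
  inside <- vapply(seq_len(16), function(i) {
    p <- c(ctr$lon[i], ctr$lat[i])
    d <- (b[2] - cc[2]) * (a[1] - cc[1]) + (cc[1] - b[1]) * (a[2] - cc[2])
    l1 <- ((b[2] - cc[2]) * (p[1] - cc[1]) + (cc[1] - b[1]) * (p[2] - cc[2])) / d
    l2 <- ((cc[2] - a[2]) * (p[1] - cc[1]) + (a[1] - cc[1]) * (p[2] - cc[2])) / d
    l3 <- 1 - l1 - l2
    l1 >= 0 && l2 >= 0 && l3 >= 0
  }, logical(1))
  expect_identical(as.vector(mask_matrix(mask)), inside)

  # buffering only adds cells
  buf <- direct_extent(tri, g, buffer_deg = 1)
  expect_true(all(mask_matrix(buf)[mask_matrix(mask)]))
  expect_gt(sum(mask_matrix(buf)), sum(mask_matrix(mask)))

  collinear <- data.frame(lon = c(0, 1, 2), lat = c(0, 1, 2))
  expect_error(direct_extent(collinear, g), "collinear")
})

test_that("indirect surfaces pass soil through transfer then loadings", {
  v <- matrix(1:12, 3, 4)
  soil <- soil_grid_set(list(Al = raster_grid(0, 0, 1, 3, 4, v),
                             Cu = raster_grid(0, 0, 1, 3, 4, v * 2)))
  reg_id <- data.frame(element = c("Al", "Cu"), slope = 1, intercept = 0)
  rownames(reg_id) <- reg_id$element

  one_hot <- indirect_surface(soil, reg_id, c(1, 0))
  expect_equal(one_hot$values, v)
  expect_equal(indirect_surface(soil, reg_id, c(0, 0))$values, matrix(0, 3, 4))

  # one element, slope 2 intercept 1, loading 1: soil 3 -> 7
  soil1 <- soil_grid_set(list(Al = raster_grid(0, 0, 1, 1, 1, matrix(3))))
  reg1 <- data.frame(element = "Al", slope = 2, intercept = 1)
  rownames(reg1) <- "Al"
  expect_equal(indirect_surface(soil1, reg1, 1)$values[1, 1], 7)

  # hypothetical fur is truncated at zero before scoring
  regn <- data.frame(element = "Al", slope = -10, intercept = 0)
  rownames(regn) <- "Al"
  expect_equal(indirect_surface(soil1, regn, 1)$values[1, 1], 0)
  expect_error(indirect_surface(soil, reg1, c(1, 0)), "missing regression")
})

test_that("merging keeps each cell from its owning surface, no blending", {
  g0 <- raster_grid(0, 0, 1, 4, 4)
  direct <- raster_grid(0, 0, 1, 4, 4, matrix(1, 4, 4))
  indirect <- raster_grid(0, 0, 1, 4, 4, matrix(2, 4, 4))
  range <- full_range_mask(g0)
  all_mask <- full_range_mask(g0)
  none_mask <- full_range_mask(g0); none_mask$values[] <- 0

  bm_all <- merge_basemap(direct, all_mask, indirect, range, sigma = 1)
  expect_equal(bm_all$mu$values, direct$values)
  bm_none <- merge_basemap(direct, none_mask, indirect, range, sigma = 1)
  expect_equal(bm_none$mu$values, indirect$values)

  checker <- full_range_mask(g0)
  checker$values <- outer(1:4, 1:4, function(r, c) (r + c) %% 2)
  bm <- merge_basemap(direct, checker, indirect, range, sigma = 1)
  for (r in 1:4) for (c in 1:4)
    expect_equal(bm$mu$values[r, c],
                 if ((r + c) %% 2 == 1) direct$values[r, c] else indirect$values[r, c])
  # out-of-range cells are no-data; region labels partition the range
  range2 <- full_range_mask(g0); range2$values[1, 1] <- 0
  bm2 <- merge_basemap(direct, checker, indirect, range2, sigma = 1)
  expect_true(is.na(bm2$mu$values[1, 1]))
  expect_true(all(bm2$region$values[-1] %in% c(1, 2)))
  expect_error(merge_basemap(direct, checker, indirect, range, sigma = 0), "sigma")
})

test_that("sigma is the residual SD of actual on predicted with n-2 df", {
  x <- c(1, 2, 3, 4)
  r <- c(-1, 1, 1, -1)           # valid OLS residuals: sum r = sum r*x = 0
  y <- 2 + 0.5 * x + r
  expect_equal(estimate_sigma(x, y), sqrt(sum(r^2) / 2))
  expect_equal(sqrt(sum(r^2) / 2), sqrt(2))
  suppressWarnings(expect_error(estimate_sigma(x, 2 + 0.5 * x), "zero"))
  expect_error(estimate_sigma(c(1, 2), c(1, 2)), "at least 3")
  expect_error(estimate_sigma(rep(1, 5), rnorm(5)), "constant")
})

test_that("the published dispersion is interpreted as a variance by default", {
  expect_equal(reference_sigma(), sqrt(9.696))
  expect_equal(reference_sigma(mode = "sd"), 9.696)
})

test_that("surface correlation: identity, negation, independence", {
  set.seed(9)
  g <- raster_grid(0, 0, 0.5, 20, 20, matrix(rnorm(400), 20, 20))
  expect_equal(surface_correlation(g, g, n_points = 150, seed = 4), 1)
  neg <- g; neg$values <- -g$values
  expect_equal(surface_correlation(g, neg, n_points = 150, seed = 4), -1)
  other <- g; other$values <- matrix(rnorm(400), 20, 20)
  expect_lt(abs(surface_correlation(g, other, n_points = 150, seed = 4)), 0.25)
  expect_error(surface_correlation(g, other, n_points = 2), "at least 3")
})

test_that("built basemaps keep the direct portion exact under leave-one-out", {
  sim <- simulate_landscape(small_config(seed = 25, n = 25, signal = "strong"))
  m <- fit_gwpca(sim$profiles, bandwidth = 12)
  reg <- fit_element_regressions(sim$profiles,
                                 soil_at_locations(sim$soil, sim$profiles))
  bm <- build_basemap(sim$profiles, m, sim$soil, reg)
  expect_s3_class(bm, "basemap")
  expect_gt(bm$sigma, 0)
  # merged map restricted to the direct mask is bit-identical to the IDW surface
  scores <- score_samples(m, sim$profiles)
  direct <- idw_interpolate(scores, sim$soil$template)
  dmask <- mask_matrix(direct_extent(sim$profiles, sim$soil$template))
  expect_identical(bm$mu$values[dmask], direct$values[dmask])

  # removing one sample keeps exactness at the remaining nodes
  drop1 <- element_profile_set(as.data.frame(sim$profiles)[-1, ],
                               profile_elements(sim$profiles))
  sc1 <- score_samples(m, drop1)
  direct1 <- idw_interpolate(sc1, sim$soil$template)
  rc <- cell_of(sim$soil$template, drop1$lon, drop1$lat)
  solo <- !(duplicated(rc) | duplicated(rc, fromLast = TRUE))
  expect_equal(direct1$values[as.matrix(rc[solo, ])], sc1$PC1[solo])
})
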