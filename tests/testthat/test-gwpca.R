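# minimal model stub for functions that only need a few fields
stub_model <- function(...) structure(list(...), class = "gwpca_model")

test_that("uniform kernel with a global bandwidth reproduces global PCA", {
  ps <- make_profiles(n = 100, elements = canonical_elements(), seed = 31)
  m <- fit_gwpca(ps, bandwidth = 1e6, kernel = "uniform", adaptive = FALSE)
  x <- profile_matrix(ps)
  ref <- eigen(stats::cor(x), symmetric = TRUE)
  # eigenvalues: every location matches the global spectrum to 1e-8 relative
  for (i in c(1, 50, 100))
    expect_equal(m$local_eigenvalues[i, ], ref$values, tolerance = 1e-8)
  # loadings match after applying the same sign convention
  v <- ref$vectors
  for (j in seq_len(ncol(v))) if (v[which.max(abs(v[, j])), j] < 0) v[, j] <- -v[, j]
  expect_equal(unname(m$local_loadings[1, , ]), v, tolerance = 1e-8)
  expect_equal(unname(m$summary_loadings), v, tolerance = 1e-8)
})

test_that("two perfectly correlated elements put all variance on PC1", {
  set.seed(7)
  al <- abs(rnorm(30, 10, 3))
  ps <- element_profile_set(
    data.frame(sample_id = sprintf("c%02d", 1:30),
               lon = runif(30), lat = runif(30),
               Al = al, Cu = 2 * al), c("Al", "Cu"))
  m <- fit_gwpca(ps, bandwidth = 10, kernel = "bisquare", adaptive = TRUE)
  expect_true(all(abs(m$local_eigenvalues[, 1] /
                        rowSums(m$local_eigenvalues) - 1) < 1e-10))
})

test_that("local weighted covariance eigenpairs match a brute-force oracle", {
  df <- data.frame(sample_id = c("p1", "p2", "p3", "p4"),
                   lon = c(-85, -84, -83.5, -84.6),
                   lat = c(33, 34.2, 33.4, 33.9),
                   Al = c(3, 7, 5, 9), Cu = c(10, 2, 6, 5))
  ps <- element_profile_set(df, c("Al", "Cu"))
  k <- 3
  m <- fit_gwpca(ps, bandwidth = k, kernel = "bisquare", adaptive = TRUE)

  x <- cbind(df$Al, df$Cu)
  z <- scale(x)  # same standardization: mean 0, sd 1 (n-1 denominator)
  for (i in 1:4) {
    d <- oracle_haversine_km(df$lon[i], df$lat[i], df$lon, df$lat)
    b <- sort(d)[k]
    w <- ifelse(d < b, (1 - (d / b)^2)^2, 0)
    w <- w / sum(w)
    mu <- c(sum(w * z[, 1]), sum(w * z[, 2]))
    zc <- sweep(z, 2, mu)
    C <- matrix(0, 2, 2)
    for (j in 1:4) C <- C + w[j] * zc[j, ] %*% t(zc[j, ])
    C <- C / (1 - sum(w^2))
    eg <- eigen(C, symmetric = TRUE)
    expect_equal(m$local_eigenvalues[i, ], eg$values, tolerance = 1e-10)
    for (j in 1:2) {
      v <- eg$vectors[, j]
      if (v[which.max(abs(v))] < 0) v <- -v
      expect_equal(unname(m$local_loadings[i, , j]), v, tolerance = 1e-10)
    }
  }
})

test_that("fitted models satisfy the spectral invariants", {
  sim <- simulate_landscape(small_config(seed = 23, n = 30))
  m <- fit_gwpca(sim$profiles, bandwidth = 15)
  expect_true(all(m$local_eigenvalues >= 0))
  expect_true(all(is.finite(m$local_eigenvalues)))
  for (i in c(1, 15, 30)) {
    V <- m$local_loadings[i, , ]
    expect_equal(crossprod(V), diag(ncol(V)), tolerance = 1e-8,
                 ignore_attr = TRUE)
    # sign convention: largest-|entry| of every vector is positive
    for (j in seq_len(ncol(V)))
      expect_gt(V[which.max(abs(V[, j])), j], 0)
  }
  expect_equal(sum(m$proportions), 1)
  expect_true(all(m$proportions >= 0 & m$proportions <= 1))
  expect_equal(m$retained, sum(m$eigen_mean > 1))
  # contract: more samples than elements
  tiny <- element_profile_set(as.data.frame(sim$profiles)[1:10, ],
                              profile_elements(sim$profiles))
  expect_error(fit_gwpca(tiny, bandwidth = 5), "more samples")
})

test_that("loading summaries align signs and reduce by the mean", {
  v <- c(0.6, 0.8)
  L <- array(NA_real_, c(3, 2, 2))
  for (i in 1:3) { L[i, , 1] <- v; L[i, , 2] <- c(0.8, -0.6) }
  m <- stub_model(local_loadings = L, elements = c("Al", "Cu"))
  expect_equal(unname(summarize_loadings(m)[, 1]), v)

  # sign-flipped copies align back to the common vector
  L2 <- L; L2[2, , 1] <- -v
  m2 <- stub_model(local_loadings = L2, elements = c("Al", "Cu"))
  expect_equal(unname(summarize_loadings(m2)[, 1]), v)

  # two distinct unit vectors at equal weight: normalized mean
  a <- c(1, 0); b <- c(0.6, 0.8)
  L3 <- array(NA_real_, c(2, 2, 2))
  L3[1, , 1] <- a; L3[2, , 1] <- b
  L3[1, , 2] <- c(0, 1); L3[2, , 2] <- c(0, 1)
  m3 <- stub_model(local_loadings = L3, elements = c("Al", "Cu"))
  mean_ab <- (a + b) / 2
  expect_equal(unname(summarize_loadings(m3)[, 1]), mean_ab / sqrt(sum(mean_ab^2)))
})

test_that("raw-mode scores are loadings dot raw concentrations", {
  ps <- make_profiles(n = 10, elements = c("Al", "Cu", "Ba"), seed = 3)
  expect_equal(score_samples(rep(0, 3), ps)$PC1, rep(0, 10))

  v <- c(0.2, 0.5, 0.8)
  s1 <- score_samples(v, ps)$PC1
  expect_equal(s1, as.vector(profile_matrix(ps) %*% v))
  # doubling all concentrations doubles the score
  doubled <- as.data.frame(ps)
  doubled[c("Al", "Cu", "Ba")] <- 2 * doubled[c("Al", "Cu", "Ba")]
  s2 <- score_samples(v, element_profile_set(doubled, c("Al", "Cu", "Ba")))$PC1
  expect_equal(s2, 2 * s1)
  # reordering samples reorders scores identically
  perm <- c(5, 1, 9, 2, 10, 3, 8, 4, 7, 6)
  ps_perm <- element_profile_set(as.data.frame(ps)[perm, ], c("Al", "Cu", "Ba"))
  expect_equal(score_samples(v, ps_perm)$PC1, s1[perm])
  expect_error(score_samples(c(0.1, 0.2), ps), "mismatch")
})

test_that("a mean-concentration profile scores near the published weight sum", {
  ref <- reference_element_table()
  load <- reference_loading_table()
  prof <- element_profile_set(
    data.frame(sample_id = "mean_bat", lon = -85, lat = 35,
               as.data.frame(as.list(setNames(ref$mean_ppb, ref$element))),
               check.names = FALSE),
    elements = ref$element)
  score <- score_samples(load$pc1_loading, prof)$PC1
  # sum of the published PC1 weight column is 15.30; scoring the mean profile
  # with the printed (2-dp) loadings reproduces it to rounding error
  expect_equal(sum(load$pc1_weight), 15.30, tolerance = 1e-8)
  expect_lt(abs(score - sum(load$pc1_weight)), 0.5)
})

test_that("variance table proportions and Kaiser retention are arithmetic", {
  m <- stub_model(eigen_mean = c(7, 3.5, 3.5))
  vt <- variance_table(m)
  expect_equal(vt$proportion, c(0.5, 0.25, 0.25))
  expect_equal(sum(vt$retained), 3)

  expect_equal(variance_table(stub_model(eigen_mean = c(2, 2)))$proportion,
               c(0.5, 0.5))
  vt2 <- variance_table(stub_model(eigen_mean = c(1.4, 0.9, 0.7)))
  expect_equal(sum(vt2$retained), 1)
})

test_that("element weights are loading times mean concentration", {
  load <- reference_loading_table()
  ref <- reference_element_table()
  w <- element_weights(load$pc1_loading, ref$mean_ppb)
  ba <- which(ref$element == "Ba")
  expect_equal(w[ba], 0.28 * 5.415)
  expect_lt(abs(w[ba] - load$pc1_weight[ba]), 0.01)  # printed 1.51
  mg <- which(ref$element == "Mg")
  expect_equal(w[mg], 0.18 * 51.891, tolerance = 1e-12)
  expect_equal(element_weights(0, 5.415), 0)
})

test_that("bandwidth selection minimizes the LOO reconstruction error", {
  ps <- make_profiles(n = 20, elements = c("Al", "Cu", "Ba"), seed = 12)
  expect_equal(as.numeric(select_bandwidth(ps, candidates = 8)), 8)

  cand <- c(5, 8, 12, 20)
  bw <- select_bandwidth(ps, candidates = cand)
  cv <- attr(bw, "cv")$cv
  expect_equal(min(cv), cv[match(as.numeric(bw), cand)])
  for (b in cand)
    expect_gte(gwpca_cv_score(ps, b), gwpca_cv_score(ps, as.numeric(bw)) - 1e-12)
  expect_error(select_bandwidth(ps, candidates = numeric(0)), "empty")
  expect_error(select_bandwidth(ps[1:3, ], candidates = 2), "at least 5")
})

test_that("the CV score matches an explicit brute-force recomputation", {
  df <- data.frame(sample_id = paste0("t", 1:5),
                   lon = c(-84, -85, -83, -84.5, -83.7),
                   lat = c(33, 34, 33.5, 34.4, 32.8),
                   Al = c(4, 8, 6, 3, 9), Cu = c(11, 3, 7, 8, 2))
  ps <- element_profile_set(df, c("Al", "Cu"))
  k <- 3
  x <- cbind(df$Al, df$Cu)
  z <- scale(x)
  total <- 0
  for (i in 1:5) {
    d <- oracle_haversine_km(df$lon[i], df$lat[i], df$lon[-i], df$lat[-i])
    b <- sort(d)[k]
    w <- ifelse(d < b, (1 - (d / b)^2)^2, 0); w <- w / sum(w)
    zo <- z[-i, , drop = FALSE]
    mu <- colSums(zo * w)
    zc <- sweep(zo, 2, mu)
    C <- matrix(0, 2, 2)
    for (j in 1:4) C <- C + w[j] * zc[j, ] %*% t(zc[j, ])
    C <- C / (1 - sum(w^2))
    v1 <- eigen(C, symmetric = TRUE)$vectors[, 1]
    r <- z[i, ] - mu
    resid <- r - v1 * sum(v1 * r)
    total <- total + sum(resid^2)
  }
  expect_equal(gwpca_cv_score(ps, k), total, tolerance = 1e-10)
})

test_that("permutation test finds spatial gradients and stays calibrated on noise", {
  # constant scores: undefined statistic, p = 1 with a warning
  ps0 <- make_profiles(n = 12, elements = c("Al", "Cu"), seed = 2)
  m0 <- stub_model(summary_loadings = matrix(0, 2, 2),
                   elements = c("Al", "Cu"))
  expect_warning(res0 <- permutation_test(ps0, m0, n_perm = 99), "constant")
  expect_equal(res0$p_value, 1)

  # strong west-east gradient in scores
  set.seed(5)
  n <- 30
  lon <- runif(n, -90, -80); lat <- runif(n, 32, 40)
  ps1 <- element_profile_set(
    data.frame(sample_id = sprintf("g%02d", 1:n), lon = lon, lat = lat,
               Al = (lon + 91) * 10, Cu = abs(rnorm(n, 5, 1))), c("Al", "Cu"))
  m1 <- stub_model(summary_loadings = diag(2), elements = c("Al", "Cu"))
  res1 <- permutation_test(ps1, m1, n_perm = 199, seed = 7)
  expect_lte(res1$p_value, 0.01)

  # null calibration: shuffled locations give few false positives
  base <- make_profiles(n = 25, elements = c("Al", "Cu", "Ba"), seed = 44)
  m2 <- stub_model(summary_loadings = diag(3), elements = c("Al", "Cu", "Ba"))
  set.seed(101)
  pvals <- vapply(1:50, function(r) {
    d <- as.data.frame(base)
    idx <- sample(nrow(d))
    d$lon <- d$lon[idx]; d$lat <- d$lat[idx]
    permutation_test(element_profile_set(d, profile_elements(base)),
                     m2, n_perm = 99, seed = r)$p_value
  }, numeric(1))
  expect_lte(mean(pvals < 0.05), 0.15)
  expect_error(permutation_test(ps0, m0, n_perm = 10), "at least 99")
})
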