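#' Kernel weights around one location
#'
#' Distance-decay weights used by the geographically weighted PCA. Distances
#' are great-circle km. With an adaptive bandwidth the kernel scale at a
#' location is the distance to its \code{bandwidth}-th nearest sample, so the
#' fit uses a comparable number of neighbours everywhere; with a fixed
#' bandwidth the scale is a constant km radius.
#'
#' @param d vector of distances (km) from the focal location to each sample.
#' @param bandwidth adaptive: neighbour count (integer >= 2); fixed: radius
#'   in km.
#' @param kernel \code{"bisquare"} (default), \code{"gaussian"} or
#'   \code{"uniform"}.
#' @param adaptive logical; interpret \code{bandwidth} as a neighbour count?
#' @return weights normalized to sum to one.
#' @keywords internal
#' @export
kernel_weights <- function(d, bandwidth, kernel = c("bisquare", "gaussian", "uniform"),
                           adaptive = TRUE) {
  kernel <- match.arg(kernel)
  if (adaptive) {
    k <- min(as.integer(bandwidth), length(d))
    if (k < 2) stop("adaptive bandwidth must cover at least 2 samples")
    b <- sort(d, partial = k)[k]
  } else b <- bandwidth
  if (!is.finite(b) || b <= 0) stop("non-positive kernel bandwidth")
  w <- switch(kernel,
    bisquare = ifelse(d < b, (1 - (d / b)^2)^2, 0),
    gaussian = exp(-0.5 * (d / b)^2),
    uniform  = as.numeric(d <= b)
  )
  s <- sum(w)
  if (!is.finite(s) || s <= .Machine$double.eps * length(d))
    stop("kernel weights numerically singular at this bandwidth")
  w / s
}

# Weighted mean + unbiased weighted covariance eigendecomposition.
# Weights must sum to 1; the 1/(1 - sum(w^2)) correction makes the uniform
# 1/n case agree exactly with the n-1 denominator of stats::cov.
weighted_eigen <- function(z, w) {
  mu <- colSums(z * w)
  zc <- sweep(z, 2, mu)
  cw <- crossprod(zc * sqrt(w)) / (1 - sum(w^2))
  eig <- eigen(cw, symmetric = TRUE)
  v <- eig$vectors
  for (j in seq_len(ncol(v))) {           # sign convention: largest-|entry| > 0
    i <- which.max(abs(v[, j]))
    if (v[i, j] < 0) v[, j] <- -v[, j]
  }
  list(values = pmax(eig$values, 0), vectors = v, center = mu)
}

#' Fit a geographically weighted PCA
#'
#' At each sample location, the element concentrations (standardized to zero
#' mean and unit SD per element, i.e. correlation scale) are decomposed by an
#' eigenanalysis of the kernel-weighted covariance, with weights from
#' \code{\link{kernel_weights}}. Eigenvalues are sorted descending; every
#' loading vector is flipped so its largest-magnitude entry is positive,
#' making results reproducible across eigendecomposition backends. The
#' location-wise loadings are summarized into one loading set per component
#' (see \code{\link{summarize_loadings}}) and components are retained by the
#' Kaiser rule (mean eigenvalue > 1 on the correlation scale).
#'
#' @param profiles an \code{element_profile_set} with more samples than
#'   elements.
#' @param bandwidth kernel bandwidth (neighbour count if \code{adaptive},
#'   else km); see \code{\link{select_bandwidth}}.
#' @param kernel kernel name; bisquare by default.
#' @param adaptive logical, adaptive (neighbour-count) bandwidth?
#' @return a \code{gwpca_model}: kernel spec; element means/SDs used for
#'   standardization; per-location loadings (\code{n x p x p} array) and
#'   eigenvalues (\code{n x p}); mean eigen spectrum, variance proportions
#'   and Kaiser-retained count; summary loadings (p x p, one column per
#'   component, unit norm).
#' @export
fit_gwpca <- function(profiles, bandwidth, kernel = "bisquare", adaptive = TRUE) {
  x <- profile_matrix(profiles)
  n <- nrow(x); p <- ncol(x)
  if (n <= p) stop("need more samples (", n, ") than elements (", p, ")")
  mu <- colMeans(x); sd <- apply(x, 2, stats::sd)
  if (any(sd == 0)) stop("constant element(s): ",
                         paste(colnames(x)[sd == 0], collapse = ", "))
  z <- sweep(sweep(x, 2, mu), 2, sd, "/")
  dmat <- dist_matrix_km(profiles$lon, profiles$lat, profiles$lon, profiles$lat)
  loadings <- array(NA_real_, c(n, p, p),
                    dimnames = list(profiles$sample_id, colnames(x), NULL))
  eigenvalues <- matrix(NA_real_, n, p, dimnames = list(profiles$sample_id, NULL))
  for (i in seq_len(n)) {
    w <- kernel_weights(dmat[i, ], bandwidth, kernel, adaptive)
    eg <- weighted_eigen(z, w)
    loadings[i, , ] <- eg$vectors
    eigenvalues[i, ] <- eg$values
  }
  eigen_mean <- colMeans(eigenvalues)
  model <- structure(list(
    kernel = kernel, bandwidth = bandwidth, adaptive = adaptive,
    elements = colnames(x), means = mu, sds = sd,
    coords = data.frame(lon = profiles$lon, lat = profiles$lat),
    local_loadings = loadings, local_eigenvalues = eigenvalues,
    eigen_mean = eigen_mean,
    proportions = eigen_mean / sum(eigen_mean),
    retained = sum(eigen_mean > 1)
  ), class = "gwpca_model")
  model$summary_loadings <- summarize_loadings(model)
  model
}

#' @export
print.gwpca_model <- function(x, ...) {
  cat(sprintf("gwpca_model: %d samples, %d elements, %s kernel, bandwidth %g (%s)\n",
              nrow(x$coords), length(x$elements), x$kernel, x$bandwidth,
              if (x$adaptive) "adaptive neighbours" else "km"),
      sprintf("  variance proportions: %s\n",
              paste(sprintf("%.3f", x$proportions[seq_len(min(4, length(x$proportions)))]),
                    collapse = " ")),
      sprintf("  Kaiser-retained components: %d\n", x$retained), sep = "")
  invisible(x)
}

#' Collapse local loadings to one loading set per component
#'
#' Local loading vectors of one component can differ in sign and direction
#' from place to place. Each location's vector is aligned to the first
#' location's (flipped when their dot product is negative), then reduced
#' element-wise by the mean (or median) and renormalized to unit norm, with
#' the largest-magnitude entry kept positive.
#'
#' @param model a \code{gwpca_model}.
#' @param method \code{"mean"} (default) or \code{"median"}.
#' @return matrix (elements x components) of unit-norm summary loadings.
#' @export
summarize_loadings <- function(model, method = c("mean", "median")) {
  method <- match.arg(method)
  L <- model$local_loadings
  n <- dim(L)[1]; p <- dim(L)[2]
  out <- matrix(NA_real_, p, p, dimnames = list(model$elements, NULL))
  for (j in seq_len(p)) {
    vs <- L[, , j, drop = FALSE]
    dim(vs) <- c(n, p)
    ref <- vs[1, ]
    flip <- as.vector(vs %*% ref) < 0
    vs[flip, ] <- -vs[flip, ]
    v <- if (method == "mean") colMeans(vs) else apply(vs, 2, stats::median)
    nv <- sqrt(sum(v^2))
    if (nv == 0) stop("degenerate summary loading for component ", j)
    v <- v / nv
    i <- which.max(abs(v))
    if (v[i] < 0) v <- -v
    out[, j] <- v
  }
  out
}

#' Principal-component scores for element profiles
#'
#' The default (\code{mode = "raw"}) scores an individual as the dot product
#' of its raw ppb concentrations with the summary loading vector, the scale
#' on which the basemap and assignment operate (scores are then positive for
#' positive-loaded panels). \code{mode = "standardized"} scores the
#' standardized concentrations instead (conventional PCA scores, centred
#' near zero).
#'
#' @param object a \code{gwpca_model}, or a loading matrix/vector whose rows
#'   follow the profile element order (raw mode only).
#' @param profiles an \code{element_profile_set} with matching element order.
#' @param mode \code{"raw"} (default) or \code{"standardized"}.
#' @param components which components to score (default 1).
#' @return a \code{score_set}: data.frame with \code{sample_id},
#'   \code{lon}, \code{lat} and one \code{PC<k>} column per component.
#' @export
score_samples <- function(object, profiles, mode = c("raw", "standardized"),
                          components = 1) {
  mode <- match.arg(mode)
  x <- profile_matrix(profiles)
  if (inherits(object, "gwpca_model")) {
    if (!identical(object$elements, profile_elements(profiles)))
      stop("element order mismatch between model and profiles")
    V <- object$summary_loadings[, components, drop = FALSE]
    if (mode == "standardized")
      x <- sweep(sweep(x, 2, object$means), 2, object$sds, "/")
  } else {
    V <- cbind(object)[, components, drop = FALSE]
    if (nrow(V) != ncol(x))
      stop("element order mismatch: loading length ", nrow(V),
           " vs ", ncol(x), " elements")
    if (mode == "standardized")
      stop("standardized scoring needs a gwpca_model (means and SDs)")
  }
  s <- x %*% V
  colnames(s) <- paste0("PC", components)
  out <- data.frame(sample_id = profiles$sample_id,
                    lon = profiles$lon, lat = profiles$lat, s,
                    check.names = FALSE)
  class(out) <- c("score_set", "data.frame")
  out
}

#' Variance-explained table and Kaiser retention
#'
#' @param model a \code{gwpca_model}.
#' @return data.frame with \code{component}, \code{eigenvalue} (mean of the
#'   local spectra), \code{proportion}, \code{cumulative} and
#'   \code{retained} (eigenvalue > 1, the Kaiser rule on correlation-scale
#'   eigenvalues).
#' @export
variance_table <- function(model) {
  ev <- model$eigen_mean
  data.frame(component = seq_along(ev), eigenvalue = ev,
             proportion = ev / sum(ev),
             cumulative = cumsum(ev) / sum(ev),
             retained = ev > 1)
}

#' Element weights: loading times mean concentration
#'
#' The weight of an element on a component is its summary loading multiplied
#' by its mean concentration, expressing how much of a typical individual's
#' score the element contributes.
#'
#' @param loadings numeric vector (one component) or matrix (elements x
#'   components) of loadings.
#' @param means mean concentrations in the same element order.
#' @return same shape as \code{loadings}.
#' @export
element_weights <- function(loadings, means) {
  L <- cbind(loadings)
  if (nrow(L) != length(means)) stop("element order mismatch")
  w <- L * means
  if (is.null(dim(loadings))) unname(drop(w)) else w
}

#' Leave-one-out cross-validation score of a bandwidth
#'
#' The reconstruction error used by \code{\link{select_bandwidth}}: for each
#' sample, a local PCA is fitted at its location from the remaining samples
#' and the held-out standardized profile is projected onto the leading
#' \code{ncomp} local components; the score is the total squared residual.
#'
#' @inheritParams fit_gwpca
#' @param ncomp number of leading components used in reconstruction.
#' @return total squared reconstruction residual (smaller is better).
#' @export
gwpca_cv_score <- function(profiles, bandwidth, kernel = "bisquare",
                           adaptive = TRUE, ncomp = 1) {
  x <- profile_matrix(profiles)
  n <- nrow(x); p <- ncol(x)
  mu <- colMeans(x); sd <- apply(x, 2, stats::sd)
  z <- sweep(sweep(x, 2, mu), 2, sd, "/")
  dmat <- dist_matrix_km(profiles$lon, profiles$lat, profiles$lon, profiles$lat)
  total <- 0
  for (i in seq_len(n)) {
    w <- kernel_weights(dmat[i, -i], bandwidth, kernel, adaptive)
    eg <- weighted_eigen(z[-i, , drop = FALSE], w)
    V <- eg$vectors[, seq_len(ncomp), drop = FALSE]
    r <- z[i, ] - eg$center
    resid <- r - V %*% crossprod(V, r)
    total <- total + sum(resid^2)
  }
  total
}

#' Select the GW-PCA bandwidth by cross-validation
#'
#' Evaluates \code{\link{gwpca_cv_score}} over the candidate bandwidths and
#' returns the minimizer.
#'
#' @inheritParams gwpca_cv_score
#' @param candidates numeric vector of candidate bandwidths (neighbour
#'   counts if \code{adaptive}, else km); by default neighbour counts
#'   spanning 10\% to 100\% of the sample size.
#' @return the selected bandwidth, with the per-candidate scores attached as
#'   attribute \code{"cv"}.
#' @export
select_bandwidth <- function(profiles, kernel = "bisquare", candidates = NULL,
                             adaptive = TRUE, ncomp = 1) {
  n <- nrow(profiles)
  if (n < 5) stop("need at least 5 samples to select a bandwidth")
  if (is.null(candidates)) {
    if (!adaptive) stop("candidates must be given for a fixed bandwidth")
    candidates <- unique(pmax(4L, round(seq(0.1, 1, by = 0.15) * n)))
  }
  if (!length(candidates)) stop("empty candidate list")
  cv <- vapply(candidates, function(b) {
    tryCatch(gwpca_cv_score(profiles, b, kernel, adaptive, ncomp),
             error = function(e) Inf)
  }, numeric(1))
  if (all(!is.finite(cv)))
    stop("all candidate bandwidths degenerate for this sample set")
  best <- candidates[which.min(cv)]
  attr(best, "cv") <- data.frame(bandwidth = candidates, cv = cv)
  best
}

#' Monte-Carlo permutation test of spatial structure in PC1 scores
#'
#' Tests whether the leading component scores are spatially structured. The
#' statistic is Moran's I of the PC1 scores with inverse-distance weights
#' (computed with \pkg{ape}); the null distribution permutes scores over the
#' sampling locations. The p-value is
#' \code{(1 + count(perm >= observed)) / (n_perm + 1)}.
#'
#' @param profiles the scored \code{element_profile_set}.
#' @param model the fitted \code{gwpca_model}.
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed for the permutations.
#' @return list with \code{statistic} (observed Moran's I), \code{p_value},
#'   \code{n_perm}.
#' @export
permutation_test <- function(profiles, model, n_perm = 199, seed = 1) {
  if (n_perm < 99) stop("n_perm must be at least 99")
  scores <- score_samples(model, profiles)$PC1
  if (stats::sd(scores) == 0) {
    warning("constant scores: Moran's I undefined, returning p = 1")
    return(list(statistic = NA_real_, p_value = 1, n_perm = n_perm))
  }
  d <- dist_matrix_km(profiles$lon, profiles$lat, profiles$lon, profiles$lat)
  w <- 1 / pmax(d, 1e-6)
  diag(w) <- 0
  obs <- ape::Moran.I(scores, w)$observed
  perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    ape::Moran.I(sample(scores), w)$observed
  }, numeric(1)))
  list(statistic = obs,
       p_value = (1 + sum(perm >= obs)) / (n_perm + 1),
       n_perm = n_perm)
}
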