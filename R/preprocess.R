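#' Extract soil values at sample locations
#'
#' Looks up, for every sample, the value of each element's soil grid at the
#' cell containing the sample location.
#'
#' @param soil a \code{soil_grid_set}.
#' @param profiles an \code{element_profile_set} whose locations fall inside
#'   the soil extent.
#' @return numeric matrix (samples x elements), rownames = sample ids.
#' @export
soil_at_locations <- function(soil, profiles) {
  stopifnot(is_soil_grid_set(soil))
  els <- profile_elements(profiles)
  miss <- setdiff(els, soil_elements(soil))
  if (length(miss)) stop("no soil grid for element(s): ", paste(miss, collapse = ", "))
  rc <- cell_of(soil$template, profiles$lon, profiles$lat)
  if (anyNA(rc$row))
    stop("sample(s) outside soil extent: ",
         paste(profiles$sample_id[is.na(rc$row)], collapse = ", "))
  out <- sapply(els, function(el) soil$grids[[el]]$values[as.matrix(rc)])
  out <- matrix(out, nrow = nrow(profiles), dimnames = list(profiles$sample_id, els))
  if (anyNA(out)) {
    bad <- profiles$sample_id[apply(is.na(out), 1, any)]
    stop("sample(s) on no-data soil cells: ", paste(bad, collapse = ", "))
  }
  out
}

#' Robust Mahalanobis outlier screening
#'
#' Computes squared Mahalanobis distances of the element profiles from a
#' robust (minimum covariance determinant) location/scatter estimate and
#' flags samples whose squared distance exceeds the chi-square quantile with
#' one degree of freedom per element. The MCD subset search runs under a
#' fixed internal RNG state on canonically ordered rows, so the flags are
#' deterministic and invariant to sample order; the caller's random seed is
#' untouched.
#'
#' @param profiles an \code{element_profile_set} with more samples than
#'   elements.
#' @param quantile chi-square probability for the cutoff, in (0, 1];
#'   \code{1} flags nothing. Default 0.975.
#' @param method \code{"mcd"} (robust, default) or \code{"classical"}
#'   (plain mean/covariance, mainly for verification).
#' @return an \code{outlier_report}: list with per-sample \code{distance}
#'   (squared), the \code{cutoff}, \code{flagged} ids, and the estimator used.
#' @export
flag_outliers <- function(profiles, quantile = 0.975, method = c("mcd", "classical")) {
  method <- match.arg(method)
  if (!(quantile > 0 && quantile <= 1)) stop("quantile must be in (0, 1]")
  x <- profile_matrix(profiles)
  p <- ncol(x); n <- nrow(x)
  if (n <= p) stop("need more samples (", n, ") than elements (", p, ")")
  ord <- order(rownames(x))
  xs <- x[ord, , drop = FALSE]
  est <- if (method == "mcd") {
    fit <- try(with_seed(20201019L, MASS::cov.rob(xs, method = "mcd")), silent = TRUE)
    if (inherits(fit, "try-error"))
      stop("robust scatter estimation failed (singular scatter); ",
           "consider an element subset or method = 'classical': ",
           attr(fit, "condition")$message)
    list(center = fit$center, cov = fit$cov)
  } else {
    list(center = colMeans(xs), cov = stats::cov(xs))
  }
  cov_inv <- try(solve(est$cov), silent = TRUE)
  if (inherits(cov_inv, "try-error"))
    stop("singular scatter matrix; consider an element subset or regularization")
  d2_sorted <- stats::mahalanobis(xs, est$center, est$cov)
  d2 <- d2_sorted[match(rownames(x), rownames(xs))]
  names(d2) <- rownames(x)
  cutoff <- if (quantile == 1) Inf else stats::qchisq(quantile, df = p)
  structure(list(distance = d2, cutoff = cutoff,
                 flagged = names(d2)[d2 > cutoff],
                 quantile = quantile, method = method,
                 center = est$center, cov = est$cov),
            class = "outlier_report")
}

#' Drop flagged samples from a profile set
#'
#' @param profiles an \code{element_profile_set}.
#' @param report an \code{outlier_report} from \code{\link{flag_outliers}}.
#' @return the profile set without the flagged samples.
#' @export
drop_outliers <- function(profiles, report) {
  stopifnot(inherits(report, "outlier_report"))
  keep <- !(profiles$sample_id %in% report$flagged)
  element_profile_set(as.data.frame(profiles)[keep, , drop = FALSE],
                      profile_elements(profiles))
}

#' Per-element soil-to-fur transfer regressions
#'
#' Ordinary least squares of fur concentration (response) on soil
#' concentration (predictor), one model per element: slope, intercept,
#' R-squared, the two-sided p-value for the slope from the t distribution
#' with n - 2 df, and the residual SD (n - 2 denominator).
#'
#' @param profiles an \code{element_profile_set} (fur concentrations).
#' @param soil_values matrix from \code{\link{soil_at_locations}} with the
#'   same samples and elements.
#' @return an \code{element_regression_set}: data.frame with one row per
#'   element and columns \code{element}, \code{slope}, \code{intercept},
#'   \code{r_squared}, \code{p_value}, \code{residual_sd}, \code{n}.
#' @export
fit_element_regressions <- function(profiles, soil_values) {
  els <- profile_elements(profiles)
  fur <- profile_matrix(profiles)
  if (!all(els %in% colnames(soil_values)))
    stop("soil_values lacks element(s): ",
         paste(setdiff(els, colnames(soil_values)), collapse = ", "))
  if (nrow(soil_values) != nrow(fur)) stop("sample count mismatch")
  if (nrow(fur) < 3) stop("need at least 3 paired observations per element")
  rows <- lapply(els, function(el) {
    x <- soil_values[, el]; y <- fur[, el]
    if (stats::var(x) == 0)
      stop("zero soil variance for element ", el, "; cannot fit its regression")
    fit <- stats::lm(y ~ x)
    sm <- summary(fit)
    data.frame(element = el,
               slope = unname(stats::coef(fit)[2]),
               intercept = unname(stats::coef(fit)[1]),
               r_squared = sm$r.squared,
               p_value = sm$coefficients[2, 4],
               residual_sd = sm$sigma,
               n = length(y))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- out$element
  class(out) <- c("element_regression_set", "data.frame")
  out
}
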