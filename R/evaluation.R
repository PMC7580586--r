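#' Leave-k-out cross-validated evaluation of the assignment pipeline
#'
#' Repeatedly holds out \code{k} individuals, rebuilds the whole assignment
#' machinery from the remaining training samples (summary loadings, transfer
#' regressions, direct + indirect basemap, and sigma unless fixed), assigns
#' each held-out individual back to the rebuilt basemap, and aggregates
#' accuracy (fraction correct, buffer rescues included) and precision (range
#' fraction, averaged over correctly assigned individuals only).
#'
#' @param profiles the known-origin \code{element_profile_set}.
#' @param soil \code{soil_grid_set} covering the sample extent (template of
#'   the basemap).
#' @param range optional \code{range_mask}; defaults to the full grid.
#' @param k held-out individuals per replicate (default 3).
#' @param reps number of replicates (default 100). Held-out sets are drawn
#'   independently per replicate, without replacement within a replicate.
#' @param thresholds probability thresholds to sweep (default 0.5, 0.66,
#'   0.75); the first is the primary threshold used in the headline report.
#' @param buffer_km rescue radius in km (default 10).
#' @param bandwidth GW-PCA bandwidth; \code{NULL} (default) selects it once
#'   on the full sample set and holds it fixed across replicates.
#' @param kernel,adaptive kernel spec, as in \code{\link{fit_gwpca}}.
#' @param power IDW power.
#' @param buffer_deg direct-extent hull buffer (degrees).
#' @param sigma fixed assignment sigma; \code{NULL} (default) re-estimates it
#'   within each replicate from the training residuals, preventing leakage.
#' @param mode scoring mode (\code{"raw"} default).
#' @param seed integer seed; the same seed reproduces the partitions and the
#'   report exactly.
#' @return an \code{evaluation_report}: list with \code{results} (one row
#'   per held-out individual per replicate), \code{per_replicate},
#'   \code{pooled} (accuracy, mean probability, precision summary),
#'   \code{by_threshold}, and the settings used.
#' @export
leave_k_out_cv <- function(profiles, soil, range = NULL, k = 3, reps = 100,
                           thresholds = c(0.5, 0.66, 0.75), buffer_km = 10,
                           bandwidth = NULL, kernel = "bisquare", adaptive = TRUE,
                           power = 2, buffer_deg = 0, sigma = NULL,
                           mode = "raw", seed = 1) {
  n <- nrow(profiles)
  if (k < 1 || reps < 1) stop("need k >= 1 and reps >= 1")
  if (k >= n) stop("k (", k, ") must be smaller than the sample count (", n, ")")
  if (is.null(range)) range <- full_range_mask(soil$template)
  if (is.null(bandwidth))
    bandwidth <- as.numeric(select_bandwidth(profiles, kernel, adaptive = adaptive))
  holdout <- with_seed(seed, t(replicate(reps, sample.int(n, k))))
  holdout <- matrix(holdout, nrow = reps)

  primary <- thresholds[1]
  rows <- vector("list", reps)
  sweep_rows <- vector("list", reps)
  for (r in seq_len(reps)) {
    out_idx <- holdout[r, ]
    train <- element_profile_set(as.data.frame(profiles)[-out_idx, , drop = FALSE],
                                 profile_elements(profiles))
    test <- as.data.frame(profiles)[out_idx, , drop = FALSE]
    model <- fit_gwpca(train, bandwidth, kernel, adaptive)
    regressions <- fit_element_regressions(train, soil_at_locations(soil, train))
    bm <- build_basemap(train, model, soil, regressions, range,
                        power = power, buffer_deg = buffer_deg,
                        sigma = sigma, mode = mode)
    test_scores <- score_samples(model, element_profile_set(test, profile_elements(profiles)),
                                 mode = mode)
    rr <- vector("list", k); sw <- vector("list", k)
    for (j in seq_len(k)) {
      surf <- likelihood_surface(test_scores$PC1[j], bm)
      cls <- classify_assignment(surf, test$lon[j], test$lat[j],
                                 threshold = primary, buffer_km = buffer_km)
      rr[[j]] <- data.frame(rep = r, sample_id = test$sample_id[j],
                            lon = test$lon[j], lat = test$lat[j],
                            y_star = test_scores$PC1[j],
                            probability = cls$probability,
                            correct = cls$correct, rescued = cls$rescued,
                            range_fraction = range_fraction(surf, range, primary),
                            sigma = bm$sigma)
      sw[[j]] <- do.call(rbind, lapply(thresholds, function(th) {
        c2 <- classify_assignment(surf, test$lon[j], test$lat[j],
                                  threshold = th, buffer_km = buffer_km)
        data.frame(rep = r, sample_id = test$sample_id[j], threshold = th,
                   correct = c2$correct,
                   range_fraction = range_fraction(surf, range, th))
      }))
    }
    rows[[r]] <- do.call(rbind, rr)
    sweep_rows[[r]] <- do.call(rbind, sw)
  }
  results <- do.call(rbind, rows)
  sweep_df <- do.call(rbind, sweep_rows)

  per_replicate <- do.call(rbind, lapply(split(results, results$rep), function(d) {
    data.frame(rep = d$rep[1], n_holdout = nrow(d),
               accuracy = mean(d$correct),
               mean_probability = mean(d$probability),
               mean_range_fraction = if (any(d$correct))
                 mean(d$range_fraction[d$correct]) else NA_real_)
  }))
  by_threshold <- do.call(rbind, lapply(split(sweep_df, sweep_df$threshold), function(d) {
    data.frame(threshold = d$threshold[1],
               accuracy = mean(d$correct),
               mean_range_fraction = if (any(d$correct))
                 mean(d$range_fraction[d$correct]) else NA_real_)
  }))
  rownames(per_replicate) <- rownames(by_threshold) <- NULL
  pooled <- list(accuracy = accuracy_summary(results),
                 mean_probability = mean(results$probability),
                 precision = if (any(results$correct))
                   precision_summary(results) else NULL)
  structure(list(results = results, per_replicate = per_replicate,
                 by_threshold = by_threshold, pooled = pooled,
                 settings = list(k = k, reps = reps, thresholds = thresholds,
                                 buffer_km = buffer_km, bandwidth = bandwidth,
                                 kernel = kernel, adaptive = adaptive,
                                 power = power, buffer_deg = buffer_deg,
                                 sigma = sigma, mode = mode, seed = seed,
                                 n = n)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  p <- x$pooled
  cat(sprintf("evaluation_report: %d reps x %d held out (n = %d, seed %d)\n",
              x$settings$reps, x$settings$k, x$settings$n, x$settings$seed))
  cat(sprintf("  pooled accuracy %.3f, mean probability %.3f\n",
              p$accuracy, p$mean_probability))
  if (!is.null(p$precision))
    cat(sprintf("  range fraction over correct: mean %.3f (min %.3f, max %.3f)\n",
                p$precision["mean"], p$precision["min"], p$precision["max"]))
  invisible(x)
}

#' Pooled assignment accuracy
#'
#' Fraction of results classified correct (threshold hits plus buffer
#' rescues).
#'
#' @param results data.frame of assignment results with a logical
#'   \code{correct} column (e.g. \code{report$results}).
#' @return accuracy in [0, 1].
#' @export
accuracy_summary <- function(results) {
  if (!nrow(results)) stop("empty result list")
  mean(results$correct)
}

#' Precision summary over correctly assigned individuals
#'
#' Mean, minimum and maximum range fraction, computed over correct
#' assignments only: an incorrectly assigned individual's surface says
#' nothing about how tightly a correct assignment constrains the origin.
#'
#' @param results data.frame with logical \code{correct} and numeric
#'   \code{range_fraction} columns.
#' @return named numeric vector \code{c(mean, min, max, n_correct)}.
#' @export
precision_summary <- function(results) {
  rf <- results$range_fraction[results$correct]
  if (!length(rf)) stop("no correctly assigned individuals: precision undefined")
  c(mean = mean(rf), min = min(rf), max = max(rf), n_correct = length(rf))
}

#' Re-classify stored assignment surfaces over a threshold sweep
#'
#' @param assignments list of assignments, each a list with elements
#'   \code{surface} (an \code{assignment_surface}), \code{lon}, \code{lat}
#'   (the true location).
#' @param thresholds thresholds in (0, 1); default 0.5, 0.66, 0.75.
#' @param range \code{range_mask} for the precision computation.
#' @param buffer_km rescue radius (default 10).
#' @return data.frame with one row per threshold: \code{accuracy} and
#'   \code{mean_range_fraction} over correct assignments.
#' @export
threshold_sweep <- function(assignments, thresholds = c(0.5, 0.66, 0.75),
                            range, buffer_km = 10) {
  if (any(thresholds <= 0 | thresholds >= 1)) stop("thresholds must be in (0, 1)")
  do.call(rbind, lapply(thresholds, function(th) {
    cls <- lapply(assignments, function(a)
      cbind(classify_assignment(a$surface, a$lon, a$lat, th, buffer_km),
            range_fraction = range_fraction(a$surface, range, th)))
    d <- do.call(rbind, cls)
    data.frame(threshold = th, accuracy = mean(d$correct),
               mean_range_fraction = if (any(d$correct))
                 mean(d$range_fraction[d$correct]) else NA_real_)
  }))
}

#' Serialize / restore an evaluation report (JSON)
#'
#' Round-trips the full report losslessly (all numeric content at full
#' precision).
#'
#' @param report an \code{evaluation_report}.
#' @param path output JSON path.
#' @export
write_evaluation_report <- function(report, path) {
  stopifnot(inherits(report, "evaluation_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_evaluation_report
#' @return \code{read_evaluation_report}: the restored
#'   \code{evaluation_report}.
#' @export
read_evaluation_report <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!is.null(x$pooled$precision)) x$pooled$precision <- unlist(x$pooled$precision)
  structure(x, class = "evaluation_report")
}
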