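#' Published reference tables for eastern red bat fur
#'
#' Small plain-text tables of published reference values for the 14-element
#' fur panel of \emph{Lasiurus borealis}, bundled for worked examples and
#' for checking the pipeline's arithmetic against known results:
#' \itemize{
#'   \item \code{reference_element_table()}: per-element mean and SD of fur
#'     concentration (ppb) and the fur-soil regression R-squared and p-value.
#'   \item \code{reference_loading_table()}: summary PC loadings and weights
#'     (loading x mean concentration) for the first three components, with
#'     the variance proportions (0.50, 0.12, 0.10) attached as attribute
#'     \code{"proportion_variance"}.
#'   \item \code{reference_validation_table()}: 15 independent validation
#'     individuals with sampling location, PC1 value, assignment probability
#'     at the sampling cell and range fraction predicted; \code{footnote}
#'     \code{"a"} marks individuals below the 0.5 threshold at their cell
#'     but rescued by an above-threshold cell within 10 km, \code{"b"}
#'     marks incorrect assignments.
#' }
#'
#' @return a data.frame (see above).
#' @name reference_tables
NULL

ref_path <- function(file) {
  p <- system.file("extdata", file, package = "elementscape")
  if (p == "") stop("bundled reference table not found: ", file)
  p
}

#' @rdname reference_tables
#' @export
reference_element_table <- function() {
  utils::read.csv(ref_path("lborealis_fur_elements.csv"), stringsAsFactors = FALSE)
}

#' @rdname reference_tables
#' @export
reference_loading_table <- function() {
  df <- utils::read.csv(ref_path("lborealis_pca_loadings.csv"), stringsAsFactors = FALSE)
  attr(df, "proportion_variance") <- c(PC1 = 0.50, PC2 = 0.12, PC3 = 0.10)
  df
}

#' @rdname reference_tables
#' @export
reference_validation_table <- function() {
  df <- utils::read.csv(ref_path("lborealis_validation_assignments.csv"),
                        stringsAsFactors = FALSE)
  df$footnote[is.na(df$footnote)] <- ""
  df
}

#' Assignment results from the reference validation table
#'
#' Applies the threshold-plus-buffer-rescue classification rule to the
#' bundled validation individuals: an individual is correct when its
#' probability at the sampling cell reaches the threshold, or when it is
#' flagged as buffer-rescued (footnote \code{"a"}: an above-threshold cell
#' within the 10 km nightly travel distance). The result feeds
#' \code{\link{accuracy_summary}} and \code{\link{precision_summary}}
#' directly.
#'
#' @param threshold probability threshold (default 0.5, compared with
#'   \code{>=}).
#' @return data.frame with \code{lon}, \code{lat}, \code{y_star},
#'   \code{probability}, \code{rescued}, \code{correct},
#'   \code{range_fraction}.
#' @export
validation_assignment_results <- function(threshold = 0.5) {
  df <- reference_validation_table()
  rescued <- df$footnote == "a"
  data.frame(lon = df$lon, lat = df$lat, y_star = df$pc_value,
             probability = df$probability,
             rescued = rescued,
             correct = df$probability >= threshold | rescued,
             range_fraction = df$range_percent)
}
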