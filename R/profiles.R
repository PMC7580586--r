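#' Canonical trace-element panel
#'
#' The 14-element panel measured in fur by ICP-MS: Al, Ni, Cu, Rb, Y, Mo, Sn,
#' Ba, Cs, Ce, Hg, Mg, Mn, Fe, in this fixed order. All concentrations in the
#' package are parts per billion (ppb).
#'
#' @return character vector of element symbols.
#' @export
canonical_elements <- function() {
  c("Al", "Ni", "Cu", "Rb", "Y", "Mo", "Sn", "Ba", "Cs", "Ce", "Hg", "Mg", "Mn", "Fe")
}

#' Element profile sets
#'
#' An element profile set is the pipeline's sample currency: one row per
#' individual, with a unique \code{sample_id}, WGS84 coordinates
#' (\code{lon}, \code{lat}, decimal degrees) and one concentration column per
#' element (ppb, non-negative, no missing values). The element order is fixed
#' at construction and shared by every record.
#'
#' @param df data.frame with columns \code{sample_id}, \code{lon}, \code{lat}
#'   and one numeric column per element.
#' @param elements character vector giving the element columns and their
#'   order; defaults to \code{\link{canonical_elements}}.
#' @return a data.frame of class \code{element_profile_set} with an
#'   \code{elements} attribute.
#' @export
element_profile_set <- function(df, elements = canonical_elements()) {
  if (anyDuplicated(elements)) stop("element list has duplicates")
  need <- c("sample_id", "lon", "lat")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing required column(s): ", paste(miss, collapse = ", "))
  miss_el <- setdiff(elements, names(df))
  if (length(miss_el))
    stop("missing element column(s): ", paste(miss_el, collapse = ", "))
  df <- df[, c(need, elements), drop = FALSE]
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  for (el in elements) {
    v <- df[[el]]
    if (!is.numeric(v)) stop("non-numeric concentration in column ", el)
    if (anyNA(v)) {
      bad <- df$sample_id[is.na(v)]
      stop("missing ", el, " concentration for sample(s): ",
           paste(bad, collapse = ", "))
    }
    if (any(v < 0)) {
      bad <- df$sample_id[v < 0]
      stop("negative ", el, " concentration for sample(s): ",
           paste(bad, collapse = ", "))
    }
  }
  if (anyNA(df$lon) || anyNA(df$lat)) stop("missing coordinates")
  rownames(df) <- NULL
  structure(df, elements = elements,
            class = c("element_profile_set", "data.frame"))
}

#' @rdname element_profile_set
#' @param x object to query.
#' @export
profile_elements <- function(x) attr(x, "elements")

#' Concentration matrix of a profile set
#'
#' @param profiles an \code{element_profile_set}.
#' @return numeric matrix (samples x elements), rownames = sample ids.
#' @export
profile_matrix <- function(profiles) {
  m <- as.matrix(as.data.frame(profiles)[, profile_elements(profiles), drop = FALSE])
  rownames(m) <- profiles$sample_id
  m
}

#' Read / write the sample table CSV
#'
#' The on-disk format is a header CSV with columns \code{sample_id},
#' \code{lon}, \code{lat} and one column per requested element (ppb). Extra
#' columns are ignored with a warning; a missing requested element, a
#' non-numeric concentration, or a duplicate id is a hard ingest error naming
#' the offender. Write-then-read reproduces the set to full precision.
#'
#' @param path CSV file path.
#' @param elements element columns to require, in order.
#' @return \code{read_profile_table}: an \code{element_profile_set}.
#' @export
read_profile_table <- function(path, elements = canonical_elements()) {
  if (!file.exists(path)) stop("sample table not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  miss <- setdiff(c("sample_id", "lon", "lat", elements), names(df))
  if (length(miss))
    stop("sample table ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  extra <- setdiff(names(df), c("sample_id", "lon", "lat", elements))
  if (length(extra))
    warning("ignoring extra column(s) in ", path, ": ",
            paste(extra, collapse = ", "))
  for (el in elements) {
    if (!is.numeric(df[[el]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[el]]))))[1]
      stop("non-numeric ", el, " concentration at row ", bad, " of ", path)
    }
  }
  element_profile_set(df, elements)
}

#' @rdname read_profile_table
#' @param profiles an \code{element_profile_set} to write.
#' @export
write_profile_table <- function(profiles, path) {
  df <- as.data.frame(profiles)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))  # exact round-trip
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
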