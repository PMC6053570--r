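## Geographic predictors: planar Euclidean distances between sites, PCNM
## spatial eigenvectors, and the population -> region lookup.

#' Euclidean distance matrix between sampling locations
#'
#' Coordinates are treated as planar decimal degrees (no projection), so
#' `d_ij = sqrt(dlat^2 + dlon^2)`. A `project = TRUE` option rescales
#' longitude by `cos(mean latitude)` to approximate kilometre-faithful
#' relative distances; the default mirrors the common practice of running
#' spatial eigenfunction analysis on raw coordinates.
#'
#' @param coords data.frame with columns `latitude` and `longitude`
#'   (decimal degrees); row identity gives the site labels, or pass `labels`.
#' @param labels optional site labels.
#' @param project logical; scale longitudes by `cos(mean(lat))`.
#' @return A `dist` object with site labels.
#' @export
euclidean_distance <- function(coords, labels = NULL, project = FALSE) {
  stopifnot(all(c("latitude", "longitude") %in% names(coords)))
  if (nrow(coords) < 2L) stopf("need at least 2 sites")
  if (!all(is.finite(coords$latitude)) || !all(is.finite(coords$longitude)))
    stopf("non-finite coordinates")
  lon <- coords$longitude
  if (project) lon <- lon * cos(mean(coords$latitude) * pi / 180)
  m <- cbind(coords$latitude, lon)
  rownames(m) <- labels %||% rownames(coords) %||% seq_len(nrow(coords))
  dist(m)
}

#' PCNM spatial eigenvectors
#'
#' Principal coordinates of neighbour matrices: the inter-site distance
#' matrix is truncated (distances beyond the threshold replaced by four
#' times the threshold), double-centred as `-D^2/2`, and eigendecomposed;
#' axes with positive eigenvalues are returned as spatial predictors. The
#' default truncation is the longest edge of the minimum spanning tree of
#' the sites (the smallest threshold keeping the network connected). Axis
#' scores are scaled by the square root of their eigenvalue and the sign of
#' each axis is fixed so its first nonzero score is positive.
#'
#' @param d a `dist` object (e.g. from [euclidean_distance()]).
#' @param truncation optional truncation distance; `NULL` for the MST
#'   default.
#' @return An object of class `pcnm_axes`: `vectors` (sites x axes, columns
#'   `PCNM1..k`), `values` (positive eigenvalues, descending), `threshold`.
#' @export
pcnm_axes <- function(d, truncation = NULL) {
  stopifnot(inherits(d, "dist"))
  if (all(d == 0)) stopf("no positive axes (all sites coincident)")
  p <- if (is.null(truncation)) vegan::pcnm(d)
       else vegan::pcnm(d, threshold = truncation)
  if (is.null(p$vectors) || ncol(as.matrix(p$vectors)) == 0L)
    stopf("no positive axes")
  vec <- as.matrix(p$vectors)
  val <- p$values[seq_len(ncol(vec))]
  ## vegan returns unit-norm eigenvectors; rescale to sqrt-eigenvalue scores
  vec <- sweep(vec, 2L, sqrt(val) / sqrt(colSums(vec^2)), `*`)
  for (j in seq_len(ncol(vec))) {
    nz <- which(abs(vec[, j]) > 1e-12)[1L]
    if (!is.na(nz) && vec[nz, j] < 0) vec[, j] <- -vec[, j]
  }
  colnames(vec) <- paste0("PCNM", seq_len(ncol(vec)))
  rownames(vec) <- attr(d, "Labels")
  structure(list(vectors = vec, values = val, threshold = p$threshold),
            class = "pcnm_axes")
}

#' @export
print.pcnm_axes <- function(x, ...) {
  cat(sprintf("pcnm_axes: %d positive axes over %d sites (truncation %.4g)\n",
              ncol(x$vectors), nrow(x$vectors), x$threshold))
  invisible(x)
}

#' Map a population to its geographic region
#'
#' @param population character vector of population names.
#' @param map population frame with `population` and `region` columns
#'   (default [default_populations()]).
#' @return Character vector of regions (`western_jutland`,
#'   `eastern_jutland`, `islands`).
#' @export
assign_region <- function(population, map = default_populations()) {
  i <- match(population, map$population)
  if (anyNA(i)) stopf("unknown population(s): %s",
                      paste(unique(population[is.na(i)]), collapse = ", "))
  map$region[i]
}
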