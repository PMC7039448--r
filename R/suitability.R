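#' Project a fitted model across a landscape
#'
#' Computes fractional-cover covariates in the `radius_m` disc around every
#' cell center (the same disc rule used when building training tables) and
#' feeds them to the model; predictions are rescaled to the declared 0-1000
#' suitability range.
#'
#' @param model an `sdm_fit` or `sdm_ensemble`.
#' @param landcover a [landcover_raster()].
#' @param radius_m covariate buffer radius (m), default 100.
#' @param provenance free-text origin tag stored on the raster.
#' @return a [suitability_raster()] on the 0-1000 scale.
#' @export
project_suitability <- function(model, landcover, radius_m = 100,
                                provenance = NULL) {
  classes <- if (inherits(model, "sdm_ensemble")) {
    model$members[[1L]]$classes
  } else {
    model$classes
  }
  miss <- setdiff(classes, unname(landcover$class_names))
  if (length(miss)) fail("model covariates missing from raster: %s",
                         paste(miss, collapse = ", "))
  covers <- fractional_cover_stack(landcover, radius_m, classes)
  nr <- nrow(landcover$grid); nc <- ncol(landcover$grid)
  newdata <- as.data.frame(matrix(covers, nr * nc, length(classes),
                                  dimnames = list(NULL, classes)),
                           check.names = FALSE)
  p <- predict(model, newdata)
  suitability_raster(matrix(p * 1000, nr, nc), landcover$cell_size_m,
                     landcover$origin_xy, scale = "0-1000",
                     provenance = provenance)
}

#' Zero out area-exclusive covers
#'
#' Sets suitability to 0 on pixels whose land-cover class was not available
#' to the model of a given study area (e.g. vineyards in the plain-area map
#' and rice paddies in the hills-area map); all other pixels are unchanged.
#'
#' @param suit a [suitability_raster()].
#' @param landcover the parent [landcover_raster()].
#' @param excluded_classes character vector of class names to zero.
#' @return a [suitability_raster()] on the same scale.
#' @export
mask_exclusive_covers <- function(suit, landcover, excluded_classes) {
  if (!same_geometry(suit, landcover)) fail("geometry mismatch")
  if (!length(excluded_classes)) return(suit)
  unknown <- setdiff(excluded_classes, unname(landcover$class_names))
  if (length(unknown)) fail("unknown class name(s): %s",
                            paste(unknown, collapse = ", "))
  codes <- as.integer(names(landcover$class_names)[
    match(excluded_classes, unname(landcover$class_names))])
  g <- suit$grid
  g[landcover$grid %in% codes] <- 0
  suitability_raster(g, suit$cell_size_m, suit$origin_xy, scale = suit$scale,
                     provenance = suit$provenance)
}

#' Integrate two suitability maps by per-pixel maximum
#'
#' @param a,b [suitability_raster()]s with identical geometry and scale.
#' @return a [suitability_raster()].
#' @export
merge_max <- function(a, b) {
  if (!same_geometry(a, b)) fail("geometry mismatch")
  if (!identical(a$scale, b$scale)) fail("scale mismatch (%s vs %s)",
                                         a$scale, b$scale)
  suitability_raster(pmax(a$grid, b$grid), a$cell_size_m, a$origin_xy,
                     scale = a$scale,
                     provenance = paste("max(", a$provenance, ",",
                                        b$provenance, ")"))
}

#' Normalize a 0-1000 suitability map to 0-1
#'
#' Division by the declared 1000 ceiling (not by the observed maximum, which
#' would let the empirical maximum redefine the scale).
#'
#' @param suit a [suitability_raster()] on the 0-1000 scale.
#' @return a [suitability_raster()] on the 0-1 scale.
#' @export
normalize_suitability <- function(suit) {
  if (!identical(suit$scale, "0-1000")) fail("expected a 0-1000 scale raster")
  suitability_raster(suit$grid / 1000, suit$cell_size_m, suit$origin_xy,
                     scale = "0-1", provenance = suit$provenance)
}

#' Share of the landscape above a suitability threshold
#'
#' Percentage of non-missing pixels with suitability strictly greater than
#' the threshold (occurrence probability "higher than" the cutoff).
#'
#' @param suit a [suitability_raster()] on the 0-1 scale.
#' @param threshold suitability cutoff (default 0.5).
#' @return percentage in `[0, 100]`.
#' @export
suitable_fraction <- function(suit, threshold = 0.5) {
  if (!identical(suit$scale, "0-1")) fail("expected a 0-1 scale raster")
  v <- suit$grid[!is.na(suit$grid)]
  if (!length(v)) fail("all-missing raster")
  100 * sum(v > threshold) / length(v)
}
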