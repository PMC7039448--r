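#' Fractional land-cover within a buffer
#'
#' The covariate convention throughout the package: a raster cell belongs to
#' the buffer iff its *center* lies within `radius_m` of the probe point,
#' and the fraction is the share of in-buffer cell centers carrying the
#' class. At the raster edge the denominator is the (smaller) set of
#' on-raster in-buffer cells. Because the classes partition the landscape,
#' the fractions at any point sum to 1.
#'
#' @param landcover a [landcover_raster()].
#' @param point numeric length-2 (x, y) in meters.
#' @param radius_m buffer radius (> 0).
#' @param class_code integer land-cover code.
#' @return the fraction in `[0, 1]`.
#' @export
fractional_cover <- function(landcover, point, radius_m, class_code) {
  if (radius_m <= 0) fail("radius_m must be > 0")
  cs <- landcover$cell_size_m
  rc <- cell_at(landcover, point[1L], point[2L])
  if (any(is.na(rc))) fail("point (%g, %g) is off-raster", point[1L], point[2L])
  span <- ceiling(radius_m / cs) + 1L
  rows <- max(1L, rc[1L] - span):min(nrow(landcover$grid), rc[1L] + span)
  cols <- max(1L, rc[2L] - span):min(ncol(landcover$grid), rc[2L] + span)
  cx <- landcover$origin_xy[1L] + (cols - 0.5) * cs
  cy <- landcover$origin_xy[2L] - (rows - 0.5) * cs
  d2 <- outer((cy - point[2L])^2, (cx - point[1L])^2, `+`)
  inbuf <- d2 <= radius_m^2
  if (!any(inbuf)) fail("buffer contains zero cell centers")
  sub <- landcover$grid[rows, cols, drop = FALSE]
  sum(sub[inbuf] == class_code, na.rm = TRUE) / sum(inbuf)
}

# Cell-center disc offsets for a buffer radius, as (dr, dc) pairs.
disc_offsets <- function(radius_m, cell_size_m) {
  span <- ceiling(radius_m / cell_size_m)
  off <- expand.grid(dr = -span:span, dc = -span:span)
  keep <- (off$dr^2 + off$dc^2) * cell_size_m^2 <= radius_m^2
  off[keep, , drop = FALSE]
}

#' Fractional covers at every cell center
#'
#' Moving-window equivalent of [fractional_cover()] evaluated at all cell
#' centers at once; exact, not an approximation (same disc rule).
#'
#' @inheritParams fractional_cover
#' @param classes character vector of class names to compute (default all
#'   classes named on the raster).
#' @return a 3-d array `[row, col, class]` of fractions.
#' @export
fractional_cover_stack <- function(landcover, radius_m,
                                   classes = unname(landcover$class_names)) {
  nr <- nrow(landcover$grid); nc <- ncol(landcover$grid)
  off <- disc_offsets(radius_m, landcover$cell_size_m)
  code_of <- stats::setNames(as.integer(names(landcover$class_names)),
                             unname(landcover$class_names))
  miss <- setdiff(classes, names(code_of))
  if (length(miss)) fail("unknown class name(s): %s", paste(miss, collapse = ", "))
  num <- array(0, dim = c(nr, nc, length(classes)),
               dimnames = list(NULL, NULL, classes))
  den <- matrix(0, nr, nc)
  ind <- lapply(classes, function(cl) {
    m <- landcover$grid == code_of[[cl]]
    m[is.na(m)] <- FALSE
    m
  })
  for (k in seq_len(nrow(off))) {
    dr <- off$dr[k]; dc <- off$dc[k]
    if (max(1L, 1L - dr) > min(nr, nr - dr) ||
        max(1L, 1L - dc) > min(nc, nc - dc)) next
    r_dst <- max(1L, 1L - dr):min(nr, nr - dr)
    c_dst <- max(1L, 1L - dc):min(nc, nc - dc)
    r_src <- r_dst + dr; c_src <- c_dst + dc
    den[r_dst, c_dst] <- den[r_dst, c_dst] + 1
    for (j in seq_along(classes)) {
      num[r_dst, c_dst, j] <- num[r_dst, c_dst, j] +
        ind[[j]][r_src, c_src, drop = FALSE]
    }
  }
  for (j in seq_along(classes)) num[, , j] <- num[, , j] / den
  num
}

#' Build a covariate table for occurrence points
#'
#' One row per occurrence record with the fractional cover of each requested
#' class in the `radius_m` buffer, plus `label` and `study_area` columns.
#' Column order is fixed by `classes` and recorded in attribute
#' `"covariate_classes"`. Per-study-area tables are built by passing that
#' area's class set (excluding the other area's exclusive class).
#'
#' @param landcover a [landcover_raster()].
#' @param occurrences an [occurrence_set()].
#' @param radius_m buffer radius in meters (default 100).
#' @param classes character vector of class names defining the columns.
#' @return a `covariate_table` data.frame.
#' @export
build_covariate_table <- function(landcover, occurrences, radius_m = 100,
                                  classes = unname(landcover$class_names)) {
  code_of <- stats::setNames(as.integer(names(landcover$class_names)),
                             unname(landcover$class_names))
  miss <- setdiff(classes, names(code_of))
  if (length(miss)) fail("unknown class name(s): %s", paste(miss, collapse = ", "))
  n <- nrow(occurrences)
  m <- matrix(NA_real_, n, length(classes), dimnames = list(NULL, classes))
  if (n > 0) {
    rc <- cell_at(landcover, occurrences$x, occurrences$y)
    off <- which(is.na(rc[, 1L]))
    if (length(off)) fail("occurrence point off-raster at row %d", off[1L])
    for (i in seq_len(n)) {
      for (cl in classes) {
        m[i, cl] <- fractional_cover(landcover,
                                     c(occurrences$x[i], occurrences$y[i]),
                                     radius_m, code_of[[cl]])
      }
    }
  }
  tab <- data.frame(m, check.names = FALSE)
  tab$label <- occurrences$label
  tab$study_area <- occurrences$study_area
  attr(tab, "covariate_classes") <- classes
  attr(tab, "radius_m") <- radius_m
  class(tab) <- c("covariate_table", "data.frame")
  tab
}

#' Covariate column names of a table
#' @param table a `covariate_table` (or plain data.frame with the attribute).
#' @return character vector.
#' @export
covariate_classes <- function(table) {
  cl <- attr(table, "covariate_classes")
  if (is.null(cl)) cl <- setdiff(names(table), c("label", "study_area"))
  cl
}

#' Pairwise Pearson collinearity screen
#'
#' Sample Pearson correlation (n - 1 denominator) for every unordered pair
#' of covariate columns; pairs with `|r|` above the threshold are flagged.
#' Zero-variance columns are excluded from the pairs and reported. The
#' screen reports only — dropping variables is a caller decision.
#'
#' @param table a `covariate_table`.
#' @param threshold flag threshold on `|r|` (default 0.60).
#' @return a `collinearity_report` list with elements `pairs` (data.frame
#'   class_a, class_b, pearson_r), `flagged`, `threshold`, `zero_variance`.
#' @export
collinearity_screen <- function(table, threshold = 0.60) {
  vars <- covariate_classes(table)
  if (nrow(table) < 3L) fail("collinearity screen needs >= 3 rows")
  x <- as.matrix(as.data.frame(table)[, vars, drop = FALSE])
  v <- apply(x, 2L, stats::var)
  zero <- vars[v == 0 | is.na(v)]
  keep <- setdiff(vars, zero)
  if (length(keep) < 2L) fail("collinearity screen needs >= 2 non-constant columns")
  cm <- stats::cor(x[, keep, drop = FALSE])
  idx <- which(upper.tri(cm), arr.ind = TRUE)
  pairs <- data.frame(class_a = keep[idx[, 1L]], class_b = keep[idx[, 2L]],
                      pearson_r = cm[idx])
  rep <- list(pairs = pairs,
              flagged = pairs[abs(pairs$pearson_r) > threshold, , drop = FALSE],
              threshold = threshold, zero_variance = zero)
  class(rep) <- "collinearity_report"
  rep
}

#' @export
print.collinearity_report <- function(x, ...) {
  cat(sprintf("Collinearity screen: %d pairs, threshold |r| > %.2f\n",
              nrow(x$pairs), x$threshold))
  if (length(x$zero_variance)) {
    cat(" zero-variance (excluded):", paste(x$zero_variance, collapse = ", "),
        "\n")
  }
  if (nrow(x$flagged)) {
    for (i in seq_len(nrow(x$flagged))) {
      cat(sprintf(" flagged: %s ~ %s  r = %.3f\n", x$flagged$class_a[i],
                  x$flagged$class_b[i], x$flagged$pearson_r[i]))
    }
  } else cat(" no pair flagged\n")
  invisible(x)
}
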