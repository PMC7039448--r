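#' Synthetic landscape configuration
#'
#' Describes a rectangular landscape split into three horizontal strata
#' (a northern massif, a central plain, southern hills), with a per-stratum
#' target mix over nine land-cover classes, two rectangular study sub-areas
#' (a plain "ticino" analogue and a hills "apennine" analogue), classes
#' confined to a single sub-area, and 1-cell-wide rivers crossing the plain.
#'
#' Defaults emulate a two-study-area landscape in which rice paddies occur
#' only in the plain sub-area and vineyards only in the hills sub-area, the
#' massif is woodland-dominated, the plain is arable/rice with scattered
#' urban cover, and the hills mix woodland, vineyards and cultivation.
#'
#' @param width_cells,height_cells grid dimensions.
#' @param cell_size_m cell edge in meters.
#' @param strata named numeric vector of three fractional band heights
#'   (north_massif, central_plain, south_hills) summing to 1.
#' @param class_mix named list, one element per stratum, each a named numeric
#'   vector of target class fractions summing to 1.
#' @param exclusive_classes named character vector mapping class name to the
#'   single sub-area ("ticino" or "apennine") it may occur in.
#' @param subareas named list of two rectangles, each
#'   `c(xmin, xmax, ymin, ymax)` as fractions of width/height (y from top).
#' @param patch_scale_cells Gaussian smoothing scale (cells) controlling
#'   patch size.
#' @param river_count number of north-south rivers crossing the plain.
#' @param seed integer seed.
#' @return a `landscape_config` list.
#' @export
landscape_config <- function(width_cells = 200L, height_cells = 200L,
                             cell_size_m = 100,
                             strata = c(north_massif = 0.30,
                                        central_plain = 0.40,
                                        south_hills = 0.30),
                             class_mix = default_class_mix(),
                             exclusive_classes = c(rice_paddies = "ticino",
                                                   vineyards = "apennine"),
                             subareas = list(
                               ticino = c(0.05, 0.55, 0.32, 0.68),
                               apennine = c(0.25, 0.95, 0.72, 0.98)),
                             patch_scale_cells = 5,
                             river_count = 2L,
                             seed = 1L) {
  if (width_cells < 1 || height_cells < 1) fail("zero-sized raster")
  if (length(strata) != 3L ||
      !identical(names(strata),
                 c("north_massif", "central_plain", "south_hills"))) {
    fail("strata must name north_massif, central_plain, south_hills in order")
  }
  if (abs(sum(strata) - 1) > 1e-9) fail("stratum heights must sum to 1")
  if (!setequal(names(class_mix), names(strata))) {
    fail("class_mix must have one element per stratum")
  }
  for (s in names(class_mix)) {
    m <- class_mix[[s]]
    if (abs(sum(m) - 1) > 1e-9) {
      fail("class_mix for stratum '%s' sums to %.12g, not 1", s, sum(m))
    }
    if (any(m < 0 | m > 1)) fail("class fractions must lie in [0,1]")
  }
  for (cl in names(exclusive_classes)) {
    hosts <- vapply(names(class_mix), function(s) cl %in% names(class_mix[[s]]),
                    TRUE)
    if (sum(hosts) != 1L) {
      fail("exclusive class '%s' must appear in exactly one stratum mix", cl)
    }
    if (!exclusive_classes[[cl]] %in% names(subareas)) {
      fail("exclusive class '%s' names unknown sub-area '%s'", cl,
           exclusive_classes[[cl]])
    }
  }
  if (patch_scale_cells <= 0) fail("patch_scale_cells must be > 0")
  cfg <- list(width_cells = as.integer(width_cells),
              height_cells = as.integer(height_cells),
              cell_size_m = cell_size_m, strata = strata,
              class_mix = class_mix, exclusive_classes = exclusive_classes,
              subareas = subareas, patch_scale_cells = patch_scale_cells,
              river_count = as.integer(river_count), seed = as.integer(seed))
  class(cfg) <- "landscape_config"
  cfg
}

#' The nine land-cover classes
#' @return named integer vector code -> position; names are the class names.
#' @export
landcover_classes <- function() {
  c(urban = 1L, arable = 2L, rice_paddies = 3L, vineyards = 4L,
    complex_cultivations = 5L, meadows = 6L, transitional_woodland = 7L,
    woodland = 8L, water = 9L)
}

#' @rdname landscape_config
#' @export
default_class_mix <- function() {
  list(
    north_massif = c(woodland = 0.55, transitional_woodland = 0.15,
                     meadows = 0.15, arable = 0.05, urban = 0.05,
                     water = 0.05),
    central_plain = c(arable = 0.35, rice_paddies = 0.20, urban = 0.15,
                      complex_cultivations = 0.10, meadows = 0.05,
                      woodland = 0.08, water = 0.07),
    south_hills = c(woodland = 0.30, vineyards = 0.15, arable = 0.20,
                    complex_cultivations = 0.15, transitional_woodland = 0.10,
                    meadows = 0.05, urban = 0.03, water = 0.02))
}

# Row ranges (north = row 1) of the three strata.
stratum_rows <- function(config) {
  h <- config$height_cells
  cuts <- round(cumsum(config$strata) * h)
  cuts[3] <- h
  list(north_massif = seq_len(cuts[1]),
       central_plain = if (cuts[2] > cuts[1]) (cuts[1] + 1):cuts[2] else integer(),
       south_hills = if (h > cuts[2]) (cuts[2] + 1):h else integer())
}

#' Stratum name of each raster row
#' @param config a `landscape_config`.
#' @return character vector of length `height_cells`.
#' @export
stratum_of_rows <- function(config) {
  sr <- stratum_rows(config)
  out <- character(config$height_cells)
  for (s in names(sr)) out[sr[[s]]] <- s
  out
}

#' Logical mask of a study sub-area
#'
#' @param config a `landscape_config`.
#' @param name sub-area name, e.g. "ticino" or "apennine".
#' @return logical matrix, TRUE inside the sub-area rectangle.
#' @export
subarea_mask <- function(config, name) {
  if (!name %in% names(config$subareas)) fail("unknown sub-area '%s'", name)
  r <- config$subareas[[name]]
  h <- config$height_cells; w <- config$width_cells
  rows <- max(1L, floor(r[3] * h) + 1L):min(h, ceiling(r[4] * h))
  cols <- max(1L, floor(r[1] * w) + 1L):min(w, ceiling(r[2] * w))
  m <- matrix(FALSE, h, w)
  m[rows, cols] <- TRUE
  m
}

# Separable Gaussian smoothing with edge renormalisation.
smooth_field <- function(m, sd_cells) {
  half <- max(1L, ceiling(3 * sd_cells))
  k <- dnorm(-half:half, sd = sd_cells)
  k <- k / sum(k)
  conv1 <- function(x) {
    n <- length(x)
    xp <- c(rep(x[1L], half), x, rep(x[n], half))
    as.numeric(stats::filter(xp, k, sides = 2L))[(half + 1L):(half + n)]
  }
  m2 <- apply(m, 2L, conv1)
  t(apply(t(m2), 2L, conv1))
}

#' Generate a synthetic land-cover raster
#'
#' Patch structure comes from smoothed random fields: one iid Gaussian noise
#' field per class is smoothed at `patch_scale_cells` and rank-transformed to
#' a uniform margin; each cell takes the class maximising
#' `log(u_k) / w_k` with `w_k` the cell's stratum target fraction, which
#' draws class k with probability close to `w_k` while preserving the
#' smoothed fields' spatial autocorrelation. Classes confined to one sub-area
#' are excluded from the argmax elsewhere. Rivers are then carved as
#' 1-cell-wide connected north-south water runs crossing the central plain.
#'
#' @param config a `landscape_config`.
#' @return a [landcover_raster()] with the config attached as attribute
#'   `"config"`.
#' @export
generate_landscape <- function(config) {
  stopifnot(inherits(config, "landscape_config"))
  classes <- landcover_classes()
  h <- config$height_cells; w <- config$width_cells
  used <- unique(unlist(lapply(config$class_mix, names)))
  unknown <- setdiff(used, names(classes))
  if (length(unknown)) fail("unknown class name(s): %s",
                            paste(unknown, collapse = ", "))

  grid <- with_seed(config$seed, {
    u <- lapply(used, function(cl) {
      f <- smooth_field(matrix(stats::rnorm(h * w), h, w),
                        config$patch_scale_cells)
      matrix(rank(f, ties.method = "first") / (h * w + 1), h, w)
    })
    names(u) <- used

    score <- array(-Inf, dim = c(h, w, length(used)),
                   dimnames = list(NULL, NULL, used))
    srows <- stratum_rows(config)
    for (s in names(srows)) {
      rows <- srows[[s]]
      if (!length(rows)) next
      mix <- config$class_mix[[s]]
      for (cl in names(mix)) {
        if (mix[[cl]] > 0) {
          score[rows, , cl] <- log(u[[cl]][rows, , drop = FALSE]) / mix[[cl]]
        }
      }
    }
    for (cl in names(config$exclusive_classes)) {
      if (!cl %in% used) next
      allowed <- subarea_mask(config, config$exclusive_classes[[cl]])
      sc <- score[, , cl]
      sc[!allowed] <- -Inf
      score[, , cl] <- sc
    }
    pick <- apply(score, c(1L, 2L), which.max)
    g <- matrix(classes[used[pick]], h, w)

    # rivers: connected 1-cell-wide north-south water runs across the plain
    plain <- srows$central_plain
    if (config$river_count > 0L && length(plain)) {
      for (i in seq_len(config$river_count)) {
        col <- sample.int(w, 1L)
        for (r in plain) {
          g[r, col] <- classes[["water"]]
          col <- min(w, max(1L, col + sample(c(-1L, 0L, 1L), 1L)))
        }
      }
    }
    g
  })

  cn <- names(classes)
  names(cn) <- as.character(classes)
  lc <- landcover_raster(grid, class_names = cn,
                         cell_size_m = config$cell_size_m,
                         origin_xy = c(0, h * config$cell_size_m))
  attr(lc, "config") <- config
  lc
}
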