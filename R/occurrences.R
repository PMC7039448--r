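#' Occurrence sets
#'
#' Labeled occurrence points: planar x/y in meters, the study sub-area the
#' point belongs to, and a label that is either `"presence"` or
#' `"pseudo_absence"`.
#'
#' @param x,y numeric coordinates (m).
#' @param study_area character sub-area names.
#' @param label character, `"presence"` or `"pseudo_absence"`.
#' @return a data.frame of class `occurrence_set`.
#' @export
occurrence_set <- function(x = numeric(), y = numeric(),
                           study_area = character(), label = character()) {
  bad <- !label %in% c("presence", "pseudo_absence")
  if (any(bad)) {
    fail("invalid label '%s' at row %d (must be presence or pseudo_absence)",
         label[which(bad)[1L]], which(bad)[1L])
  }
  df <- data.frame(x = as.numeric(x), y = as.numeric(y),
                   study_area = as.character(study_area),
                   label = as.character(label))
  class(df) <- c("occurrence_set", "data.frame")
  df
}

#' Virtual species configuration
#'
#' The virtual species occupies cells with probability
#' `plogis(beta0 + sum_k beta_k * cover_k)`, where `cover_k` is the
#' fractional cover of class k in a disc of `buffer_radius_m` around the
#' cell center. Default coefficients describe a woodland-associated,
#' urban-averse carnivore that also follows riparian cover.
#'
#' @param beta0 intercept on the log-odds scale.
#' @param betas named numeric vector of log-odds coefficients per class.
#' @param buffer_radius_m covariate buffer radius (m), default 100.
#' @param n_presence number of presence points to draw.
#' @param seed integer seed.
#' @return a `virtual_species_config` list.
#' @export
virtual_species_config <- function(beta0 = -2,
                                   betas = c(woodland = 4,
                                             transitional_woodland = 2,
                                             water = 2.5, meadows = 1,
                                             complex_cultivations = 0.5,
                                             arable = -1.5, vineyards = -0.5,
                                             rice_paddies = -2.5, urban = -4),
                                   buffer_radius_m = 100,
                                   n_presence = 96L, seed = 1L) {
  if (buffer_radius_m <= 0) fail("buffer_radius_m must be > 0")
  if (n_presence < 0) fail("n_presence must be >= 0")
  cfg <- list(beta0 = beta0, betas = betas, buffer_radius_m = buffer_radius_m,
              n_presence = as.integer(n_presence), seed = as.integer(seed))
  class(cfg) <- "virtual_species_config"
  cfg
}

#' Sample presences of a virtual species
#'
#' Draws `n_presence` cells without replacement from the masked cells with
#' probability proportional to the species' logistic suitability; points are
#' placed at cell centers so buffer covariates are exactly recomputable.
#'
#' @param landcover a [landcover_raster()].
#' @param vs a [virtual_species_config()].
#' @param area_mask logical matrix matching the raster; TRUE = candidate cell.
#' @param study_area sub-area name recorded on each point.
#' @return an [occurrence_set()] of presences.
#' @export
sample_virtual_occurrences <- function(landcover, vs, area_mask,
                                       study_area = "area") {
  stopifnot(inherits(vs, "virtual_species_config"))
  if (!identical(dim(area_mask), dim(landcover$grid))) {
    fail("area_mask geometry does not match the raster")
  }
  classes <- landcover$class_names
  unknown <- setdiff(names(vs$betas), unname(classes))
  if (length(unknown)) fail("betas name classes absent from the raster: %s",
                            paste(unknown, collapse = ", "))
  idx <- which(area_mask)
  if (vs$n_presence > length(idx)) {
    fail("n_presence (%d) exceeds candidate cells (%d)", vs$n_presence,
         length(idx))
  }
  if (vs$n_presence == 0L) {
    return(occurrence_set())
  }
  covers <- fractional_cover_stack(landcover, vs$buffer_radius_m)
  eta <- rep(vs$beta0, length(idx))
  for (cl in names(vs$betas)) {
    eta <- eta + vs$betas[[cl]] * covers[, , cl][idx]
  }
  p <- stats::plogis(eta)
  sel <- with_seed(vs$seed, {
    if (all(p == 0)) fail("all candidate cells have zero suitability")
    idx[sample.int(length(idx), vs$n_presence, prob = p)]
  })
  rc <- arrayInd(sel, dim(landcover$grid))
  xy <- cell_center(landcover, rc[, 1L], rc[, 2L])
  occurrence_set(xy[, "x"], xy[, "y"], study_area,
                 rep("presence", length(sel)))
}

#' Generate uniformly random pseudo-absence points
#'
#' Pseudo-absences are placed at the centers of cells drawn uniformly (with
#' replacement) over the mask, matching plain random generation within the
#' study-area boundary; presence cells are not excluded.
#'
#' @param landcover a [landcover_raster()] supplying geometry.
#' @param area_mask logical matrix; TRUE = inside the study area.
#' @param n number of points.
#' @param seed integer seed.
#' @param study_area sub-area name recorded on each point.
#' @return an [occurrence_set()] of pseudo-absences.
#' @export
generate_pseudo_absences <- function(landcover, area_mask, n, seed = 1L,
                                     study_area = "area") {
  if (n < 0) fail("n must be >= 0")
  idx <- which(area_mask)
  if (!length(idx) && n > 0) fail("empty mask with n > 0")
  if (n == 0) return(occurrence_set())
  sel <- with_seed(seed, idx[sample.int(length(idx), n, replace = TRUE)])
  rc <- arrayInd(sel, dim(landcover$grid))
  xy <- cell_center(landcover, rc[, 1L], rc[, 2L])
  occurrence_set(xy[, "x"], xy[, "y"], study_area,
                 rep("pseudo_absence", n))
}

#' Read and write occurrence tables
#'
#' CSV files carry the header `x,y,study_area,label`. The supplementary-file
#' layout (columns x, y, area, presence flag in an XLSX workbook) is also
#' accepted; XLSX is converted through the system `python` interpreter's
#' openpyxl module. Unknown labels and missing coordinates are rejected with
#' the offending row number; duplicate coordinates are retained.
#'
#' @param path file path (`.csv` or `.xlsx`).
#' @param format `"csv"`, `"xlsx"`, or `"auto"` (by extension).
#' @param occ an [occurrence_set()] (for writing).
#' @return an [occurrence_set()].
#' @export
import_occurrences <- function(path, format = c("auto", "csv", "xlsx")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.xlsx$", path, ignore.case = TRUE)) "xlsx" else "csv"
  }
  if (format == "xlsx") {
    py <- Sys.which("python")
    if (py == "") fail("reading XLSX requires a python interpreter on PATH")
    tmp <- tempfile(fileext = ".csv")
    code <- paste(
      "import sys, csv, openpyxl",
      "wb = openpyxl.load_workbook(sys.argv[1], read_only=True)",
      "ws = wb.active",
      "w = csv.writer(open(sys.argv[2], 'w', newline=''))",
      paste("[w.writerow(['' if c is None else c for c in row])",
            "for row in ws.iter_rows(values_only=True)]"),
      sep = "; ")
    status <- system2(py, c("-c", shQuote(code), shQuote(path), shQuote(tmp)))
    if (status != 0L) fail("python/openpyxl conversion of '%s' failed", path)
    path <- tmp
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df) <- tolower(trimws(names(df)))
  # sniff the supplementary-file layout: an 'area' column and a presence flag
  if (!"study_area" %in% names(df) && "area" %in% names(df)) {
    names(df)[names(df) == "area"] <- "study_area"
  }
  if (!"label" %in% names(df) && "presence" %in% names(df)) {
    df$label <- ifelse(df$presence %in% c(1, "1", TRUE, "presence"),
                       "presence", "pseudo_absence")
  }
  need <- c("x", "y", "study_area", "label")
  miss <- setdiff(need, names(df))
  if (length(miss)) fail("occurrence file lacks column(s): %s",
                         paste(miss, collapse = ", "))
  bad <- which(!is.finite(df$x) | !is.finite(df$y))
  if (length(bad)) fail("missing coordinates at row %d", bad[1L])
  occurrence_set(df$x, df$y, df$study_area, df$label)
}

#' Write a synthetic supplementary-layout occurrence file
#'
#' Builds a SYNTHETIC stand-in for a supplementary occurrence workbook:
#' virtual-species presences and uniform pseudo-absences for both study
#' areas at the reference counts (96/71 presences, 300/500
#' pseudo-absences), written in the supplementary layout
#' (columns x, y, area, presence). The data are simulated, not field
#' records.
#'
#' @param path output path (`.csv`, or `.xlsx` via python/openpyxl).
#' @param seed integer seed.
#' @return the path, invisibly.
#' @export
write_synthetic_s1 <- function(path, seed = 1L) {
  cfg <- default_run_config()
  cfg$landscape$width_cells <- 96L
  cfg$landscape$height_cells <- 96L
  cfg$seed <- as.integer(seed)
  m <- run_pipeline(cfg, stages = "simulate", quiet = TRUE)
  occ <- m$occurrences
  df <- data.frame(x = occ$x, y = occ$y, area = occ$study_area,
                   presence = as.integer(occ$label == "presence"))
  if (grepl("\\.xlsx$", path, ignore.case = TRUE)) {
    tmp <- tempfile(fileext = ".csv")
    utils::write.csv(df, tmp, row.names = FALSE)
    py <- Sys.which("python")
    if (py == "") fail("writing XLSX requires a python interpreter on PATH")
    code <- paste(
      "import sys, csv, openpyxl",
      "wb = openpyxl.Workbook()", "ws = wb.active",
      "[ws.append(r) for r in csv.reader(open(sys.argv[1]))]",
      "wb.save(sys.argv[2])", sep = "; ")
    status <- system2(py, c("-c", shQuote(code), shQuote(tmp), shQuote(path)))
    if (status != 0L) fail("python/openpyxl write of '%s' failed", path)
  } else {
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname import_occurrences
#' @export
write_occurrences <- function(occ, path) {
  utils::write.csv(as.data.frame(occ)[, c("x", "y", "study_area", "label")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
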