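#' Pipeline run configuration
#'
#' One structured configuration drives the whole analysis. Every numeric
#' default lives here and nowhere else. `default_run_config()` encodes the
#' reference study conditions: a 200 x 200-cell landscape at 100-m
#' resolution, 96 and 71 virtual-species presences in the plain ("ticino")
#' and hills ("apennine") study areas, 300 and 500 uniform pseudo-absences
#' (proportional to the sub-area surfaces), a 100-m covariate buffer with a
#' 0.60 Pearson screen, GLM + GBM + MaxEnt evaluated over three 75/25
#' splits, a 0.5 suitability cutoff, exponential resistance with r_max 100,
#' a 1-km source grid thinned to one centroid per 5 km in the northern
#' massif, and 100-km / 850-km dispersal scenarios. `demo_run_config()` is
#' a small 64 x 64 run with 60 presences per area for quick end-to-end
#' checks.
#'
#' @return a nested configuration list of class `run_config`.
#' @export
default_run_config <- function() {
  cfg <- list(
    version = 1L,
    seed = 1L,
    landscape = list(width_cells = 200L, height_cells = 200L,
                     cell_size_m = 100, patch_scale_cells = 5,
                     river_count = 2L),
    occurrences = list(source = "synthetic",
                       path = NULL,
                       n_presence = list(ticino = 96L, apennine = 71L),
                       pseudo_absence = list(ticino = 300L, apennine = 500L)),
    covariates = list(radius_m = 100, collinearity_threshold = 0.60),
    models = c("glm", "gbm", "maxent"),
    cv = list(train_fraction = 0.75, n_reps = 3L),
    gbm = list(n_stages = 500L, learning_rate = 0.05, max_depth = 3L),
    suitability = list(threshold = 0.5),
    resistance = list(r_max = 100),
    sources = list(grid_size_m = 1000, rarefy_stratum = "north_massif",
                   rarefy_dist_m = 5000),
    scenarios = list(low = 100, high = 850),
    importance = list(n_permutations = 10L))
  class(cfg) <- "run_config"
  cfg
}

#' @rdname default_run_config
#' @export
demo_run_config <- function() {
  cfg <- default_run_config()
  cfg$landscape$width_cells <- 64L
  cfg$landscape$height_cells <- 64L
  cfg$occurrences$n_presence <- list(ticino = 60L, apennine = 60L)
  cfg$gbm$n_stages <- 100L
  cfg
}

# recursively merge user values into defaults, rejecting unknown keys
merge_config <- function(defaults, user, path = "") {
  for (k in names(user)) {
    full <- if (path == "") k else paste0(path, ".", k)
    if (!k %in% names(defaults)) fail("unknown config key '%s'", full)
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      if (!is.list(user[[k]])) fail("config key '%s' must be a mapping", full)
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]], full)
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Validate a pipeline configuration
#'
#' Reads a YAML file (or takes a list), fills defaults, rejects unknown
#' keys, and range-checks every value. The keys `version` and `seed` are
#' mandatory in user-supplied configurations.
#'
#' @param config path to a YAML file, or a named list.
#' @return a validated `run_config`.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) fail("config file '%s' does not exist", config)
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  if (inherits(config, "run_config")) {
    user <- unclass(config)
  } else {
    if (!is.list(config)) fail("config must be a file path or a list")
    user <- config
    miss <- setdiff(c("version", "seed"), names(user))
    if (length(miss)) fail("missing mandatory config key(s): %s",
                           paste(miss, collapse = ", "))
  }
  cfg <- merge_config(unclass(default_run_config()), user)
  if (!identical(as.integer(cfg$version), 1L)) {
    fail("unsupported config version '%s'", cfg$version)
  }
  chk <- function(ok, key, msg) if (!ok) fail("config key '%s' %s", key, msg)
  chk(cfg$landscape$width_cells >= 8 && cfg$landscape$height_cells >= 8,
      "landscape", "needs width/height of at least 8 cells")
  chk(cfg$landscape$cell_size_m > 0, "landscape.cell_size_m", "must be > 0")
  chk(cfg$cv$train_fraction > 0 && cfg$cv$train_fraction < 1,
      "cv.train_fraction", "must lie strictly between 0 and 1")
  chk(cfg$cv$n_reps >= 1, "cv.n_reps", "must be >= 1")
  chk(all(cfg$models %in% c("glm", "gbm", "maxent")), "models",
      "may only contain glm, gbm, maxent")
  chk(length(cfg$models) >= 1, "models", "needs at least one model")
  chk(cfg$covariates$radius_m > 0, "covariates.radius_m", "must be > 0")
  chk(cfg$suitability$threshold >= 0 && cfg$suitability$threshold < 1,
      "suitability.threshold", "must lie in [0, 1)")
  chk(cfg$resistance$r_max > 1, "resistance.r_max", "must be > 1")
  chk(all(unlist(cfg$occurrences$pseudo_absence) >= 0),
      "occurrences.pseudo_absence", "counts must be >= 0")
  chk(all(unlist(cfg$occurrences$n_presence) >= 0),
      "occurrences.n_presence", "counts must be >= 0")
  chk(all(unlist(cfg$scenarios) > 0), "scenarios", "thresholds must be > 0")
  if (identical(cfg$occurrences$source, "file") &&
      (is.null(cfg$occurrences$path) || !file.exists(cfg$occurrences$path))) {
    fail("config key 'occurrences.path' must name an existing file")
  }
  class(cfg) <- "run_config"
  cfg
}

# Drop covariate columns that are constant on this table (a rare class can
# be constant within one training split even when variable overall).
drop_constant_covariates <- function(tab) {
  vars <- covariate_classes(tab)
  keep <- vars[vapply(vars, function(v) stats::var(tab[[v]]) > 0, TRUE)]
  if (length(keep) == length(vars)) return(tab)
  out <- tab[, c(keep, "label", "study_area"), drop = FALSE]
  attr(out, "covariate_classes") <- keep
  class(out) <- class(tab)
  out
}

# fitting closures for the configured model kinds
pipeline_fitters <- function(cfg, seed) {
  fitters <- list(
    glm = function(tab) fit_sdm_glm(drop_constant_covariates(tab)),
    gbm = function(tab) fit_sdm_gbm(drop_constant_covariates(tab),
                                    n_stages = cfg$gbm$n_stages,
                                    learning_rate = cfg$gbm$learning_rate,
                                    max_depth = cfg$gbm$max_depth,
                                    seed = seed),
    maxent = function(tab) fit_sdm_maxent(drop_constant_covariates(tab),
                                          seed = seed))
  fitters[cfg$models]
}

#' Run the corridor-prediction pipeline
#'
#' Executes the full analysis: synthetic landscape (or supplied
#' occurrences), buffer covariates and collinearity screen, per-area model
#' fitting with replicated evaluation and accuracy-weighted ensembles,
#' landscape-wide projection with exclusive-cover zeroing, per-pixel-max
#' integration and normalisation, exponential resistance, source selection
#' with northern-massif rarefaction, and both dispersal scenarios of
#' factorial least-cost-path density and cumulative resistant kernels.
#'
#' @param config a `run_config` (see [validate_config()]).
#' @param outdir optional output directory; when given, rasters (ESRI
#'   ASCII), tables (CSV) and a JSON manifest with per-artifact checksums
#'   are written there.
#' @param stages run only through this stage: `"simulate"`, `"fit"`,
#'   `"project"`, or `"connect"` (default, everything).
#' @param quiet suppress progress messages.
#' @return a `run_manifest` list with all intermediate objects and a
#'   `summary` element of headline numbers.
#' @export
run_pipeline <- function(config = default_run_config(), outdir = NULL,
                         stages = c("connect", "simulate", "fit", "project"),
                         quiet = FALSE) {
  stages <- match.arg(stages)
  stage_rank <- c(simulate = 1, fit = 2, project = 3, connect = 4)[[stages]]
  cfg <- validate_config(config)
  say <- function(...) if (!quiet) message(sprintf(...))
  seeds <- spawn_seeds(cfg$seed,
                       c("landscape", "vs_ticino", "vs_apennine",
                         "pa_ticino", "pa_apennine", "cv_ticino",
                         "cv_apennine", "fit_ticino", "fit_apennine",
                         "importance"))

  say("stage simulate: generating %d x %d landscape",
      cfg$landscape$height_cells, cfg$landscape$width_cells)
  lcfg <- landscape_config(width_cells = cfg$landscape$width_cells,
                           height_cells = cfg$landscape$height_cells,
                           cell_size_m = cfg$landscape$cell_size_m,
                           patch_scale_cells = cfg$landscape$patch_scale_cells,
                           river_count = cfg$landscape$river_count,
                           seed = seeds[["landscape"]])
  lc <- generate_landscape(lcfg)
  areas <- names(lcfg$subareas)
  masks <- lapply(areas, function(a) subarea_mask(lcfg, a))
  names(masks) <- areas

  occ <- NULL
  if (identical(cfg$occurrences$source, "synthetic")) {
    occ_list <- list()
    for (a in areas) {
      vs <- virtual_species_config(
        buffer_radius_m = cfg$covariates$radius_m,
        n_presence = cfg$occurrences$n_presence[[a]],
        seed = seeds[[paste0("vs_", a)]])
      pres <- sample_virtual_occurrences(lc, vs, masks[[a]], study_area = a)
      pa <- generate_pseudo_absences(lc, masks[[a]],
                                     cfg$occurrences$pseudo_absence[[a]],
                                     seed = seeds[[paste0("pa_", a)]],
                                     study_area = a)
      occ_list[[a]] <- rbind(pres, pa)
    }
    occ <- do.call(rbind, occ_list)
    class(occ) <- c("occurrence_set", "data.frame")
  } else {
    occ <- import_occurrences(cfg$occurrences$path)
    areas <- intersect(areas, unique(occ$study_area))
  }
  for (a in areas) {
    say("  %s: %d presences, %d pseudo-absences", a,
        sum(occ$study_area == a & occ$label == "presence"),
        sum(occ$study_area == a & occ$label == "pseudo_absence"))
  }
  manifest <- list(config = unclass(cfg), seeds = as.list(seeds),
                   landscape_config = lcfg, landcover = lc, occurrences = occ)
  if (stage_rank < 2) return(finish_manifest(manifest, outdir, quiet))

  say("stage fit: covariates and per-area ensembles (%s)",
      paste(cfg$models, collapse = " + "))
  exclusive <- lcfg$exclusive_classes
  all_classes <- names(landcover_classes())
  per_area <- list()
  for (a in areas) {
    drop_cls <- names(exclusive)[exclusive != a]
    classes <- setdiff(all_classes, drop_cls)
    rows <- occ[occ$study_area == a, , drop = FALSE]
    tab <- build_covariate_table(lc, rows, cfg$covariates$radius_m, classes)
    v <- vapply(covariate_classes(tab),
                function(cl) stats::var(tab[[cl]]), 0)
    dropped_zero <- names(v)[v == 0]
    if (length(dropped_zero)) {
      say("  %s: dropping zero-variance covariate(s): %s", a,
          paste(dropped_zero, collapse = ", "))
      keep <- setdiff(covariate_classes(tab), dropped_zero)
      tab <- build_covariate_table(lc, rows, cfg$covariates$radius_m, keep)
    }
    screen <- collinearity_screen(tab, cfg$covariates$collinearity_threshold)
    for (i in seq_len(nrow(screen$flagged))) {
      say("  %s: collinear pair %s ~ %s (r = %.2f)", a,
          screen$flagged$class_a[i], screen$flagged$class_b[i],
          screen$flagged$pearson_r[i])
    }
    fitters <- pipeline_fitters(cfg, seeds[[paste0("fit_", a)]])
    ev <- cross_validate(tab, fitters,
                         train_fraction = cfg$cv$train_fraction,
                         n_reps = cfg$cv$n_reps,
                         seed = seeds[[paste0("cv_", a)]])
    members <- lapply(fitters, function(f) f(tab))
    ens <- sdm_ensemble(members, ev, metric = "auc")
    imp <- variable_importance(ens, tab,
                               n_permutations = cfg$importance$n_permutations,
                               seed = seeds[["importance"]])
    say("  %s: mean test AUC %s", a,
        paste(sprintf("%s %.3f", names(ens$weights),
                      vapply(names(ens$weights), function(m)
                        mean(ev$auc[ev$model == m]), 0)), collapse = ", "))
    per_area[[a]] <- list(table = tab, screen = screen, eval = ev,
                          ensemble = ens, importance = imp,
                          dropped_zero_variance = dropped_zero)
  }
  manifest$per_area <- per_area
  if (stage_rank < 3) return(finish_manifest(manifest, outdir, quiet))

  say("stage project: landscape-wide suitability")
  suit_area <- list()
  for (a in areas) {
    s <- project_suitability(per_area[[a]]$ensemble, lc,
                             radius_m = cfg$covariates$radius_m,
                             provenance = a)
    drop_cls <- names(exclusive)[exclusive != a]
    suit_area[[a]] <- mask_exclusive_covers(s, lc, drop_cls)
  }
  integrated <- normalize_suitability(Reduce(merge_max, suit_area))
  suit_norm <- lapply(suit_area, normalize_suitability)
  suitable_pct <- vapply(suit_norm, suitable_fraction,
                         threshold = cfg$suitability$threshold, 0)
  integrated_pct <- suitable_fraction(integrated, cfg$suitability$threshold)
  say("  suitable fraction: %s; integrated %.2f%%",
      paste(sprintf("%s %.2f%%", names(suitable_pct), suitable_pct),
            collapse = ", "), integrated_pct)
  manifest$suitability <- list(per_area = suit_norm, integrated = integrated,
                               suitable_pct = as.list(suitable_pct),
                               integrated_pct = integrated_pct)
  if (stage_rank < 4) return(finish_manifest(manifest, outdir, quiet))

  say("stage connect: resistance, sources and both dispersal scenarios")
  res <- suitability_to_resistance(integrated, cfg$resistance$r_max)
  sources <- select_sources(integrated,
                            grid_size_m = cfg$sources$grid_size_m,
                            threshold = cfg$suitability$threshold,
                            strata = stratum_of_rows(lcfg),
                            rarefy_stratum = cfg$sources$rarefy_stratum,
                            rarefy_dist_m = cfg$sources$rarefy_dist_m)
  say("  %d source locations", nrow(sources))
  cg <- build_cost_graph(res)
  scen <- list()
  for (nm in names(cfg$scenarios)) {
    sc <- dispersal_scenario(nm, threshold_km = cfg$scenarios[[nm]])
    lcp <- factorial_lcp(res, sources, sc, cg = cg)
    kern <- resistant_kernel(res, sources, sc, cg = cg)
    scen[[nm]] <- list(scenario = sc, lcp_density = lcp, kernel = kern,
                       extent_pct = connectivity_extent(lcp),
                       kernel_extent_pct = connectivity_extent(kern),
                       skipped_pairs = attr(lcp, "skipped"))
    say("  %s (%g km): %.2f%% of cells on a least-cost path, %d pairs skipped",
        nm, sc$threshold_km, scen[[nm]]$extent_pct,
        nrow(scen[[nm]]$skipped_pairs))
  }
  manifest$resistance <- res
  manifest$sources <- sources
  manifest$scenarios <- scen
  finish_manifest(manifest, outdir, quiet)
}

# attach the summary block, write artifacts + JSON manifest if requested
finish_manifest <- function(manifest, outdir, quiet) {
  s <- list()
  if (!is.null(manifest$occurrences)) {
    occ <- manifest$occurrences
    for (a in unique(occ$study_area)) {
      s[[paste0("n_presence_", a)]] <-
        sum(occ$study_area == a & occ$label == "presence")
      s[[paste0("n_pseudo_absence_", a)]] <-
        sum(occ$study_area == a & occ$label == "pseudo_absence")
    }
  }
  if (!is.null(manifest$per_area)) {
    for (a in names(manifest$per_area)) {
      ev <- manifest$per_area[[a]]$eval
      s[[paste0("mean_auc_", a)]] <- mean(ev$auc)
      s[[paste0("mean_tss_", a)]] <- mean(ev$tss)
    }
  }
  if (!is.null(manifest$suitability)) {
    for (a in names(manifest$suitability$suitable_pct)) {
      s[[paste0("suitable_pct_", a)]] <- manifest$suitability$suitable_pct[[a]]
    }
    s$suitable_pct_integrated <- manifest$suitability$integrated_pct
  }
  if (!is.null(manifest$sources)) s$n_sources <- nrow(manifest$sources)
  if (!is.null(manifest$scenarios)) {
    for (nm in names(manifest$scenarios)) {
      s[[paste0("extent_pct_", nm)]] <- manifest$scenarios[[nm]]$extent_pct
      s[[paste0("kernel_extent_pct_", nm)]] <-
        manifest$scenarios[[nm]]$kernel_extent_pct
    }
  }
  manifest$summary <- s
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    paths <- character()
    w <- function(fname, writer) {
      p <- file.path(outdir, fname)
      writer(p)
      paths <<- c(paths, p)
    }
    w("landcover.asc", function(p) write_ascii_grid(manifest$landcover, p))
    w("occurrences.csv", function(p) write_occurrences(manifest$occurrences, p))
    if (!is.null(manifest$per_area)) {
      for (a in names(manifest$per_area)) {
        pa <- manifest$per_area[[a]]
        w(paste0("eval_", a, ".csv"), function(p)
          utils::write.csv(as.data.frame(pa$eval), p, row.names = FALSE))
        w(paste0("importance_", a, ".csv"), function(p)
          utils::write.csv(pa$importance, p, row.names = FALSE))
      }
    }
    if (!is.null(manifest$suitability)) {
      w("suitability_integrated.asc", function(p)
        write_ascii_grid(manifest$suitability$integrated, p))
    }
    if (!is.null(manifest$sources)) {
      w("sources.csv", function(p) write_sources(manifest$sources, p))
    }
    if (!is.null(manifest$scenarios)) {
      for (nm in names(manifest$scenarios)) {
        w(paste0("lcp_density_", nm, ".asc"), function(p)
          write_ascii_grid(manifest$scenarios[[nm]]$lcp_density, p))
        w(paste0("kernel_", nm, ".asc"), function(p)
          write_ascii_grid(manifest$scenarios[[nm]]$kernel, p))
        w(paste0("skipped_pairs_", nm, ".csv"), function(p)
          utils::write.csv(manifest$scenarios[[nm]]$skipped_pairs, p,
                           row.names = FALSE))
      }
    }
    w("resistance.asc", function(p)
      if (!is.null(manifest$resistance))
        write_ascii_grid(manifest$resistance, p))
    paths <- paths[file.exists(paths)]
    manifest$checksums <- as.list(tools::md5sum(paths))
    names(manifest$checksums) <- basename(paths)
    jsonlite::write_json(
      list(config = manifest$config, seeds = manifest$seeds,
           summary = manifest$summary, checksums = manifest$checksums),
      file.path(outdir, "manifest.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  }
  class(manifest) <- "run_manifest"
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest>\n")
  for (k in names(x$summary)) {
    v <- x$summary[[k]]
    cat(sprintf("  %-28s %s\n", k,
                if (is.numeric(v)) format(round(v, 4)) else v))
  }
  invisible(x)
}
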