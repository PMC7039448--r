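#' Suitability-to-resistance conversion
#'
#' Negative-exponential transform `R(h) = r_max^(1 - h)`: fully suitable
#' habitat (h = 1) costs 1, fully unsuitable habitat (h = 0) costs `r_max`,
#' and resistance rises only steeply where suitability is low, so large
#' portions of the landscape stay permeable. Strictly decreasing in h.
#'
#' @param suit a [suitability_raster()] on the 0-1 scale.
#' @param r_max maximum resistance (> 1), default 100.
#' @return a [resistance_raster()] (NA pixels stay NA = untraversable).
#' @export
suitability_to_resistance <- function(suit, r_max = 100) {
  if (!identical(suit$scale, "0-1")) fail("expected a 0-1 scale raster")
  if (r_max <= 1) fail("r_max must be > 1")
  v <- suit$grid[!is.na(suit$grid)]
  if (length(v) && (min(v) < 0 || max(v) > 1)) fail("suitability outside [0,1]")
  resistance_raster(r_max^(1 - suit$grid), suit$cell_size_m, suit$origin_xy)
}

#' Select connectivity source locations
#'
#' A square selection grid (default 1 km) is laid over the raster from its
#' top-left corner; a grid cell qualifies when it contains at least one
#' pixel with suitability strictly above the threshold, and its centroid
#' (of the clipped cell extent at the raster edge) becomes a source.
#' Within `rarefy_stratum`, qualifying centroids are thinned to one per
#' `rarefy_dist_m` square block, keeping the centroid whose cell has the
#' highest maximum suitability (ties: lowest grid row, then column) — used
#' to emulate sporadic occupancy of the northern massif.
#'
#' @param suit a [suitability_raster()] on the 0-1 scale.
#' @param grid_size_m selection-grid cell edge (default 1000).
#' @param threshold suitability cutoff (default 0.5).
#' @param strata optional character vector giving the stratum name of each
#'   raster row (see [stratum_of_rows()]); sources are tagged with the
#'   stratum of their centroid row.
#' @param rarefy_stratum stratum name to thin, or `NULL` for no thinning.
#' @param rarefy_dist_m thinning block edge (default 5000).
#' @return a `source_set` data.frame (x, y, source_cell_id, stratum).
#' @export
select_sources <- function(suit, grid_size_m = 1000, threshold = 0.5,
                           strata = NULL, rarefy_stratum = NULL,
                           rarefy_dist_m = 5000) {
  if (!identical(suit$scale, "0-1")) fail("expected a 0-1 scale raster")
  if (grid_size_m <= 0) fail("grid_size_m must be > 0")
  cs <- suit$cell_size_m
  nr <- nrow(suit$grid); nc <- ncol(suit$grid)
  per <- grid_size_m / cs
  nI <- ceiling(nr / per)
  nJ <- ceiling(nc / per)
  rows_of <- function(I) (floor((I - 1) * per) + 1L):min(nr, ceiling(I * per))
  cols_of <- function(J) (floor((J - 1) * per) + 1L):min(nc, ceiling(J * per))
  out <- list()
  for (I in seq_len(nI)) {
    rr <- rows_of(I)
    for (J in seq_len(nJ)) {
      cc <- cols_of(J)
      block <- suit$grid[rr, cc, drop = FALSE]
      mx <- suppressWarnings(max(block, na.rm = TRUE))
      if (is.finite(mx) && mx > threshold) {
        # centroid of the clipped cell extent
        x0 <- suit$origin_xy[1L] + (J - 1) * grid_size_m
        x1 <- min(suit$origin_xy[1L] + J * grid_size_m,
                  suit$origin_xy[1L] + nc * cs)
        y0 <- suit$origin_xy[2L] - (I - 1) * grid_size_m
        y1 <- max(suit$origin_xy[2L] - I * grid_size_m,
                  suit$origin_xy[2L] - nr * cs)
        cx <- (x0 + x1) / 2
        cy <- (y0 + y1) / 2
        crow <- cell_at(suit, cx, cy)[1L]
        st <- if (!is.null(strata)) strata[crow] else NA_character_
        out[[length(out) + 1L]] <- data.frame(
          x = cx, y = cy, grid_row = I, grid_col = J, max_suit = mx,
          stratum = st)
      }
    }
  }
  if (!length(out)) {
    src <- data.frame(x = numeric(), y = numeric(),
                      source_cell_id = character(), stratum = character())
    class(src) <- c("source_set", "data.frame")
    return(src)
  }
  df <- do.call(rbind, out)
  if (!is.null(rarefy_stratum)) {
    inside <- !is.na(df$stratum) & df$stratum == rarefy_stratum
    keep_idx <- which(!inside)
    sub <- df[inside, , drop = FALSE]
    if (nrow(sub)) {
      bx <- floor((sub$x - suit$origin_xy[1L]) / rarefy_dist_m)
      by <- floor((suit$origin_xy[2L] - sub$y) / rarefy_dist_m)
      for (blk in split(seq_len(nrow(sub)), paste(bx, by))) {
        o <- blk[order(-sub$max_suit[blk], sub$grid_row[blk],
                       sub$grid_col[blk])]
        keep_idx <- c(keep_idx, which(inside)[o[1L]])
      }
    }
    df <- df[sort(keep_idx), , drop = FALSE]
  }
  src <- data.frame(x = df$x, y = df$y,
                    source_cell_id = sprintf("g%d_%d", df$grid_row,
                                             df$grid_col),
                    stratum = df$stratum)
  class(src) <- c("source_set", "data.frame")
  src
}

#' Write a source set
#'
#' CSV (x, y, id, stratum) or a UNICOR-style XY point file (two
#' whitespace-separated coordinate columns, no header).
#'
#' @param sources a `source_set`.
#' @param path output path.
#' @param format `"csv"` or `"xy"`.
#' @export
write_sources <- function(sources, path, format = c("csv", "xy")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(as.data.frame(sources), path, row.names = FALSE,
                     quote = FALSE)
  } else {
    writeLines(sprintf("%.6f %.6f", sources$x, sources$y), path)
  }
  invisible(path)
}

# ---- cost graph and shortest paths ------------------------------------

#' Build the cost graph of a resistance raster
#'
#' Nodes are traversable (non-NA) cells; undirected edges connect
#' 8-neighborhood (or 4-neighborhood) adjacent cells with weight
#' `cell_size * (R_i + R_j) / 2`, diagonal edges additionally scaled by
#' sqrt(2). With uniform resistance 1 the cost of a path is its metric
#' length in meters. Nodata cells carry no edges, so paths cannot cut
#' through them.
#'
#' @param res a [resistance_raster()].
#' @param neighborhood 8 (default) or 4.
#' @return a `cost_graph` list: igraph `graph`, `cell_index` (linear raster
#'   index per vertex), `vertex_of` (vertex id per raster cell, NA if
#'   untraversable), and the raster geometry.
#' @export
build_cost_graph <- function(res, neighborhood = 8) {
  if (!neighborhood %in% c(4, 8)) fail("neighborhood must be 4 or 8")
  g <- res$grid
  nr <- nrow(g); nc <- ncol(g)
  trav <- which(!is.na(g))
  if (!length(trav)) fail("no traversable cell")
  vertex_of <- rep(NA_integer_, nr * nc)
  vertex_of[trav] <- seq_along(trav)
  steps <- list(c(0L, 1L, 1), c(1L, 0L, 1))
  if (neighborhood == 8) {
    steps <- c(steps, list(c(1L, 1L, sqrt(2)), c(1L, -1L, sqrt(2))))
  }
  from <- integer(); to <- integer(); wt <- numeric()
  for (s in steps) {
    dr <- s[1L]; dc <- s[2L]; mult <- s[3L]
    if (max(1L, 1L - dr) > min(nr, nr - dr) ||
        max(1L, 1L - dc) > min(nc, nc - dc)) next
    r_src <- max(1L, 1L - dr):min(nr, nr - dr)
    c_src <- max(1L, 1L - dc):min(nc, nc - dc)
    a <- as.vector(outer(r_src, (c_src - 1L) * nr, `+`))
    b <- a + dr + dc * nr
    ok <- !is.na(vertex_of[a]) & !is.na(vertex_of[b])
    a <- a[ok]; b <- b[ok]
    from <- c(from, vertex_of[a])
    to <- c(to, vertex_of[b])
    wt <- c(wt, res$cell_size_m * mult * (g[a] + g[b]) / 2)
  }
  graph <- igraph::make_empty_graph(n = length(trav), directed = FALSE)
  if (length(from)) {
    graph <- igraph::add_edges(graph, rbind(from, to))
    igraph::E(graph)$weight <- wt
  }
  cg <- list(graph = graph, cell_index = trav, vertex_of = vertex_of,
             dim = c(nr, nc), cell_size_m = res$cell_size_m,
             origin_xy = res$origin_xy)
  class(cg) <- "cost_graph"
  cg
}

# linear raster index -> vertex, with validation
graph_vertex <- function(cg, cell) {
  v <- cg$vertex_of[cell]
  if (any(is.na(v))) fail("cell %d is untraversable", cell[which(is.na(v))[1L]])
  v
}

#' Single-source cost distances
#'
#' Exact Dijkstra shortest-path costs from one source cell to every cell;
#' unreachable or untraversable cells are `Inf`/`NA`.
#'
#' @param cg a `cost_graph`.
#' @param source_cell linear raster index (column-major) of the source.
#' @return numeric matrix of costs with the raster's dimensions
#'   (NA = untraversable, Inf = unreachable).
#' @export
cost_distance <- function(cg, source_cell) {
  v <- graph_vertex(cg, source_cell)
  d <- igraph::distances(cg$graph, v = v, algorithm = "dijkstra")[1L, ]
  out <- matrix(NA_real_, cg$dim[1L], cg$dim[2L])
  out[cg$cell_index] <- d
  out
}

#' Least-cost path between two cells
#'
#' @param cg a `cost_graph`.
#' @param src,dst linear raster indices (column-major).
#' @return list with `path` (ordered linear cell indices, NULL when `dst`
#'   is unreachable) and `cost` (Inf when unreachable).
#' @export
least_cost_path <- function(cg, src, dst) {
  vs <- graph_vertex(cg, src)
  vd <- graph_vertex(cg, dst)
  if (src == dst) return(list(path = src, cost = 0))
  sp <- suppressWarnings(
    igraph::shortest_paths(cg$graph, from = vs, to = vd, mode = "all",
                           output = "both"))
  verts <- as.integer(sp$vpath[[1L]])
  if (!length(verts)) return(list(path = NULL, cost = Inf))
  cost <- sum(igraph::E(cg$graph)$weight[as.integer(sp$epath[[1L]])])
  list(path = cg$cell_index[verts], cost = cost)
}

# map source points to linear cell indices on the graph's raster
source_cells <- function(cg, sources) {
  fake <- list(grid = matrix(NA, cg$dim[1L], cg$dim[2L]),
               cell_size_m = cg$cell_size_m, origin_xy = cg$origin_xy)
  rc <- cell_at(fake, sources$x, sources$y)
  off <- which(is.na(rc[, 1L]))
  if (length(off)) fail("source %d lies off the raster", off[1L])
  rc[, 1L] + (rc[, 2L] - 1L) * cg$dim[1L]
}

#' Dispersal scenario
#'
#' @param name `"low"` (100 km) or `"high"` (850 km), or any label when
#'   `threshold_km` is given explicitly.
#' @param threshold_km maximum Euclidean source-pair separation in km.
#' @return a `dispersal_scenario` list.
#' @export
dispersal_scenario <- function(name = c("low", "high"), threshold_km = NULL) {
  if (is.null(threshold_km)) {
    name <- match.arg(name)
    threshold_km <- c(low = 100, high = 850)[[name]]
  } else {
    name <- as.character(name[1L])
  }
  if (threshold_km <= 0) fail("threshold_km must be > 0")
  sc <- list(name = name, threshold_km = threshold_km)
  class(sc) <- "dispersal_scenario"
  sc
}

#' Factorial least-cost-path density
#'
#' For every unordered source pair whose Euclidean separation does not
#' exceed the scenario threshold, the least-cost path is traced and every
#' cell on it incremented by one; the sum over all pairs is the path
#' density map. Pairs with an unreachable endpoint are skipped and counted
#' in the attached report. Optionally the pair filter can use cost distance
#' instead of Euclidean distance.
#'
#' @param res a [resistance_raster()].
#' @param sources a `source_set` with at least one point.
#' @param scenario a [dispersal_scenario()].
#' @param cg optional pre-built `cost_graph` (rebuilt from `res` if NULL).
#' @param filter `"euclidean"` (default) or `"cost"` pair-inclusion rule.
#' @return a [density_raster()]; attribute `"skipped"` is a data.frame of
#'   skipped pairs.
#' @export
factorial_lcp <- function(res, sources, scenario, cg = NULL,
                          filter = c("euclidean", "cost")) {
  filter <- match.arg(filter)
  if (!nrow(sources)) fail("empty source set")
  if (is.null(cg)) cg <- build_cost_graph(res)
  cells <- source_cells(cg, sources)
  n <- length(cells)
  dens <- matrix(0, cg$dim[1L], cg$dim[2L])
  skipped <- list()
  lim <- scenario$threshold_km * 1000
  if (n >= 2L) {
    eu <- as.matrix(stats::dist(cbind(sources$x, sources$y)))
    for (i in seq_len(n - 1L)) {
      js <- which(eu[i, ] <= lim)
      js <- js[js > i]
      if (filter == "cost" && length(js)) {
        dc <- igraph::distances(cg$graph, v = graph_vertex(cg, cells[i]),
                                to = graph_vertex(cg, cells[js]))[1L, ]
        skip_far <- js[!is.finite(dc) | dc > lim]
        js <- js[is.finite(dc) & dc <= lim]
      }
      if (!length(js)) next
      sp <- suppressWarnings(
        igraph::shortest_paths(cg$graph, from = graph_vertex(cg, cells[i]),
                               to = graph_vertex(cg, cells[js]),
                               mode = "all", output = "vpath"))
      for (k in seq_along(js)) {
        verts <- as.integer(sp$vpath[[k]])
        if (!length(verts) && cells[i] != cells[js[k]]) {
          skipped[[length(skipped) + 1L]] <- data.frame(
            from = i, to = js[k], reason = "unreachable")
          next
        }
        path <- if (length(verts)) cg$cell_index[verts] else cells[i]
        dens[path] <- dens[path] + 1
      }
    }
  }
  out <- density_raster(dens, cg$cell_size_m, cg$origin_xy,
                        scenario = scenario$name)
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(from = integer(), to = integer(), reason = character())
  out
}

#' Cumulative resistant Gaussian kernel
#'
#' Around each source a Gaussian kernel of *cost* distance is computed,
#' `exp(-d^2 / (2 sigma^2))` for cost distance `d` up to the dispersal
#' threshold `D = threshold_km * 1000` (in cost units; on uniform
#' resistance 1 cost equals metric path length) and 0 beyond it, with
#' bandwidth `sigma = D / 3` so truncation removes under 1.2% of the
#' kernel mass. Kernels are summed over sources.
#'
#' @inheritParams factorial_lcp
#' @return a [density_raster()] of cumulative kernel mass.
#' @export
resistant_kernel <- function(res, sources, scenario, cg = NULL) {
  if (!nrow(sources)) fail("empty source set")
  if (is.null(cg)) cg <- build_cost_graph(res)
  cells <- source_cells(cg, sources)
  D <- scenario$threshold_km * 1000
  sigma <- D / 3
  d <- igraph::distances(cg$graph, v = graph_vertex(cg, cells),
                         algorithm = "dijkstra")
  k <- exp(-d^2 / (2 * sigma^2))
  k[!is.finite(d) | d > D] <- 0
  total <- colSums(k)
  dens <- matrix(0, cg$dim[1L], cg$dim[2L])
  dens[cg$cell_index] <- total
  density_raster(dens, cg$cell_size_m, cg$origin_xy, scenario = scenario$name)
}

#' Share of the landscape supporting movement
#'
#' Percentage of non-missing cells with path density strictly above the
#' threshold (default 0: any least-cost path or kernel mass counts).
#'
#' @param density a [density_raster()].
#' @param threshold density cutoff (default 0).
#' @return percentage in `[0, 100]`.
#' @export
connectivity_extent <- function(density, threshold = 0) {
  v <- density$grid[!is.na(density$grid)]
  if (!length(v)) fail("all-missing raster")
  100 * sum(v > threshold) / length(v)
}
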