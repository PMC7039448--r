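# Independent oracles and tiny fixtures shared across the suite.

# Uniform single-class land-cover raster.
uniform_lc <- function(nr = 5, nc = 5, class = "woodland", cell = 10) {
  codes <- landcover_classes()
  g <- matrix(codes[[class]], nr, nc)
  cn <- names(codes)
  names(cn) <- as.character(codes)
  landcover_raster(g, cn, cell)
}

# Checkerboard of two classes.
checkerboard_lc <- function(nr = 21, nc = 21, cell = 20,
                            classes = c("arable", "woodland")) {
  codes <- landcover_classes()
  g <- matrix(codes[[classes[1L]]], nr, nc)
  alt <- outer(seq_len(nr), seq_len(nc), function(r, c) (r + c) %% 2 == 0)
  g[alt] <- codes[[classes[2L]]]
  cn <- names(codes)
  names(cn) <- as.character(codes)
  landcover_raster(g, cn, cell)
}

# Brute-force fractional cover: enumerate every cell center in the disc.
oracle_fraction <- function(lc, point, radius, code) {
  nr <- nrow(lc$grid); nc <- ncol(lc$grid)
  hit <- 0L; tot <- 0L
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    ctr <- cell_center(lc, r, c)
    if ((ctr[1] - point[1])^2 + (ctr[2] - point[2])^2 <= radius^2) {
      tot <- tot + 1L
      if (lc$grid[r, c] == code) hit <- hit + 1L
    }
  }
  hit / tot
}

# Brute-force single-source shortest-path costs on a resistance matrix:
# Bellman-Ford-style relaxation over the 8-neighborhood, independent of the
# package's igraph-backed implementation.
oracle_dijkstra <- function(res_grid, cell_size, src_rc) {
  nr <- nrow(res_grid); nc <- ncol(res_grid)
  d <- matrix(Inf, nr, nc)
  d[src_rc[1], src_rc[2]] <- 0
  moves <- rbind(c(-1, 0, 1), c(1, 0, 1), c(0, -1, 1), c(0, 1, 1),
                 c(-1, -1, sqrt(2)), c(-1, 1, sqrt(2)),
                 c(1, -1, sqrt(2)), c(1, 1, sqrt(2)))
  repeat {
    changed <- FALSE
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      if (is.na(res_grid[r, c]) || !is.finite(d[r, c])) next
      for (m in seq_len(nrow(moves))) {
        r2 <- r + moves[m, 1]; c2 <- c + moves[m, 2]
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
        if (is.na(res_grid[r2, c2])) next
        w <- cell_size * moves[m, 3] *
          (res_grid[r, c] + res_grid[r2, c2]) / 2
        if (d[r, c] + w < d[r2, c2] - 1e-12) {
          d[r2, c2] <- d[r, c] + w
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  d
}

# Brute-force AUC: average pairwise comparison with ties counted one half.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == "presence" | labels == TRUE | labels == 1]
  neg <- scores[!(labels == "presence" | labels == TRUE | labels == 1)]
  tot <- 0
  for (p in pos) for (n in neg) {
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Minimal covariate table straight from vectors.
make_table <- function(..., label) {
  df <- data.frame(..., check.names = FALSE)
  vars <- names(df)
  df$label <- label
  df$study_area <- "toy"
  attr(df, "covariate_classes") <- vars
  class(df) <- c("covariate_table", "data.frame")
  df
}

# Small uniform resistance raster.
uniform_res <- function(nr, nc, value = 1, cell = 1) {
  resistance_raster(matrix(value, nr, nc), cell)
}
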