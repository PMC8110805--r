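# Small fixture builders and independent oracles shared across tests.
# Oracles deliberately use naive formulations (loops, enumeration, Monte
# Carlo) distinct from the implementation paths they check.

make_spec <- function(nr = 3, nc = 3, xll = 0, yll = 0, cs = 1,
                      crs = "local-equal-area-km") {
  grid_spec(nr, nc, xll, yll, cs, crs)
}

make_suit <- function(values, ..., scale = "unit") {
  values <- as.matrix(values)
  suitability_grid(values, make_spec(nrow(values), ncol(values), ...),
                   scale = scale)
}

make_binary <- function(values, ...) {
  values <- as.matrix(values)
  binary_grid(values, make_spec(nrow(values), ncol(values), ...))
}

make_category <- function(values, ...) {
  values <- as.matrix(values)
  category_grid(values, make_spec(nrow(values), ncol(values), ...))
}

# a compact simulation setup for pipeline-level tests
small_cfg <- function(seed = 42, ...) {
  defaults <- list(
    seed = seed,
    extent_size = 500, latent_cell = 10,
    model_resolutions = c(25, 20, 10, 10, 50, 40, 10),
    autocorrelation_length = 80,
    n_occurrences = 200, n_zones = 9, extent_jitter = 20
  )
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# --- independent oracles ----------------------------------------------------

# brute-force lookup of the cell containing a point: scan every cell
oracle_cell_lookup <- function(spec, x, y) {
  ext <- spec_extent(spec)
  for (i in seq_len(spec$n_rows)) {
    for (j in seq_len(spec$n_cols)) {
      x0 <- spec$xll + (j - 1) * spec$cell_size
      y1 <- spec$yll + (spec$n_rows - i + 1) * spec$cell_size
      if (x >= x0 && x < x0 + spec$cell_size &&
          y > y1 - spec$cell_size && y <= y1) {
        return(c(i, j))
      }
    }
  }
  NULL
}

# sort-and-scan fixed-omission threshold: largest observed value whose
# strictly-below fraction does not exceed p
oracle_threshold <- function(values, p) {
  s <- sort(values)
  best <- s[1]
  for (v in unique(s)) {
    if (sum(s < v) / length(s) <= p) best <- v
  }
  best
}

# point-in-polygon by explicit edge-crossing count (scalar, loop-based;
# independent of the package's vectorised routine)
oracle_in_poly <- function(x, y, poly) {
  n <- nrow(poly)
  crossings <- 0L
  for (k in seq_len(n)) {
    x1 <- poly[k, 1]; y1 <- poly[k, 2]
    k2 <- if (k == n) 1L else k + 1L
    x2 <- poly[k2, 1]; y2 <- poly[k2, 2]
    if ((y1 <= y && y2 > y) || (y2 <= y && y1 > y)) {
      xc <- x1 + (y - y1) / (y2 - y1) * (x2 - x1)
      if (xc > x) crossings <- crossings + 1L
    }
  }
  crossings %% 2L == 1L
}

# Monte-Carlo category fractions of a polygon over a category grid
oracle_zone_fractions <- function(poly, g, n_pts = 100000, seed = 99) {
  set.seed(seed)
  bb <- polygon_bbox(poly)
  px <- runif(n_pts, bb["xmin"], bb["xmax"])
  py <- runif(n_pts, bb["ymin"], bb["ymax"])
  keep <- vapply(seq_len(n_pts), function(k) oracle_in_poly(px[k], py[k], poly),
                 logical(1))
  px <- px[keep]; py <- py[keep]
  spec <- g$spec
  col <- floor((px - spec$xll) / spec$cell_size) + 1
  row <- spec$n_rows - floor((py - spec$yll) / spec$cell_size)
  ok <- col >= 1 & col <= spec$n_cols & row >= 1 & row <= spec$n_rows
  vals <- rep(NA_real_, length(px))
  vals[ok] <- g$values[cbind(row[ok], col[ok])]
  vals <- vals[!is.na(vals)]
  out <- vapply(1:3, function(k) mean(vals == k), numeric(1))
  names(out) <- c("1", "2", "3")
  out
}
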