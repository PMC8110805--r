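#' Build the common analysis grid over the intersection of model extents
#'
#' The harmonized grid of square cells (default 25 km) covers the geometric
#' intersection of all source extents — the smallest extent common to every
#' model. With the default `anchor = NULL` the grid's lower-left corner sits
#' on the intersection corner and the row/column counts are
#' `ceiling(extent / cell_size)`, so the grid covers the whole intersection.
#' Supplying an anchor point instead snaps the grid outward onto the lattice
#' `anchor + k * cell_size`, which makes repeated runs with overlapping but
#' differing inputs share cell boundaries.
#'
#' @param extents List of extent rectangles `c(xmin, xmax, ymin, ymax)` (as
#'   returned by [spec_extent()]), one per source model.
#' @param cell_size Target cell edge length in CRS units (default 25).
#' @param crs CRS identifier of the working grid.
#' @param anchor Optional `c(x, y)` lattice anchor; `NULL` anchors at the
#'   intersection's lower-left corner.
#' @return A [grid_spec()] with a `provenance` attribute holding the source
#'   extents and the intersection rectangle.
#' @export
build_common_grid <- function(extents, cell_size = 25,
                              crs = "local-equal-area-km", anchor = NULL) {
  stopifnot(length(extents) >= 1, cell_size > 0)
  ex <- do.call(rbind, lapply(extents, function(e) e[c("xmin", "xmax",
                                                       "ymin", "ymax")]))
  xmin <- max(ex[, "xmin"]); xmax <- min(ex[, "xmax"])
  ymin <- max(ex[, "ymin"]); ymax <- min(ex[, "ymax"])
  if (xmin >= xmax || ymin >= ymax) {
    stop("model extents have an empty intersection", call. = FALSE)
  }
  eps <- 1e-9
  if (is.null(anchor)) {
    xll <- xmin; yll <- ymin
  } else {
    xll <- anchor[1] + floor((xmin - anchor[1]) / cell_size + eps) * cell_size
    yll <- anchor[2] + floor((ymin - anchor[2]) / cell_size + eps) * cell_size
  }
  n_cols <- ceiling((xmax - xll) / cell_size - eps)
  n_rows <- ceiling((ymax - yll) / cell_size - eps)
  spec <- grid_spec(n_rows, n_cols, xll, yll, cell_size, crs)
  attr(spec, "provenance") <- list(
    source_extents = ex,
    intersection = c(xmin = xmin, xmax = xmax, ymin = ymin, ymax = ymax)
  )
  spec
}

# overlap lengths between two sets of 1-D intervals: rows = target, cols = src
interval_overlap <- function(t_lo, t_hi, s_lo, s_hi) {
  lo <- outer(t_lo, s_lo, pmax)
  hi <- outer(t_hi, s_hi, pmin)
  w <- hi - lo
  w[w < 0] <- 0
  w
}

# x/y overlap weight matrices from a source spec to a target spec
overlap_weights <- function(src, target) {
  sx <- src$xll + src$cell_size * (0:src$n_cols)
  tx <- target$xll + target$cell_size * (0:target$n_cols)
  wx <- interval_overlap(tx[-length(tx)], tx[-1], sx[-length(sx)], sx[-1])
  # rows run north to south: row i spans [ytop - i*cs, ytop - (i-1)*cs]
  sy_top <- src$yll + src$cell_size * src$n_rows
  ty_top <- target$yll + target$cell_size * target$n_rows
  s_hi <- sy_top - src$cell_size * (seq_len(src$n_rows) - 1)
  t_hi <- ty_top - target$cell_size * (seq_len(target$n_rows) - 1)
  wy <- interval_overlap(t_hi - target$cell_size, t_hi,
                         s_hi - src$cell_size, s_hi)
  list(wx = wx, wy = wy)
}

# nearest-cell (centre containment) lookup of src values at target centres
resample_centers <- function(values, src, target) {
  cx <- cell_center_x(target, seq_len(target$n_cols))
  cy <- cell_center_y(target, seq_len(target$n_rows))
  col <- floor((cx - src$xll) / src$cell_size) + 1
  row <- src$n_rows - floor((cy - src$yll) / src$cell_size)
  col[col < 1 | col > src$n_cols] <- NA
  row[row < 1 | row > src$n_rows] <- NA
  out <- matrix(NA_real_, target$n_rows, target$n_cols)
  ok_r <- which(!is.na(row)); ok_c <- which(!is.na(col))
  out[ok_r, ok_c] <- values[row[ok_r], col[ok_c], drop = FALSE]
  out
}

#' Aggregate a binary map onto a target grid
#'
#' Harmonization of categorical (suitable/unsuitable) maps between grids in
#' the same CRS. When the target cell is at least as coarse as the source,
#' each target cell aggregates the area-weighted overlap of source cells:
#'
#' * `majority_area` (default): suitable iff the suitable fraction of the
#'   non-nodata overlap is `>= cutoff` (default 0.5; the exact-tie case goes
#'   to suitable, the precautionary choice for a public-health map).
#' * `any_suitable`: suitable iff any overlapping source area is suitable.
#' * `fraction_cutoff`: `majority_area` with a caller-chosen `cutoff`.
#'
#' A target cell is nodata when nodata (or area outside the source extent)
#' covers more than half of it. When the target is strictly finer than the
#' source no sub-cell information is invented: each target cell takes the
#' class of the source cell containing its centre.
#'
#' @param src A [binary_grid()].
#' @param target Target [grid_spec()] (e.g. from [build_common_grid()]).
#' @param rule Aggregation rule; see Details.
#' @param cutoff Suitable-fraction cutoff for `fraction_cutoff`.
#' @return A [binary_grid()] on `target`.
#' @export
regrid_binary <- function(src, target,
                          rule = c("majority_area", "any_suitable",
                                   "fraction_cutoff"),
                          cutoff = 0.5) {
  rule <- match.arg(rule)
  stopifnot(inherits(src, "binary_grid"), inherits(target, "grid_spec"))
  if (!identical(src$spec$crs, target$crs)) {
    stop("source grid and target grid are in different CRSs", call. = FALSE)
  }
  if (specs_aligned(src$spec, target)) {
    return(binary_grid(src$values, target))
  }
  se <- spec_extent(src$spec); te <- spec_extent(target)
  if (se["xmin"] >= te["xmax"] || se["xmax"] <= te["xmin"] ||
      se["ymin"] >= te["ymax"] || se["ymax"] <= te["ymin"]) {
    stop("source grid does not overlap the target grid", call. = FALSE)
  }
  if (target$cell_size < src$spec$cell_size) {
    return(binary_grid(resample_centers(src$values, src$spec, target), target))
  }
  w <- overlap_weights(src$spec, target)
  s1 <- src$values; s1[is.na(s1)] <- 0
  valid <- (!is.na(src$values)) * 1
  suit_area <- w$wy %*% s1 %*% t(w$wx)
  valid_area <- w$wy %*% valid %*% t(w$wx)
  cell_area <- target$cell_size^2
  out <- matrix(NA_real_, target$n_rows, target$n_cols)
  ok <- valid_area >= cell_area / 2
  frac <- suit_area[ok] / valid_area[ok]
  out[ok] <- switch(rule,
    majority_area = (frac >= 0.5) * 1,
    any_suitable = (suit_area[ok] > 1e-12) * 1,
    fraction_cutoff = (frac >= cutoff) * 1
  )
  binary_grid(out, target)
}

# area-weighted mean aggregation of a continuous surface (generator plumbing;
# centre lookup when the target is finer)
regrid_mean <- function(values, src, target) {
  if (specs_aligned(src, target)) return(values)
  if (target$cell_size < src$cell_size) {
    return(resample_centers(values, src, target))
  }
  w <- overlap_weights(src, target)
  v0 <- values; v0[is.na(v0)] <- 0
  valid <- (!is.na(values)) * 1
  num <- w$wy %*% v0 %*% t(w$wx)
  den <- w$wy %*% valid %*% t(w$wx)
  out <- num / den
  out[den < target$cell_size^2 / 2] <- NA
  out
}
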