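#' Grid geometry specification
#'
#' A `grid_spec` describes a regular grid of square cells in a projected,
#' equal-area working CRS: row/column counts, the lower-left corner of the
#' grid, the cell size (in CRS units, e.g. km) and an opaque CRS identifier.
#' All grids combined by downstream operations must share an identical
#' `grid_spec` ("alignment"); nothing is ever resampled silently.
#'
#' Rows are stored north-to-south: row 1 of a value matrix is the northernmost
#' row, matching the on-disk order of ESRI ASCII grids.
#'
#' @param n_rows,n_cols Positive integer grid dimensions.
#' @param xll,yll Coordinates of the lower-left corner of the grid.
#' @param cell_size Positive cell edge length in CRS units (cells are square).
#' @param crs CRS identifier string; grids with different identifiers refuse
#'   to combine.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(n_rows, n_cols, xll, yll, cell_size,
                      crs = "local-equal-area-km") {
  stopifnot(
    length(n_rows) == 1L, length(n_cols) == 1L,
    n_rows >= 1L, n_cols >= 1L,
    is.finite(xll), is.finite(yll),
    is.finite(cell_size), cell_size > 0
  )
  structure(
    list(
      n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
      xll = as.numeric(xll), yll = as.numeric(yll),
      cell_size = as.numeric(cell_size), crs = as.character(crs)
    ),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  ext <- spec_extent(x)
  cat(sprintf(
    "<grid_spec> %d x %d cells of %g, extent [%g, %g] x [%g, %g], crs '%s'\n",
    x$n_rows, x$n_cols, x$cell_size,
    ext["xmin"], ext["xmax"], ext["ymin"], ext["ymax"], x$crs
  ))
  invisible(x)
}

#' Extent rectangle of a grid spec
#'
#' @param spec A `grid_spec`.
#' @return Named numeric vector `c(xmin, xmax, ymin, ymax)`.
#' @export
spec_extent <- function(spec) {
  c(
    xmin = spec$xll,
    xmax = spec$xll + spec$n_cols * spec$cell_size,
    ymin = spec$yll,
    ymax = spec$yll + spec$n_rows * spec$cell_size
  )
}

#' Test whether two grid specs are aligned
#'
#' Aligned means every geometry field (dimensions, origin, cell size, CRS)
#' is equal; coordinates are compared with a small absolute tolerance to
#' absorb round-tripping through text formats.
#'
#' @param a,b `grid_spec` objects.
#' @param tol Absolute coordinate tolerance.
#' @return `TRUE` or `FALSE`.
#' @export
specs_aligned <- function(a, b, tol = 1e-9) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    abs(a$xll - b$xll) <= tol && abs(a$yll - b$yll) <= tol &&
    abs(a$cell_size - b$cell_size) <= tol && identical(a$crs, b$crs)
}

stop_if_misaligned <- function(a, b, what = "grids") {
  if (!specs_aligned(a, b)) {
    stop(sprintf(
      "%s are not aligned (identical grid_spec required); refusing to combine",
      what
    ), call. = FALSE)
  }
  invisible(TRUE)
}

# internal constructor shared by all grid kinds; values is a numeric matrix
# (n_rows x n_cols, row 1 = north), NA = nodata
new_sgrid <- function(values, spec, kind, extra = list()) {
  stopifnot(inherits(spec, "grid_spec"), is.matrix(values))
  if (nrow(values) != spec$n_rows || ncol(values) != spec$n_cols) {
    stop("value matrix dimensions do not match grid_spec", call. = FALSE)
  }
  structure(
    c(list(values = values, spec = spec), extra),
    class = c(paste0(kind, "_grid"), "sgrid")
  )
}

#' @export
print.sgrid <- function(x, ...) {
  kind <- sub("_grid$", "", class(x)[1])
  v <- x$values
  nv <- sum(!is.na(v))
  cat(sprintf(
    "<%s grid> %d x %d (%d non-nodata cells)",
    kind, x$spec$n_rows, x$spec$n_cols, nv
  ))
  if (nv > 0) {
    cat(sprintf(", range [%g, %g]", min(v, na.rm = TRUE), max(v, na.rm = TRUE)))
  }
  cat("\n")
  invisible(x)
}

#' Continuous habitat-suitability surface
#'
#' Wraps a matrix of continuous suitability scores with its grid geometry and
#' the scale the scores are expressed on. Published suitability surfaces come
#' on either a 0-1 or a 0-100 scale; [normalize_scale()] brings everything to
#' the unit interval before thresholding.
#'
#' @param values Numeric matrix (`n_rows x n_cols`, row 1 = north); `NA` is
#'   nodata.
#' @param spec A [grid_spec()].
#' @param scale `"unit"` (values in \[0, 1\]) or `"percent"` (\[0, 100\]).
#' @return A `suitability_grid`.
#' @export
suitability_grid <- function(values, spec, scale = c("unit", "percent")) {
  scale <- match.arg(scale)
  hi <- if (scale == "unit") 1 else 100
  v <- values[!is.na(values)]
  if (length(v) && (min(v) < 0 || max(v) > hi)) {
    stop(sprintf(
      "suitability values outside declared '%s' scale range [0, %g]",
      scale, hi
    ), call. = FALSE)
  }
  new_sgrid(values, spec, "suitability", list(scale = scale))
}

#' Rescale a suitability surface to the unit interval
#'
#' Percent-scale surfaces are divided by 100; unit-scale surfaces pass through
#' unchanged, so the operation is idempotent.
#'
#' @param g A [suitability_grid()].
#' @return A `suitability_grid` with `scale = "unit"`.
#' @export
normalize_scale <- function(g) {
  stopifnot(inherits(g, "suitability_grid"))
  if (g$scale == "unit") return(g)
  suitability_grid(g$values / 100, g$spec, scale = "unit")
}

#' Binary suitable/unsuitable map
#'
#' @param values Matrix over \{0, 1, NA\}; 1 = suitable, 0 = unsuitable.
#' @param spec A [grid_spec()].
#' @return A `binary_grid`.
#' @export
binary_grid <- function(values, spec) {
  v <- values[!is.na(values)]
  if (length(v) && !all(v %in% c(0, 1))) {
    stop("binary grid values must be 0, 1 or nodata", call. = FALSE)
  }
  new_sgrid(values, spec, "binary")
}

#' Inter-model agreement map
#'
#' Per-cell count of binarized models predicting suitable conditions,
#' i.e. an integer in `[0, n_models]` or nodata.
#'
#' @param values Integer matrix.
#' @param spec A [grid_spec()].
#' @param n_models Number of models summed.
#' @return An `agreement_grid`.
#' @export
agreement_grid <- function(values, spec, n_models) {
  stopifnot(n_models >= 1)
  v <- values[!is.na(values)]
  if (length(v) && (min(v) < 0 || max(v) > n_models || any(v != round(v)))) {
    stop("agreement values must be integers in [0, n_models]", call. = FALSE)
  }
  new_sgrid(values, spec, "agreement", list(n_models = as.integer(n_models)))
}

#' Three-level consensus category map
#'
#' Codes: 1 = unsuitable with low uncertainty, 2 = high uncertainty,
#' 3 = suitable with low uncertainty.
#'
#' @param values Matrix over \{1, 2, 3, NA\}.
#' @param spec A [grid_spec()].
#' @return A `category_grid`.
#' @export
category_grid <- function(values, spec) {
  v <- values[!is.na(values)]
  if (length(v) && !all(v %in% 1:3)) {
    stop("category codes must be 1, 2, 3 or nodata", call. = FALSE)
  }
  new_sgrid(values, spec, "category")
}

#' Nine-class suitability-change trajectory map
#'
#' Codes are `10 * present + future` over the category codes 1-3, i.e. the
#' nine values 11, 12, 13, 21, 22, 23, 31, 32, 33.
#'
#' @param values Matrix over the nine codes or NA.
#' @param spec A [grid_spec()].
#' @return A `trajectory_grid`.
#' @export
trajectory_grid <- function(values, spec) {
  v <- values[!is.na(values)]
  if (length(v) && !all(v %in% trajectory_codes())) {
    stop("trajectory codes must be one of 11..33 (pq, p,q in 1:3) or nodata",
         call. = FALSE)
  }
  new_sgrid(values, spec, "trajectory")
}

#' The nine trajectory codes
#'
#' @return Integer vector `c(11, 12, 13, 21, 22, 23, 31, 32, 33)`.
#' @export
trajectory_codes <- function() {
  as.integer(outer(1:3 * 10L, 1:3, `+`))
}

# cell centre coordinates, vectorised over rows/cols
cell_center_x <- function(spec, col) spec$xll + (col - 0.5) * spec$cell_size
cell_center_y <- function(spec, row) {
  spec$yll + (spec$n_rows - row + 0.5) * spec$cell_size
}

# map points to (row, col); returns NA indices for points outside the extent
point_to_cell <- function(spec, x, y) {
  col <- floor((x - spec$xll) / spec$cell_size) + 1
  row <- spec$n_rows - floor((y - spec$yll) / spec$cell_size)
  bad <- col < 1 | col > spec$n_cols | row < 1 | row > spec$n_rows |
    !is.finite(x) | !is.finite(y)
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  list(row = as.integer(row), col = as.integer(col))
}
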