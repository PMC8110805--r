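#' Read a single-band raster from an ESRI ASCII grid
#'
#' Parses the standard `.asc` header (`ncols`, `nrows`, `xllcorner` or
#' `xllcenter`, `cellsize`, optional `nodata_value`) followed by row-major
#' values, northernmost row first. Cells are square by format definition and
#' the raster is single band; the value scale is auto-detected: a maximum
#' non-nodata value above `scale_cutoff` is taken as a 0-100 ("percent")
#' surface, otherwise 0-1 ("unit"). The cutoff sits above 1 so unit-scale
#' surfaces with minor >1 artifacts are not misread; pass `scale` to override
#' detection entirely.
#'
#' @param path Path to an `.asc` file.
#' @param crs CRS identifier recorded on the grid (the file format carries
#'   none); all grids combined downstream must agree on it.
#' @param scale `NULL` for auto-detection, or `"unit"`/`"percent"`.
#' @param scale_cutoff Detection cutoff for the maximum value (default 1.5).
#' @return A [suitability_grid()].
#' @export
read_suitability_asc <- function(path, crs = "local-equal-area-km",
                                 scale = NULL, scale_cutoff = 1.5) {
  parsed <- read_asc(path, crs)
  if (is.null(scale)) {
    mx <- suppressWarnings(max(parsed$values, na.rm = TRUE))
    scale <- if (is.finite(mx) && mx > scale_cutoff) "percent" else "unit"
  }
  suitability_grid(parsed$values, parsed$spec, scale = scale)
}

#' Read an integer category or trajectory raster
#'
#' @param path Path to an `.asc` file written by [write_category_asc()].
#' @param kind `"category"` (codes 1-3) or `"trajectory"` (codes 11-33).
#' @param crs CRS identifier recorded on the grid.
#' @return A `category_grid` or `trajectory_grid`.
#' @export
read_category_asc <- function(path, kind = c("category", "trajectory"),
                              crs = "local-equal-area-km") {
  kind <- match.arg(kind)
  parsed <- read_asc(path, crs)
  if (kind == "category") {
    category_grid(parsed$values, parsed$spec)
  } else {
    trajectory_grid(parsed$values, parsed$spec)
  }
}

# shared .asc parser: returns list(values, spec)
read_asc <- function(path, crs) {
  if (!file.exists(path)) stop("cannot read raster: ", path, call. = FALSE)
  lines <- readLines(path, n = 7L)
  hdr <- list()
  n_hdr <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) == 2 && !is.na(suppressWarnings(as.numeric(parts[2]))) &&
        grepl("^[A-Za-z_]+$", parts[1])) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
      n_hdr <- n_hdr + 1L
    } else {
      break
    }
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr))) {
    stop("not a valid ASCII grid (missing ", paste(setdiff(need, names(hdr)),
         collapse = ", "), "): ", path, call. = FALSE)
  }
  nc <- as.integer(hdr$ncols)
  nr <- as.integer(hdr$nrows)
  cs <- hdr$cellsize
  if ("xllcorner" %in% names(hdr)) {
    xll <- hdr$xllcorner
  } else if ("xllcenter" %in% names(hdr)) {
    xll <- hdr$xllcenter - cs / 2
  } else {
    stop("ASCII grid missing xllcorner/xllcenter: ", path, call. = FALSE)
  }
  if ("yllcorner" %in% names(hdr)) {
    yll <- hdr$yllcorner
  } else if ("yllcenter" %in% names(hdr)) {
    yll <- hdr$yllcenter - cs / 2
  } else {
    stop("ASCII grid missing yllcorner/yllcenter: ", path, call. = FALSE)
  }
  nodata <- if ("nodata_value" %in% names(hdr)) hdr$nodata_value else NULL
  vals <- scan(path, what = numeric(), skip = n_hdr, quiet = TRUE)
  if (length(vals) != nr * nc) {
    stop(sprintf("ASCII grid %s: expected %d values, found %d",
                 path, nr * nc, length(vals)), call. = FALSE)
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.null(nodata)) m[m == nodata] <- NA
  list(values = m, spec = grid_spec(nr, nc, xll, yll, cs, crs))
}

# shared .asc writer
write_asc <- function(values, spec, path, nodata = -9999, digits = 10) {
  m <- values
  m[is.na(m)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", spec$n_cols),
    sprintf("nrows %d", spec$n_rows),
    sprintf("xllcorner %.10g", spec$xll),
    sprintf("yllcorner %.10g", spec$yll),
    sprintf("cellsize %.10g", spec$cell_size),
    sprintf("NODATA_value %g", nodata)
  ), con)
  fmt_row <- function(r) paste(formatC(r, digits = digits, format = "g"),
                               collapse = " ")
  writeLines(vapply(seq_len(nrow(m)), function(i) fmt_row(m[i, ]),
                    character(1)), con)
  invisible(path)
}

#' Write a continuous suitability raster as an ESRI ASCII grid
#'
#' @param g A [suitability_grid()].
#' @param path Output `.asc` path.
#' @param digits Significant digits written per cell.
#' @return `path`, invisibly.
#' @export
write_suitability_asc <- function(g, path, digits = 10) {
  stopifnot(inherits(g, "suitability_grid"))
  write_asc(g$values, g$spec, path, digits = digits)
}

#' Write an integer-coded category or trajectory raster with its palette
#'
#' Writes the codes as an ASCII grid plus a JSON sidecar
#' (`<path>.palette.json`) mapping every code present to a hex colour, in the
#' spirit of a raster colour table. Codes round-trip losslessly through
#' [read_category_asc()].
#'
#' @param g A `category_grid` or `trajectory_grid`.
#' @param path Output `.asc` path.
#' @param palette Named character vector code -> hex colour covering every
#'   code present in `g` (see [category_palette()], [trajectory_palette()]).
#' @return `path`, invisibly.
#' @export
write_category_asc <- function(g, path, palette = NULL) {
  stopifnot(inherits(g, "category_grid") || inherits(g, "trajectory_grid"))
  codes <- sort(unique(g$values[!is.na(g$values)]))
  if (is.null(palette)) {
    palette <- if (inherits(g, "category_grid")) category_palette()
               else trajectory_palette()
  }
  missing <- setdiff(as.character(codes), names(palette))
  if (length(missing)) {
    stop("palette has no colour for code(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  write_asc(g$values, g$spec, path, digits = 12)
  jsonlite::write_json(as.list(palette), paste0(path, ".palette.json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' Read species occurrence points from CSV
#'
#' Rows whose coordinates are missing or non-finite are dropped; the number
#' dropped is recorded in the `n_dropped` attribute and reported via
#' `message()`. Duplicate points are retained (no thinning at read time).
#'
#' @param path CSV path.
#' @param lon_col,lat_col Column names holding longitude/easting and
#'   latitude/northing in the working CRS.
#' @param id_col Optional id column name.
#' @return An `occurrence_set`: data.frame with columns `x`, `y` and
#'   optionally `id`; attribute `n_dropped`.
#' @export
read_occurrences_csv <- function(path, lon_col = "lon", lat_col = "lat",
                                 id_col = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c(lon_col, lat_col, id_col), names(df))
  if (length(miss)) {
    stop("occurrence CSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  occurrence_set(
    x = suppressWarnings(as.numeric(df[[lon_col]])),
    y = suppressWarnings(as.numeric(df[[lat_col]])),
    id = if (!is.null(id_col)) df[[id_col]] else NULL
  )
}

#' Construct an occurrence set from coordinates
#'
#' @param x,y Numeric coordinate vectors in the working CRS.
#' @param id Optional record ids.
#' @return An `occurrence_set` data.frame; non-finite rows are dropped and
#'   counted in the `n_dropped` attribute.
#' @export
occurrence_set <- function(x, y, id = NULL) {
  keep <- is.finite(x) & is.finite(y)
  out <- data.frame(x = x[keep], y = y[keep])
  if (!is.null(id)) out$id <- id[keep]
  n_drop <- sum(!keep)
  if (n_drop > 0) {
    message(sprintf("occurrence_set: dropped %d record(s) with missing or non-finite coordinates", n_drop))
  }
  attr(out, "n_dropped") <- n_drop
  class(out) <- c("occurrence_set", "data.frame")
  out
}

#' Write occurrences to CSV
#'
#' @param occ An `occurrence_set`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_occurrences_csv <- function(occ, path) {
  df <- as.data.frame(occ)
  names(df)[1:2] <- c("lon", "lat")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Persist a common-grid definition as JSON
#'
#' @param spec A [grid_spec()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_grid_spec_json <- function(spec, path) {
  jsonlite::write_json(
    list(n_rows = spec$n_rows, n_cols = spec$n_cols, xll = spec$xll,
         yll = spec$yll, cell_size = spec$cell_size, crs = spec$crs),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a common-grid definition from JSON
#'
#' @param path JSON path written by [write_grid_spec_json()].
#' @return A [grid_spec()].
#' @export
read_grid_spec_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  grid_spec(j$n_rows, j$n_cols, j$xll, j$yll, j$cell_size, j$crs)
}
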