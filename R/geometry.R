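#' Zone polygon set
#'
#' Holds named polygons (e.g. functional urban areas) in the working CRS.
#' Each polygon is a single outer ring given as a two-column matrix of
#' vertices; the ring may be open (first vertex not repeated). Holes and
#' multipolygons are out of scope.
#'
#' @param ids Character vector of unique zone ids.
#' @param names Human-readable zone names (defaults to the ids).
#' @param polygons List of two-column numeric matrices (x, y vertices).
#' @return A `zone_set`.
#' @export
zone_set <- function(ids, polygons, names = ids) {
  stopifnot(length(ids) == length(polygons), length(names) == length(ids))
  if (anyDuplicated(ids)) stop("zone ids must be unique", call. = FALSE)
  polygons <- lapply(polygons, function(p) {
    p <- as.matrix(p)
    stopifnot(ncol(p) == 2, nrow(p) >= 3, all(is.finite(p)))
    # drop a repeated closing vertex; rings are stored open
    if (all(p[1, ] == p[nrow(p), ])) p <- p[-nrow(p), , drop = FALSE]
    if (abs(polygon_area(p)) <= 0) stop("degenerate zone polygon", call. = FALSE)
    p
  })
  structure(
    list(id = as.character(ids), name = as.character(names),
         polygon = polygons),
    class = "zone_set"
  )
}

#' @export
print.zone_set <- function(x, ...) {
  cat(sprintf("<zone_set> %d zone(s)\n", length(x$id)))
  invisible(x)
}

#' @export
length.zone_set <- function(x) length(x$id)

#' Signed polygon area (shoelace formula)
#'
#' @param p Two-column matrix of ring vertices (open ring).
#' @return Signed area; positive for counter-clockwise rings.
#' @export
polygon_area <- function(p) {
  n <- nrow(p)
  if (n < 3) return(0)
  x <- p[, 1]; y <- p[, 2]
  j <- c(n, seq_len(n - 1))
  sum(x[j] * y - x * y[j]) / 2
}

#' Clip a polygon to an axis-aligned rectangle
#'
#' Sutherland-Hodgman clipping against the four half-planes of the rectangle.
#' Adequate for convex clip windows; the subject polygon may be any simple
#' ring.
#'
#' @param p Two-column vertex matrix (open ring).
#' @param xmin,xmax,ymin,ymax Rectangle bounds.
#' @return Clipped vertex matrix (possibly 0 rows).
#' @export
clip_polygon_rect <- function(p, xmin, xmax, ymin, ymax) {
  clip_half <- function(pts, inside, intersect) {
    n <- nrow(pts)
    if (n == 0) return(pts)
    out <- matrix(numeric(0), ncol = 2)
    ins <- inside(pts)
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      a <- pts[i, ]; b <- pts[j, ]
      if (ins[i]) {
        out <- rbind(out, a)
        if (!ins[j]) out <- rbind(out, intersect(a, b))
      } else if (ins[j]) {
        out <- rbind(out, intersect(a, b))
      }
    }
    out
  }
  ix <- function(a, b, x) { # intersection with vertical line
    t <- (x - a[1]) / (b[1] - a[1])
    c(x, a[2] + t * (b[2] - a[2]))
  }
  iy <- function(a, b, y) {
    t <- (y - a[2]) / (b[2] - a[2])
    c(a[1] + t * (b[1] - a[1]), y)
  }
  p <- clip_half(p, function(q) q[, 1] >= xmin, function(a, b) ix(a, b, xmin))
  p <- clip_half(p, function(q) q[, 1] <= xmax, function(a, b) ix(a, b, xmax))
  p <- clip_half(p, function(q) q[, 2] >= ymin, function(a, b) iy(a, b, ymin))
  p <- clip_half(p, function(q) q[, 2] <= ymax, function(a, b) iy(a, b, ymax))
  p
}

#' Area of the intersection of a polygon with a rectangle
#'
#' @inheritParams clip_polygon_rect
#' @return Non-negative intersection area.
#' @export
polygon_rect_area <- function(p, xmin, xmax, ymin, ymax) {
  q <- clip_polygon_rect(p, xmin, xmax, ymin, ymax)
  if (nrow(q) < 3) 0 else abs(polygon_area(q))
}

#' Point-in-polygon test (crossing number)
#'
#' Even-odd rule, vectorised over points. Points exactly on an edge may fall
#' on either side; callers needing exact boundary handling should use the
#' area-based routines instead.
#'
#' @param px,py Point coordinate vectors.
#' @param p Two-column polygon vertex matrix (open ring).
#' @return Logical vector.
#' @export
points_in_polygon <- function(px, py, p) {
  n <- nrow(p)
  inside <- rep(FALSE, length(px))
  xj <- p[c(n, seq_len(n - 1)), 1]
  yj <- p[c(n, seq_len(n - 1)), 2]
  xi <- p[, 1]; yi <- p[, 2]
  for (k in seq_len(n)) {
    crosses <- ((yi[k] > py) != (yj[k] > py)) &
      (px < (xj[k] - xi[k]) * (py - yi[k]) / (yj[k] - yi[k]) + xi[k])
    inside <- xor(inside, crosses)
  }
  inside
}

#' Polygon bounding box
#'
#' @param p Two-column vertex matrix.
#' @return `c(xmin, xmax, ymin, ymax)`.
#' @export
polygon_bbox <- function(p) {
  c(xmin = min(p[, 1]), xmax = max(p[, 1]),
    ymin = min(p[, 2]), ymax = max(p[, 2]))
}

#' Read zone polygons from GeoJSON
#'
#' Accepts a FeatureCollection of Polygon features (outer ring only; holes
#' are rejected). Feature ids are taken from an `id` property, the feature
#' `id` member, or generated; names from a `name` property. Coordinates are
#' taken to be in the working CRS.
#'
#' @param path GeoJSON path.
#' @return A [zone_set()].
#' @export
read_zones_geojson <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(j$type) || j$type != "FeatureCollection") {
    stop("expected a GeoJSON FeatureCollection: ", path, call. = FALSE)
  }
  feats <- j$features
  ids <- character(0); nms <- character(0); polys <- list()
  for (k in seq_along(feats)) {
    f <- feats[[k]]
    g <- f$geometry
    if (is.null(g) || g$type != "Polygon") {
      stop("zone feature ", k, " is not a Polygon", call. = FALSE)
    }
    if (length(g$coordinates) != 1) {
      stop("zone feature ", k, " has interior rings (holes unsupported)",
           call. = FALSE)
    }
    ring <- do.call(rbind, lapply(g$coordinates[[1]],
                                  function(pt) c(pt[[1]], pt[[2]])))
    id <- f$properties$id
    if (is.null(id)) id <- f$id
    if (is.null(id)) id <- sprintf("zone_%03d", k)
    nm <- f$properties$name
    if (is.null(nm)) nm <- id
    ids <- c(ids, as.character(id))
    nms <- c(nms, as.character(nm))
    polys[[length(polys) + 1]] <- ring
  }
  zone_set(ids, polys, nms)
}

#' Write zone polygons to GeoJSON
#'
#' @param zones A [zone_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_zones_geojson <- function(zones, path) {
  feats <- lapply(seq_along(zones$id), function(k) {
    p <- zones$polygon[[k]]
    ring <- lapply(seq_len(nrow(p)), function(i) c(p[i, 1], p[i, 2]))
    ring[[length(ring) + 1]] <- ring[[1]] # close the ring on disk
    list(
      type = "Feature",
      properties = list(id = zones$id[k], name = zones$name[k]),
      geometry = list(type = "Polygon", coordinates = list(ring))
    )
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = feats),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
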