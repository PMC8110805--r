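#' Worst-case zonal classification rule
#'
#' A zone's baseline category is the one with the widest spatial coverage.
#' The precautionary override replaces it with the zone's second-largest
#' category when that category covers at least
#' `second_category_min_fraction` of the zone (default one third) and the
#' substitution yields a strictly more unfavourable trajectory. Severity
#' increases with the category code (1 < 2 < 3) and trajectories are ordered
#' lexicographically by (future severity, present severity).
#'
#' @param second_category_min_fraction Minimum zone fraction of the
#'   second-largest category for the override to fire; 1 disables it.
#' @param mode `"independent"` considers substituting each timeframe on its
#'   own (both may be substituted); `"single"` adopts only the one
#'   substitution giving the most unfavourable trajectory.
#' @return A `zonal_rule`.
#' @export
zonal_rule <- function(second_category_min_fraction = 1 / 3,
                       mode = c("independent", "single")) {
  stopifnot(second_category_min_fraction > 0,
            second_category_min_fraction <= 1)
  structure(
    list(second_category_min_fraction = second_category_min_fraction,
         mode = match.arg(mode)),
    class = "zonal_rule"
  )
}

#' Category area fractions of a polygon zone
#'
#' By default the exact intersection area of the polygon with every grid cell
#' is computed (polygon clipping), so cells partially covered by the zone
#' contribute proportionally; `method = "centers"` instead counts the cells
#' whose centre falls in the polygon, a fast approximation for large grids.
#' Fractions are taken over the polygon's non-nodata overlap area, so nodata
#' inside (or outside) the zone never distorts the composition.
#'
#' @param polygon Two-column vertex matrix in the working CRS.
#' @param g A [category_grid()].
#' @param method `"exact"` or `"centers"`.
#' @return Named fractions for categories "1", "2", "3" (sum to 1), with the
#'   non-nodata overlap area in the `area` attribute.
#' @export
zone_category_fractions <- function(polygon, g,
                                    method = c("exact", "centers")) {
  method <- match.arg(method)
  stopifnot(inherits(g, "category_grid"))
  spec <- g$spec
  bb <- polygon_bbox(polygon)
  cs <- spec$cell_size
  ext <- spec_extent(spec)
  c_lo <- max(1L, floor((bb["xmin"] - spec$xll) / cs) + 1)
  c_hi <- min(spec$n_cols, floor((bb["xmax"] - spec$xll) / cs) + 1)
  r_lo <- max(1L, spec$n_rows - floor((bb["ymax"] - spec$yll) / cs))
  r_hi <- min(spec$n_rows, spec$n_rows - floor((bb["ymin"] - spec$yll) / cs))
  if (c_lo > c_hi || r_lo > r_hi ||
      bb["xmin"] >= ext["xmax"] || bb["xmax"] <= ext["xmin"] ||
      bb["ymin"] >= ext["ymax"] || bb["ymax"] <= ext["ymin"]) {
    stop("zone polygon does not overlap the category grid", call. = FALSE)
  }
  area_by_cat <- c(`1` = 0, `2` = 0, `3` = 0)
  if (method == "exact") {
    for (i in r_lo:r_hi) {
      y_hi <- spec$yll + (spec$n_rows - i + 1) * cs
      for (j in c_lo:c_hi) {
        k <- g$values[i, j]
        if (is.na(k)) next
        x_lo <- spec$xll + (j - 1) * cs
        a <- polygon_rect_area(polygon, x_lo, x_lo + cs, y_hi - cs, y_hi)
        if (a > 0) area_by_cat[k] <- area_by_cat[k] + a
      }
    }
  } else {
    rows <- r_lo:r_hi; cols <- c_lo:c_hi
    cx <- cell_center_x(spec, cols); cy <- cell_center_y(spec, rows)
    pts <- expand.grid(row = rows, col = cols)
    inside <- points_in_polygon(cell_center_x(spec, pts$col),
                                cell_center_y(spec, pts$row), polygon)
    vals <- g$values[cbind(pts$row, pts$col)][inside]
    vals <- vals[!is.na(vals)]
    for (k in 1:3) area_by_cat[k] <- sum(vals == k) * cs^2
  }
  total <- sum(area_by_cat)
  if (total <= 0) {
    stop("zone polygon has no non-nodata overlap with the grid",
         call. = FALSE)
  }
  out <- area_by_cat / total
  attr(out, "area") <- total
  out
}

#' Baseline category of a zone: widest spatial coverage
#'
#' Exact ties are broken toward the higher-severity (higher-code) category.
#'
#' @param fractions Named category fractions (from
#'   [zone_category_fractions()]).
#' @return Category code (1, 2 or 3).
#' @export
assign_baseline <- function(fractions) {
  f <- as.numeric(fractions[c("1", "2", "3")])
  stopifnot(all(is.finite(f)), all(f >= 0))
  # which.max on the reversed vector prefers the higher code on ties
  4L - which.max(rev(f))
}

# is trajectory (p1, f1) strictly more unfavourable than (p0, f0)?
trajectory_worse <- function(p1, f1, p0, f0) {
  f1 > f0 || (f1 == f0 && p1 > p0)
}

second_category <- function(fractions) {
  f <- as.numeric(fractions[c("1", "2", "3")])
  first <- assign_baseline(fractions)
  rest <- setdiff(1:3, first)
  # among the remaining categories prefer the larger fraction, ties toward
  # the higher-severity code
  rest <- rest[order(-f[rest], -rest)]
  list(code = rest[1], fraction = f[rest[1]])
}

#' Precautionary worst-case adjustment of zone categories
#'
#' Starting from the baseline (widest-coverage) categories for the two
#' timeframes, considers replacing either timeframe's category with that
#' timeframe's second-largest category. A replacement is adopted when the
#' second category covers at least `rule$second_category_min_fraction` of
#' the zone and the substituted trajectory is strictly more unfavourable
#' than the baseline trajectory. The adjustment can only increase trajectory
#' severity, never decrease it.
#'
#' @param present_fractions,future_fractions Named category fractions per
#'   timeframe.
#' @param rule A [zonal_rule()].
#' @return List with `present`, `future` (final category codes),
#'   `baseline_present`, `baseline_future`, and `worst_case_applied`.
#' @export
worst_case_adjust <- function(present_fractions, future_fractions,
                              rule = zonal_rule()) {
  stopifnot(inherits(rule, "zonal_rule"))
  bp <- assign_baseline(present_fractions)
  bf <- assign_baseline(future_fractions)
  min_f <- rule$second_category_min_fraction
  cand <- list()
  sp <- second_category(present_fractions)
  if (sp$fraction >= min_f && trajectory_worse(sp$code, bf, bp, bf)) {
    cand$present <- sp$code
  }
  sf <- second_category(future_fractions)
  if (sf$fraction >= min_f && trajectory_worse(bp, sf$code, bp, bf)) {
    cand$future <- sf$code
  }
  fp <- bp; ff <- bf
  if (rule$mode == "independent") {
    if (!is.null(cand$present)) fp <- cand$present
    if (!is.null(cand$future)) ff <- cand$future
  } else if (length(cand)) {
    # adopt the single substitution with the most unfavourable outcome
    opts <- list()
    if (!is.null(cand$present)) opts <- c(opts, list(c(cand$present, bf)))
    if (!is.null(cand$future)) opts <- c(opts, list(c(bp, cand$future)))
    best <- opts[[1]]
    for (o in opts[-1]) {
      if (trajectory_worse(o[1], o[2], best[1], best[2])) best <- o
    }
    fp <- best[1]; ff <- best[2]
  }
  list(
    present = fp, future = ff,
    baseline_present = bp, baseline_future = bf,
    worst_case_applied = (fp != bp) || (ff != bf)
  )
}

#' Summarize consensus categories over a set of zones
#'
#' Computes per-zone category fractions for both timeframes, the baseline
#' (widest-coverage) categories, the worst-case override, the final
#' trajectory code and its colour, and cohort-level percentages: the share
#' of zones in each final category, per timeframe. Zones with no non-nodata
#' overlap are reported in `excluded` and omitted from the percentages.
#'
#' @param zones A [zone_set()].
#' @param present,future Aligned [category_grid()]s for the two timeframes.
#' @param rule A [zonal_rule()].
#' @param method Passed to [zone_category_fractions()].
#' @return List with `zones` (one row per summarized zone), `cohort`
#'   (percentage of zones per category and timeframe) and `excluded`
#'   (zone ids with zero overlap).
#' @export
summarize_zones <- function(zones, present, future, rule = zonal_rule(),
                            method = c("exact", "centers")) {
  method <- match.arg(method)
  stopifnot(inherits(zones, "zone_set"))
  stop_if_misaligned(present$spec, future$spec, "category maps")
  pal <- trajectory_palette()
  rows <- list(); excluded <- character(0)
  for (k in seq_along(zones$id)) {
    poly <- zones$polygon[[k]]
    fp <- tryCatch(zone_category_fractions(poly, present, method),
                   error = function(e) NULL)
    ff <- tryCatch(zone_category_fractions(poly, future, method),
                   error = function(e) NULL)
    if (is.null(fp) || is.null(ff)) {
      excluded <- c(excluded, zones$id[k])
      next
    }
    adj <- worst_case_adjust(fp, ff, rule)
    code <- 10L * adj$present + adj$future
    rows[[length(rows) + 1]] <- data.frame(
      zone_id = zones$id[k], name = zones$name[k],
      present_frac_1 = fp[["1"]], present_frac_2 = fp[["2"]],
      present_frac_3 = fp[["3"]],
      future_frac_1 = ff[["1"]], future_frac_2 = ff[["2"]],
      future_frac_3 = ff[["3"]],
      baseline_present = adj$baseline_present,
      baseline_future = adj$baseline_future,
      final_present = adj$present, final_future = adj$future,
      worst_case_applied = adj$worst_case_applied,
      final_trajectory = code,
      color = unname(pal[as.character(code)]),
      stringsAsFactors = FALSE
    )
  }
  if (length(excluded)) {
    warning("zones with no grid overlap excluded: ",
            paste(excluded, collapse = ", "), call. = FALSE)
  }
  if (!length(rows)) stop("no zone overlaps the grids", call. = FALSE)
  df <- do.call(rbind, rows)
  cohort <- do.call(rbind, lapply(c("present", "future"), function(tf) {
    col <- paste0("final_", tf)
    data.frame(
      timeframe = tf, category = 1:3,
      pct_zones = vapply(1:3, function(k) 100 * mean(df[[col]] == k),
                         numeric(1))
    )
  }))
  list(zones = df, cohort = cohort, excluded = excluded)
}
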