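#' Extract suitability values at occurrence points
#'
#' Looks up the grid cell containing each occurrence. Points outside the grid
#' extent and points landing on nodata cells are dropped; both counts are
#' returned so threshold tables can report how many records informed each
#' model.
#'
#' @param g A [suitability_grid()], normalized to unit scale.
#' @param occ An `occurrence_set`.
#' @param dedupe_cells If `TRUE`, occurrences sharing a grid cell count once
#'   (spatial thinning to the model's resolution); default keeps every record.
#' @return List with `values` (numeric vector, one per retained occurrence),
#'   `n_used`, `n_outside`, `n_nodata`.
#' @export
extract_values <- function(g, occ, dedupe_cells = FALSE) {
  stopifnot(inherits(g, "suitability_grid"), inherits(occ, "occurrence_set"))
  if (g$scale != "unit") {
    stop("suitability grid must be normalized to unit scale first",
         call. = FALSE)
  }
  idx <- point_to_cell(g$spec, occ$x, occ$y)
  outside <- is.na(idx$row)
  vals <- rep(NA_real_, nrow(occ))
  inb <- which(!outside)
  vals[inb] <- g$values[cbind(idx$row[inb], idx$col[inb])]
  nodata <- !outside & is.na(vals)
  keep <- !outside & !nodata
  if (dedupe_cells) {
    cell <- (idx$row - 1L) * g$spec$n_cols + idx$col
    keep <- keep & !duplicated(cell)
  }
  if (!any(keep)) {
    stop("no occurrence overlaps a non-nodata cell of the grid", call. = FALSE)
  }
  list(
    values = vals[keep],
    n_used = sum(keep),
    n_outside = sum(outside),
    n_nodata = sum(nodata)
  )
}

#' Fixed-omission (presence percentile) threshold
#'
#' Returns the suitability value below which at most `fraction` of the
#' occurrence values fall. Under the default `lower_empirical` rule the
#' threshold is the largest observed value whose strictly-below fraction does
#' not exceed `fraction`, which guarantees the omission bound exactly on the
#' calibration data and is reproducible across platforms. The
#' `linear_interpolation` rule returns the conventional interpolated sample
#' quantile (`stats::quantile`, type 7) instead; it does not carry the exact
#' guarantee.
#'
#' @param values Numeric vector of suitability values at occurrences.
#' @param fraction Omission fraction in (0, 0.5); typically 0.05 or 0.10.
#' @param rule Quantile convention.
#' @return A single threshold value.
#' @export
presence_threshold <- function(values, fraction = 0.05,
                               rule = c("lower_empirical",
                                        "linear_interpolation")) {
  rule <- match.arg(rule)
  if (!length(values)) stop("no occurrence values supplied", call. = FALSE)
  if (any(!is.finite(values))) {
    stop("occurrence values contain non-finite entries", call. = FALSE)
  }
  stopifnot(fraction > 0, fraction < 0.5)
  if (rule == "linear_interpolation") {
    return(unname(stats::quantile(values, fraction, type = 7)))
  }
  n <- length(values)
  u <- sort(unique(values))
  # strictly-below count for each candidate threshold u[k]
  below <- c(0, cumsum(tabulate(match(values, u), length(u))))[seq_along(u)]
  ok <- below / n <= fraction + 1e-12
  u[max(which(ok))]
}

#' Per-model threshold record
#'
#' Bundles a calibrated threshold with its provenance: which model, how many
#' occurrence records informed it and how many were dropped.
#'
#' @param model_id Model identifier.
#' @param threshold Threshold in \[0, 1\].
#' @param fraction Omission fraction used.
#' @param n_used,n_dropped Occurrence record counts.
#' @param rule Quantile rule used.
#' @return A `model_threshold`.
#' @export
model_threshold <- function(model_id, threshold, fraction,
                            n_used, n_dropped = 0L,
                            rule = "lower_empirical") {
  stopifnot(threshold >= 0, threshold <= 1, n_used >= 1)
  structure(
    list(model_id = as.character(model_id), threshold = threshold,
         fraction = fraction, n_used = as.integer(n_used),
         n_dropped = as.integer(n_dropped), rule = rule),
    class = "model_threshold"
  )
}

#' Calibrate a model's presence threshold on occurrences
#'
#' Convenience wrapper: [extract_values()] then [presence_threshold()].
#'
#' @param g The model's present-day [suitability_grid()] (unit scale).
#' @param occ An `occurrence_set`.
#' @param model_id Model identifier recorded on the result.
#' @inheritParams presence_threshold
#' @inheritParams extract_values
#' @return A [model_threshold()].
#' @export
calibrate_threshold <- function(g, occ, model_id, fraction = 0.05,
                                rule = c("lower_empirical",
                                         "linear_interpolation"),
                                dedupe_cells = FALSE) {
  rule <- match.arg(rule)
  ex <- extract_values(g, occ, dedupe_cells = dedupe_cells)
  model_threshold(
    model_id,
    presence_threshold(ex$values, fraction, rule),
    fraction,
    n_used = ex$n_used,
    n_dropped = ex$n_outside + ex$n_nodata,
    rule = rule
  )
}

#' Binarize a suitability surface at a threshold
#'
#' A cell is suitable (1) iff its value is greater than or equal to the
#' threshold, so an occurrence sitting exactly at the threshold falls in the
#' suitable class. Nodata is preserved.
#'
#' @param g A [suitability_grid()] on the unit scale.
#' @param threshold A [model_threshold()] or a bare number in \[0, 1\].
#' @return A [binary_grid()].
#' @export
binarize <- function(g, threshold) {
  stopifnot(inherits(g, "suitability_grid"))
  if (g$scale != "unit") {
    stop("normalize the suitability grid before binarizing", call. = FALSE)
  }
  t <- if (inherits(threshold, "model_threshold")) threshold$threshold
       else threshold
  stopifnot(is.numeric(t), length(t) == 1, t >= 0, t <= 1)
  binary_grid((g$values >= t) * 1, g$spec)
}

#' Transfer a present-day threshold to a future projection
#'
#' Future projections are binarized with the threshold calibrated on the
#' matching model's present-day prediction; the model ids must agree.
#'
#' @param present A [model_threshold()] calibrated on present-day conditions.
#' @param future_g The same model's future [suitability_grid()] (unit scale).
#' @param model_id Model id of `future_g`.
#' @return A [binary_grid()].
#' @export
transfer_threshold <- function(present, future_g, model_id) {
  stopifnot(inherits(present, "model_threshold"))
  if (!identical(as.character(model_id), present$model_id)) {
    stop(sprintf(
      "threshold transfer across models refused: threshold is for '%s', future grid is for '%s'",
      present$model_id, model_id
    ), call. = FALSE)
  }
  binarize(future_g, present)
}

#' Assemble a threshold table
#'
#' @param thresholds List of [model_threshold()] objects.
#' @return data.frame with one row per model (model_id, omission_fraction,
#'   threshold, n_used, n_dropped, rule), mirroring a supplementary
#'   threshold table.
#' @export
threshold_table <- function(thresholds) {
  do.call(rbind, lapply(thresholds, function(t) {
    data.frame(
      model_id = t$model_id, omission_fraction = t$fraction,
      threshold = t$threshold, n_used = t$n_used, n_dropped = t$n_dropped,
      rule = t$rule, stringsAsFactors = FALSE
    )
  }))
}
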