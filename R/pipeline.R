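#' Run the full consensus-mapping pipeline
#'
#' End-to-end workflow over an ensemble of continuous suitability surfaces:
#'
#' 1. normalize every surface to the unit scale;
#' 2. calibrate each model's fixed-omission presence threshold on the
#'    occurrences against its present-day surface (at native resolution) and
#'    binarize; future surfaces are binarized with the matching model's
#'    present-day threshold;
#' 3. build the common grid over the intersection of all model extents and
#'    harmonize every binary map onto it;
#' 4. sum into agreement maps and classify into the three consensus
#'    categories per timeframe (rules default to "majority plus one":
#'    5 of 7, 4 of 5);
#' 5. cross the two timeframes into the nine-class trajectory map and its
#'    area report;
#' 6. summarize categories over the zone polygons with the worst-case
#'    override.
#'
#' The whole pipeline is deterministic, and present-day results do not
#' depend on whether future surfaces are supplied.
#'
#' @param models List of models, each `list(model_id =, present =
#'   suitability_grid, future = suitability_grid or NULL)`. At least two
#'   present-day models; every future surface requires a present-day one
#'   (threshold transfer).
#' @param occurrences An `occurrence_set`.
#' @param zones Optional [zone_set()]; `NULL` skips the zonal stage.
#' @param omission Vector of omission fractions (default `c(0.05, 0.10)`);
#'   the pipeline is run once per fraction.
#' @param cell_size Common-grid cell size (default 25).
#' @param regrid_rule Categorical aggregation rule, see [regrid_binary()].
#' @param present_rule,future_rule Optional [consensus_rule()]s; default
#'   "majority plus one" for the respective ensemble sizes.
#' @param zonal_rule A [zonal_rule()].
#' @param threshold_rule Quantile convention, see [presence_threshold()].
#' @param zone_method Zonal statistics method, see
#'   [zone_category_fractions()].
#' @param anchor Optional common-grid lattice anchor, see
#'   [build_common_grid()].
#' @return A result bundle: list with `common_grid`, `manifest`, and one
#'   entry per omission fraction (named e.g. `"p05"`) holding `thresholds`
#'   (data.frame), `binary_present`, `binary_future`, `agreement_present`,
#'   `agreement_future`, `category_present`, `category_future`,
#'   `trajectory`, `area_report`, `zone_summary`.
#' @export
run_all <- function(models, occurrences, zones = NULL,
                    omission = c(0.05, 0.10), cell_size = 25,
                    regrid_rule = "majority_area",
                    present_rule = NULL, future_rule = NULL,
                    zonal_rule = sdmconsensus::zonal_rule(),
                    threshold_rule = "lower_empirical",
                    zone_method = "exact",
                    anchor = NULL) {
  stopifnot(length(models) >= 2)
  ids <- vapply(models, `[[`, character(1), "model_id")
  if (anyDuplicated(ids)) stop("duplicate model ids", call. = FALSE)
  for (m in models) {
    if (is.null(m$present)) {
      stop(sprintf("model '%s' has no present-day surface", m$model_id),
           call. = FALSE)
    }
  }
  models <- lapply(models, function(m) {
    m$present <- normalize_scale(m$present)
    if (!is.null(m$future)) m$future <- normalize_scale(m$future)
    m
  })
  has_future <- vapply(models, function(m) !is.null(m$future), logical(1))

  extents <- lapply(models, function(m) spec_extent(m$present$spec))
  common <- build_common_grid(extents, cell_size = cell_size,
                              crs = models[[1]]$present$spec$crs,
                              anchor = anchor)

  n_p <- length(models)
  n_f <- sum(has_future)
  rule_p <- if (is.null(present_rule)) consensus_rule(n_p) else present_rule
  rule_f <- if (n_f >= 2) {
    if (is.null(future_rule)) consensus_rule(n_f) else future_rule
  } else NULL

  bundle <- list(common_grid = common)
  for (p in omission) {
    stage <- function(what, expr) {
      tryCatch(expr, error = function(e) {
        stop(sprintf("pipeline stage '%s' failed: %s", what,
                     conditionMessage(e)), call. = FALSE)
      })
    }
    thresholds <- stage("threshold", lapply(models, function(m) {
      calibrate_threshold(m$present, occurrences, m$model_id,
                          fraction = p, rule = threshold_rule)
    }))
    bin_p <- stage("binarize", lapply(seq_along(models), function(i) {
      regrid_binary(binarize(models[[i]]$present, thresholds[[i]]),
                    common, rule = regrid_rule)
    }))
    names(bin_p) <- ids
    bin_f <- stage("binarize_future", lapply(which(has_future), function(i) {
      regrid_binary(
        transfer_threshold(thresholds[[i]], models[[i]]$future, ids[i]),
        common, rule = regrid_rule
      )
    }))
    names(bin_f) <- ids[has_future]

    agree_p <- stage("consensus", sum_models(bin_p))
    cat_p <- categorize(agree_p, rule_p)
    agree_f <- NULL; cat_f <- NULL; traj <- NULL; report <- NULL
    zsum <- NULL
    if (!is.null(rule_f)) {
      agree_f <- stage("consensus_future", sum_models(bin_f))
      cat_f <- categorize(agree_f, rule_f)
      traj <- stage("trajectory", classify_trajectory(cat_p, cat_f))
      report <- area_report(traj)
      if (!is.null(zones) && length(zones$id)) {
        zsum <- stage("zones", summarize_zones(zones, cat_p, cat_f,
                                               rule = zonal_rule,
                                               method = zone_method))
      }
    }
    bundle[[omission_key(p)]] <- list(
      omission = p,
      thresholds = threshold_table(thresholds),
      binary_present = bin_p, binary_future = bin_f,
      agreement_present = agree_p, agreement_future = agree_f,
      category_present = cat_p, category_future = cat_f,
      trajectory = traj, area_report = report,
      zone_summary = zsum
    )
  }
  bundle$manifest <- run_manifest(models, omission, cell_size, regrid_rule,
                                  rule_p, rule_f, zonal_rule)
  bundle
}

omission_key <- function(p) sprintf("p%02d", round(100 * p))

run_manifest <- function(models, omission, cell_size, regrid_rule,
                         rule_p, rule_f, zonal_rule) {
  list(
    n_models_present = length(models),
    n_models_future = sum(vapply(models, function(m) !is.null(m$future),
                                 logical(1))),
    model_ids = vapply(models, `[[`, character(1), "model_id"),
    omission_fractions = omission,
    cell_size = cell_size,
    regrid_rule = regrid_rule,
    present_rule = unclass(rule_p),
    future_rule = if (!is.null(rule_f)) unclass(rule_f),
    zonal_rule = unclass(zonal_rule),
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("sdmconsensus"))
  )
}

#' Write a result bundle to disk
#'
#' Persists, per omission fraction, the threshold table (CSV), agreement and
#' category rasters (ASCII grid + palette sidecars), the trajectory raster,
#' the area report (CSV + JSON aggregates) and the zone summary (CSV), plus
#' the common-grid definition and the run manifest (JSON).
#'
#' @param bundle Result of [run_all()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_grid_spec_json(bundle$common_grid, file.path(dir, "common_grid.json"))
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  for (key in names(bundle)) {
    res <- bundle[[key]]
    if (!is.list(res) || is.null(res$thresholds)) next
    sub <- file.path(dir, key)
    dir.create(sub, showWarnings = FALSE)
    utils::write.csv(res$thresholds, file.path(sub, "thresholds.csv"),
                     row.names = FALSE)
    write_asc(res$agreement_present$values, res$agreement_present$spec,
              file.path(sub, "agreement_present.asc"))
    write_category_asc(res$category_present,
                       file.path(sub, "category_present.asc"))
    if (!is.null(res$category_future)) {
      write_asc(res$agreement_future$values, res$agreement_future$spec,
                file.path(sub, "agreement_future.asc"))
      write_category_asc(res$category_future,
                         file.path(sub, "category_future.asc"))
      write_category_asc(res$trajectory, file.path(sub, "trajectory.asc"))
      utils::write.csv(res$area_report$table,
                       file.path(sub, "trajectory_areas.csv"),
                       row.names = FALSE)
      jsonlite::write_json(res$area_report$aggregates,
                           file.path(sub, "trajectory_aggregates.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    if (!is.null(res$zone_summary)) {
      utils::write.csv(res$zone_summary$zones,
                       file.path(sub, "zone_summary.csv"), row.names = FALSE)
      utils::write.csv(res$zone_summary$cohort,
                       file.path(sub, "zone_cohort.csv"), row.names = FALSE)
    }
  }
  invisible(dir)
}

#' Human-readable summary of a result bundle
#'
#' Restates, per omission fraction, the category composition of both
#' timeframes, the trajectory aggregates on both bases, and the zone cohort
#' percentages, as markdown lines. Values are taken verbatim from the
#' bundle's own reports.
#'
#' @param bundle Result of [run_all()].
#' @param digits Digits for printed percentages.
#' @return Character vector of markdown lines, invisibly printed with
#'   `cat()` when `print = TRUE`.
#' @param print Print the lines to the console.
#' @export
report <- function(bundle, digits = 1, print = TRUE) {
  pc <- function(x) sprintf(paste0("%.", digits, "f%%"), 100 * x)
  lines <- character(0)
  add <- function(...) lines <<- c(lines, sprintf(...))
  add("# Consensus-mapping run summary")
  add("")
  add("- common grid: %d x %d cells of %g",
      bundle$common_grid$n_rows, bundle$common_grid$n_cols,
      bundle$common_grid$cell_size)
  for (key in names(bundle)) {
    res <- bundle[[key]]
    if (!is.list(res) || is.null(res$thresholds)) next
    add("")
    add("## Omission fraction %g", res$omission)
    fp <- category_fractions(res$category_present)
    add("- present categories (unsuitable / uncertain / suitable): %s / %s / %s",
        pc(fp[["1"]]), pc(fp[["2"]]), pc(fp[["3"]]))
    if (!is.null(res$category_future)) {
      ff <- category_fractions(res$category_future)
      add("- future categories  (unsuitable / uncertain / suitable): %s / %s / %s",
          pc(ff[["1"]]), pc(ff[["2"]]), pc(ff[["3"]]))
      ag <- res$area_report$aggregates
      add("- remains suitable: %s of the study area",
          pc(ag$remain_suitable$fraction_of_study_area))
      add("- newly suitable: %s of the study area (of which %s starts from consensually unsuitable)",
          pc(ag$newly_suitable$fraction_of_study_area),
          pc(ag$newly_suitable_from_unsuitable$share_of_newly_suitable))
      add("- remains unsuitable: %s; uncertain in the future: %s",
          pc(ag$remain_unsuitable$fraction_of_study_area),
          pc(ag$uncertain_future$fraction_of_study_area))
    }
    if (!is.null(res$zone_summary)) {
      co <- res$zone_summary$cohort
      for (tf in c("present", "future")) {
        s <- co[co$timeframe == tf, ]
        add("- urban zones (%s): %.0f%% unsuitable, %.0f%% uncertain, %.0f%% suitable",
            tf, s$pct_zones[1], s$pct_zones[2], s$pct_zones[3])
      }
    }
  }
  if (print) cat(paste(lines, collapse = "\n"), "\n")
  invisible(lines)
}
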