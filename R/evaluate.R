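#' Evaluate consensus recovery of the latent suitable/unsuitable pattern
#'
#' For a synthetic ensemble the ground truth is known: the latent field and
#' its own fixed-omission threshold (calibrated on the generated occurrences)
#' define the true suitable/unsuitable pattern. This runs the consensus
#' pipeline on the ensemble's present-day models and measures how often the
#' consensus category agrees with the truth on cells whose latent value is at
#' least `margin` away from the threshold — cells near the threshold are
#' genuinely ambiguous and are assessed separately: where model noise is
#' large, the high-uncertainty class should concentrate there.
#'
#' @param ens A synthetic ensemble from [generate_ensemble()].
#' @param omission Omission fraction for all thresholds (default 0.05).
#' @param margin Latent distance from the threshold defining "clear" cells.
#' @param cell_size Common-grid cell size.
#' @return List: `threshold` (latent truth threshold), `recovery` (agreement
#'   fraction on clear cells), `n_clear` (their count),
#'   `uncertain_mean_dist` and `certain_mean_dist` (mean latent distance to
#'   the threshold for cells classified high-uncertainty vs low-uncertainty),
#'   `uncertain_near_fraction` (share of high-uncertainty cells within
#'   `margin` of the threshold), `category` (the present-day
#'   [category_grid()]), `latent_common` (latent means on the common grid).
#' @export
evaluate_recovery <- function(ens, omission = 0.05, margin = 0.1,
                              cell_size = 25) {
  b <- run_all(ens$models, ens$occurrences, zones = NULL,
               omission = omission, cell_size = cell_size)
  res <- b[[omission_key(omission)]]
  cat_p <- res$category_present
  common <- b$common_grid
  latent <- ens$latent_present
  t_true <- presence_threshold(
    extract_values(latent, ens$occurrences)$values, omission
  )
  lat_common <- regrid_mean(latent$values, latent$spec, common)
  ok <- !is.na(cat_p$values) & !is.na(lat_common)
  truth_suit <- lat_common >= t_true + margin
  truth_unsuit <- lat_common <= t_true - margin
  clear <- ok & (truth_suit | truth_unsuit)
  hit <- (truth_suit & cat_p$values == 3) | (truth_unsuit & cat_p$values == 1)
  dist <- abs(lat_common - t_true)
  unc <- ok & cat_p$values == 2
  cert <- ok & cat_p$values != 2
  list(
    threshold = t_true,
    recovery = sum(hit[clear]) / sum(clear),
    n_clear = sum(clear),
    uncertain_mean_dist = if (any(unc)) mean(dist[unc]) else NA_real_,
    certain_mean_dist = mean(dist[cert]),
    uncertain_near_fraction = if (any(unc)) mean(dist[unc] < margin)
                              else NA_real_,
    category = cat_p,
    latent_common = lat_common
  )
}
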