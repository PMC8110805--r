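#' Configuration of the synthetic study system
#'
#' The generator emulates the statistical structure of a multi-model
#' suitability ensemble for a temperate continent: a shared latent
#' suitability field (spatially autocorrelated, uniform on \[0, 1\] after
#' rank transform), per-model surfaces equal to the latent field plus
#' independent autocorrelated noise at heterogeneous native resolutions and
#' slightly differing extents, a warmed-future latent field with a smooth
#' poleward (northward) suitability increment, occurrence points sampled
#' with acceptance probability equal to latent suitability, and
#' non-overlapping jittered rectangular zone polygons standing in for
#' functional urban areas.
#'
#' Defaults mirror the study system the pipeline is built for: seven models
#' for the present day of which five carry a future projection, native
#' resolutions spanning roughly 1-55 km, a 2000 x 2000 km working extent in
#' an equal-area CRS with km units, and 65 urban zones.
#'
#' @param seed Integer seed; the whole generator is deterministic given it.
#' @param n_models Number of present-day models.
#' @param has_future Logical vector (length `n_models`): which models carry
#'   a future projection (default: 5 of 7).
#' @param extent_size Side length of the square latent extent (km).
#' @param latent_cell Latent grid cell size (km).
#' @param model_resolutions Native cell sizes per model (km).
#' @param model_scales Value scale per model (`"unit"`/`"percent"`), to
#'   exercise scale normalization.
#' @param model_noise_sd Standard deviation of per-model noise on the unit
#'   suitability scale.
#' @param autocorrelation_length Gaussian-kernel bandwidth of the random
#'   fields (km).
#' @param n_occurrences Number of occurrence points.
#' @param future_shift Northward suitability increment at the northern edge
#'   (0 at the southern edge, linear in between).
#' @param n_zones Number of zone polygons.
#' @param extent_jitter Maximum inward shrink of each model's extent per
#'   side (km), so extents differ across models.
#' @param crs CRS identifier stamped on all generated objects.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_models = 7L,
                       has_future = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE,
                                      FALSE)[seq_len(n_models)],
                       extent_size = 2000,
                       latent_cell = 5,
                       model_resolutions = c(25, 18, 5, 5, 50, 55, 1),
                       model_scales = rep(c("unit", "percent"),
                                          length.out = n_models),
                       model_noise_sd = 0.1,
                       autocorrelation_length = 200,
                       n_occurrences = 500L,
                       future_shift = 0.3,
                       n_zones = 65L,
                       extent_jitter = 40,
                       crs = "local-equal-area-km") {
  stopifnot(n_models >= 2, length(has_future) == n_models,
            length(model_resolutions) >= n_models,
            all(model_resolutions > 0), latent_cell > 0,
            autocorrelation_length > 0, model_noise_sd >= 0,
            extent_jitter >= 0, future_shift >= 0)
  n <- round(extent_size / latent_cell)
  structure(list(
    seed = as.integer(seed), n_models = as.integer(n_models),
    has_future = has_future,
    latent_spec = grid_spec(n, n, 0, 0, latent_cell, crs),
    model_resolutions = model_resolutions[seq_len(n_models)],
    model_scales = model_scales,
    model_noise_sd = model_noise_sd,
    autocorrelation_length = autocorrelation_length,
    n_occurrences = as.integer(n_occurrences),
    future_shift = future_shift,
    n_zones = as.integer(n_zones),
    extent_jitter = extent_jitter,
    crs = crs
  ), class = "sim_config")
}

# banded row-stochastic Gaussian smoothing matrix (edges renormalized)
kernel_matrix <- function(n, sigma_cells) {
  if (sigma_cells <= 0) return(diag(n))
  r <- min(n - 1, max(1L, ceiling(3 * sigma_cells)))
  offs <- -r:r
  w <- exp(-offs^2 / (2 * sigma_cells^2))
  K <- matrix(0, n, n)
  for (d in seq_along(offs)) {
    idx <- seq_len(n) + offs[d]
    ok <- idx >= 1 & idx <= n
    K[cbind(which(ok), idx[ok])] <- K[cbind(which(ok), idx[ok])] + w[d]
  }
  K / rowSums(K)
}

# smooth white noise into an autocorrelated field on a grid spec
smooth_field <- function(noise, spec, length_scale) {
  sigma <- length_scale / spec$cell_size
  Kr <- kernel_matrix(spec$n_rows, sigma)
  Kc <- kernel_matrix(spec$n_cols, sigma)
  Kr %*% noise %*% t(Kc)
}

#' Generate the shared latent suitability field
#'
#' White noise convolved with a Gaussian kernel of bandwidth
#' `autocorrelation_length`, then rank-transformed to `rank / (n + 1)` so the
#' marginal distribution is uniform on (0, 1). Deterministic given
#' `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return A [suitability_grid()] on the latent grid (unit scale).
#' @export
generate_latent_field <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  spec <- cfg$latent_spec
  set.seed(cfg$seed)
  z <- matrix(stats::rnorm(spec$n_rows * spec$n_cols),
              spec$n_rows, spec$n_cols)
  f <- smooth_field(z, spec, cfg$autocorrelation_length)
  u <- matrix(rank(f, ties.method = "average") / (length(f) + 1),
              spec$n_rows, spec$n_cols)
  suitability_grid(u, spec, scale = "unit")
}

#' Generate the warmed-future latent field
#'
#' Adds a smooth northward-increasing increment to the latent field: zero at
#' the southern edge, `cfg$future_shift` at the northern edge, clipped to
#' \[0, 1\]. Emulates poleward expansion of suitable conditions under
#' mid-century warming.
#'
#' @param latent The present-day latent [suitability_grid()].
#' @param cfg A [sim_config()].
#' @return A [suitability_grid()] (unit scale).
#' @export
generate_future <- function(latent, cfg) {
  stopifnot(inherits(latent, "suitability_grid"))
  spec <- latent$spec
  yc <- cell_center_y(spec, seq_len(spec$n_rows))
  ext <- spec_extent(spec)
  fr <- (yc - ext["ymin"]) / (ext["ymax"] - ext["ymin"])
  inc <- matrix(cfg$future_shift * fr, spec$n_rows, spec$n_cols)
  suitability_grid(pmin(pmax(latent$values + inc, 0), 1), spec,
                   scale = "unit")
}

# a model's perturbed extent and native grid, deterministic per model index
model_spec <- function(cfg, m) {
  set.seed(cfg$seed + 100L * m)
  cs <- cfg$model_resolutions[m]
  ext <- spec_extent(cfg$latent_spec)
  mar <- stats::runif(4, 0, cfg$extent_jitter) # W, S, E, N inward shrink
  xll <- ext["xmin"] + mar[1]
  yll <- ext["ymin"] + mar[2]
  n_cols <- floor((ext["xmax"] - mar[3] - xll) / cs)
  n_rows <- floor((ext["ymax"] - mar[4] - yll) / cs)
  grid_spec(n_rows, n_cols, xll, yll, cs, cfg$crs)
}

#' Generate one model's suitability surface
#'
#' The latent field plus independent autocorrelated noise (rescaled to
#' standard deviation `model_noise_sd`), clipped to \[0, 1\], aggregated to
#' the model's native resolution over its perturbed extent, and expressed on
#' the model's declared value scale. Models therefore agree where the latent
#' field is extreme and disagree near suitability 0.5, as real ensembles do
#' at transition zones.
#'
#' @param latent A latent [suitability_grid()] (present or future).
#' @param m Model index in `1:cfg$n_models`.
#' @param cfg A [sim_config()].
#' @param timeframe `"present"` or `"future"`; noise is independent between
#'   timeframes but the native grid is shared within a model.
#' @return A [suitability_grid()] on the model's native grid.
#' @export
generate_model_surface <- function(latent, m, cfg,
                                   timeframe = c("present", "future")) {
  timeframe <- match.arg(timeframe)
  stopifnot(inherits(cfg, "sim_config"), m >= 1, m <= cfg$n_models)
  spec_m <- model_spec(cfg, m)
  lat_spec <- latent$spec
  set.seed(cfg$seed + 100L * m + if (timeframe == "present") 1L else 2L)
  vals <- latent$values
  if (cfg$model_noise_sd > 0) {
    z <- matrix(stats::rnorm(lat_spec$n_rows * lat_spec$n_cols),
                lat_spec$n_rows, lat_spec$n_cols)
    noise <- smooth_field(z, lat_spec, cfg$autocorrelation_length)
    noise <- noise / stats::sd(noise) * cfg$model_noise_sd
    vals <- vals + noise
  }
  vals <- pmin(pmax(vals, 0), 1)
  out <- regrid_mean(vals, lat_spec, spec_m)
  scale <- cfg$model_scales[m]
  if (scale == "percent") out <- out * 100
  suitability_grid(out, spec_m, scale = scale)
}

#' Sample occurrence points biased toward suitable conditions
#'
#' Rejection sampling: candidate points uniform over the latent extent are
#' accepted with probability equal to the latent suitability of their cell,
#' until `cfg$n_occurrences` points are collected. Deterministic given the
#' seed.
#'
#' @param latent The latent [suitability_grid()].
#' @param cfg A [sim_config()].
#' @return An `occurrence_set`.
#' @export
generate_occurrences <- function(latent, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 7777L)
  ext <- spec_extent(latent$spec)
  n_want <- cfg$n_occurrences
  xs <- numeric(0); ys <- numeric(0)
  guard <- 0L
  while (length(xs) < n_want && guard < 1000L) {
    guard <- guard + 1L
    m <- max(100L, 2L * (n_want - length(xs)))
    px <- stats::runif(m, ext["xmin"], ext["xmax"])
    py <- stats::runif(m, ext["ymin"], ext["ymax"])
    u <- stats::runif(m)
    idx <- point_to_cell(latent$spec, px, py)
    p <- latent$values[cbind(idx$row, idx$col)]
    acc <- !is.na(p) & u < p
    xs <- c(xs, px[acc]); ys <- c(ys, py[acc])
  }
  if (length(xs) < n_want) {
    stop("occurrence sampling failed to reach the requested count",
         call. = FALSE)
  }
  occurrence_set(xs[seq_len(n_want)], ys[seq_len(n_want)],
                 id = sprintf("occ_%04d", seq_len(n_want)))
}

#' Generate non-overlapping zone polygons
#'
#' Zones are jittered rectangles placed in separate slots of a regular
#' layout inside the latent extent (shrunk by the extent jitter so every
#' zone lies inside all model extents); slot containment guarantees zero
#' pairwise overlap.
#'
#' @param cfg A [sim_config()].
#' @return A [zone_set()] (empty if `n_zones = 0`).
#' @export
generate_zones <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_zones == 0L) {
    return(structure(list(id = character(0), name = character(0),
                          polygon = list()), class = "zone_set"))
  }
  set.seed(cfg$seed + 9999L)
  ext <- spec_extent(cfg$latent_spec)
  pad <- cfg$extent_jitter
  x0 <- ext["xmin"] + pad; x1 <- ext["xmax"] - pad
  y0 <- ext["ymin"] + pad; y1 <- ext["ymax"] - pad
  g <- ceiling(sqrt(cfg$n_zones))
  pitch_x <- (x1 - x0) / g; pitch_y <- (y1 - y0) / g
  slots <- sample(g * g, cfg$n_zones)
  polys <- lapply(slots, function(s) {
    gi <- (s - 1) %% g; gj <- (s - 1) %/% g
    cx <- x0 + (gi + stats::runif(1, 0.35, 0.65)) * pitch_x
    cy <- y0 + (gj + stats::runif(1, 0.35, 0.65)) * pitch_y
    hw <- stats::runif(1, 0.10, 0.16) * pitch_x
    hh <- stats::runif(1, 0.10, 0.16) * pitch_y
    base <- rbind(
      c(cx - hw, cy - hh), c(cx + hw, cy - hh),
      c(cx + hw, cy + hh), c(cx - hw, cy + hh)
    )
    jit <- matrix(stats::runif(8, -0.15, 0.15), 4, 2) *
      cbind(rep(hw, 4), rep(hh, 4))
    base + jit
  })
  zone_set(sprintf("fua_%02d", seq_len(cfg$n_zones)), polys,
           sprintf("Urban area %02d", seq_len(cfg$n_zones)))
}

#' Generate a full synthetic ensemble
#'
#' Orchestrates the generator: present and future latent fields, per-model
#' present (and, where configured, future) surfaces, occurrences, and zone
#' polygons. Fully deterministic given `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return List with `cfg`, `latent_present`, `latent_future`, `models`
#'   (list of `model_id`, `present`, `future` or `NULL`), `occurrences`,
#'   `zones`.
#' @export
generate_ensemble <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  latent <- generate_latent_field(cfg)
  latent_future <- generate_future(latent, cfg)
  models <- lapply(seq_len(cfg$n_models), function(m) {
    list(
      model_id = sprintf("model_%02d", m),
      present = generate_model_surface(latent, m, cfg, "present"),
      future = if (cfg$has_future[m]) {
        generate_model_surface(latent_future, m, cfg, "future")
      }
    )
  })
  list(
    cfg = cfg,
    latent_present = latent,
    latent_future = latent_future,
    models = models,
    occurrences = generate_occurrences(latent, cfg),
    zones = generate_zones(cfg)
  )
}
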