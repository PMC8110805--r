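#' Cross present and future categories into trajectory classes
#'
#' Each cell's trajectory is the ordered pair of consensus categories,
#' encoded `10 * present + future`, giving nine classes (11 ... 33). A cell
#' is nodata when either timeframe is nodata.
#'
#' @param present,future Aligned [category_grid()]s.
#' @return A [trajectory_grid()].
#' @export
classify_trajectory <- function(present, future) {
  stopifnot(inherits(present, "category_grid"),
            inherits(future, "category_grid"))
  stop_if_misaligned(present$spec, future$spec, "category maps")
  trajectory_grid(10 * present$values + future$values, present$spec)
}

trajectory_labels <- function() {
  cat_lab <- c("unsuitable", "uncertain", "suitable")
  codes <- trajectory_codes()
  stats::setNames(
    sprintf("%s -> %s", cat_lab[codes %/% 10], cat_lab[codes %% 10]),
    codes
  )
}

#' Area statistics of a trajectory map
#'
#' Cells of the common grid are equal-area, so area fractions are cell-count
#' fractions over the non-nodata cells. Besides the per-code table, named
#' aggregates are reported on two explicit bases, because headline shares can
#' be read either against the whole study area or against the newly suitable
#' area only:
#'
#' * `remain_suitable` (code 33), `newly_suitable` (13, 23),
#'   `newly_suitable_from_unsuitable` (13), `remain_unsuitable` (11),
#'   `uncertain_future` (12, 22, 32), `suitable_future` (13, 23, 33),
#'   `suitable_present` (31, 32, 33), `uncertain_present` (21, 22, 23) —
#'   each with its member codes, cell count and fraction of the study area;
#' * for the subsets of the newly suitable area, additionally their share of
#'   `newly_suitable` (`share_of_newly_suitable`).
#'
#' @param t A [trajectory_grid()].
#' @return List with `table` (data.frame: code, label, n_cells, fraction),
#'   `aggregates` (named list), and `n_cells` (non-nodata cell count).
#' @export
area_report <- function(t) {
  stopifnot(inherits(t, "trajectory_grid"))
  v <- t$values[!is.na(t$values)]
  if (!length(v)) stop("trajectory grid is all nodata", call. = FALSE)
  codes <- trajectory_codes()
  n <- vapply(codes, function(k) sum(v == k), numeric(1))
  tab <- data.frame(
    code = codes,
    label = unname(trajectory_labels()),
    n_cells = n,
    fraction = n / length(v),
    stringsAsFactors = FALSE
  )
  agg_def <- list(
    remain_suitable = 33,
    newly_suitable = c(13, 23),
    newly_suitable_from_unsuitable = 13,
    newly_suitable_from_uncertain = 23,
    remain_unsuitable = 11,
    uncertain_future = c(12, 22, 32),
    suitable_future = c(13, 23, 33),
    suitable_present = c(31, 32, 33),
    uncertain_present = c(21, 22, 23),
    unsuitable_future = c(11, 21, 31)
  )
  frac_of <- function(members) sum(tab$fraction[tab$code %in% members])
  newly <- frac_of(agg_def$newly_suitable)
  aggregates <- lapply(names(agg_def), function(nm) {
    members <- agg_def[[nm]]
    out <- list(
      codes = members,
      n_cells = sum(tab$n_cells[tab$code %in% members]),
      fraction_of_study_area = frac_of(members)
    )
    if (nm %in% c("newly_suitable_from_unsuitable",
                  "newly_suitable_from_uncertain")) {
      out$share_of_newly_suitable <-
        if (newly > 0) out$fraction_of_study_area / newly else NA_real_
    }
    out
  })
  names(aggregates) <- names(agg_def)
  list(table = tab, aggregates = aggregates, n_cells = length(v))
}

#' Traffic-light palette for the three consensus categories
#'
#' Green is the most favourable situation from the human viewpoint
#' (consensually unsuitable for the vector), yellow is high uncertainty and
#' red is consensual suitability.
#'
#' @return Named character vector of hex colours for codes 1, 2, 3.
#' @export
category_palette <- function() {
  c("1" = "#1A9850", "2" = "#FFD700", "3" = "#D73027")
}

#' Traffic-light-derived palette for the nine trajectory classes
#'
#' Diagonal codes (11, 22, 33) keep the pure category colours; off-diagonal
#' codes blend the present and future category colours in CIE Lab space with
#' the future endpoint weighted 2:1, since the future state dominates the
#' prospective risk reading. All nine colours are distinct.
#'
#' @param future_weight Weight of the future endpoint in the blend.
#' @return Named character vector of hex colours for the nine codes.
#' @export
trajectory_palette <- function(future_weight = 2 / 3) {
  base <- category_palette()
  lab <- grDevices::convertColor(t(grDevices::col2rgb(base)) / 255,
                                 from = "sRGB", to = "Lab")
  codes <- trajectory_codes()
  cols <- vapply(codes, function(k) {
    p <- k %/% 10; q <- k %% 10
    if (p == q) return(unname(base[p])) # pure category colour, no round trip
    mix <- (1 - future_weight) * lab[p, ] + future_weight * lab[q, ]
    rgbv <- grDevices::convertColor(matrix(mix, 1), from = "Lab", to = "sRGB")
    rgbv <- pmin(pmax(rgbv, 0), 1)
    grDevices::rgb(rgbv[1], rgbv[2], rgbv[3])
  }, character(1))
  stats::setNames(cols, codes)
}
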