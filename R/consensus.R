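#' Consensus classification rule
#'
#' A cell is classified with low uncertainty when at least `min_agree` of the
#' `n_models` binarized predictions agree on the same class; otherwise the
#' cell is high-uncertainty. The default `min_agree = floor(n/2) + 2`
#' ("majority plus one") gives the rules used for ensembles of seven
#' (at least 5 of 7) and five (at least 4 of 5) models.
#'
#' @param n_models Ensemble size.
#' @param min_agree Minimum number of agreeing models for a low-uncertainty
#'   class; must satisfy `n_models / 2 < min_agree <= n_models`.
#' @return A `consensus_rule`.
#' @export
consensus_rule <- function(n_models, min_agree = floor(n_models / 2) + 2) {
  stopifnot(n_models >= 2)
  if (!(min_agree > n_models / 2 && min_agree <= n_models)) {
    stop("min_agree must exceed half the ensemble and not exceed it",
         call. = FALSE)
  }
  structure(list(n_models = as.integer(n_models),
                 min_agree = as.integer(min_agree)),
            class = "consensus_rule")
}

#' Sum aligned binary maps into an agreement map
#'
#' Per-cell count of models predicting suitable. All maps must share an
#' identical grid (misalignment is an error, never silently resampled). By
#' default a cell is nodata as soon as any contributor is nodata, restricting
#' the analysis to the extent common to every model; `lenient = TRUE` instead
#' sums over the available models and records the per-cell contributor count
#' in the `n_available` field (callers must then scale the rule accordingly).
#'
#' @param maps List of two or more [binary_grid()]s on one grid.
#' @param lenient Nodata handling; see Details.
#' @return An [agreement_grid()] with `n_models = length(maps)`.
#' @export
sum_models <- function(maps, lenient = FALSE) {
  stopifnot(length(maps) >= 2)
  lapply(maps, function(m) stopifnot(inherits(m, "binary_grid")))
  spec <- maps[[1]]$spec
  for (m in maps[-1]) stop_if_misaligned(spec, m$spec, "binary maps")
  arr <- vapply(maps, function(m) m$values, maps[[1]]$values)
  dim(arr) <- c(spec$n_rows * spec$n_cols, length(maps))
  if (lenient) {
    s <- rowSums(arr, na.rm = TRUE)
    avail <- rowSums(!is.na(arr))
    s[avail == 0] <- NA
    g <- agreement_grid(matrix(s, spec$n_rows, spec$n_cols), spec,
                        n_models = length(maps))
    g$n_available <- matrix(avail, spec$n_rows, spec$n_cols)
    g
  } else {
    s <- rowSums(arr)
    agreement_grid(matrix(s, spec$n_rows, spec$n_cols), spec,
                   n_models = length(maps))
  }
}

#' Classify agreement into the three consensus categories
#'
#' Codes: 3 (suitable, low uncertainty) where at least `min_agree` models
#' predict suitable; 1 (unsuitable, low uncertainty) where at least
#' `min_agree` predict unsuitable; 2 (high uncertainty) otherwise, i.e. where
#' only about half of the models agree on either class.
#'
#' @param a An [agreement_grid()].
#' @param rule A [consensus_rule()] with matching `n_models`.
#' @return A [category_grid()].
#' @export
categorize <- function(a, rule) {
  stopifnot(inherits(a, "agreement_grid"), inherits(rule, "consensus_rule"))
  if (a$n_models != rule$n_models) {
    stop(sprintf("rule is for %d models but agreement map sums %d",
                 rule$n_models, a$n_models), call. = FALSE)
  }
  s <- a$values
  out <- matrix(NA_real_, nrow(s), ncol(s))
  out[s >= rule$min_agree] <- 3
  out[(rule$n_models - s) >= rule$min_agree] <- 1
  out[!is.na(s) & is.na(out)] <- 2
  category_grid(out, a$spec)
}

#' Category fractions of a category map
#'
#' @param g A [category_grid()].
#' @return Named numeric vector: fraction of non-nodata cells in categories
#'   1, 2 and 3 (sums to 1).
#' @export
category_fractions <- function(g) {
  stopifnot(inherits(g, "category_grid"))
  v <- g$values[!is.na(g$values)]
  if (!length(v)) stop("category grid is all nodata", call. = FALSE)
  out <- vapply(1:3, function(k) mean(v == k), numeric(1))
  names(out) <- c("1", "2", "3")
  out
}
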