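test_that("extract_values reads the cell under each occurrence", {
  g <- make_suit(matrix(c(0.8, 0.2, 0.4, 0.6), 2, 2, byrow = TRUE))
  # centre of the top-left cell (row 1, col 1)
  occ <- occurrence_set(c(0.5), c(1.5))
  ex <- extract_values(g, occ)
  expect_equal(ex$values, 0.8)
  expect_equal(ex$n_used, 1)
})

test_that("occurrences outside the extent or on nodata are dropped and counted", {
  vals <- matrix(c(0.8, NA, 0.4, 0.6), 2, 2, byrow = TRUE)
  g <- make_suit(vals)
  occ <- occurrence_set(
    x = c(0.5, 1.5, 5.0, 0.5),
    y = c(1.5, 1.5, 1.5, 0.5)
  )
  ex <- extract_values(g, occ)
  expect_equal(ex$n_used, 2)
  expect_equal(ex$n_outside, 1)
  expect_equal(ex$n_nodata, 1)
  expect_equal(sort(ex$values), c(0.4, 0.8))
  # nothing overlapping is an explicit error
  far <- occurrence_set(100, 100)
  expect_error(extract_values(g, far), "no occurrence overlaps")
  # unit scale required
  pct <- make_suit(vals * 100, scale = "percent")
  expect_error(extract_values(pct, occ), "unit scale")
})

test_that("extracted values match a brute-force cell-index oracle", {
  set.seed(7)
  g <- make_suit(matrix(runif(30), 5, 6), xll = -3, yll = 2, cs = 0.7)
  px <- runif(100, -3, -3 + 6 * 0.7)
  py <- runif(100, 2, 2 + 5 * 0.7)
  ex <- extract_values(g, occurrence_set(px, py))
  expected <- vapply(seq_along(px), function(k) {
    ij <- oracle_cell_lookup(g$spec, px[k], py[k])
    g$values[ij[1], ij[2]]
  }, numeric(1))
  expect_equal(ex$values, expected)
})

test_that("per-cell deduplication thins repeated occurrences", {
  g <- make_suit(matrix(c(0.8, 0.2, 0.4, 0.6), 2, 2, byrow = TRUE))
  occ <- occurrence_set(c(0.4, 0.6, 1.5), c(1.5, 1.4, 0.5))
  expect_equal(extract_values(g, occ)$n_used, 3)
  expect_equal(extract_values(g, occ, dedupe_cells = TRUE)$n_used, 2)
})

test_that("presence threshold obeys the fixed-omission definition", {
  # degenerate distribution: the single value is the threshold
  expect_equal(presence_threshold(rep(0.6, 20), 0.05), 0.6)
  expect_equal(presence_threshold(rep(0.6, 20), 0.10), 0.6)
  # ten equally spaced values, fraction 0.10: at most one value strictly below
  v <- seq(0.1, 1.0, by = 0.1)
  t10 <- presence_threshold(v, 0.10)
  expect_equal(t10, oracle_threshold(v, 0.10))
  expect_lte(sum(v < t10), 1)
  expect_error(presence_threshold(c(0.2, NA), 0.05), "non-finite")
  expect_error(presence_threshold(numeric(0), 0.05), "no occurrence")
  # interpolated rule matches the conventional sample quantile
  expect_equal(presence_threshold(v, 0.10, rule = "linear_interpolation"),
               unname(quantile(v, 0.10, type = 7)))
})

test_that("omission bound holds over many random value lists", {
  set.seed(11)
  for (rep in 1:50) {
    n <- sample(5:400, 1)
    v <- round(runif(n), sample(c(1, 2, 3, 6), 1)) # ties common at low digits
    for (p in c(0.05, 0.10)) {
      t <- presence_threshold(v, p)
      expect_lte(sum(v < t) / n, p)
      expect_equal(t, oracle_threshold(v, p))
    }
    # thresholds are ordered across fractions
    expect_lte(presence_threshold(v, 0.05), presence_threshold(v, 0.10))
  }
  # 1000 simulated values, fraction 0.05: at most 50 strictly below
  v <- runif(1000)
  expect_lte(sum(v < presence_threshold(v, 0.05)), 50)
})

test_that("binarize applies 'suitable iff value >= threshold' and keeps nodata", {
  vals <- matrix(c(0.1, 0.5, NA, 0.9), 2, 2)
  g <- make_suit(vals)
  b0 <- binarize(g, 0)
  expect_true(all(b0$values[!is.na(vals)] == 1))
  expect_true(is.na(b0$values[is.na(vals)]))
  b_hi <- binarize(g, 1)
  expect_equal(sum(b_hi$values, na.rm = TRUE), 0)
  # the boundary cell is suitable
  expect_equal(binarize(g, 0.5)$values[2, 1], 1)
  # raising the threshold never gains suitable cells
  set.seed(3)
  gg <- make_suit(matrix(runif(100), 10, 10))
  n_suit <- vapply(seq(0, 1, by = 0.05), function(t) {
    sum(binarize(gg, t)$values)
  }, numeric(1))
  expect_true(all(diff(n_suit) <= 0))
})

test_that("binarization is invariant to the value scale of the input", {
  set.seed(5)
  vals <- matrix(runif(64), 8, 8)
  g_unit <- make_suit(vals)
  g_pct <- make_suit(vals * 100, scale = "percent")
  occ <- occurrence_set(runif(40, 0, 8), runif(40, 0, 8))
  t_unit <- calibrate_threshold(g_unit, occ, "m")
  t_pct <- calibrate_threshold(normalize_scale(g_pct), occ, "m")
  expect_equal(t_pct$threshold, t_unit$threshold)
  expect_equal(binarize(normalize_scale(g_pct), t_pct)$values,
               binarize(g_unit, t_unit)$values)
})

test_that("threshold transfer reuses the present-day threshold per model", {
  set.seed(9)
  vals <- matrix(runif(100), 10, 10)
  present <- make_suit(vals)
  occ <- occurrence_set(runif(50, 0, 10), runif(50, 0, 10))
  t <- calibrate_threshold(present, occ, "model_a", fraction = 0.05)
  # identical future grid gives the identical binary map
  expect_equal(transfer_threshold(t, present, "model_a")$values,
               binarize(present, t)$values)
  # uniformly warmer future never loses suitable cells
  future <- make_suit(pmin(vals + 0.2, 1))
  expect_gte(sum(transfer_threshold(t, future, "model_a")$values),
             sum(binarize(present, t)$values))
  # transfer across models is refused
  expect_error(transfer_threshold(t, future, "model_b"), "refused")
})

test_that("suitable sets nest across omission fractions", {
  set.seed(13)
  vals <- matrix(runif(144), 12, 12)
  g <- make_suit(vals)
  occ <- occurrence_set(runif(80, 0, 12), runif(80, 0, 12))
  b05 <- binarize(g, calibrate_threshold(g, occ, "m", 0.05))
  b10 <- binarize(g, calibrate_threshold(g, occ, "m", 0.10))
  # every cell suitable at 10% omission is suitable at 5% omission
  expect_true(all(b05$values[b10$values == 1] == 1))
})

test_that("threshold tables carry provenance per model", {
  t1 <- model_threshold("a", 0.2, 0.05, 100, 3)
  t2 <- model_threshold("b", 0.4, 0.05, 90, 13)
  tab <- threshold_table(list(t1, t2))
  expect_equal(tab$model_id, c("a", "b"))
  expect_equal(tab$threshold, c(0.2, 0.4))
  expect_equal(tab$n_dropped, c(3, 13))
  expect_error(model_threshold("a", 1.2, 0.05, 10), "threshold")
})
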