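# Decision-matrix construction, cell resolution, weight resolution and
# validation.

make_small <- function(cells, directions = "maximize", weights = 1) {
  decision_matrix(cells,
                  criteria_table(id = paste0("C", seq_len(ncol(cells))),
                                 direction = directions, weight = weights))
}

test_that("numeric matrices resolve to themselves and resolution is idempotent", {
  cells <- matrix(c(1, 2, 3, 4), 2, 2)
  m <- make_small(cells)
  r <- resolve_cells(m)
  expect_equal(unname(r), cells)
  expect_identical(resolve_cells(r), r)
})

test_that("linguistic cells defuzzify through the scale", {
  cells <- matrix(c("H", "1.5", "VL", "2.5"), 2, 2)
  m <- make_small(cells)
  r <- resolve_cells(m)
  expect_equal(unname(r), matrix(c(0.75, 1.5, 0.25 / 3, 2.5), 2, 2))
  bad <- make_small(matrix(c("H", "huge", "M", "L"), 2, 2))
  expect_error(resolve_cells(bad), class = "missing_scale_entry")
})

test_that("incomplete grids are rejected at construction", {
  expect_error(make_small(matrix(c("H", NA, "M", "L"), 2, 2)),
               class = "missing_cell")
  expect_error(make_small(matrix(c("H", "", "M", "L"), 2, 2)),
               class = "missing_cell")
  expect_no_error(make_small(matrix(1:6, 2, 3))) # complete 2x3 grid is fine
})

test_that("weights resolve, normalise to 1 and preserve ratios", {
  crit <- criteria_table(id = paste0("C", 1:4), weight = "H")
  expect_equal(unname(resolve_weights(crit)), rep(0.25, 4))

  # the study's 10 VH + 7 H + 3 M distribution
  crit2 <- criteria_table(id = paste0("C", 1:20),
                          weight = rep(c("VH", "H", "M"), c(10, 7, 3)))
  w <- resolve_weights(crit2)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  denom <- 10 * 11 / 12 + 7 * 0.75 + 3 * 0.5 # 15.91666...
  expect_equal(unname(w[1]), (11 / 12) / denom, tolerance = 1e-12)   # 0.0575916
  expect_equal(unname(w[11]), 0.75 / denom, tolerance = 1e-12)       # 0.0471204
  expect_equal(unname(w[18]), 0.5 / denom, tolerance = 1e-12)        # 0.0314136

  crit3 <- criteria_table(id = c("a", "b", "c"), weight = c(2, 1, 1))
  expect_equal(unname(resolve_weights(crit3)), c(0.5, 0.25, 0.25))
  crit3$weight <- crit3$weight * 17.3 # uniform rescaling is a no-op
  expect_equal(unname(resolve_weights(crit3)), c(0.5, 0.25, 0.25),
               tolerance = 1e-12)
})

test_that("non-positive numeric weights are rejected", {
  crit <- criteria_table(id = c("a", "b"), weight = c(1, -1))
  expect_error(resolve_weights(crit), class = "invalid_weight")
  crit$weight <- c("H", "0")
  expect_error(resolve_weights(crit), class = "invalid_weight")
})

test_that("validation reports too-few alternatives and zero-spread columns", {
  ok <- generate_matrix(generator_config(n_alternatives = 5, seed = 3))
  expect_equal(nrow(validate_matrix(ok)), 0)

  one <- decision_matrix(matrix(1:3, 1, 3),
                         criteria_table(id = c("a", "b", "c")))
  v <- validate_matrix(one)
  expect_true("too_few_alternatives" %in% v$code)

  flat <- make_small(cbind(c(1, 1, 1), c(1, 2, 3)))
  v2 <- validate_matrix(flat)
  expect_true("zero_spread" %in% v2$code)
  expect_equal(v2$severity[v2$code == "zero_spread"], "warning")
})

test_that("criteria metadata is validated", {
  expect_error(criteria_table(id = c("a", "a")), class = "duplicate_id")
  expect_error(criteria_table(id = "a", direction = "up"),
               class = "invalid_direction")
  cells <- matrix(1:4, 2, 2)
  expect_error(decision_matrix(cells, criteria_table(id = "onlyone")),
               class = "shape_error")
})
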