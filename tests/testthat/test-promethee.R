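# The outranking engine: preference indices, flows, preorder, ranking and
# the unicriterion decomposition.

two_alt_model <- function() {
  cells <- rbind(a = c(1, 0), b = c(0, 1))
  decision_matrix(cells,
                  criteria_table(id = c("C1", "C2"), weight = c(0.7, 0.3),
                                 pref = pref_spec("usual")))
}

test_that("the hand-computed two-alternative case reproduces through the whole chain", {
  res <- promethee(two_alt_model())
  expect_equal(res$pi["a", "b"], 0.7)
  expect_equal(res$pi["b", "a"], 0.3)
  expect_equal(res$flows$phi_plus, c(0.7, 0.3))
  expect_equal(res$flows$phi_minus, c(0.3, 0.7))
  expect_equal(res$flows$phi_net, c(0.4, -0.4))
  expect_equal(res$flows$rank, c(1L, 2L))
})

test_that("identical rows give zero preference everywhere and a full tie", {
  cells <- matrix(5, 3, 2)
  m <- decision_matrix(cells, criteria_table(id = c("C1", "C2"),
                                             pref = pref_spec("usual")))
  res <- promethee(m)
  expect_true(all(res$pi == 0))
  expect_equal(res$flows$phi_net, rep(0, 3))
  expect_equal(res$flows$rank, rep(1L, 3))
  expect_true(all(res$flows$tied))
  expect_true(all(res$partial_order[upper.tri(res$partial_order)] == "indifferent"))
})

test_that("the negative flow is the positive flow of the transposed index matrix", {
  for (seed in 1:10) {
    m <- random_test_matrix(seed)
    res <- promethee(m)
    expect_equal(negative_flow(res$pi), positive_flow(t(res$pi)))
  }
})

test_that("flows require at least two alternatives and matching shapes", {
  expect_error(positive_flow(matrix(0, 1, 1)), class = "insufficient_alternatives")
  expect_error(net_flow(1:3, 1:2), class = "shape_error")
  expect_error(aggregated_preference(matrix(1:4, 2, 2), c(1), list(pref_spec("usual")),
                                     "maximize"),
               class = "shape_error")
})

test_that("vectorized engine agrees with the literal triple-loop oracle", {
  for (seed in 1:25) {
    m <- random_test_matrix(seed)
    res <- promethee(m)
    o <- oracle_flows(res$resolved, res$weights, m$criteria$direction,
                      unname(res$spreads))
    expect_equal(unname(res$pi), o$pi, tolerance = 1e-12)
    expect_equal(res$flows$phi_plus, o$plus, tolerance = 1e-12)
    expect_equal(res$flows$phi_minus, o$minus, tolerance = 1e-12)
    expect_equal(res$flows$phi_net, o$net, tolerance = 1e-12)
  }
})

test_that("net flows always sum to zero", {
  for (seed in 1:25) {
    res <- promethee(random_test_matrix(seed))
    expect_lt(abs(sum(res$flows$phi_net)), 1e-9)
    expect_true(all(res$flows$phi_plus >= 0 & res$flows$phi_plus <= 1))
    expect_true(all(res$flows$phi_minus >= 0 & res$flows$phi_minus <= 1))
  }
})

test_that("a columnwise-dominant alternative outranks and wins the net ranking", {
  cells <- rbind(a = c(3, 10, 1), b = c(2, 10, 2), c = c(1, 12, 3))
  m <- decision_matrix(cells,
                       criteria_table(id = c("C1", "C2", "C3"),
                                      direction = c("maximize", "maximize", "minimize"),
                                      weight = c(1, 2, 1),
                                      pref = pref_spec("gaussian")))
  res <- promethee(m)
  # a is at least as good as b everywhere and strictly better on C1 and C3
  expect_gt(res$flows$phi_net[1], res$flows$phi_net[2])
  expect_equal(res$partial_order["a", "b"], "preferred")
  expect_equal(res$partial_order["b", "a"], "outranked")
})

test_that("the preorder detects incomparability when the two flows disagree", {
  # brute-force search over small random problems until the pattern
  # phi+(a) > phi+(b) and phi-(a) > phi-(b) fires
  found <- FALSE
  for (seed in 1:200) {
    res <- promethee(random_test_matrix(seed, n_max = 5, k_max = 4))
    p <- res$flows$phi_plus
    q <- res$flows$phi_minus
    n <- length(p)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i != j && p[i] - p[j] > 1e-6 && q[i] - q[j] > 1e-6) {
        expect_equal(unname(res$partial_order[i, j]), "incomparable")
        expect_equal(unname(res$partial_order[j, i]), "incomparable")
        found <- TRUE
      }
    }
    if (found) break
  }
  expect_true(found)
})

test_that("complete ranking is descending, stable and flags ties", {
  r <- complete_ranking(c(a = 0.4, b = -0.4))
  expect_equal(r$rank, c(1L, 2L))
  r2 <- complete_ranking(c(x = 0.1, y = 0.3, z = 0.1))
  expect_equal(r2$alternative, c("y", "x", "z"))
  expect_equal(r2$rank, c(1L, 2L, 2L))
  expect_equal(r2$tied, c(FALSE, TRUE, TRUE))
})

test_that("unicriterion flows decompose the net flow", {
  # K = 1: the single unicriterion flow is the net flow itself
  cells <- matrix(c(1, 4, 2, 8), 4, 1)
  m1 <- decision_matrix(cells, criteria_table(id = "C1", pref = pref_spec("gaussian")))
  r1 <- promethee(m1)
  expect_equal(unname(r1$unicriterion[, 1]), r1$flows$phi_net, tolerance = 1e-12)

  for (seed in 101:110) {
    m <- random_test_matrix(seed, n_max = 5, k_max = 3)
    res <- promethee(m)
    recomposed <- as.numeric(res$unicriterion %*% res$weights)
    expect_equal(recomposed, res$flows$phi_net, tolerance = 1e-9)
  }

  flat <- decision_matrix(matrix(2, 3, 2),
                          criteria_table(id = c("C1", "C2"), pref = pref_spec("usual")))
  expect_true(all(promethee(flat)$unicriterion == 0))
})

test_that("flows are invariant to translation, positive rescaling and weight rescaling", {
  for (seed in c(11, 12, 13)) {
    m <- random_test_matrix(seed)
    base <- promethee(m)$flows

    shifted <- m
    shifted$cells[, 1] <- shifted$cells[, 1] + 57.3
    expect_equal(promethee(shifted)$flows$phi_net, base$phi_net, tolerance = 1e-9)

    scaled <- m
    scaled$cells[, 2] <- scaled$cells[, 2] * 1000 # auto spread rescales too
    expect_equal(promethee(scaled)$flows$phi_net, base$phi_net, tolerance = 1e-9)

    reweighted <- m
    reweighted$criteria$weight <- reweighted$criteria$weight * 42
    expect_equal(promethee(reweighted)$flows$phi_net, base$phi_net, tolerance = 1e-9)
  }
})

test_that("permuting alternative rows permutes the flows identically", {
  m <- random_test_matrix(21)
  n <- nrow(m$cells)
  perm <- withr::with_seed(4, sample.int(n))
  mp <- decision_matrix(m$cells[perm, , drop = FALSE], m$criteria,
                        m$alternatives[perm, , drop = FALSE], m$scale)
  base <- promethee(m)$flows
  permed <- promethee(mp)$flows
  expect_equal(permed$phi_net, base$phi_net[perm], tolerance = 1e-12)
  expect_equal(permed$rank, base$rank[perm])
})

test_that("dominance is preserved: the strictly-better row gets the higher net flow", {
  for (seed in 31:40) {
    m <- random_test_matrix(seed)
    planted <- plant_dominant_alternative(m, m$alternatives$id[2])
    res <- promethee(planted)
    expect_equal(res$flows$rank[2], 1L)
    expect_true(all(res$flows$phi_net[2] > res$flows$phi_net[-2]))
  }
})
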