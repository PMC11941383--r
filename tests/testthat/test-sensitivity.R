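# Weight-change sensitivity: reruns, ranking comparison and Monte Carlo
# stability.

test_that("an empty change list reproduces the baseline flow table bit-for-bit", {
  m <- sequencing_study_matrix()
  base <- promethee(m)
  rerun <- promethee(apply_weight_changes(m, list()))
  expect_identical(rerun$flows, base$flows)
  expect_identical(rerun$pi, base$pi)
})

test_that("weight changes touch only the listed criteria and not the input model", {
  m <- sequencing_study_matrix()
  m2 <- apply_weight_changes(m, list(C8 = "H"))
  expect_equal(as.character(m2$criteria$weight[m2$criteria$id == "C8"]), "H")
  same <- m$criteria$id != "C8"
  expect_equal(m2$criteria$weight[same], m$criteria$weight[same])
  expect_equal(as.character(m$criteria$weight[m$criteria$id == "C8"]), "VH")
  expect_error(apply_weight_changes(m, list(C99 = "H")), class = "unknown_criterion")
})

test_that("comparing a ranking with itself gives zero displacement and concordance 1", {
  res <- promethee(sequencing_study_matrix())
  rep <- compare_rankings(res, res)
  expect_true(all(rep$displacement$displacement == 0))
  expect_equal(rep$concordance, 1)
  expect_equal(nrow(rep$reversals), 0)
})

test_that("a full reversal of four alternatives has concordance -1", {
  cells <- matrix(c(4, 3, 2, 1), 4, 1)
  m <- decision_matrix(cells, criteria_table(id = "C1", pref = pref_spec("usual")))
  up <- promethee(m)
  mdown <- decision_matrix(cells, criteria_table(id = "C1", direction = "minimize",
                                                 pref = pref_spec("usual")))
  down <- promethee(mdown)
  rep <- compare_rankings(up, down)
  expect_equal(rep$concordance, -1)
  expect_equal(nrow(rep$reversals), choose(4, 2))
  expect_error(compare_rankings(up, promethee(sequencing_study_matrix())),
               class = "shape_error")
})

test_that("a planted winner keeps rank 1 under the six-criterion weight change", {
  m <- plant_dominant_alternative(sequencing_study_matrix(), "T5")
  base <- promethee(m)
  after <- promethee(apply_weight_changes(m, sequencing_sensitivity_changes()))
  rep <- compare_rankings(base, after)
  winner <- rep$displacement[rep$displacement$alternative == "T5", ]
  expect_equal(winner$rank_before, 1L)
  expect_equal(winner$displacement, 0L)
})

test_that("Monte Carlo stability is seeded-deterministic and degenerate at zero noise", {
  m <- generate_matrix(generator_config(n_alternatives = 6,
                                        weight_distribution = c(VH = 3, H = 3),
                                        seed = 9))
  base <- promethee(m)
  t0 <- monte_carlo_weight_stability(m, relative_noise = 0, n_draws = 20, seed = 5)
  for (i in seq_len(nrow(m$cells)))
    expect_equal(unname(t0[i, base$flows$rank[i]]), 1)

  t1 <- monte_carlo_weight_stability(m, 0.2, 100, seed = 11)
  t2 <- monte_carlo_weight_stability(m, 0.2, 100, seed = 11)
  expect_identical(t1, t2)
  expect_equal(unname(rowSums(t1)), rep(1, nrow(t1)))

  planted <- plant_dominant_alternative(m, "A3")
  tp <- monte_carlo_weight_stability(planted, 0.2, 100, seed = 13)
  expect_equal(unname(tp["A3", "rank1"]), 1) # dominance holds for all positive weights

  expect_error(monte_carlo_weight_stability(m, -0.1, 10, seed = 1),
               class = "invalid_argument")
  expect_error(monte_carlo_weight_stability(m, 0.1, 0, seed = 1),
               class = "invalid_argument")
})
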