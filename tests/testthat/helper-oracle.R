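# Independent brute-force PROMETHEE oracle: literal triple loops over the
# aggregated-preference, flow and net-flow definitions, no vectorisation, no
# calls into the engine's pairwise machinery.

oracle_gaussian <- function(d, s) {
  if (d <= 0) return(0)
  if (s <= 0) return(0)
  1 - exp(-d^2 / (2 * s^2))
}

oracle_flows <- function(resolved, weights, directions, spreads) {
  n <- nrow(resolved)
  K <- ncol(resolved)
  pi_mat <- matrix(0, n, n)
  for (t in seq_len(n)) {
    for (tp in seq_len(n)) {
      if (t == tp) next
      acc <- 0
      for (k in seq_len(K)) {
        d <- resolved[t, k] - resolved[tp, k]
        if (directions[k] == "minimize") d <- -d
        acc <- acc + weights[k] * oracle_gaussian(d, spreads[k])
      }
      pi_mat[t, tp] <- acc
    }
  }
  plus <- numeric(n)
  minus <- numeric(n)
  for (t in seq_len(n)) {
    for (tp in seq_len(n)) {
      if (t == tp) next
      plus[t] <- plus[t] + pi_mat[t, tp] / (n - 1)
      minus[t] <- minus[t] + pi_mat[tp, t] / (n - 1)
    }
  }
  list(pi = pi_mat, plus = plus, minus = minus, net = plus - minus)
}

# random all-numeric matrix with mixed directions, gaussian auto spread
random_test_matrix <- function(seed, n_max = 8, k_max = 6) {
  withr::with_seed(seed, {
    n <- sample(3:n_max, 1)
    K <- sample(2:k_max, 1)
    cells <- matrix(rnorm(n * K, mean = 10, sd = 4), n, K)
    directions <- sample(c("maximize", "minimize"), K, replace = TRUE)
    weights <- runif(K, 0.2, 2)
    criteria <- criteria_table(id = paste0("C", seq_len(K)),
                               direction = directions, weight = weights,
                               pref = pref_spec("gaussian"))
    decision_matrix(cells, criteria)
  })
}
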