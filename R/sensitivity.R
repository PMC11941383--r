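# Weight-change sensitivity analysis: single reruns, ranking comparison and
# Monte Carlo weight perturbation.

as_change_frame <- function(changes) {
  if (is.null(changes) || (is.data.frame(changes) && nrow(changes) == 0L) ||
      length(changes) == 0L)
    return(data.frame(criterion_id = character(), new_weight = character(),
                      stringsAsFactors = FALSE))
  if (is.data.frame(changes)) {
    if (!all(c("criterion_id", "new_weight") %in% names(changes)))
      condition_stop("changes need columns criterion_id and new_weight", "shape_error")
    return(changes)
  }
  # named list/vector: id -> new weight
  if (is.null(names(changes)))
    condition_stop("changes must be a data.frame or a named list", "shape_error")
  out <- data.frame(criterion_id = names(changes), stringsAsFactors = FALSE)
  out$new_weight <- unname(as.list(changes))
  out
}

#' Apply criterion weight changes
#'
#' Returns a copy of the model with the listed criterion weights replaced;
#' the input model is untouched and weight renormalisation happens downstream
#' in [resolve_weights()].
#'
#' @param m A [decision_matrix()].
#' @param changes A data.frame with columns `criterion_id`, `new_weight`
#'   (linguistic term or positive number), or a named list/vector
#'   `list(C8 = "H", ...)`. An empty list is a no-op.
#' @return A new `decision_matrix`.
#' @export
apply_weight_changes <- function(m, changes) {
  if (!inherits(m, "decision_matrix"))
    condition_stop("apply_weight_changes() expects a decision_matrix", "shape_error")
  ch <- as_change_frame(changes)
  if (nrow(ch) == 0L) return(m)
  idx <- match(ch$criterion_id, m$criteria$id)
  if (anyNA(idx))
    condition_stop(sprintf("unknown criterion id '%s'",
                           ch$criterion_id[which(is.na(idx))[1L]]),
                   "unknown_criterion")
  weight <- m$criteria$weight
  if (is.numeric(weight) && !all(vapply(ch$new_weight, is.numeric, logical(1L))))
    weight <- as.character(weight)
  for (i in seq_len(nrow(ch)))
    weight[idx[i]] <- if (is.list(ch$new_weight)) ch$new_weight[[i]] else ch$new_weight[i]
  m$criteria$weight <- weight
  m
}

#' Compare two rankings
#'
#' Quantifies how a ranking moved between a baseline and a modified analysis:
#' per-alternative rank displacement, the pairs whose order reversed, and the
#' Kendall tau-b concordance of the two net-flow orderings (tau-b handles
#' ties; 1 means identical order, -1 a full reversal).
#'
#' @param before,after [promethee()] results over the same alternatives.
#' @return An object of class `"sensitivity_report"`: list with
#'   `displacement` (data.frame alternative, rank_before, rank_after,
#'   displacement), `concordance` (scalar in \[-1, 1\]), `reversals`
#'   (data.frame of reversed pairs).
#' @export
compare_rankings <- function(before, after) {
  fb <- if (inherits(before, "promethee_result")) before$flows else before
  fa <- if (inherits(after, "promethee_result")) after$flows else after
  if (!setequal(fb$alternative, fa$alternative) ||
      nrow(fb) != nrow(fa))
    condition_stop("the two rankings cover different alternative sets", "shape_error")
  fa <- fa[match(fb$alternative, fa$alternative), ]
  disp <- data.frame(alternative = fb$alternative,
                     rank_before = fb$rank, rank_after = fa$rank,
                     displacement = fa$rank - fb$rank,
                     stringsAsFactors = FALSE)
  tau <- stats::cor(fb$phi_net, fa$phi_net, method = "kendall")
  n <- nrow(fb)
  pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  flipped <- (fb$rank[pairs[, 1L]] - fb$rank[pairs[, 2L]]) *
             (fa$rank[pairs[, 1L]] - fa$rank[pairs[, 2L]]) < 0
  reversals <- data.frame(
    alternative_a = fb$alternative[pairs[flipped, 1L]],
    alternative_b = fb$alternative[pairs[flipped, 2L]],
    stringsAsFactors = FALSE)
  structure(list(displacement = disp, concordance = tau, reversals = reversals,
                 before = fb, after = fa),
            class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("<sensitivity_report: concordance (Kendall tau-b) = %.4f, %d reversal pair(s)>\n",
              x$concordance, nrow(x$reversals)))
  moved <- x$displacement[x$displacement$displacement != 0, ]
  if (nrow(moved) == 0L) cat("  no alternative changed rank\n")
  else print(moved, row.names = FALSE)
  invisible(x)
}

#' Monte Carlo weight-stability analysis
#'
#' Generalises a single weight-change experiment: each draw perturbs every
#' normalised weight multiplicatively by (1 + u) with u uniform on
#' \[-relative_noise, +relative_noise\], renormalises, reruns the ranking and
#' tallies which rank each alternative attains. The seed fully determines the
#' result.
#'
#' @param m A [decision_matrix()].
#' @param relative_noise Relative perturbation half-width, >= 0.
#' @param n_draws Number of Monte Carlo draws, >= 1.
#' @param seed Integer RNG seed.
#' @return An n x n matrix of rank frequencies (rows alternatives, columns
#'   ranks, entries proportions of draws), with attribute `"n_draws"`.
#' @export
monte_carlo_weight_stability <- function(m, relative_noise = 0.2, n_draws = 500L,
                                         seed = 1L) {
  if (!is.numeric(relative_noise) || relative_noise < 0)
    condition_stop("relative_noise must be >= 0", "invalid_argument")
  if (!is.numeric(n_draws) || n_draws < 1)
    condition_stop("n_draws must be >= 1", "invalid_argument")
  base_w <- resolve_weights(m)
  n <- nrow(m$cells)
  counts <- matrix(0L, n, n,
                   dimnames = list(m$alternatives$id, paste0("rank", seq_len(n))))
  withr::with_seed(seed, {
    for (i in seq_len(n_draws)) {
      u <- stats::runif(length(base_w), -relative_noise, relative_noise)
      w <- base_w * (1 + u)
      w <- w / sum(w)
      res <- promethee(m, weights = w)
      idx <- cbind(seq_len(n), res$flows$rank)
      counts[idx] <- counts[idx] + 1L
    }
  })
  freq <- counts / n_draws
  attr(freq, "n_draws") <- as.integer(n_draws)
  freq
}
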