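# The outranking core: aggregated preference indices, positive/negative/net
# flows, the partial preorder, the complete net-flow ranking and the
# unicriterion decomposition.

resolve_spreads <- function(resolved, specs) {
  vapply(seq_along(specs), function(k) {
    sp <- specs[[k]]
    if (sp$kind != "gaussian") return(NA_real_)
    if (identical(sp$s, "auto") || is.null(sp$s))
      estimate_gaussian_spread(resolved[, k]) else sp$s
  }, numeric(1L))
}

per_criterion_preference <- function(column, spec, direction, spread = NA_real_) {
  d <- outer(column, column, "-")
  if (direction == "minimize") d <- -d
  p <- preference_value(d, spec, s = if (is.na(spread)) NULL else spread)
  diag(p) <- 0
  p
}

#' Aggregated preference index matrix
#'
#' For every ordered pair of alternatives (a, b), the weighted sum over
#' criteria of the preference degree of a over b:
#' pi(a, b) = sum_k w_k * P_k(d_k(a, b)), where d_k is the signed evaluation
#' difference oriented by the criterion's direction. With weights summing to
#' 1, pi lies in \[0, 1\]; the diagonal is 0.
#'
#' @param resolved n x K numeric matrix of defuzzified evaluations
#'   (see [resolve_cells()]).
#' @param weights K-vector of normalised weights (see [resolve_weights()]).
#' @param specs List of K [pref_spec()] objects.
#' @param directions Character vector of K directions.
#' @param spreads Optional K-vector of resolved Gaussian spreads; computed
#'   from the data where missing.
#' @return n x n matrix of preference indices.
#' @export
aggregated_preference <- function(resolved, weights, specs, directions,
                                  spreads = NULL) {
  n <- nrow(resolved)
  K <- ncol(resolved)
  if (length(weights) != K || length(specs) != K || length(directions) != K)
    condition_stop("weights, specs and directions must have one entry per criterion",
                   "shape_error")
  if (is.null(spreads)) spreads <- resolve_spreads(resolved, specs)
  pi_mat <- matrix(0, n, n, dimnames = list(rownames(resolved), rownames(resolved)))
  for (k in seq_len(K)) {
    pk <- per_criterion_preference(resolved[, k], specs[[k]], directions[k], spreads[k])
    pi_mat <- pi_mat + weights[k] * pk
  }
  pi_mat
}

#' Outranking flows
#'
#' The positive flow of an alternative is the average strength with which it
#' outranks all others, `rowMeans` of the preference index over the n - 1
#' opponents; the negative flow is the average strength with which it is
#' outranked (the column counterpart). The net flow is their difference and
#' sums to 0 over alternatives.
#'
#' @param pi n x n preference index matrix (n >= 2).
#' @return Numeric n-vector.
#' @export
positive_flow <- function(pi) {
  n <- nrow(pi)
  if (is.null(n) || n < 2L)
    condition_stop("flows need at least 2 alternatives", "insufficient_alternatives")
  rowSums(pi) / (n - 1)
}

#' @rdname positive_flow
#' @export
negative_flow <- function(pi) {
  n <- nrow(pi)
  if (is.null(n) || n < 2L)
    condition_stop("flows need at least 2 alternatives", "insufficient_alternatives")
  colSums(pi) / (n - 1)
}

#' @rdname positive_flow
#' @param phi_plus,phi_minus Positive and negative flow vectors of equal
#'   length.
#' @export
net_flow <- function(phi_plus, phi_minus) {
  if (length(phi_plus) != length(phi_minus))
    condition_stop("flow vectors must have equal length", "shape_error")
  phi_plus - phi_minus
}

#' PROMETHEE I partial preorder
#'
#' Pairwise comparison from the two flows: a is preferred to b when it is at
#' least as strong and strictly less weak (or strictly stronger and equally
#' weak); the two are indifferent when both flows agree; they are
#' incomparable when the flows disagree in direction (a stronger but also
#' weaker than b). Flow equality is tested with an absolute tolerance, since
#' exact float equality would make indifference unreachable.
#'
#' @param phi_plus,phi_minus Flow vectors from the same preference matrix.
#' @param tol Absolute tolerance for flow equality.
#' @return An n x n character matrix over
#'   `"preferred"`, `"outranked"`, `"indifferent"`, `"incomparable"`,
#'   `"self"`; `"preferred"` in row a, column b means a outranks b, and the
#'   transposed cell is `"outranked"`.
#' @export
partial_order <- function(phi_plus, phi_minus, tol = 1e-9) {
  n <- length(phi_plus)
  dplus <- outer(phi_plus, phi_plus, "-")
  dminus <- outer(phi_minus, phi_minus, "-")
  eq_p <- abs(dplus) <= tol
  eq_m <- abs(dminus) <= tol
  gt_p <- dplus > tol
  gt_m <- dminus > tol
  lt_p <- dplus < -tol
  lt_m <- dminus < -tol

  pref <- ((gt_p | eq_p) & lt_m) | (gt_p & eq_m)
  indiff <- eq_p & eq_m
  incomp <- (gt_p & gt_m) | (lt_p & lt_m)

  rel <- matrix("incomparable", n, n,
                dimnames = list(names(phi_plus), names(phi_plus)))
  rel[incomp] <- "incomparable"
  rel[t(pref)] <- "outranked"
  rel[pref] <- "preferred"
  rel[indiff] <- "indifferent"
  diag(rel) <- "self"
  rel
}

#' Complete ranking from net flows
#'
#' Alternatives are ranked in descending net-flow order. Net flows equal
#' within the tolerance are tied: they share the better rank, keep the input
#' order among themselves, and are flagged.
#'
#' @param phi_net Named vector of net flows (or a flow table, see
#'   [promethee()]).
#' @param tol Absolute tolerance for treating two net flows as tied.
#' @return A data.frame with columns `rank`, `alternative`, `phi_net`,
#'   `tied`, ordered by rank (ties in input order).
#' @export
complete_ranking <- function(phi_net, tol = 1e-9) {
  if (is.data.frame(phi_net)) {
    nm <- phi_net$alternative
    phi_net <- stats::setNames(phi_net$phi_net, nm)
  }
  n <- length(phi_net)
  nm <- names(phi_net)
  if (is.null(nm)) nm <- paste0("A", seq_len(n))
  ord <- order(-phi_net, seq_len(n)) # stable descending
  rk <- integer(n)
  tied <- logical(n)
  r <- 1L
  i <- 1L
  while (i <= n) {
    grp <- i
    while (grp < n && abs(phi_net[ord[grp + 1L]] - phi_net[ord[i]]) <= tol)
      grp <- grp + 1L
    members <- sort(ord[i:grp]) # input order inside a tie group
    ord[i:grp] <- members
    rk[members] <- r
    tied[members] <- length(members) > 1L
    r <- r + length(members)
    i <- grp + 1L
  }
  out <- data.frame(rank = rk[ord], alternative = nm[ord],
                    phi_net = unname(phi_net[ord]), tied = tied[ord],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Unicriterion net flows
#'
#' Per-criterion strength/weakness decomposition of the net flow: for each
#' criterion k, phi_k(a) is the average over opponents b of
#' P_k(d(a,b)) - P_k(d(b,a)). Positive entries are the criteria on which an
#' alternative gains against the field, negative entries where it loses; the
#' weighted sum over criteria recovers the aggregate net flow.
#'
#' @inheritParams aggregated_preference
#' @return n x K numeric matrix of unicriterion net flows.
#' @export
unicriterion_net_flows <- function(resolved, specs, directions, spreads = NULL) {
  n <- nrow(resolved)
  if (n < 2L)
    condition_stop("flows need at least 2 alternatives", "insufficient_alternatives")
  if (is.null(spreads)) spreads <- resolve_spreads(resolved, specs)
  out <- matrix(0, n, ncol(resolved), dimnames = dimnames(resolved))
  for (k in seq_len(ncol(resolved))) {
    pk <- per_criterion_preference(resolved[, k], specs[[k]], directions[k], spreads[k])
    out[, k] <- (rowSums(pk) - colSums(pk)) / (n - 1)
  }
  out
}

#' Run the full fuzzy PROMETHEE analysis
#'
#' Resolves linguistic cells and weights, estimates per-criterion Gaussian
#' spreads where requested, computes the aggregated preference index matrix,
#' positive/negative/net outranking flows, the PROMETHEE I partial preorder,
#' the complete PROMETHEE II ranking and the unicriterion decomposition.
#'
#' @param m A [decision_matrix()].
#' @param weights Optional explicit normalised weight vector overriding the
#'   matrix's criterion weights (used by the sensitivity machinery).
#' @param tol Tolerance for flow-equality tests in the preorder and ranking.
#' @return An object of class `"promethee_result"` with components
#'   `flows` (data.frame: alternative, phi_plus, phi_minus, phi_net, rank,
#'   tied), `ranking` (flows ordered by rank), `pi` (n x n preference index),
#'   `unicriterion` (n x K), `partial_order` (n x n relation matrix),
#'   `weights`, `spreads`, `resolved`.
#' @examples
#' m <- generate_matrix(generator_config(n_alternatives = 6, seed = 1))
#' res <- promethee(m)
#' res$ranking
#' @export
promethee <- function(m, weights = NULL, tol = 1e-9) {
  if (!inherits(m, "decision_matrix"))
    condition_stop("promethee() expects a decision_matrix", "shape_error")
  if (nrow(m$cells) < 2L)
    condition_stop("ranking needs at least 2 alternatives", "insufficient_alternatives")
  resolved <- resolve_cells(m)
  if (is.null(weights)) weights <- resolve_weights(m)
  specs <- m$criteria$pref
  directions <- m$criteria$direction
  spreads <- resolve_spreads(resolved, specs)

  pi_mat <- aggregated_preference(resolved, weights, specs, directions, spreads)
  plus <- positive_flow(pi_mat)
  minus <- negative_flow(pi_mat)
  net <- net_flow(plus, minus)
  ranking <- complete_ranking(net, tol = tol)
  rk <- stats::setNames(ranking$rank, ranking$alternative)
  tied <- stats::setNames(ranking$tied, ranking$alternative)
  ids <- m$alternatives$id
  flows <- data.frame(alternative = ids,
                      phi_plus = unname(plus[ids]),
                      phi_minus = unname(minus[ids]),
                      phi_net = unname(net[ids]),
                      rank = unname(rk[ids]),
                      tied = unname(tied[ids]),
                      stringsAsFactors = FALSE)
  structure(list(
    flows = flows,
    ranking = flows[order(flows$rank, match(flows$alternative, ids)), ],
    pi = pi_mat,
    unicriterion = unicriterion_net_flows(resolved, specs, directions, spreads),
    partial_order = partial_order(plus, minus, tol = tol),
    weights = weights,
    spreads = stats::setNames(spreads, m$criteria$id),
    resolved = resolved,
    matrix = m
  ), class = "promethee_result")
}

#' @export
print.promethee_result <- function(x, digits = 4, ...) {
  cat(sprintf("<promethee_result: %d alternatives, %d criteria>\n",
              nrow(x$flows), ncol(x$unicriterion)))
  r <- x$ranking
  r$phi_net <- round(r$phi_net, digits)
  r$phi_plus <- round(r$phi_plus, digits)
  r$phi_minus <- round(r$phi_minus, digits)
  print(r[, c("rank", "alternative", "phi_net", "phi_plus", "phi_minus")],
        row.names = FALSE)
  invisible(x)
}
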