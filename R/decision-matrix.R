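# The decision matrix: alternatives x criteria evaluations, per-criterion
# direction / weight / preference specification, cell and weight resolution.

#' Build a criteria table
#'
#' Convenience constructor for the criteria argument of [decision_matrix()].
#'
#' @param id Character vector of unique criterion identifiers (e.g. `"C8"`).
#' @param direction `"maximize"` or `"minimize"`, recycled if scalar.
#' @param weight Criterion importance: linguistic terms (`"VH"`, `"High"`, ...)
#'   and/or positive numbers. Mixed vectors are allowed (pass as character).
#' @param label Free-text labels; defaults to `id`.
#' @param pref A [pref_spec()] applied to every criterion, or a list of one
#'   spec per criterion. Defaults to the Gaussian function with auto spread.
#' @return A data.frame with columns `id`, `label`, `direction`, `weight` and
#'   a list-column `pref`.
#' @export
criteria_table <- function(id, direction = "maximize", weight = 1, label = id,
                           pref = pref_spec("gaussian")) {
  k <- length(id)
  if (anyDuplicated(id))
    condition_stop("criterion ids must be unique", "duplicate_id")
  direction <- rep_len(direction, k)
  if (!all(direction %in% c("maximize", "minimize")))
    condition_stop("direction must be 'maximize' or 'minimize'", "invalid_direction")
  if (inherits(pref, "pref_spec")) pref <- rep(list(pref), k)
  if (length(pref) != k)
    condition_stop("need one pref_spec per criterion", "shape_error")
  out <- data.frame(id = as.character(id), label = as.character(label),
                    direction = direction, stringsAsFactors = FALSE)
  out$weight <- rep_len(weight, k)
  out$pref <- pref
  out
}

#' Decision matrix
#'
#' The complete dataset of a multi-criteria selection problem: n alternatives
#' evaluated on K criteria, where each evaluation is either a numeric
#' measurement or a linguistic term from a fuzzy scale, and each criterion
#' carries an optimisation direction, an importance weight (linguistic or
#' numeric) and a preference-function specification.
#'
#' @param cells An n x K matrix (or data.frame) of evaluations. A numeric
#'   matrix means all-crisp data; a character matrix may mix number tokens and
#'   linguistic terms. No missing cells are allowed.
#' @param criteria A data.frame as produced by [criteria_table()].
#' @param alternatives Optional data.frame with columns `id` (unique) and
#'   `label`, plus any metadata columns; defaults to the rownames of `cells`
#'   (or A1..An).
#' @param scale The [fuzzy_scale()] used to resolve linguistic cells and
#'   weights.
#' @return An object of class `"decision_matrix"`.
#' @export
decision_matrix <- function(cells, criteria, alternatives = NULL,
                            scale = default_fuzzy_scale()) {
  if (is.data.frame(cells)) cells <- as.matrix(cells)
  if (!is.matrix(cells))
    condition_stop("cells must be a matrix", "shape_error")
  if (!is.data.frame(criteria) || !all(c("id", "direction", "weight") %in% names(criteria)))
    condition_stop("criteria must be a data.frame with id, direction, weight",
                   "shape_error")
  if (is.null(criteria$label)) criteria$label <- criteria$id
  if (is.null(criteria$pref)) criteria$pref <- rep(list(pref_spec("gaussian")), nrow(criteria))
  if (ncol(cells) != nrow(criteria))
    condition_stop(sprintf("cells have %d columns but %d criteria given",
                           ncol(cells), nrow(criteria)), "shape_error")
  if (anyDuplicated(criteria$id))
    condition_stop("criterion ids must be unique", "duplicate_id")
  if (!all(criteria$direction %in% c("maximize", "minimize")))
    condition_stop("direction must be 'maximize' or 'minimize'", "invalid_direction")

  if (is.null(alternatives)) {
    ids <- rownames(cells)
    if (is.null(ids)) ids <- paste0("A", seq_len(nrow(cells)))
    alternatives <- data.frame(id = ids, label = ids, stringsAsFactors = FALSE)
  }
  if (is.null(alternatives$label)) alternatives$label <- alternatives$id
  if (anyDuplicated(alternatives$id))
    condition_stop("alternative ids must be unique", "duplicate_id")
  if (nrow(alternatives) != nrow(cells))
    condition_stop("alternatives do not match the cell rows", "shape_error")

  miss <- is.na(cells) | (is.character(cells) & trimws(cells) == "")
  if (any(miss)) {
    ij <- which(miss, arr.ind = TRUE)[1L, ]
    condition_stop(sprintf("missing cell at row %d, column %d", ij[1L], ij[2L]),
                   "missing_cell")
  }
  dimnames(cells) <- list(alternatives$id, criteria$id)
  structure(list(cells = cells, criteria = criteria,
                 alternatives = alternatives, scale = scale),
            class = "decision_matrix")
}

#' @export
print.decision_matrix <- function(x, ...) {
  wt <- table(vapply(x$criteria$weight, as.character, character(1L)))
  cat(sprintf("<decision_matrix: %d alternatives x %d criteria (%d minimized)>\n",
              nrow(x$cells), ncol(x$cells),
              sum(x$criteria$direction == "minimize")))
  cat("  weights:", paste(names(wt), wt, sep = "x", collapse = ", "), "\n")
  invisible(x)
}

#' Resolve evaluations to a crisp numeric grid
#'
#' Defuzzification of the decision matrix: numeric cells pass through
#' unchanged; linguistic cells are replaced by the Yager index of their fuzzy
#' number under the matrix's scale. This is the preprocessing step before the
#' outranking computation.
#'
#' @param m A [decision_matrix()], or an already-numeric matrix (returned
#'   as-is, so the operation is idempotent on its own output).
#' @return An n x K numeric matrix with the same dimnames.
#' @export
resolve_cells <- function(m) {
  if (is.matrix(m) && is.numeric(m)) return(m)
  if (!inherits(m, "decision_matrix"))
    condition_stop("resolve_cells() expects a decision_matrix", "shape_error")
  cells <- m$cells
  if (is.numeric(cells)) return(cells)
  out <- matrix(NA_real_, nrow(cells), ncol(cells), dimnames = dimnames(cells))
  num <- suppressWarnings(as.numeric(trimws(cells)))
  out[] <- num
  ling <- is.na(num)
  if (any(ling)) {
    idx <- which(ling)
    toks <- trimws(cells[idx])
    vals <- vapply(toks, function(tk) {
      canon <- parse_term(tk, quiet = TRUE)
      key <- if (!is.na(canon) && canon %in% names(m$scale)) canon else tk
      if (!key %in% names(m$scale)) {
        ij <- which(cells == tk & ling, arr.ind = TRUE)[1L, ]
        condition_stop(sprintf("cell '%s' (row %d, column %d) is not numeric and not in the fuzzy scale",
                               tk, ij[1L], ij[2L]), "missing_scale_entry")
      }
      yager_index(m$scale[[key]])
    }, numeric(1L))
    out[idx] <- vals
  }
  out
}

resolve_one_weight <- function(w, scale) {
  if (is.numeric(w)) {
    if (!is.finite(w) || w <= 0)
      condition_stop("numeric criterion weights must be positive", "invalid_weight")
    return(w)
  }
  tok <- trimws(as.character(w))
  num <- suppressWarnings(as.numeric(tok))
  if (!is.na(num)) {
    if (num <= 0) condition_stop("numeric criterion weights must be positive", "invalid_weight")
    return(num)
  }
  term_to_value(tok, scale)
}

#' Resolve and normalise criterion weights
#'
#' Linguistic weights are defuzzified with the Yager index; numeric weights
#' are taken as-is. The resulting vector is divided by its sum, so weights
#' always sum to 1 -- this bounds the aggregated preference index in
#' \[0, 1\] and makes flows comparable across problems with different
#' numbers of criteria.
#'
#' @param criteria A criteria data.frame (see [criteria_table()]) or a
#'   [decision_matrix()].
#' @param scale Fuzzy scale for linguistic weights.
#' @return Named numeric vector of K positive weights summing to 1.
#' @export
resolve_weights <- function(criteria, scale = default_fuzzy_scale()) {
  if (inherits(criteria, "decision_matrix")) {
    scale <- criteria$scale
    criteria <- criteria$criteria
  }
  w <- vapply(seq_len(nrow(criteria)),
              function(i) resolve_one_weight(criteria$weight[[i]], scale),
              numeric(1L))
  names(w) <- criteria$id
  w / sum(w)
}

#' Validate a decision matrix
#'
#' Reporting (non-throwing) check of the structural invariants: unique ids,
#' complete grid, at least two alternatives, resolvable cells and weights.
#' Criterion columns with zero spread are flagged as warnings: they cannot
#' discriminate between alternatives (every pairwise preference is 0).
#'
#' @param m A [decision_matrix()].
#' @return A data.frame with columns `severity` (`"error"`/`"warning"`),
#'   `code` and `message`; zero rows when the matrix is fully valid.
#' @export
validate_matrix <- function(m) {
  out <- data.frame(severity = character(), code = character(),
                    message = character(), stringsAsFactors = FALSE)
  note <- function(severity, code, message) {
    rbind(out, data.frame(severity = severity, code = code, message = message,
                          stringsAsFactors = FALSE))
  }
  if (!inherits(m, "decision_matrix"))
    return(note("error", "not_a_matrix", "object is not a decision_matrix"))
  if (nrow(m$cells) < 2L)
    out <- note("error", "too_few_alternatives",
                sprintf("n = %d alternatives; ranking needs n >= 2", nrow(m$cells)))
  if (anyDuplicated(m$alternatives$id))
    out <- note("error", "duplicate_id", "duplicate alternative ids")
  if (anyDuplicated(m$criteria$id))
    out <- note("error", "duplicate_id", "duplicate criterion ids")
  if (any(is.na(m$cells)))
    out <- note("error", "missing_cell", "matrix has missing cells")

  resolved <- tryCatch(resolve_cells(m), error = function(e) e)
  if (inherits(resolved, "error")) {
    out <- note("error", "unresolvable_cell", conditionMessage(resolved))
  } else if (nrow(resolved) >= 2L) {
    spread <- apply(resolved, 2L, stats::sd)
    for (j in which(spread == 0))
      out <- note("warning", "zero_spread",
                  sprintf("criterion %s has a constant column (zero spread)",
                          m$criteria$id[j]))
  }
  wts <- tryCatch(resolve_weights(m), error = function(e) e)
  if (inherits(wts, "error"))
    out <- note("error", "invalid_weight", conditionMessage(wts))
  out
}
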