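# File interfaces: decision-matrix CSV, criteria configuration (YAML/JSON),
# ranking reports and partial-order edge lists.

read_structured <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) jsonlite::read_json(path)
  else yaml::read_yaml(path)
}

scale_from_config <- function(cfg) {
  if (is.null(cfg)) return(default_fuzzy_scale())
  entries <- lapply(cfg, function(v) {
    v <- as.numeric(unlist(v))
    if (length(v) != 3L)
      condition_stop("scale entries must be [lower, mode, upper] triples",
                     "invalid_scale")
    tfn(v[1L], v[2L], v[3L])
  })
  names(entries) <- names(cfg)
  fuzzy_scale(entries)
}

pref_from_config <- function(cfg) {
  if (is.null(cfg)) return(pref_spec("gaussian"))
  s <- cfg$s
  if (!is.null(s) && !identical(s, "auto")) s <- as.numeric(s)
  pref_spec(kind = cfg$kind %||% "gaussian",
            q = if (!is.null(cfg$q)) as.numeric(cfg$q),
            p = if (!is.null(cfg$p)) as.numeric(cfg$p),
            s = s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a criteria configuration file
#'
#' The configuration is YAML (or JSON, by extension) with a `criteria` list
#' -- each entry carrying `id`, optional `label`, `direction`, `weight`
#' (linguistic term or number) and an optional `preference` block
#' (`kind`, `q`, `p`, `s`) -- plus an optional custom `scale` of
#' term -> \[lower, mode, upper\] triples.
#'
#' @param path Path to the configuration file.
#' @return List with elements `criteria` (data.frame, see [criteria_table()])
#'   and `scale` (a [fuzzy_scale()]).
#' @export
read_criteria_config <- function(path) {
  cfg <- read_structured(path)
  if (is.null(cfg$criteria))
    condition_stop("config has no 'criteria' block", "invalid_config")
  crit <- cfg$criteria
  alternatives <- NULL
  if (!is.null(cfg$alternatives))
    alternatives <- data.frame(
      id = vapply(cfg$alternatives, function(x) as.character(x$id), character(1L)),
      label = vapply(cfg$alternatives, function(x) as.character(x$label %||% x$id),
                     character(1L)),
      stringsAsFactors = FALSE)
  ids <- vapply(crit, function(x) as.character(x$id), character(1L))
  labels <- vapply(crit, function(x) as.character(x$label %||% x$id), character(1L))
  dirs <- vapply(crit, function(x) as.character(x$direction %||% "maximize"),
                 character(1L))
  weights <- vapply(crit, function(x) {
    if (is.null(x$weight)) condition_stop(
      sprintf("criterion %s has no weight", x$id), "invalid_config")
    as.character(x$weight)
  }, character(1L))
  prefs <- lapply(crit, function(x) pref_from_config(x$preference))
  list(criteria = criteria_table(id = ids, direction = dirs, weight = weights,
                                 label = labels, pref = prefs),
       scale = scale_from_config(cfg$scale),
       alternatives = alternatives)
}

#' Read a decision matrix from CSV + configuration
#'
#' The CSV has one header row of criterion ids, a first column of
#' alternative ids (header `alternative`) and one row per alternative; cells
#' are numbers or linguistic tokens (`VH`/`H`/`M`/`L`/`VL` or full words,
#' case-insensitive, surrounding whitespace ignored). Cells that are neither
#' raise a parse error with row/column coordinates.
#'
#' @param matrix_path CSV of evaluations.
#' @param config_path Criteria configuration (see [read_criteria_config()]).
#' @return A [decision_matrix()].
#' @export
read_decision_matrix <- function(matrix_path, config_path) {
  cfg <- read_criteria_config(config_path)
  raw <- utils::read.csv(matrix_path, check.names = FALSE,
                         colClasses = "character", strip.white = TRUE)
  if (ncol(raw) < 2L)
    condition_stop("matrix CSV needs an alternative column plus criteria", "parse_error")
  alt_ids <- trimws(raw[[1L]])
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  cells[] <- trimws(cells)
  crit_ids <- cfg$criteria$id
  if (!setequal(colnames(cells), crit_ids))
    condition_stop(sprintf("matrix columns do not match configured criteria (missing: %s)",
                           paste(setdiff(crit_ids, colnames(cells)), collapse = ", ")),
                   "parse_error")
  cells <- cells[, crit_ids, drop = FALSE]
  bad <- !is_term_token(cells) & is.na(suppressWarnings(as.numeric(cells))) &
         !(cells %in% names(cfg$scale))
  if (any(bad)) {
    ij <- which(matrix(bad, nrow(cells)), arr.ind = TRUE)[1L, ]
    condition_stop(sprintf("cannot parse cell '%s' at row %d, column %s",
                           cells[ij[1L], ij[2L]], ij[1L], crit_ids[ij[2L]]),
                   "parse_error")
  }
  rownames(cells) <- alt_ids
  alternatives <- NULL
  if (!is.null(cfg$alternatives)) {
    alternatives <- cfg$alternatives[match(alt_ids, cfg$alternatives$id), ,
                                     drop = FALSE]
    if (anyNA(alternatives$id))
      condition_stop("matrix rows not covered by the config's alternatives block",
                     "parse_error")
    rownames(alternatives) <- NULL
  }
  decision_matrix(cells, cfg$criteria, alternatives, scale = cfg$scale)
}

#' Write a decision matrix to CSV + configuration
#'
#' Inverse of [read_decision_matrix()]: linguistic cells and weights are
#' preserved as terms (not pre-defuzzified), so a write/read round trip
#' reproduces the model.
#'
#' @param m A [decision_matrix()].
#' @param matrix_path,config_path Output paths (YAML or JSON config by
#'   extension).
#' @return Invisibly, the two paths.
#' @export
write_decision_matrix <- function(m, matrix_path, config_path) {
  cells <- m$cells
  if (is.numeric(cells)) {
    fm <- matrix(sprintf("%.15g", cells),
                 nrow(cells), ncol(cells), dimnames = dimnames(cells))
    cells <- fm
  }
  df <- data.frame(alternative = m$alternatives$id, cells,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, matrix_path, row.names = FALSE, quote = FALSE)

  crit_list <- lapply(seq_len(nrow(m$criteria)), function(i) {
    cr <- m$criteria[i, ]
    sp <- cr$pref[[1L]]
    pref <- list(kind = sp$kind)
    if (!is.null(sp$q)) pref$q <- sp$q
    if (!is.null(sp$p)) pref$p <- sp$p
    if (!is.null(sp$s)) pref$s <- sp$s
    list(id = cr$id, label = cr$label, direction = cr$direction,
         weight = if (is.numeric(cr$weight)) cr$weight else as.character(cr$weight),
         preference = pref)
  })
  scale_list <- lapply(m$scale, function(t) c(t$lower, t$mode, t$upper))
  alt_list <- lapply(seq_len(nrow(m$alternatives)), function(i)
    list(id = m$alternatives$id[i], label = m$alternatives$label[i]))
  cfg <- list(criteria = crit_list, alternatives = alt_list, scale = scale_list)
  if (grepl("\\.json$", config_path, ignore.case = TRUE))
    jsonlite::write_json(cfg, config_path, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(cfg, config_path)
  invisible(c(matrix_path, config_path))
}

#' Write a ranking report
#'
#' Emits the PROMETHEE II ranking as a CSV with columns `rank`,
#' `alternative`, `phi_net`, `phi_plus`, `phi_minus`, values printed at the
#' requested precision (round-half-even, presentation only: the computation
#' is full precision). Optionally writes a companion JSON with the
#' full-precision flows, weights and spreads.
#'
#' @param result A [promethee()] result.
#' @param path Output CSV path.
#' @param precision Decimal places for the presentation columns (default 4).
#' @param full_precision_path Optional JSON path for the exact values.
#' @return Invisibly, the report data.frame (formatted columns).
#' @export
write_ranking_report <- function(result, path, precision = 4,
                                 full_precision_path = NULL) {
  if (!inherits(result, "promethee_result"))
    condition_stop("write_ranking_report() expects a promethee_result", "shape_error")
  if (precision < 0) condition_stop("precision must be >= 0", "invalid_argument")
  r <- result$ranking
  lab <- result$matrix$alternatives$label[
    match(r$alternative, result$matrix$alternatives$id)]
  out <- data.frame(rank = r$rank,
                    alternative = ifelse(is.na(lab), r$alternative, lab),
                    phi_net = formatC(round(r$phi_net, precision),
                                      digits = precision, format = "f"),
                    phi_plus = formatC(round(r$phi_plus, precision),
                                       digits = precision, format = "f"),
                    phi_minus = formatC(round(r$phi_minus, precision),
                                        digits = precision, format = "f"),
                    stringsAsFactors = FALSE)
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  if (!is.null(full_precision_path)) {
    payload <- list(flows = result$flows,
                    weights = as.list(result$weights),
                    spreads = as.list(result$spreads))
    jsonlite::write_json(payload, full_precision_path, auto_unbox = TRUE,
                         digits = NA, dataframe = "rows")
  }
  invisible(out)
}

#' Partial-order edge list
#'
#' Flattens the PROMETHEE I relation matrix into an edge list. Each
#' `preferred` edge is directed (a outranks b, reported once); `indifferent`
#' and `incomparable` pairs are symmetric and reported once with a < b in
#' input order.
#'
#' @param result A [promethee()] result (or a relation matrix from
#'   [partial_order()]).
#' @return A data.frame with columns `a`, `relation`, `b`.
#' @export
partial_order_edges <- function(result) {
  rel <- if (inherits(result, "promethee_result")) result$partial_order else result
  n <- nrow(rel)
  ids <- rownames(rel)
  rows <- list()
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    r <- rel[i, j]
    if (r == "preferred" ||
        (i < j && r %in% c("indifferent", "incomparable")))
      rows[[length(rows) + 1L]] <- data.frame(a = ids[i], relation = r, b = ids[j],
                                              stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(a = character(), relation = character(), b = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
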