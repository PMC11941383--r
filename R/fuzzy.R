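# Triangular fuzzy numbers, the 5-level linguistic scale, and Yager-index
# defuzzification.

condition_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "fpromethee_error")))
}

#' Triangular fuzzy number
#'
#' A triangular fuzzy number is defined by its left bound (membership 0), its
#' mode (membership 1) and its right bound (membership 0). In the (N, a, b)
#' parameterisation common in the fuzzy-MCDM literature, N is the mode, a the
#' distance from the mode to the left bound and b the distance to the right
#' bound; both forms describe the same set and `tfn()` stores the bounds.
#'
#' @param lower Left bound (real, membership 0).
#' @param mode Peak of the membership function (membership 1).
#' @param upper Right bound (real, membership 0).
#'
#' @return An object of class `"tfn"` with fields `lower`, `mode`, `upper`.
#'   A degenerate `lower == mode == upper` triple is a crisp number and is
#'   allowed.
#' @examples
#' tfn(0.5, 0.75, 1)
#' yager_index(tfn(0.5, 0.75, 1)) # 0.75: symmetric, defuzzifies to its mode
#' @export
tfn <- function(lower, mode, upper) {
  vals <- c(lower = lower, mode = mode, upper = upper)
  if (!is.numeric(vals) || length(vals) != 3L || !all(is.finite(vals)))
    condition_stop("tfn() needs three finite numeric values", "invalid_fuzzy_number")
  if (lower > mode || mode > upper)
    condition_stop(
      sprintf("invalid triangular fuzzy number: need lower <= mode <= upper, got (%g, %g, %g)",
              lower, mode, upper),
      "invalid_fuzzy_number")
  structure(list(lower = lower, mode = mode, upper = upper), class = "tfn")
}

#' @export
print.tfn <- function(x, ...) {
  cat(sprintf("<tfn (%g, %g, %g)>\n", x$lower, x$mode, x$upper))
  invisible(x)
}

is_tfn <- function(x) inherits(x, "tfn")

#' Yager-index defuzzification
#'
#' Collapses a triangular fuzzy number to a single representative real using
#' the Yager index (3N - a + b)/3, where N is the mode, a = mode - lower and
#' b = upper - mode. Algebraically this equals the centroid
#' (lower + mode + upper)/3 of the triangle, so it weighs every point of the
#' set, not just the peak.
#'
#' @param x A [tfn()].
#' @return The defuzzified value, a single real in `[x$lower, x$upper]`.
#' @examples
#' yager_index(tfn(0.75, 1, 1)) # 11/12
#' @export
yager_index <- function(x) {
  if (!is_tfn(x)) condition_stop("yager_index() expects a tfn", "invalid_fuzzy_number")
  a <- x$mode - x$lower
  b <- x$upper - x$mode
  (3 * x$mode - a + b) / 3
}

# canonical term labels, best to worst
.term_levels <- c("VH", "H", "M", "L", "VL")

.term_aliases <- c(
  vh = "VH", veryhigh = "VH", "very high" = "VH",
  h = "H", high = "H",
  m = "M", moderate = "M", medium = "M",
  l = "L", low = "L",
  vl = "VL", verylow = "VL", "very low" = "VL"
)

#' Parse a linguistic term token
#'
#' Tokens are matched case-insensitively after trimming whitespace; both the
#' abbreviations (VH, H, M, L, VL) and the full words ("Very High", "moderate",
#' ...) are accepted.
#'
#' @param token Character scalar (or vector) to parse.
#' @param quiet If `TRUE`, return `NA` for unrecognised tokens instead of
#'   erroring.
#' @return Canonical abbreviation(s) among `"VH", "H", "M", "L", "VL"`.
#' @export
parse_term <- function(token, quiet = FALSE) {
  key <- tolower(trimws(as.character(token)))
  out <- unname(.term_aliases[key])
  if (!quiet && anyNA(out)) {
    bad <- token[is.na(out)][1L]
    condition_stop(sprintf("unrecognised linguistic term '%s'", bad), "unknown_term")
  }
  out
}

is_term_token <- function(token) !is.na(parse_term(token, quiet = TRUE))

#' Linguistic fuzzy scale
#'
#' A fuzzy scale maps each linguistic term to a triangular fuzzy number. The
#' default 5-level scale is VH = (0.75, 1, 1), H = (0.50, 0.75, 1),
#' M = (0.25, 0.50, 0.75), L = (0, 0.25, 0.50), VL = (0, 0, 0.25); custom
#' scales (any set of terms) may be supplied wherever a scale is accepted.
#'
#' @param ... Named [tfn()] objects, e.g. `fuzzy_scale(VH = tfn(0.75, 1, 1))`.
#'   Names are canonicalised through [parse_term()] when they match one of the
#'   five standard terms; other names are kept verbatim.
#' @return An object of class `"fuzzy_scale"`: a named list of `tfn`s.
#' @export
fuzzy_scale <- function(...) {
  entries <- list(...)
  if (length(entries) == 1L && is.list(entries[[1L]]) && !is_tfn(entries[[1L]]))
    entries <- entries[[1L]]
  if (length(entries) == 0L || is.null(names(entries)) || any(names(entries) == ""))
    condition_stop("fuzzy_scale() needs named tfn entries", "invalid_scale")
  nm <- vapply(names(entries), function(n) {
    canon <- parse_term(n, quiet = TRUE)
    if (is.na(canon)) n else canon
  }, character(1L))
  if (anyDuplicated(nm))
    condition_stop("duplicate terms in fuzzy scale", "invalid_scale")
  for (e in entries) if (!is_tfn(e))
    condition_stop("every scale entry must be a tfn", "invalid_scale")
  names(entries) <- nm
  structure(entries, class = "fuzzy_scale")
}

#' @rdname fuzzy_scale
#' @export
default_fuzzy_scale <- function() {
  fuzzy_scale(
    VH = tfn(0.75, 1.00, 1.00),
    H  = tfn(0.50, 0.75, 1.00),
    M  = tfn(0.25, 0.50, 0.75),
    L  = tfn(0.00, 0.25, 0.50),
    VL = tfn(0.00, 0.00, 0.25)
  )
}

#' @export
print.fuzzy_scale <- function(x, ...) {
  cat(sprintf("<fuzzy_scale: %d terms>\n", length(x)))
  for (nm in names(x))
    cat(sprintf("  %-4s (%g, %g, %g)  -> %.6f\n", nm,
                x[[nm]]$lower, x[[nm]]$mode, x[[nm]]$upper, yager_index(x[[nm]])))
  invisible(x)
}

#' Defuzzify a linguistic term
#'
#' Looks the term up in a fuzzy scale and returns the Yager index of its
#' triangular fuzzy number. On the default scale the values are strictly
#' increasing from VL to VH.
#'
#' @param term Term label (abbreviation or full word for the standard five).
#' @param scale A [fuzzy_scale()]; defaults to the standard 5-level scale.
#' @return The defuzzified value of the term's fuzzy number.
#' @examples
#' term_to_value("M") # 0.5
#' @export
term_to_value <- function(term, scale = default_fuzzy_scale()) {
  canon <- parse_term(term, quiet = TRUE)
  key <- if (!is.na(canon) && canon %in% names(scale)) canon else as.character(term)
  if (!key %in% names(scale))
    condition_stop(sprintf("term '%s' is not in the fuzzy scale", term),
                   "missing_scale_entry")
  yager_index(scale[[key]])
}
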