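# Preference functions: the generalised criteria of the PROMETHEE family.

.pref_kinds <- c("usual", "u_shape", "v_shape", "level", "linear", "gaussian")

#' Preference-function specification
#'
#' A preference function maps the advantage d of one alternative over another
#' on a criterion to a preference degree in \[0, 1\]; d <= 0 always maps to 0.
#' The six classical kinds are supported:
#'
#' * `usual`: 1 for any d > 0.
#' * `u_shape`: 1 for d > q, else 0 (indifference threshold q).
#' * `v_shape`: d/p capped at 1 (preference threshold p).
#' * `level`: 0 below q, 0.5 between q and p, 1 above p.
#' * `linear`: ramps from 0 at q to 1 at p (v_shape is the q = 0 case).
#' * `gaussian`: 1 - exp(-d^2 / (2 s^2)), a smooth ramp governed by a spread
#'   parameter s. With `s = "auto"` (the default) s is estimated per criterion
#'   as the sample standard deviation of the resolved evaluation column, so
#'   preference degrees reflect how large a difference is relative to the
#'   criterion's own dispersion.
#'
#' @param kind One of `r paste0('"', .pref_kinds, '"', collapse = ", ")`.
#' @param q Indifference threshold, >= 0 (u_shape, level, linear).
#' @param p Preference threshold, > q (v_shape, level, linear).
#' @param s Gaussian spread, a positive number or `"auto"`.
#' @return An object of class `"pref_spec"`.
#' @examples
#' pref_spec("gaussian")           # auto spread
#' pref_spec("linear", q = 0, p = 2)
#' @export
pref_spec <- function(kind = "gaussian", q = NULL, p = NULL, s = NULL) {
  kind <- match.arg(kind, .pref_kinds)
  chk_num <- function(x, what, positive = FALSE) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
        (positive && x <= 0) || (!positive && x < 0))
      condition_stop(sprintf("pref_spec: '%s' must be a %s number", what,
                             if (positive) "positive" else "non-negative"),
                     "invalid_pref_spec")
  }
  if (kind == "u_shape") {
    if (is.null(q)) condition_stop("u_shape needs q", "invalid_pref_spec")
    chk_num(q, "q")
  }
  if (kind %in% c("v_shape", "linear", "level")) {
    if (is.null(p)) condition_stop(sprintf("%s needs p", kind), "invalid_pref_spec")
    chk_num(p, "p", positive = TRUE)
    if (kind == "v_shape") q <- 0
    if (kind == "linear" && is.null(q)) q <- 0
    if (kind == "level" && is.null(q)) condition_stop("level needs q", "invalid_pref_spec")
    if (!is.null(q)) {
      chk_num(q, "q")
      if (p < q) condition_stop("pref_spec: need p >= q", "invalid_pref_spec")
    }
  }
  if (kind == "gaussian") {
    if (is.null(s)) s <- "auto"
    if (!identical(s, "auto")) chk_num(s, "s", positive = TRUE)
  }
  structure(list(kind = kind, q = q, p = p, s = s), class = "pref_spec")
}

#' @export
print.pref_spec <- function(x, ...) {
  par <- c(q = x$q, p = x$p,
           s = if (identical(x$s, "auto")) "auto" else x$s)
  cat(sprintf("<pref_spec %s%s>\n", x$kind,
              if (length(par)) paste0(" (", paste(names(par), par, sep = "=",
                                                  collapse = ", "), ")") else ""))
  invisible(x)
}

#' Signed evaluation difference on one criterion
#'
#' Returns the advantage of alternative a over alternative b, oriented so a
#' positive value always means "a is better": the raw difference for a
#' maximised criterion, its negation for a minimised one.
#'
#' @param value_a,value_b Resolved (numeric) evaluations of the two
#'   alternatives on the criterion.
#' @param direction `"maximize"` or `"minimize"`.
#' @return `value_a - value_b` or its negation. Vectorised.
#' @export
signed_difference <- function(value_a, value_b, direction = c("maximize", "minimize")) {
  direction <- match.arg(direction)
  d <- value_a - value_b
  if (direction == "minimize") -d else d
}

#' Evaluate a preference function
#'
#' @param d Signed difference(s); may be a vector or matrix.
#' @param spec A [pref_spec()].
#' @param s Resolved Gaussian spread, overriding `spec$s`. Required when the
#'   spec carries `s = "auto"`; a spread of 0 (constant criterion column)
#'   yields preference 0 everywhere.
#' @return Preference degree(s) in \[0, 1\], same shape as `d`; 0 wherever
#'   `d <= 0`.
#' @examples
#' preference_value(1, pref_spec("gaussian", s = 1)) # 1 - exp(-1/2)
#' @export
preference_value <- function(d, spec, s = NULL) {
  if (!inherits(spec, "pref_spec"))
    condition_stop("preference_value() expects a pref_spec", "invalid_pref_spec")
  pos <- d > 0
  out <- d
  out[] <- 0
  if (!any(pos)) return(out)
  dp <- d[pos]
  out[pos] <- switch(spec$kind,
    usual = 1,
    u_shape = as.numeric(dp > spec$q),
    v_shape = pmin(dp / spec$p, 1),
    level = ifelse(dp > spec$p, 1, ifelse(dp > spec$q, 0.5, 0)),
    linear = pmin(pmax((dp - spec$q) / (spec$p - spec$q), 0), 1),
    gaussian = {
      sg <- if (!is.null(s)) s else spec$s
      if (identical(sg, "auto") || is.null(sg))
        condition_stop("gaussian spread 'auto' has not been resolved; pass s",
                       "unresolved_parameter")
      if (sg <= 0) 0 else 1 - exp(-dp^2 / (2 * sg^2))
    }
  )
  out
}

#' Data-driven Gaussian spread
#'
#' The default spread for the Gaussian preference function: the sample
#' standard deviation (divisor n - 1) of a criterion's resolved evaluation
#' column. A constant column yields 0; the engine then assigns zero
#' preference on that criterion (all pairwise differences are 0 anyway).
#'
#' @param column Numeric vector of resolved evaluations, length >= 2.
#' @return The sample standard deviation.
#' @export
estimate_gaussian_spread <- function(column) {
  if (!is.numeric(column) || length(column) < 2L)
    condition_stop("spread estimation needs at least 2 values", "insufficient_data")
  stats::sd(column)
}
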