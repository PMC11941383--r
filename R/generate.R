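# Seeded generator of synthetic decision matrices shaped like a
# sequencing-platform selection study, plus dominance planting for
# recovery-style checks.

#' Generator configuration
#'
#' Describes the shape of a synthetic decision matrix: by default 15
#' alternatives evaluated on 20 criteria whose importance weights follow the
#' study distribution 10 Very High + 7 High + 3 Moderate, with a mix of
#' numeric columns (costs, error rates, throughput-like quantities) and
#' 5-level linguistic columns, and 5 minimised (cost-like) criteria.
#'
#' @param n_alternatives Number of alternatives (default 15).
#' @param weight_distribution Named integer vector mapping linguistic weight
#'   terms to criterion counts; the counts sum to the criterion total
#'   (default `c(VH = 10, H = 7, M = 3)`, i.e. 20 criteria).
#' @param fraction_linguistic_cells Fraction of criteria whose column is
#'   linguistic rather than numeric, in \[0, 1\]. The default 0.55 mirrors
#'   the study structure: 11 qualitative criteria out of 20.
#' @param n_minimize Number of minimised criteria (default 5: the cost-,
#'   time- and error-like ones). Minimised criteria are drawn from the
#'   numeric columns first.
#' @param seed Integer seed; fully determines the generated matrix.
#' @return A list of class `"generator_config"`.
#' @export
generator_config <- function(n_alternatives = 15L,
                             weight_distribution = c(VH = 10L, H = 7L, M = 3L),
                             fraction_linguistic_cells = 0.55,
                             n_minimize = 5L,
                             seed = 1L) {
  if (n_alternatives < 2L)
    condition_stop("need at least 2 alternatives", "invalid_config")
  if (is.null(names(weight_distribution)) || any(weight_distribution < 0))
    condition_stop("weight_distribution must be a named non-negative count vector",
                   "invalid_config")
  K <- sum(weight_distribution)
  if (K < 1L) condition_stop("need at least 1 criterion", "invalid_config")
  if (fraction_linguistic_cells < 0 || fraction_linguistic_cells > 1)
    condition_stop("fraction_linguistic_cells must be in [0, 1]", "invalid_config")
  if (n_minimize < 0L || n_minimize > K)
    condition_stop("n_minimize must be between 0 and the criterion count",
                   "invalid_config")
  structure(list(n_alternatives = as.integer(n_alternatives),
                 weight_distribution = weight_distribution,
                 fraction_linguistic_cells = fraction_linguistic_cells,
                 n_minimize = as.integer(n_minimize),
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Generate a synthetic decision matrix
#'
#' Draws a complete decision matrix with the shape given by the config.
#' Numeric columns emulate instrument-specification data: half are lognormal
#' (cost-, output- and error-rate-like, spanning orders of magnitude), half
#' uniform on a random range (percentage- and volume-like). Linguistic
#' columns draw the five scale terms with mild central bias. All criteria
#' use the Gaussian preference function with data-estimated spread.
#'
#' @param config A [generator_config()].
#' @return A [decision_matrix()], deterministic in `config$seed`.
#' @examples
#' m <- generate_matrix(generator_config(seed = 42))
#' dim(m$cells) # 15 x 20
#' @export
generate_matrix <- function(config = generator_config()) {
  if (!inherits(config, "generator_config"))
    condition_stop("generate_matrix() expects a generator_config", "invalid_config")
  n <- config$n_alternatives
  K <- sum(config$weight_distribution)
  n_ling <- round(config$fraction_linguistic_cells * K)

  withr::with_seed(config$seed, {
    crit_id <- paste0("C", seq_len(K))
    weight_terms <- sample(rep(names(config$weight_distribution),
                               times = config$weight_distribution))
    ling_cols <- sort(sample.int(K, n_ling))
    numeric_cols <- setdiff(seq_len(K), ling_cols)
    # cost-like minimised criteria live on numeric columns when possible
    min_pool <- c(numeric_cols, ling_cols)
    min_cols <- min_pool[seq_len(config$n_minimize)]
    direction <- ifelse(seq_len(K) %in% min_cols, "minimize", "maximize")

    cells <- matrix("", n, K)
    for (j in seq_len(K)) {
      if (j %in% ling_cols) {
        cells[, j] <- sample(c("VH", "H", "M", "L", "VL"), n, replace = TRUE,
                             prob = c(0.15, 0.25, 0.3, 0.2, 0.1))
      } else if (stats::runif(1) < 0.5) {
        # lognormal: costs, data output, error rates
        vals <- stats::rlnorm(n, meanlog = stats::runif(1, 0, 6),
                              sdlog = stats::runif(1, 0.3, 1))
        cells[, j] <- sprintf("%.15g", vals)
      } else {
        # bounded range: accuracies, sensitivities, loading volumes
        lo <- stats::runif(1, 0, 80)
        hi <- lo + stats::runif(1, 5, 50)
        cells[, j] <- sprintf("%.15g", stats::runif(n, lo, hi))
      }
    }
    criteria <- criteria_table(id = crit_id, direction = direction,
                               weight = weight_terms,
                               pref = pref_spec("gaussian"))
    alternatives <- data.frame(id = paste0("A", seq_len(n)),
                               label = paste("Alternative", seq_len(n)),
                               stringsAsFactors = FALSE)
    rownames(cells) <- alternatives$id
    decision_matrix(cells, criteria, alternatives)
  })
}

best_term <- function(scale, direction = "maximize") {
  vals <- vapply(scale, yager_index, numeric(1L))
  names(scale)[if (direction == "minimize") which.min(vals) else which.max(vals)]
}

#' Plant a dominant alternative
#'
#' Rewrites one alternative's row so it weakly dominates every other row:
#' on each criterion it takes the columnwise best value (max for maximised,
#' min for minimised, the direction's best term on linguistic columns), and on numeric
#' criteria it is pushed strictly past the best opponent by 5% of the column
#' range. Because PROMETHEE rankings preserve dominance, the planted
#' alternative must rank first under any positive weights -- the package's
#' recovery check.
#'
#' @param m A [decision_matrix()] with at least one numeric criterion column
#'   (strict improvement is impossible on a linguistic column whose best
#'   opponent already holds the top term).
#' @param target_id Alternative id to promote.
#' @return A new `decision_matrix`; the input is untouched.
#' @export
plant_dominant_alternative <- function(m, target_id) {
  if (!inherits(m, "decision_matrix"))
    condition_stop("plant_dominant_alternative() expects a decision_matrix", "shape_error")
  i <- match(target_id, m$alternatives$id)
  if (is.na(i))
    condition_stop(sprintf("unknown alternative id '%s'", target_id), "unknown_alternative")
  cells <- m$cells
  if (is.numeric(cells)) cells <- matrix(sprintf("%.15g", cells),
                                         nrow(cells), ncol(cells), dimnames = dimnames(cells))
  any_numeric <- FALSE
  for (j in seq_len(ncol(cells))) {
    others <- cells[-i, j]
    num <- suppressWarnings(as.numeric(others))
    if (anyNA(num)) { # linguistic column: take the best term for the direction
      cells[i, j] <- best_term(m$scale, m$criteria$direction[j])
      next
    }
    any_numeric <- TRUE
    margin <- 0.05 * (max(num) - min(num))
    if (margin == 0) margin <- max(abs(num[1L]) * 0.05, 1)
    best <- if (m$criteria$direction[j] == "minimize") min(num) - margin
            else max(num) + margin
    cells[i, j] <- sprintf("%.15g", best)
  }
  if (!any_numeric)
    condition_stop("cannot guarantee strict dominance: no numeric criterion column",
                   "invalid_config")
  decision_matrix(cells, m$criteria, m$alternatives, m$scale)
}

.study_alternatives <- c(
  "Avidite Base Chemistry Sequencing", "Oxford Nanopore Sequencing",
  "Illumina NextSeq 2000", "Single Molecule Fluorescent Sequencing",
  "ABI's SOLID Sequencing", "Single-Molecule Real-Time Sequencing",
  "Ion Torrent Semiconductor Sequencing", "Microfluidic Sanger Sequencing",
  "Massively Parallel Signature Sequencing", "CRISPR Cas",
  "Polony Sequencing", "GenapSys Sequencing",
  "Qiagen PyroMark Q48 Autoprep", "Maxam-Gilbert Method",
  "Applied Biosystems 3730")

.study_criteria <- data.frame(
  id = paste0("C", 1:20),
  label = c("machine design", "type of sequencing", "generation type",
            "DNA or RNA sequencing", "max read length/run", "max output data/run",
            "processing time/run", "accuracy", "diagnostic sensitivity",
            "cost per instrument", "cost/run", "mutation detection",
            "error rate", "throughput",
            "large whole-genome sequencing", "small whole-genome sequencing",
            "exome and large panel sequencing", "loading volume",
            "whole genome with single-stranded sequencing",
            "single-stranded sequencing accuracy"),
  weight = c("H", "VH", "H", "M", "VH", "VH", "VH", "VH", "VH", "VH", "H", "H",
             "VH", "H", "H", "M", "H", "M", "VH", "VH"),
  direction = "maximize",
  stringsAsFactors = FALSE)
# smaller is better for time-, cost-, error- and volume-like criteria
.study_criteria$direction[.study_criteria$id %in% c("C7", "C10", "C11", "C13", "C18")] <-
  "minimize"
# columns holding measurements rather than 5-level ratings
.study_numeric_cols <- c("C5", "C6", "C7", "C8", "C9", "C10", "C11", "C13", "C18")

#' Synthetic sequencing-technology study matrix
#'
#' A fixed 15 x 20 decision matrix mirroring the structure of a
#' sequencing-platform selection study: 15 named sequencing technologies,
#' 20 criteria (machine design through single-stranded sequencing accuracy)
#' with the 10 Very High + 7 High + 3 Moderate weight distribution, 5
#' minimised cost/time/error-like criteria, 9 numeric measurement columns
#' and 11 linguistic columns.
#'
#' The cell values are synthetic: the original study's evaluations were
#' compiled from vendor specifications and never published, so this fixture
#' reproduces the problem's structure (dimensions, labels, weights,
#' directions, column types) with plausible seeded draws, not the study's
#' data. Rankings computed from it are illustrative only.
#'
#' @param seed Seed for the cell draws (default fixed, so the fixture is
#'   stable).
#' @return A [decision_matrix()].
#' @export
sequencing_study_matrix <- function(seed = 665L) {
  crit <- .study_criteria
  n <- length(.study_alternatives)
  withr::with_seed(seed, {
    cells <- matrix("", n, nrow(crit))
    ranges <- list(
      C5 = function(n) stats::rlnorm(n, log(20), 1.6),     # max read length/run, KB
      C6 = function(n) stats::rlnorm(n, log(30), 2),       # max output/run, GB
      C7 = function(n) stats::runif(n, 4, 72),             # processing time, h
      C8 = function(n) stats::runif(n, 85, 99.9),          # accuracy, %
      C9 = function(n) stats::runif(n, 80, 99.9),          # diagnostic sensitivity, %
      C10 = function(n) stats::rlnorm(n, log(1e5), 0.9),   # instrument cost, USD
      C11 = function(n) stats::rlnorm(n, log(800), 1),     # cost/run, USD
      C13 = function(n) stats::rlnorm(n, log(1.5), 1),     # error rate, %
      C18 = function(n) stats::runif(n, 1, 50)             # loading volume, uL
    )
    for (j in seq_len(nrow(crit))) {
      cid <- crit$id[j]
      if (cid %in% .study_numeric_cols) {
        cells[, j] <- sprintf("%.15g", ranges[[cid]](n))
      } else {
        cells[, j] <- sample(c("VH", "H", "M", "L", "VL"), n, replace = TRUE,
                             prob = c(0.15, 0.25, 0.3, 0.2, 0.1))
      }
    }
    alternatives <- data.frame(id = paste0("T", seq_len(n)),
                               label = .study_alternatives,
                               stringsAsFactors = FALSE)
    rownames(cells) <- alternatives$id
    criteria <- criteria_table(id = crit$id, direction = crit$direction,
                               weight = crit$weight, label = crit$label,
                               pref = pref_spec("gaussian"))
    decision_matrix(cells, criteria, alternatives)
  })
}

#' The study's six-criterion sensitivity change
#'
#' The weight modification examined in the study's sensitivity analysis:
#' accuracy, diagnostic sensitivity, cost per instrument, cost/run,
#' throughput and loading volume are all set to the linguistic weight High
#' (regardless of their baseline term).
#'
#' @return A data.frame usable as the `changes` argument of
#'   [apply_weight_changes()].
#' @export
sequencing_sensitivity_changes <- function() {
  data.frame(criterion_id = c("C8", "C9", "C10", "C11", "C14", "C18"),
             new_weight = "H", stringsAsFactors = FALSE)
}
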