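---
title: "Fuzzy PROMETHEE outranking: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fuzzy PROMETHEE outranking: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fpromethee)
```

## The decision problem

The package ranks a set of alternatives (here: DNA sequencing platforms)
evaluated on many, possibly conflicting criteria — accuracy, diagnostic
sensitivity, instrument and per-run cost, error rate, throughput, read
length, and so on. Some criteria are hard measurements (cost in USD, error
rate in %), others are expert judgements expressed on a 5-level linguistic
scale (Very Low … Very High). The same scale is used for the criterion
importance weights.

Two modelling layers handle this mix:

1. **Fuzzy layer.** Each linguistic term maps to a triangular fuzzy number
   (TFN) $(l, m, u)$ with membership rising linearly from $l$ to the mode
   $m$ and falling to $u$. The default scale is
   VH = (0.75, 1, 1), H = (0.5, 0.75, 1), M = (0.25, 0.5, 0.75),
   L = (0, 0.25, 0.5), VL = (0, 0, 0.25). TFNs are collapsed to crisp
   numbers with the Yager index: writing $N = m$, $a = m - l$, $b = u - m$,
   the index is $(3N - a + b)/3$, which is algebraically the centroid
   $(l + m + u)/3$. The test suite exploits that identity as an independent
   oracle. Defuzzification happens once, as a preprocessing step, so the
   outranking core operates on a crisp matrix.

2. **Outranking layer (PROMETHEE).** For each ordered pair of alternatives
   $(a_t, a_{t'})$ and criterion $k$ with weight $w_k$, direction-oriented
   difference $d_k = \pm(f_k(a_t) - f_k(a_{t'}))$ and preference function
   $P_k$, the aggregated preference index is
   $$\pi(a_t, a_{t'}) = \sum_{k=1}^K w_k \, P_k(d_k).$$
   The positive and negative outranking flows average this over the $n-1$
   opponents,
   $$\Phi^+(a_t) = \tfrac{1}{n-1}\sum_{t' \ne t} \pi(a_t, a_{t'}), \qquad
     \Phi^-(a_t) = \tfrac{1}{n-1}\sum_{t' \ne t} \pi(a_{t'}, a_t),$$
   and the net flow $\Phi^{net} = \Phi^+ - \Phi^-$ gives the complete
   PROMETHEE II ranking (descending). PROMETHEE I's partial preorder is
   also reported: $a$ is *preferred* to $b$ when it is at least as strong
   and strictly less weak (or strictly stronger and equally weak),
   *indifferent* when both flows agree, and the two are *incomparable*
   when the flows disagree in direction.

## Parameters that matter

* **Preference function** (per criterion, `pref_spec()`): all six classical
  kinds are implemented. The study setting — and the package default — is
  the **Gaussian** function $P(d) = 1 - e^{-d^2/2s^2}$ for $d > 0$, which
  grades preferences smoothly instead of jumping from 0 to 1. The usual
  (0/1) function is kept around chiefly because it makes hand-checkable
  examples, and the threshold kinds (`u_shape`, `v_shape`, `level`,
  `linear`) for users who think in indifference/preference thresholds
  $q, p$ in the criterion's own units.
* **Gaussian spread `s`** (criterion units): default `"auto"`, the sample
  standard deviation (divisor $n-1$) of the criterion's resolved column.
  This makes a "large" advantage mean "large relative to how much the
  alternatives actually differ on this criterion", and it renders the flows
  invariant to positively rescaling any column (spread and differences
  scale together) — convenient when costs in dollars sit next to error
  rates in percent. An explicit numeric `s` overrides it. A constant column
  has spread 0; the engine then assigns zero preference on that criterion,
  which is consistent since every pairwise difference is also 0, and
  `validate_matrix()` flags such columns as warnings.
* **Weights**: linguistic terms or positive numbers, defuzzified with the
  same Yager index and then **normalised to sum 1**. The normalisation is a
  deliberate convention: it bounds $\pi$ in $[0,1]$, makes flows comparable
  across problems with different criterion counts, and makes uniform weight
  rescaling a no-op (a tested invariant). Whether the original Decision Lab
  runs normalised is not documented anywhere we could check; nothing in the
  reported arithmetic depends on it because only rankings and flow
  differences are interpreted.
* **Flow-equality tolerance** (`tol`, default 1e-9): exact float equality
  would make PROMETHEE I indifference unreachable, so flow comparisons in
  the preorder and tie detection in the ranking use an absolute tolerance.
  Ties share the better rank and keep input order (stable sort).

## The synthetic generator and the packaged fixture

The evaluation matrix of the motivating study was compiled from vendor
specification sheets and never published, so nothing can reproduce its
exact flows. What *is* reproducible is the problem structure, and that is
what `generator_config()` / `generate_matrix()` and the fixed fixture
`sequencing_study_matrix()` provide:

* 15 alternatives × 20 criteria;
* importance weights 10 × VH, 7 × H, 3 × M (no criterion was judged Low or
  Very Low);
* 5 minimised criteria — processing time/run, instrument cost, cost/run,
  error rate, loading volume — smaller-is-better being implied by their
  meaning; directions remain explicit, overridable config fields;
* a mixed column population: 9 numeric measurement columns (read length,
  output, time, accuracy, sensitivity, two costs, error rate, loading
  volume) and 11 linguistic columns, i.e. a linguistic fraction of 0.55,
  which is the generator default;
* numeric draws chosen to look like instrument spec sheets: lognormal for
  quantities spanning orders of magnitude (costs, output, error rates),
  uniform ranges for bounded ones (accuracy 85–99.9%, sensitivity
  80–99.9%, loading volume 1–50 µL, run time 4–72 h); linguistic columns
  draw the five terms with mild central bias. These ranges are assumptions
  stated here, not facts from any source.

One labelling wrinkle: the study's criterion legend lists "cost per
instrument" twice (C10 and C12) while its criteria list and weight table
distinguish instrument cost from cost/run and also include mutation
detection, which the legend omits. The fixture resolves C12 as *mutation
detection*; with that assignment the 20 labels reproduce the published
weight multiset exactly.

Each generator call runs under its own seed (`withr::with_seed`), so
identical configs give byte-identical serialisations and no global RNG
state is disturbed.

`plant_dominant_alternative()` rewrites one row to weakly dominate every
other (best value per column, strictly past the best opponent by 5% of the
column range on numeric columns). Since PROMETHEE preserves dominance, the
planted row must rank first under *any* positive weights — the package's
analogue of a parameter-recovery check, exercised over 50 seeds and also
after the sensitivity weight change. On a purely linguistic matrix strict
dominance cannot be guaranteed (the best opponent may already hold the top
term), so the function requires at least one numeric column.

What passing these checks does **not** show: that real vendor data would
produce any particular ranking, that criteria are uncorrelated the way the
generator draws them (real spec-sheet criteria are correlated — cost with
throughput, generation with read length), or that the linguistic scale
choices of other expert panels would agree.

## Sensitivity analysis

`apply_weight_changes()` + `compare_rankings()` replicate the study's
experiment: set accuracy, diagnostic sensitivity, instrument cost,
cost/run, throughput and loading volume to weight High and re-rank. The
study describes this as changing weights "from Very High to High", but two
of the six were already High and one Moderate in its own weight table; the
packaged experiment (`sequencing_sensitivity_changes()`) therefore *sets*
all six to High, which subsumes the stated change. Rankings are compared
by per-alternative rank displacement, the list of reversed pairs, and
Kendall's tau-b on the net-flow orderings — tau-b because the comparison
is about order, not flow magnitude, and its tie correction handles tied
flows.

The rerun re-estimates Gaussian spreads from the (unchanged) matrix, which
is deliberately a no-op: spreads depend only on the evaluation columns,
not the weights, so the baseline path and the sensitivity path are
bit-identical when the change list is empty (a tested contract).

`monte_carlo_weight_stability()` generalises the single rerun: each draw
perturbs every normalised weight multiplicatively by $1 + u$,
$u \sim U(-\varepsilon, +\varepsilon)$, renormalises and re-ranks. The
output is a rank-frequency table, deterministic in its seed. The analysis
scripts use $\varepsilon = 0.2$ and 500 draws, enough to resolve rank-1
frequencies to a few percent at negligible runtime.

## Numerical choices

* Defuzzification is implemented literally as $(3N - a + b)/3$; tests
  compare it against the centroid form at 1e-12.
* Engine-vs-oracle agreement is asserted at 1e-12 against a deliberately
  unvectorised triple-loop implementation of the definitions, on 100
  random matrices up to 8 × 6 with mixed directions and auto spreads.
* Flow conservation $\sum_a \Phi^{net}(a) = 0$ is asserted at 1e-9.
* Reports round to 4 decimals (round-half-even at the presentation layer
  only); a companion JSON carries full precision.
* Weight normalisation is checked to 1e-12; general float comparisons in
  tests use 1e-9 unless the property is exact.

Problem sizes in the checks — 100 random matrices up to 8 × 6 for the
oracle and conservation suites, 50 seeds of the 15 × 20 structure for
dominance recovery, 200–500 Monte Carlo draws — were chosen as the
smallest sizes at which each property is exercised across the whole input
space the package supports; all complete in seconds.

## Known limitations

* No GAIA-plane (principal-component) visualisation, no PROMETHEE V/VI
  extensions, no multi-decision-maker aggregation.
* Only triangular membership functions and the Yager defuzzifier;
  trapezoidal sets or center-of-gravity defuzzification over discretised
  memberships are out of scope.
* Cells are taken as already comparable numbers within a criterion; there
  is no unit conversion (KB vs GB) or imputation — missing cells are a
  hard error.
* Exact break-even weight intervals per criterion are not computed; the
  Monte Carlo sweep is the supported stability tool.
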