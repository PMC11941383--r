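# fpromethee

Fuzzy PROMETHEE I/II outranking analysis in R, built for the kind of
question a clinical genomics lab faces when choosing a sequencing
platform: fifteen candidate technologies, twenty criteria — accuracy,
diagnostic sensitivity, instrument cost, cost per run, error rate,
throughput, read length, portability, … — some measured, some judged on a
Very Low … Very High linguistic scale, some to be maximised and some
minimised. The package ranks the alternatives, explains *why* each ranks
where it does, and quantifies how stable the ranking is under weight
changes.

## The method

Linguistic evaluations and weights are modelled as triangular fuzzy
numbers on the 5-level scale VH = (0.75, 1, 1), H = (0.5, 0.75, 1),
M = (0.25, 0.5, 0.75), L = (0, 0.25, 0.5), VL = (0, 0, 0.25) and collapsed
to crisp values with the Yager index (3N − a + b)/3 — equivalently the TFN
centroid (l + m + u)/3. On the crisp matrix, PROMETHEE computes for every
ordered pair of alternatives the aggregated preference index

    π(a, b) = Σ_k  w_k · P_k(d_k(a, b)),        Σ_k w_k = 1,

with P_k a preference function (default: Gaussian,
P(d) = 1 − exp(−d²/2s²) for d > 0, spread s = the criterion's sample
standard deviation), then the outranking flows

    Φ+(a) = 1/(n−1) Σ_{b≠a} π(a, b)      (strength)
    Φ−(a) = 1/(n−1) Σ_{b≠a} π(b, a)      (weakness)
    Φnet  = Φ+ − Φ−                       (complete PROMETHEE II ranking)

plus the PROMETHEE I partial preorder (preferred / indifferent /
incomparable) and a per-criterion unicriterion decomposition of Φnet
showing each alternative's strengths and weaknesses.

## Worked example

The packaged fixture `sequencing_study_matrix()` mirrors the structure of
a published sequencing-platform assessment (15 platforms × 20 criteria,
weights 10 × VH, 7 × H, 3 × M, five minimised criteria). Its cell values
are openly synthetic — the original evaluations were never published — so
the ranking below illustrates the machinery, not any real platform
comparison.

```r
library(fpromethee)
m   <- sequencing_study_matrix()
res <- promethee(m)
res
#> <promethee_result: 15 alternatives, 20 criteria>
#>  rank alternative phi_net phi_plus phi_minus
#>     1          T5  0.1013   0.2448    0.1436
#>     2          T1  0.0967   0.2581    0.1615
#>     3          T9  0.0427   0.2528    0.2101
#>     ...
#>    15         T11 -0.1280   0.1510    0.2790
```

`phi_plus` is how strongly an alternative outranks the field on the
weighted criteria, `phi_minus` how strongly it is outranked, and their
difference `phi_net` orders the final ranking; positive entries of
`res$unicriterion` are the criteria an alternative wins on. Re-running
after the six-criterion weight change studied in the source analysis:

```r
after <- promethee(apply_weight_changes(m, sequencing_sensitivity_changes()))
compare_rankings(res, after)
#> <sensitivity_report: concordance (Kendall tau-b) = 0.9810, 1 reversal pair(s)>
#>  alternative rank_before rank_after displacement
#>           T2           5          4           -1
#>          T13           4          5            1
```

i.e. demoting accuracy, sensitivity, the two costs, throughput and
loading volume to weight High swaps a single mid-table pair and leaves the
winner untouched.

The full analysis lives in three scripts: `analysis/01_simulate.R` builds
and validates the matrix and writes `results/matrix.csv` +
`results/criteria.yaml`; `analysis/02_rank.R` ranks it and writes
`results/ranking.csv` (4-decimal presentation), `results/ranking_full.json`
(full precision), the unicriterion flow table and the partial-order edge
list; `analysis/03_sensitivity.R` runs the weight-change comparison and a
500-draw Monte Carlo weight perturbation (±20%), writing the displacement
and rank-frequency tables.

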