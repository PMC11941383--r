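#!/usr/bin/env Rscript
# Rank the platforms with fuzzy PROMETHEE II.
#
# Reads the matrix + criteria config written by 01_simulate.R, defuzzifies
# linguistic evaluations and weights with the Yager index, runs the
# Gaussian-preference outranking engine, and writes the ranking report, the
# full-precision flows, the per-criterion strength/weakness decomposition
# and the PROMETHEE I partial-preorder edge list.

suppressPackageStartupMessages(library(fpromethee))

m <- read_decision_matrix("results/matrix.csv", "results/criteria.yaml")
res <- promethee(m)
print(res)

write_ranking_report(res, "results/ranking.csv", precision = 4,
                     full_precision_path = "results/ranking_full.json")

uni <- data.frame(alternative = rownames(res$unicriterion),
                  round(res$unicriterion, 6), check.names = FALSE)
write.csv(uni, "results/unicriterion_flows.csv", row.names = FALSE)

write.csv(partial_order_edges(res), "results/partial_order.csv", row.names = FALSE)

winner <- res$ranking$alternative[1]
lab <- m$alternatives$label[match(winner, m$alternatives$id)]
cat(sprintf("\ntop alternative: %s (net flow %.4f)\n", lab, res$ranking$phi_net[1]))
cat("strongest criteria of the winner (unicriterion net flow):\n")
top_crit <- sort(res$unicriterion[winner, ], decreasing = TRUE)[1:3]
for (i in seq_along(top_crit))
  cat(sprintf("  %s: %+.4f\n", names(top_crit)[i], top_crit[i]))
cat("wrote results/ranking.csv, ranking_full.json, unicriterion_flows.csv, partial_order.csv\n")
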