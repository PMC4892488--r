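#!/usr/bin/env Rscript
# Stage 3: signed co-expression networks per condition. The soft-threshold
# power is chosen on the healthy (reference) network by the scale-free
# topology criterion (smallest power with log-log fit R^2 > 0.8 and
# negative slope, argmax fallback) and reused for the disease network.
suppressMessages(library(coexdiff))

expr <- read_expression_table("results/data/expression.tsv")
groups <- read_sample_groups("results/data/groups.tsv", reference = "healthy")
ref <- expr[, names(groups)[groups == "healthy"]]

cc <- correlation_matrix(ref)
picked <- pick_soft_threshold(cc)
write.table(picked$scan, "results/soft_threshold_scan.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

row <- picked$scan[picked$scan$beta == picked$beta, ]
cat("Chosen power beta =", picked$beta,
    ifelse(picked$reached_cut, "(R^2 criterion reached)", "(argmax fallback)"),
    "\n")
cat(sprintf("At beta = %d: R^2 = %.3f, slope = %.2f, mean connectivity = %.1f\n",
            picked$beta, row$r_squared, row$slope, row$mean_k))
cat("Wrote results/soft_threshold_scan.tsv\n")
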