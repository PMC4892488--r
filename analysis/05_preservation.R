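#!/usr/bin/env Rscript
# Stage 5: module preservation between conditions. Permutation Z statistics
# (200 random same-size gene sets per module) for density and connectivity,
# combined into Zsummary; modules with Zsummary < 5 are selected as
# candidate disease modules.
suppressMessages(library(coexdiff))

expr <- read_expression_table("results/data/expression.tsv")
groups <- read_sample_groups("results/data/groups.tsv", reference = "healthy")
ref <- expr[, names(groups)[groups == "healthy"]]
test <- expr[, names(groups)[groups != "healthy"]]

net_ref <- build_coexpression_network(ref)
net_test <- build_coexpression_network(test, beta = net_ref$beta)
dis <- tom_dissimilarity(net_ref$tom)
part <- hybrid_dynamic_cut(average_linkage(dis), dis)

pres <- module_preservation(net_ref, net_test, part, test,
                            n_perm = 200, seed = 1)
write.table(format(as.data.frame(pres), digits = 4),
            "results/preservation.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
selected <- select_weak_modules(pres, 5)
writeLines(selected, "results/selected_modules.txt")

cat("Preservation report (Zsummary, descending):\n")
print(as.data.frame(pres)[, c("module", "size", "z_density",
                              "z_connectivity", "z_summary", "category")],
      digits = 3, row.names = FALSE)
cat("Weakly preserved (Zsummary < 5, grey/gold excluded):",
    paste(selected, collapse = ", "), "\n")
cat("Wrote results/preservation.tsv, results/selected_modules.txt\n")
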