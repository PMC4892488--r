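#!/usr/bin/env Rscript
# Stage 1: generate the two-condition study dataset.
# 1,000 genes: 8 planted co-expression modules (two of which lose their
# co-expression in the disease condition), 300 background genes of which 50
# are mean-shifted, 40 healthy + 40 disease samples.
suppressMessages(library(coexdiff))

seed <- 1L
sim <- simulate_two_condition(default_paper_like_scenario(seed))
write_simulation(sim, "results/data")

cat("Simulated", nrow(sim$ref), "genes x", ncol(sim$ref), "+",
    ncol(sim$test), "samples (seed", seed, ")\n")
cat("Planted modules:", paste(sim$config$module_sizes, collapse = ", "),
    "genes; destroyed in disease:",
    paste(sim$config$destroyed_modules, collapse = ", "), "\n")
cat("Wrote expression.tsv, groups.tsv, truth.tsv under results/data/\n")
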