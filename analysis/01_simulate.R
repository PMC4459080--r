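#!/usr/bin/env Rscript
# Stage 1: generate the synthetic two-layer xenograft-style dataset.
#
# The deposited study data (mRNA microarrays plus AQUA protein scores for 29
# genes, 4 conditions, 5 treated time points, pooled controls) are not
# shipped; this generator reproduces the experiment's shape with a known
# ground truth: 40% of genes respond to treatment and their mRNA and protein
# trajectories are coupled at r = 0.7; the rest are decoupled.

library(profconcord)

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = 20260919)
sim <- generate_experiment(cfg)

write_expression_dataset(sim$mrna,
                         file.path(out, "mrna_matrix.tsv"),
                         file.path(out, "mrna_meta.tsv"))
write_expression_dataset(sim$protein,
                         file.path(out, "protein_matrix.tsv"),
                         file.path(out, "protein_meta.tsv"))
write.table(sim$truth, file.path(out, "truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("Simulated %d genes x %d mRNA samples and %d protein samples\n",
            nrow(sim$mrna$values), ncol(sim$mrna$values),
            ncol(sim$protein$values)))
cat(sprintf("%d of %d genes responsive (latent mRNA-protein coupling %.2f)\n",
            sum(sim$truth$responsive), nrow(sim$truth), cfg$coupling))
cat("Wrote matrices, metadata and truth table under", out, "\n")
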