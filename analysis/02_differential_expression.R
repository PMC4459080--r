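#!/usr/bin/env Rscript
# Stage 2: per-time-point log2 fold-changes vs pooled controls, moderated-t
# p-values, BH adjustment within each (condition, time) contrast, and DE
# profile flags (a profile is DE if any of its five time points clears
# FDR < 0.05).

library(profconcord)

data_dir <- "results/data"
mrna <- read_expression_dataset(file.path(data_dir, "mrna_matrix.tsv"),
                                "mrna", file.path(data_dir, "mrna_meta.tsv"))
protein <- read_expression_dataset(file.path(data_dir, "protein_matrix.tsv"),
                                   "protein",
                                   file.path(data_dir, "protein_meta.tsv"))

fc_mrna <- compute_fold_changes(mrna)
fc_prot <- compute_fold_changes(protein)
flags <- flag_de_profiles(fc_mrna, cutoff = 0.05)

write.table(fc_mrna, "results/fold_changes_mrna.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(fc_prot, "results/fold_changes_protein.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(flags, "results/de_flags.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("Fold changes: %d mRNA rows, %d protein rows\n",
            nrow(fc_mrna), nrow(fc_prot)))
cat(sprintf("Dynamic range of mRNA log2 fold-changes: [%.2f, %.2f]\n",
            min(fc_mrna$log_fc), max(fc_mrna$log_fc)))
cat(sprintf("%d of %d (gene, condition) profiles differentially expressed at FDR < 0.05\n",
            sum(flags$de_flag), nrow(flags)))

# how well the flags recover the generator's truth
truth <- read.delim(file.path(data_dir, "truth.tsv"))
resp <- truth$feature[truth$responsive]
cat(sprintf("Flag recall on responsive genes: %.2f; false-positive profiles: %d\n",
            mean(flags$de_flag[flags$feature %in% resp]),
            sum(flags$de_flag & !(flags$feature %in% resp))))
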