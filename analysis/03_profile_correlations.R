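#!/usr/bin/env Rscript
# Stage 3: per-profile mRNA-protein Pearson correlations over the five-point
# time course, the DE vs non-DE distribution-shift tests, and genome-wide
# correlations at three aggregation scales.

library(profconcord)
library(jsonlite)

fc_mrna <- read.delim("results/fold_changes_mrna.tsv")
fc_prot <- read.delim("results/fold_changes_protein.tsv")
flags <- read.delim("results/de_flags.tsv")

cs <- build_correlation_set(fc_mrna, fc_prot, flags)
write.table(cs, "results/profile_correlations.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("%d profile correlations (range %.2f to %.2f)\n",
            nrow(cs), min(cs$r), max(cs$r)))
cat(sprintf("Median r: DE %.3f vs non-DE %.3f\n",
            median(cs$r[cs$de_flag]), median(cs$r[!cs$de_flag])))

shift <- compare_shift(cs)
print(shift)

gw <- lapply(c(all = "all", by_condition = "by_condition", by_gene = "by_gene"),
             function(sc) genome_wide(fc_mrna, fc_prot, sc))
for (sc in names(gw))
  cat(sprintf("Genome-wide (%s): r = %.3f, n = %d, p = %.3g\n",
              sc, gw[[sc]]$r, gw[[sc]]$n, gw[[sc]]$p))

write_json(list(shift = unclass(shift), genome_wide = gw),
           "results/correlation_tests.json", auto_unbox = TRUE, digits = NA,
           pretty = TRUE)
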