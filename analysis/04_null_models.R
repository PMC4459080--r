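#!/usr/bin/env Rscript
# Stage 4: the two bespoke significance models.
#
# (1) Variance-matched simulation: a single shared linear mRNA->protein
#     relationship (OLS over all matched fold-changes); DE profiles draw
#     mRNA values from the higher-variance distribution. 100,000 simulated
#     comparisons give empirical p-values for the observed KS and Wilcoxon
#     statistics — testing whether the DE shift is a dynamic-range artifact.
# (2) Profile-label shuffling: permute the mRNA-protein pairing within the
#     DE (and separately the non-DE) group 1,000 times, pooling the shuffled
#     correlations into the reference distribution.

library(profconcord)
library(jsonlite)

fc_mrna <- read.delim("results/fold_changes_mrna.tsv")
fc_prot <- read.delim("results/fold_changes_protein.tsv")
flags <- read.delim("results/de_flags.tsv")

cs <- build_correlation_set(fc_mrna, fc_prot, flags)
shift <- compare_shift(cs)
pairs <- build_profile_pairs(fc_mrna, fc_prot, flags)

params <- estimate_simple_model_params(fc_mrna, fc_prot, flags)
cat(sprintf("Shared relationship: slope %.3f, intercept %.3f, residual sd %.3f\n",
            params$m, params$b, params$sigma_e))
cat(sprintf("mRNA fold-change sd: DE %.3f (n = %d profiles) vs non-DE %.3f (n = %d)\n",
            params$sd_high, params$n_high, params$sd_low, params$n_low))

simple <- simple_model_pvalues(params, shift$ks_D, shift$wilcoxon_W,
                               n_reps = 100000L, seed = 71)
cat(sprintf("Variance-model empirical p: KS D %.4g, Wilcoxon W %.4g\n",
            simple$D$p_empirical, simple$W$p_empirical))

sh_de <- shuffle_null_test(pairs, "de", n_reps = 1000L, seed = 72)
sh_nd <- shuffle_null_test(pairs, "nonde", n_reps = 1000L, seed = 73)
cat(sprintf("Shuffle null, DE group:     KS p %.4g, Wilcoxon p %.4g\n",
            sh_de$ks_p, sh_de$wilcoxon_p))
cat(sprintf("Shuffle null, non-DE group: KS p %.4g, Wilcoxon p %.4g\n",
            sh_nd$ks_p, sh_nd$wilcoxon_p))

write_json(list(
  simple_model = list(params = unclass(params),
                      p_D = simple$D$p_empirical, p_W = simple$W$p_empirical,
                      n_reps = simple$D$n_reps),
  shuffle_de = sh_de[c("ks_D", "ks_p", "wilcoxon_W", "wilcoxon_p",
                       "n_actual", "n_shuffled")],
  shuffle_nonde = sh_nd[c("ks_D", "ks_p", "wilcoxon_W", "wilcoxon_p",
                          "n_actual", "n_shuffled")]),
  "results/null_models.json", auto_unbox = TRUE, digits = NA, pretty = TRUE)
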