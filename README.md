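# profconcord

Do differentially expressed mRNAs track their protein products better than
mRNAs that are not differentially expressed?

Genome-wide mRNA–protein correlations are famously weak, yet differential
mRNA expression is routinely read as evidence of a protein-level difference
between conditions. This package implements a time-course analysis of that
assumption for experiments where both layers are measured on the same
samples: a panel of genes across several treatment conditions and a
five-point treated time course, with pooled untreated controls per tumour
model (the shape of a two-tumour-model xenograft drug study: 29 genes ×
4 conditions × days 1, 2, 4, 7, 14).

For each gene *g* and condition *c* the pipeline computes log2 fold-change
profiles versus pooled controls on both layers, flags DE mRNA profiles
(moderated t per contrast, Benjamini–Hochberg FDR within each
(condition, time) contrast, a profile is DE if min over its time points of
p<sub>adj</sub> < 0.05), and correlates the mRNA and protein profiles:

&nbsp;&nbsp;r<sub>gc</sub> = cor( mRNA lfc<sub>gc,1..T</sub>, protein lfc<sub>gc,1..T</sub> )&nbsp;&nbsp;(Pearson, T = 5).

The DE and non-DE correlation distributions are compared with two-sample
Kolmogorov–Smirnov and Wilcoxon rank-sum tests, and the comparison is
defended with:

- a **variance-matched simulation null** — one shared linear relationship
  y = m·x + b + e for all genes (OLS fit over all matched fold-changes),
  with mRNA values drawn from the DE-matched high-variance or non-DE-matched
  low-variance distribution; 100,000 simulated comparisons give empirical
  p-values for the observed KS/Wilcoxon statistics, testing whether the
  shift is a dynamic-range artifact;
- a **profile-shuffling null** — the mRNA–protein pairing is permuted within
  the DE (or non-DE) group 1,000 times, keeping time order within profiles,
  and the actual correlations are compared to the pooled shuffled ones;
- an **FDR-cutoff sweep** — the comparison is re-run at cutoffs 0.01–0.50
  (step 0.01) and the p-values regressed on the cutoff; a positive slope
  means the shift sharpens as DE is defined more stringently;
- **genome-wide correlations** at three aggregation scales (all
  measurements, condition means, gene means).

A synthetic-data generator reproduces the experiment's design with known
ground truth (which genes respond; the true latent mRNA–protein coupling),
so the whole pipeline is testable end to end without the original data.

## Worked example

The `analysis/` directory is a numbered workflow over the package; running
it end to end reproduces a complete analysis on the synthetic design:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_differential_expression.R
Rscript analysis/03_profile_correlations.R
Rscript analysis/04_null_models.R
Rscript analysis/05_fdr_sweep.R
```

Output of this workflow (fixed seed 20260919; 12 of 29 genes responsive,
latent coupling 0.7):

```
50 of 116 (gene, condition) profiles differentially expressed at FDR < 0.05
116 profile correlations (range -0.89 to 0.91)
Median r: DE 0.694 vs non-DE -0.052
  KS:       D = 0.8236, p = 5.29e-20
  Wilcoxon: W = 2975, p = 7.679e-14
Variance-model empirical p: KS D 0, Wilcoxon W 4e-05
Shuffle null, DE group:     KS p 0, Wilcoxon p 1.903e-15
Shuffle null, non-DE group: KS p 0.735, Wilcoxon p 0.2947
ks regression: b = 0.0003311, t(48) = 4.41, p = 5.8e-05
```

Reading it: DE profiles correlate far better with their proteins than non-DE
profiles (median r 0.69 vs −0.05; both shift tests reject strongly). The
variance-matched simulation says this is not a dynamic-range artifact — of
100,000 simulated comparisons under a single shared mRNA–protein
relationship, none reached the observed KS D. Shuffling the mRNA–protein
pairing destroys the DE group's correlations (KS p ≈ 0) but leaves the
non-DE group indistinguishable from its shuffled self (p = 0.74 / 0.29):
non-DE correlations carry no pairing-specific signal. The sweep's positive
slope shows the shift strengthening as the FDR cutoff tightens.

The same stages are available programmatically:

```r
library(profconcord)
bundle <- run_pipeline(pipeline_config(synthetic = sim_config(), seed = 1))
bundle$summary$ks_p          # DE-vs-non-DE KS p-value
bundle$simple_null$D         # variance-model empirical null for KS D
bundle$sweep                 # 50-row FDR sweep
```

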