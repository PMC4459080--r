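---
title: "Methods: concordance of differentially expressed mRNA and protein profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: concordance of differentially expressed mRNA and protein profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The question

Genome-wide correlations between mRNA and protein abundance are notoriously
weak, yet differential mRNA expression is routinely treated as a proxy for a
functional — i.e. protein-level — difference between conditions. This package
implements an analysis that tests the assumption directly in a time-course
design: for each gene in each treatment condition, correlate the mRNA and
protein log2 fold-change *profiles* across the treated time points, and ask
whether the profiles of differentially expressed (DE) mRNAs correlate better
with their protein products than those of non-DE mRNAs.

The design it targets is a two-tumour-model xenograft experiment: two drug
regimes per tumour model (four conditions), treated harvests on days 1, 2, 4,
7 and 14, pooled untreated controls per tumour model, and a small panel of
genes (29 by default) measured on both layers — 116 profile pairs in a
complete run.

## Fold-changes and differential expression

For each (gene, condition, time point) the log2 fold-change is the mean over
treated biological replicates minus the mean over that tumour model's pooled
controls. Controls are pooled across their harvest days: untreated tumours
are assumed stationary in distribution over the two-week window, so no
per-day control matching is attempted.

Significance per contrast uses a pooled-variance two-sample t-statistic. By
default the gene-wise variances within a contrast are moderated: sample
variances \(s^2_g\) (residual df \(d\)) are shrunk towards a common prior
\(s_0^2\) with prior df \(d_0\),

\[ \tilde{s}^2_g = \frac{d_0 s_0^2 + d\, s^2_g}{d_0 + d}, \qquad
   t_g = \frac{\hat\beta_g}{\tilde{s}_g\sqrt{1/n_1 + 1/n_0}}, \]

with \(t_g\) referred to a t distribution on \(d + d_0\) df. The prior is
fitted by method of moments on \(\log s^2_g\): the excess of
\(\mathrm{var}(\log s^2_g)\) over the sampling term \(\psi'(d/2)\) determines
\(d_0\) through the trigamma function (inverted by Newton iteration on the
\(1/x\) scale); when the excess is non-positive the prior is degenerate
(\(d_0 = \infty\)) and all genes share one variance. This is the standard
empirical-Bayes moderated t for small-replicate designs; a unit test verifies
it agrees with limma's independent implementation to near machine precision
on a random contrast. `moderation = "none"` exposes the textbook pooled t for
oracle testing. Contrasts with fewer than two replicates on either side keep
their fold-change but get a missing p-value — with one replicate there is no
within-group variance to estimate.

Benjamini–Hochberg adjustment is applied across genes *within each
(condition, time) contrast* — the convention of per-contrast testing — and a
(gene, condition) profile is flagged DE when any of its time points has an
adjusted p-value below the cutoff (0.05 in the main analysis). Flagging by
the minimum over five time points compounds the per-contrast FDR: with
strong signals the profile-level false-discovery proportion is roughly twice
the nominal level. That is a property of the flagging rule, not a defect,
and the robustness sweep (below) is the guard against cutoff-specific
conclusions.

## Profile correlations and the shift tests

Each complete profile pair contributes one Pearson coefficient over its five
time-ordered fold-changes. Profiles with any missing fold-change, or with
zero variance (correlation undefined), are dropped with a warning rather
than imputed — with only five points per profile any imputation would
dominate the statistic. The DE and non-DE correlation distributions are then
compared with a two-sample Kolmogorov–Smirnov test (two-sided; the KS
statistic is direction-blind, and its p-value inherits `stats::ks.test`'s
exact small-sample computation when there are no ties) and a Wilcoxon
rank-sum test, one-sided by default with alternative "DE stochastically
greater", since the scientific claim is a shift towards higher correlations.
Both sidedness choices are arguments. The stored Wilcoxon statistic is the
Mann–Whitney U of the DE group versus the non-DE group.

Genome-wide correlations are computed at three aggregation scales in
fold-change space: all (gene, condition, time) measurements pairwise;
condition means (averaging over time); and gene means (averaging over time
and conditions). Pairs with a missing member are excluded, so a single
missing measurement reduces the `all`-scale n by one while the mean scales
survive isolated gaps.

## The two null models

**Variance-matched simulation.** The DE group's higher correlations could be
a dynamic-range artifact: larger fold-changes mean a higher signal-to-noise
ratio and thus tighter correlations even if every gene shares the same
mRNA–protein relationship. The simulation makes that artifact hypothesis
concrete: a single linear relationship \(y = m x + b + e\),
\(e \sim N(0, \sigma_e^2)\), with \((m, b)\) from an OLS fit of protein on
mRNA fold-change over all matched measurements and \(\sigma_e\) the residual
SD. Each simulated comparison draws `n_high` five-point mRNA profiles from
\(N(\mu_{high}, \sigma_{high})\) (the empirical moments of mRNA fold-changes
in DE profiles) and `n_low` from the non-DE moments, maps them through the
shared relationship, correlates each profile pair, and computes the KS D and
Mann–Whitney U between the two groups of simulated correlations. The
observed statistics are referred to 100,000 such comparisons; the empirical
p-value is the fraction of simulated statistics greater than or equal to the
observed one, exactly the counting rule and with no +1 smoothing by default
(a `plus_one` option exists because the plain count can return 0). Both the
simulated and the observed Wilcoxon statistics use the same U convention, so
the ≥ comparison is well defined.

**Profile-label shuffling.** A distribution-free null for "these particular
pairings matter": permute which mRNA profile is paired with which protein
profile within the selected group (DE or non-DE), keeping every profile's
internal time order, recompute the correlations, repeat 1,000 times, and
pool all shuffled correlations into one reference distribution. The actual
correlations are compared against the pool with the same KS and Wilcoxon
tests. Two modelling choices were genuinely open and are exposed as
arguments with documented defaults: permutations allow fixed points (forcing
derangements would bias the null), and permutations cross conditions —
profiles are (gene, condition) units, and restricting to within-condition
shuffles (`within_condition = TRUE`) shrinks the permutation space
considerably at the default design size. The pooled reference sample is not
independent of the actual sample (fixed points reproduce observed
correlations), which in principle perturbs test calibration; empirically,
over hundreds of decoupled-generator datasets both p-value types are
indistinguishable from uniform, so the pragmatic pooled comparison is kept.

## The FDR-cutoff sweep

The DE definition depends on an arbitrary cutoff, so the whole comparison is
re-run at cutoffs 0.01 to 0.50 in steps of 0.01 (profile correlations are
cutoff-independent and computed once). If the correlation shift is tied to
differential expression, the comparison p-values should fall as the cutoff
tightens: an OLS regression of p-value on cutoff summarises this, reporting
slope, slope t-statistic, residual df (48 when all 50 cutoffs yield defined
tests) and two-sided p. Cutoffs with fewer than ten DE profiles are kept but
marked `small_n` — power, not validity, suffers there — and cutoffs where a
group is empty yield missing p-values with a warning. The cutoff-0.05 row of
the sweep is bit-identical to the standalone main analysis, which the test
suite asserts.

## The synthetic-data generator

The generator stands in for the deposited dataset and defines the study
conditions under which the pipeline is tested. Defaults: 29 genes, four
conditions over two tumour models, treated days {1, 2, 4, 7, 14}, 3 treated
replicates (a protein-layer override exists because protein replicate depth
commonly differs), 4 pooled controls per tumour model, replicate noise SD
0.2, latent effect SD 0.5 — keeping log2 fold-changes mostly within
[−1, 1] — 40% responsive genes, and latent mRNA–protein coupling 0.7 for
responsive genes. The responsive fraction and coupling have no directly
published counterparts; they were fixed once at values that give DE counts
and a correlation shift comparable in character to the motivating
experiment, and they are parameters, not constants.

Each responsive (gene, condition) receives a smooth latent mRNA trajectory —
white noise passed through a short symmetric kernel, centred, scaled to the
effect SD — and a protein trajectory constructed by Gram–Schmidt from the
same curve so the correlation of the two latent five-point trajectories
equals the coupling parameter *exactly*. This makes `coupling` the true
trajectory correlation by construction; replicate noise is then the only
attenuation in the recovered profile correlations, and a test verifies the
mean recovered r lands within 0.05 of the coupling under strong effects.
Non-responsive genes have null mRNA trajectories and independent smooth
protein noise. Replicate measurements add i.i.d. Gaussian noise around
baseline plus trajectory; controls share only the gene baseline. Everything
is deterministic given the config seed.

What the generator does *not* emulate: probe-level microarray structure
(probe collapsing is tested on synthetic probe expansions instead),
immunofluorescence-specific artifacts, missing-value patterns, heterogeneous
replicate counts within a layer, and between-gene baseline correlation.
Latent trajectories are exactly centred over time, so condition- and
gene-mean aggregates carry no cross-layer signal: the generator reproduces
the profile-correlation phenomenon, not the increase of genome-wide
correlation under averaging seen in real data. Passing tests therefore
certify the statistical machinery and its calibration, not biological
realism of any particular dataset.

## Calibration and test design

Two properties anchor the test suite. Under the global-null generator
(no responsive genes, coupling 0) the DE flags derive only from mRNA noise
and are independent of the protein layer, so the shift-test null holds
whatever flag cutoff is used; since almost nothing is flagged at FDR < 0.05
under the null, the calibration test flags at 0.5 to keep both groups
populated and checks the KS rejection rate at nominal 0.05 against its exact
binomial interval over 200 datasets. Second, shuffle-null p-values on the
non-DE group of decoupled data are checked for uniformity over 200 generator
seeds. Signal-recovery tests use coupling 0.9 with effect SD 0.8 and
replicate SD 0.15 — strong but within the design's fold-change range — and
require detection in at least 90% of 100 seeds with the shift always in the
"DE higher" direction.

Problem sizes throughout the suite (dataset counts of 100–200, shuffle reps
of 200–300 in calibration loops, 400–2,000 simulation reps in
self-consistency checks) were chosen to make Monte Carlo standard errors
small relative to the asserted tolerances while keeping the default test run
in the low minutes; the analysis scripts and the acceptance script use the
full 100,000 / 1,000 repetition counts of the main analysis.

## Numerical choices

- KS D inside the simulation null is accumulated in integer multiples of
  \(1/(n_1 n_2)\) so ties cancel exactly; in the degenerate noise-free case
  (\(\sigma_e = 0\)) all simulated correlations are set to sign(m)
  analytically rather than letting floating-point jitter break the ties.
- The trigamma inverse iterates Newton on the \(1/x\) scale (where the
  function is near-linear) to relative tolerance 1e-10.
- Probe collapsing breaks mean-expression ties by the lexicographically
  smallest probe id, making the collapse deterministic.
- Empty groups, all-missing profiles and sub-minimal replicate counts
  degrade to missing values with warnings, never silently; fatal errors are
  reserved for structurally invalid inputs (unmatched sample ids,
  non-numeric cells, profiles shorter than three points).
- Stage seeds in the pipeline are fixed offsets from the base seed, so
  changing one stage's repetition count never perturbs another stage's draw
  sequence.

## Limitations

The moderated t approximates, rather than reproduces, a full limma fit on
real array data (no array weights, no duplicate correlation, one contrast at
a time). Five-point correlations are noisy individually — only their
distributions are compared, and the sample correlation of a five-point
profile is biased slightly towards zero, which attenuates recovered
couplings at high noise. The shuffling null's pooled reference sample
slightly violates independence, as discussed above. And the generator's
clean Gaussian world cannot certify behaviour under real-data pathologies
such as batch structure or heavy-tailed noise.
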