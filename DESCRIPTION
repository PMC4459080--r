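Package: profconcord
Title: Concordance of Differentially Expressed mRNA and Protein Time-Course Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline asking whether mRNAs that are differentially
    expressed under a treatment correlate better with their protein products
    than mRNAs that are not. Computes per-time-point log2 fold-changes of
    treated samples against pooled untreated controls with a moderated
    t-statistic and Benjamini-Hochberg FDR control, builds per-gene,
    per-condition mRNA-protein profile correlations, compares the
    differentially-expressed and non-differentially-expressed correlation
    distributions with Kolmogorov-Smirnov and Wilcoxon tests, and assesses
    significance with two bespoke null models: a variance-matched parametric
    simulation of a single shared mRNA-protein relationship, and Monte Carlo
    shuffling of mRNA-protein profile pairings. Includes an FDR-cutoff
    robustness sweep, genome-wide correlations at three aggregation scales,
    and a synthetic-data generator emulating a two-tumour-model xenograft
    time-course design.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
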