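#' Pipeline configuration
#'
#' Either a set of input paths (expression matrices, metadata, optional probe
#' map) or a synthetic-data [sim_config()] — exactly one of the two.
#'
#' @param input Named list with `mrna`, `protein`, `meta` paths and optional
#'   `probe_map`, or `NULL`.
#' @param synthetic A [sim_config()], or `NULL`.
#' @param fdr_cutoff Main-analysis FDR cutoff (default 0.05).
#' @param moderation Variance moderation for the fold-change t-tests.
#' @param reps_simple Repetitions of the variance-matched simulation null
#'   (default 100000).
#' @param reps_shuffle Repetitions of the profile-shuffling null (default 1000).
#' @param sweep_cutoffs FDR cutoffs for the robustness sweep.
#' @param seed Base integer seed; each stochastic stage derives its own
#'   substream so changing one stage's repetition count does not perturb the
#'   others.
#' @param out_dir Output directory for artifacts, or `NULL` to skip writing.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL, synthetic = NULL,
                            fdr_cutoff = 0.05,
                            moderation = "empirical_bayes",
                            reps_simple = 100000L, reps_shuffle = 1000L,
                            sweep_cutoffs = seq(0.01, 0.50, by = 0.01),
                            seed = 1L, out_dir = NULL) {
  if (is.null(input) == is.null(synthetic))
    stop("supply exactly one of 'input' (paths) or 'synthetic' (sim_config)")
  if (!is.null(synthetic)) stopifnot(inherits(synthetic, "sim_config"))
  structure(list(input = input, synthetic = synthetic,
                 fdr_cutoff = fdr_cutoff, moderation = moderation,
                 reps_simple = as.integer(reps_simple),
                 reps_shuffle = as.integer(reps_shuffle),
                 sweep_cutoffs = sweep_cutoffs,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

# Named seed substreams: fixed offsets from the base seed, kept < 2^31.
.stage_seed <- function(base, stage) {
  offsets <- c(generator = 0L, simple = 101L, shuffle_de = 202L,
               shuffle_nonde = 303L)
  (as.integer(base) + offsets[[stage]]) %% .Machine$integer.max
}

#' Run the full concordance analysis
#'
#' End-to-end orchestration: load or simulate the two expression layers,
#' collapse probes (if a probe map is supplied), compute fold-changes and DE
#' flags, build profile correlations, run the DE-vs-non-DE shift tests, the
#' variance-matched simulation null, the profile-shuffling nulls (DE and
#' non-DE groups), the three genome-wide correlations and the FDR-cutoff
#' sweep with its regressions. Artifacts (fold-change and correlation TSVs,
#' sweep TSV, JSON summary) are written under `config$out_dir` when set.
#'
#' @param config A [pipeline_config()].
#' @return A report bundle (list) with elements `fc_mrna`, `fc_prot`,
#'   `de_flags`, `correlations`, `shift`, `simple_params`, `simple_null`
#'   (`$D`, `$W`), `shuffle_de`, `shuffle_nonde`, `genome_wide` (`$all`,
#'   `$by_condition`, `$by_gene`), `sweep`, `sweep_reg` (`$ks`,
#'   `$wilcoxon`), `truth` (synthetic runs only) and `summary` (flat list of
#'   headline numbers).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  truth <- NULL
  if (!is.null(config$synthetic)) {
    sim_cfg <- config$synthetic
    sim_cfg$seed <- .stage_seed(config$seed, "generator")
    sim <- generate_experiment(sim_cfg)
    mrna <- sim$mrna; protein <- sim$protein; truth <- sim$truth
  } else {
    inp <- config$input
    mrna <- read_expression_dataset(inp$mrna, "mrna", inp$meta)
    protein <- read_expression_dataset(inp$protein, "protein", inp$meta)
    if (!is.null(inp$probe_map))
      mrna <- collapse_probes(mrna, read_probe_map(inp$probe_map))
  }

  fc_mrna <- compute_fold_changes(mrna, moderation = config$moderation)
  fc_prot <- compute_fold_changes(protein, moderation = config$moderation)
  de_flags <- flag_de_profiles(fc_mrna, cutoff = config$fdr_cutoff)
  pairs <- build_profile_pairs(fc_mrna, fc_prot, de_flags)
  cs <- correlation_set(pairs)
  shift <- compare_shift(cs)

  simple_params <- estimate_simple_model_params(fc_mrna, fc_prot, de_flags)
  simple_null <- simple_model_pvalues(
    simple_params, observed_D = shift$ks_D, observed_W = shift$wilcoxon_W,
    n_reps = config$reps_simple, seed = .stage_seed(config$seed, "simple"))

  shuffle_de <- shuffle_null_test(pairs, "de", n_reps = config$reps_shuffle,
                                  seed = .stage_seed(config$seed, "shuffle_de"))
  shuffle_nonde <- shuffle_null_test(pairs, "nonde",
                                     n_reps = config$reps_shuffle,
                                     seed = .stage_seed(config$seed, "shuffle_nonde"))

  gw <- list(all = genome_wide(fc_mrna, fc_prot, "all"),
             by_condition = genome_wide(fc_mrna, fc_prot, "by_condition"),
             by_gene = genome_wide(fc_mrna, fc_prot, "by_gene"))

  sweep <- suppressWarnings(fdr_sweep(fc_mrna, fc_prot, config$sweep_cutoffs))
  sweep_reg <- list(ks = sweep_regression(sweep, "ks"),
                    wilcoxon = sweep_regression(sweep, "wilcoxon"))

  summary <- list(
    n_profiles = nrow(cs), n_de = shift$n_de, n_nonde = shift$n_nonde,
    ks_D = shift$ks_D, ks_p = shift$ks_p,
    wilcoxon_W = shift$wilcoxon_W, wilcoxon_p = shift$wilcoxon_p,
    simple_model_p_D = simple_null$D$p_empirical,
    simple_model_p_W = simple_null$W$p_empirical,
    shuffle_de_ks_p = shuffle_de$ks_p,
    shuffle_de_wilcoxon_p = shuffle_de$wilcoxon_p,
    shuffle_nonde_ks_p = shuffle_nonde$ks_p,
    shuffle_nonde_wilcoxon_p = shuffle_nonde$wilcoxon_p,
    genome_r_all = gw$all$r, genome_n_all = gw$all$n,
    genome_r_by_condition = gw$by_condition$r,
    genome_n_by_condition = gw$by_condition$n,
    genome_r_by_gene = gw$by_gene$r, genome_n_by_gene = gw$by_gene$n,
    sweep_rows = nrow(sweep),
    sweep_ks_slope = sweep_reg$ks$b, sweep_ks_df = sweep_reg$ks$df,
    sweep_wilcoxon_slope = sweep_reg$wilcoxon$b,
    sweep_wilcoxon_df = sweep_reg$wilcoxon$df)

  bundle <- list(fc_mrna = fc_mrna, fc_prot = fc_prot, de_flags = de_flags,
                 pairs = pairs, correlations = cs, shift = shift,
                 simple_params = simple_params, simple_null = simple_null,
                 shuffle_de = shuffle_de, shuffle_nonde = shuffle_nonde,
                 genome_wide = gw, sweep = sweep, sweep_reg = sweep_reg,
                 truth = truth, summary = summary)

  if (!is.null(config$out_dir)) .write_bundle(bundle, config$out_dir)
  bundle
}

.write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f) utils::write.table(
    x, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(bundle$fc_mrna, "fold_changes_mrna.tsv")
  wt(bundle$fc_prot, "fold_changes_protein.tsv")
  wt(bundle$correlations, "profile_correlations.tsv")
  wt(as.data.frame(unclass(bundle$sweep)), "fdr_sweep.tsv")
  if (!is.null(bundle$truth)) wt(bundle$truth, "truth.tsv")
  jsonlite::write_json(bundle$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(NULL)
}
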