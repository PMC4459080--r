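#' FDR-cutoff robustness sweep
#'
#' Re-runs the DE-vs-non-DE correlation comparison across a grid of FDR
#' cutoffs (0.01 to 0.50 in steps of 0.01 by default): at each cutoff the DE
#' profiles are re-flagged and the KS and Wilcoxon shift tests recomputed.
#' The profile correlations themselves do not depend on the cutoff, so they
#' are computed once. Cutoffs where one group is empty yield missing
#' p-values with a warning; cutoffs with fewer than ten DE profiles are
#' flagged (`small_n`) but kept, since reduced test power at such cutoffs is
#' itself informative.
#'
#' @param fc_mrna,fc_prot `FoldChangeTable`s for the two layers.
#' @param cutoffs Strictly increasing vector of FDR cutoffs.
#' @return A `SweepResult` data frame: `cutoff`, `n_de`, `n_nonde`, `ks_p`,
#'   `wilcoxon_p`, `small_n`.
#' @export
fdr_sweep <- function(fc_mrna, fc_prot, cutoffs = seq(0.01, 0.50, by = 0.01)) {
  if (!length(cutoffs)) stop("empty cutoff vector")
  if (is.unsorted(cutoffs, strictly = TRUE)) stop("cutoffs must be strictly increasing")
  # flag at a permissive cutoff once to fix the profile set, then re-threshold
  flags_all <- flag_de_profiles(fc_mrna, cutoff = 0.999999)
  cs0 <- suppressWarnings(build_correlation_set(fc_mrna, fc_prot, flags_all))
  min_p <- stats::setNames(flags_all$min_p_adj,
                           paste(flags_all$feature, flags_all$condition, sep = "\r"))
  key <- paste(cs0$feature, cs0$condition, sep = "\r")
  rows <- lapply(cutoffs, function(cut) {
    cs <- cs0
    cs$de_flag <- unname(min_p[key]) < cut
    st <- suppressWarnings(compare_shift(cs))
    data.frame(cutoff = cut, n_de = st$n_de, n_nonde = st$n_nonde,
               ks_p = st$ks_p, wilcoxon_p = st$wilcoxon_p,
               small_n = st$n_de < 10)
  })
  res <- do.call(rbind, rows)
  if (anyNA(res$ks_p))
    warning(sum(is.na(res$ks_p)), " cutoff(s) with an empty group; p-values missing",
            call. = FALSE)
  class(res) <- c("SweepResult", "data.frame")
  res
}

#' Regression of sweep p-values on FDR cutoff
#'
#' Ordinary least-squares fit of the shift-test p-value on the FDR cutoff
#' across the sweep. A positive slope — p-values falling as the cutoff
#' tightens — indicates the DE-correlation shift strengthens for more
#' stringently defined DE profiles, i.e. the phenomenon is tied to
#' differential expression rather than to a particular cutoff.
#'
#' @param sweep A `SweepResult`.
#' @param which `"ks"` or `"wilcoxon"`.
#' @return List with slope `b`, `t_stat`, residual `df`, two-sided `p`.
#' @export
sweep_regression <- function(sweep, which = c("ks", "wilcoxon")) {
  which <- match.arg(which)
  pcol <- if (which == "ks") sweep$ks_p else sweep$wilcoxon_p
  ok <- !is.na(pcol)
  if (sum(ok) < 3) stop("need >= 3 non-missing p-values for the regression")
  fit <- stats::lm(pcol[ok] ~ sweep$cutoff[ok])
  sm <- summary(fit)$coefficients
  list(b = unname(sm[2, "Estimate"]),
       t_stat = unname(sm[2, "t value"]),
       df = fit$df.residual,
       p = unname(sm[2, "Pr(>|t|)"]))
}
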