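#' Pearson product-moment correlation of two profiles
#'
#' Thin validated wrapper around the standard product-moment coefficient for
#' time-ordered fold-change profiles. Profiles shorter than 3 points or with
#' zero variance have no defined correlation and return `NA` (callers drop
#' such records with a warning rather than impute).
#'
#' @param x,y Numeric vectors of equal length >= 3, identically time-ordered.
#' @return The correlation coefficient, or `NA` if either vector is constant.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("profiles must have equal length")
  if (length(x) < 3) stop("profiles must have length >= 3")
  if (anyNA(x) || anyNA(y)) return(NA_real_)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Build aligned mRNA-protein profile pairs
#'
#' Joins the two layers' fold-change tables on (feature, condition,
#' time_point) and assembles, for every (gene, condition), the pair of
#' time-ordered log fold-change vectors plus its differential-expression
#' flag. Profiles with any missing fold-change on either layer, or not
#' covered by both layers at all time points, are dropped with a warning.
#'
#' @param mrna_fc,prot_fc `FoldChangeTable`s for the two layers.
#' @param de_flags Output of [flag_de_profiles()] (mRNA layer).
#' @return A list of class `profile_pairs`; each element has `feature`,
#'   `condition`, `mrna_lfc`, `protein_lfc` (equal-length time-ordered
#'   vectors) and `de_flag`.
#' @export
build_profile_pairs <- function(mrna_fc, prot_fc, de_flags) {
  m <- merge(mrna_fc[, c("feature", "condition", "time_point", "log_fc")],
             prot_fc[, c("feature", "condition", "time_point", "log_fc")],
             by = c("feature", "condition", "time_point"),
             suffixes = c("_mrna", "_prot"))
  m <- m[order(m$feature, m$condition, m$time_point), , drop = FALSE]
  tp_all <- sort(unique(c(mrna_fc$time_point, prot_fc$time_point)))
  flags <- stats::setNames(de_flags$de_flag,
                           paste(de_flags$feature, de_flags$condition, sep = "\r"))
  keys <- unique(m[, c("feature", "condition")])
  pairs <- list()
  n_dropped <- 0L
  for (i in seq_len(nrow(keys))) {
    sub <- m[m$feature == keys$feature[i] & m$condition == keys$condition[i], ,
             drop = FALSE]
    k <- paste(keys$feature[i], keys$condition[i], sep = "\r")
    complete <- nrow(sub) == length(tp_all) &&
      !anyNA(sub$log_fc_mrna) && !anyNA(sub$log_fc_prot) && k %in% names(flags)
    if (!complete) { n_dropped <- n_dropped + 1L; next }
    pairs[[length(pairs) + 1L]] <- list(
      feature = keys$feature[i], condition = keys$condition[i],
      mrna_lfc = sub$log_fc_mrna, protein_lfc = sub$log_fc_prot,
      time_point = sub$time_point, de_flag = unname(flags[k]))
  }
  if (n_dropped > 0)
    warning(n_dropped, " incomplete profile(s) dropped", call. = FALSE)
  structure(pairs, class = "profile_pairs")
}

#' Per-profile correlations partitioned by DE status
#'
#' Computes one Pearson coefficient per (gene, condition) profile pair over
#' the time-ordered fold-changes; constant profiles (undefined correlation)
#' are dropped with a warning.
#'
#' @param mrna_fc,prot_fc `FoldChangeTable`s for the two layers.
#' @param de_flags Output of [flag_de_profiles()].
#' @return A `CorrelationSet`: data frame with columns `feature`,
#'   `condition`, `r`, `de_flag`.
#' @export
build_correlation_set <- function(mrna_fc, prot_fc, de_flags) {
  pairs <- build_profile_pairs(mrna_fc, prot_fc, de_flags)
  correlation_set(pairs)
}

#' @rdname build_correlation_set
#' @param pairs A `profile_pairs` object.
#' @export
correlation_set <- function(pairs) {
  if (!length(pairs)) stop("no complete profile pairs")
  r <- vapply(pairs, function(p) pearson_r(p$mrna_lfc, p$protein_lfc), numeric(1))
  cs <- data.frame(feature = vapply(pairs, `[[`, character(1), "feature"),
                   condition = vapply(pairs, `[[`, character(1), "condition"),
                   r = r,
                   de_flag = vapply(pairs, `[[`, logical(1), "de_flag"),
                   stringsAsFactors = FALSE)
  if (anyNA(cs$r)) {
    warning(sum(is.na(cs$r)), " constant profile(s) dropped (correlation undefined)",
            call. = FALSE)
    cs <- cs[!is.na(cs$r), , drop = FALSE]
  }
  rownames(cs) <- NULL
  class(cs) <- c("CorrelationSet", "data.frame")
  cs
}

#' Compare DE and non-DE correlation distributions
#'
#' Two-sample Kolmogorov-Smirnov test (two-sided by default) and Wilcoxon
#' rank-sum test (one-sided by default, alternative "DE stochastically
#' greater") of the per-profile correlations of differentially expressed
#' versus non-differentially expressed mRNA profiles. The Wilcoxon statistic
#' is the Mann-Whitney U of the DE group versus the non-DE group. If either
#' group is empty the p-values are `NA` with a warning (this happens at
#' extreme FDR cutoffs in the robustness sweep).
#'
#' @param cs A `CorrelationSet`.
#' @param ks_alternative,wilcox_alternative Alternatives passed to
#'   [stats::ks.test()] and [stats::wilcox.test()]; defaults `"two.sided"`
#'   and `"greater"`.
#' @return A `ShiftTestResult`: list with `ks_D`, `ks_p`, `wilcoxon_W`,
#'   `wilcoxon_p`, `n_de`, `n_nonde`.
#' @export
compare_shift <- function(cs, ks_alternative = "two.sided",
                          wilcox_alternative = "greater") {
  de <- cs$r[cs$de_flag]
  nd <- cs$r[!cs$de_flag]
  res <- list(ks_D = NA_real_, ks_p = NA_real_,
              wilcoxon_W = NA_real_, wilcoxon_p = NA_real_,
              n_de = length(de), n_nonde = length(nd))
  if (!length(de) || !length(nd)) {
    warning("empty group (n_de = ", length(de), ", n_nonde = ", length(nd),
            "); shift tests undefined", call. = FALSE)
    class(res) <- "ShiftTestResult"
    return(res)
  }
  ks <- suppressWarnings(stats::ks.test(de, nd, alternative = ks_alternative))
  wt <- suppressWarnings(stats::wilcox.test(de, nd,
                                            alternative = wilcox_alternative))
  res$ks_D <- unname(ks$statistic)
  res$ks_p <- ks$p.value
  res$wilcoxon_W <- unname(wt$statistic)
  res$wilcoxon_p <- wt$p.value
  class(res) <- "ShiftTestResult"
  res
}

#' @export
print.ShiftTestResult <- function(x, ...) {
  cat(sprintf("DE vs non-DE correlation shift (n_de = %d, n_nonde = %d)\n",
              x$n_de, x$n_nonde))
  cat(sprintf("  KS:       D = %.4g, p = %.4g\n", x$ks_D, x$ks_p))
  cat(sprintf("  Wilcoxon: W = %.4g, p = %.4g\n", x$wilcoxon_W, x$wilcoxon_p))
  invisible(x)
}

#' Genome-wide mRNA-protein correlation
#'
#' A single Pearson coefficient pooling all genes, at one of three
#' aggregation scales: `"all"` pairs every (gene, condition, time point)
#' fold-change; `"by_condition"` first averages fold-changes over time within
#' each (gene, condition); `"by_gene"` averages over all time points and
#' conditions per gene. Pairs with a missing value on either layer are
#' excluded from `n`.
#'
#' @param mrna_fc,prot_fc `FoldChangeTable`s for the two layers.
#' @param scale One of `"all"`, `"by_condition"`, `"by_gene"`.
#' @return List with `r`, `n` and two-sided `p`.
#' @export
genome_wide <- function(mrna_fc, prot_fc,
                        scale = c("all", "by_condition", "by_gene")) {
  scale <- match.arg(scale)
  m <- merge(mrna_fc[, c("feature", "condition", "time_point", "log_fc")],
             prot_fc[, c("feature", "condition", "time_point", "log_fc")],
             by = c("feature", "condition", "time_point"),
             suffixes = c("_mrna", "_prot"))
  mean_narm <- function(v) mean(v, na.rm = TRUE)  # a mean survives isolated gaps
  if (scale == "by_condition") {
    m <- stats::aggregate(cbind(log_fc_mrna, log_fc_prot) ~ feature + condition,
                          data = m, FUN = mean_narm, na.action = stats::na.pass)
  } else if (scale == "by_gene") {
    m <- stats::aggregate(cbind(log_fc_mrna, log_fc_prot) ~ feature,
                          data = m, FUN = mean_narm, na.action = stats::na.pass)
  }
  ok <- is.finite(m$log_fc_mrna) & is.finite(m$log_fc_prot)
  x <- m$log_fc_mrna[ok]; y <- m$log_fc_prot[ok]
  if (length(x) < 3) stop("fewer than 3 matched fold-change pairs at scale ", scale)
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), n = length(x), p = ct$p.value)
}
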