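#' Per-time-point log fold-changes against pooled controls
#'
#' For every gene, condition and treated time point, computes the log2
#' fold-change as mean(treated replicates) - mean(pooled controls of the
#' condition's tumour model), together with a two-sample pooled-variance
#' t-test p-value. Controls are pooled per tumour model across their harvest
#' days; no per-day control matching is attempted. With
#' `moderation = "empirical_bayes"` (the default) gene-wise variances within
#' each (condition, time) contrast are shrunk towards a common prior fitted
#' across genes — a Smyth-style moderated t with the prior degrees of freedom
#' estimated by method of moments on the log sample variances — which keeps
#' zero-variance genes testable and stabilises small-replicate contrasts.
#' `moderation = "none"` gives the textbook pooled-variance t-test.
#'
#' Contrasts with fewer than 2 replicates on either side get `NA` p-values
#' with a warning (the fold-change is still reported when at least one
#' replicate exists per side). Benjamini-Hochberg adjustment is applied
#' across genes within each (condition, time) contrast.
#'
#' @param dataset An [expression_dataset()].
#' @param moderation `"empirical_bayes"` or `"none"`.
#' @return A `FoldChangeTable`: data frame with columns `feature`,
#'   `condition`, `time_point`, `log_fc`, `p_raw`, `p_adj`, ordered by
#'   condition, time, feature.
#' @export
compute_fold_changes <- function(dataset,
                                 moderation = c("empirical_bayes", "none")) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  moderation <- match.arg(moderation)
  meta <- dataset$samples
  vals <- dataset$values
  conds <- sort(setdiff(unique(meta$condition), "CONTROL"))
  if (!length(conds)) stop("dataset has no treated conditions")
  out <- list()
  warned <- FALSE
  for (cond in conds) {
    model <- unique(meta$tumour_model[meta$condition == cond])
    if (length(model) != 1)
      stop("condition ", cond, " maps to several tumour models")
    ctrl_ids <- meta$sample_id[meta$condition == "CONTROL" &
                                 meta$tumour_model == model]
    tps <- sort(unique(meta$time_point[meta$condition == cond]))
    for (tp in tps) {
      trt_ids <- meta$sample_id[meta$condition == cond & meta$time_point == tp]
      n1 <- length(trt_ids); n0 <- length(ctrl_ids)
      trt <- vals[, trt_ids, drop = FALSE]
      ctl <- vals[, ctrl_ids, drop = FALSE]
      lfc <- rowMeans(trt, na.rm = TRUE) - rowMeans(ctl, na.rm = TRUE)
      if (n1 < 2 || n0 < 2) {
        if (!warned) {
          warning("contrast ", cond, " day ", tp, " has < 2 replicates on one side; ",
                  "p-values set to NA", call. = FALSE)
          warned <- TRUE
        }
        p <- rep(NA_real_, nrow(vals))
      } else {
        ss1 <- rowSums((trt - rowMeans(trt))^2)
        ss0 <- rowSums((ctl - rowMeans(ctl))^2)
        df <- n1 + n0 - 2
        s2 <- (ss1 + ss0) / df
        if (moderation == "empirical_bayes") {
          sq <- .squeeze_var(s2, df)
          s2_post <- sq$s2_post
          df_total <- df + sq$df_prior
        } else {
          s2_post <- s2
          df_total <- df
        }
        se <- sqrt(s2_post * (1 / n1 + 1 / n0))
        tstat <- lfc / se
        p <- 2 * stats::pt(-abs(tstat), df = df_total)
        p[se == 0] <- NA_real_  # all-zero variance with no moderation
      }
      out[[length(out) + 1L]] <- data.frame(
        feature = rownames(vals), condition = cond, time_point = tp,
        log_fc = unname(lfc), p_raw = unname(p),
        p_adj = unname(adjust_fdr(p)),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Shrink gene-wise sample variances towards a common prior (shared residual
# df). Hierarchical model: s2 | sigma2 ~ sigma2 * chisq(df)/df and
# 1/sigma2 ~ (1/(d0*s0^2)) * chisq(d0), so log(s2) has excess variance
# trigamma(d0/2) beyond the sampling term trigamma(df/2). Method of moments
# on z = log(s2): solve trigamma(d0/2) = var(z) - trigamma(df/2); if the
# excess is non-positive the prior is degenerate (d0 = Inf) and every
# variance is replaced by the common value.
.squeeze_var <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2) {
    s0 <- mean(s2[is.finite(s2)])
    if (!is.finite(s0) || s0 <= 0) s0 <- 1e-8
    return(list(s2_post = rep(s0, length(s2)), df_prior = Inf, s2_prior = s0))
  }
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  ev <- stats::var(z) - trigamma(df / 2)
  if (is.na(ev) || ev <= 0) {
    d0 <- Inf
    s0 <- exp(mean(e))
  } else {
    d0 <- 2 * .trigamma_inverse(ev)
    s0 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  }
  s2_filled <- ifelse(ok, s2, 0)  # zero-variance genes shrink fully to prior
  if (is.infinite(d0)) {
    post <- rep(s0, length(s2))
  } else {
    post <- (d0 * s0 + df * s2_filled) / (d0 + df)
  }
  list(s2_post = post, df_prior = d0, s2_prior = s0)
}

# Newton iteration for the inverse of trigamma, on the 1/x scale where
# trigamma is nearly linear (trigamma(x) ~ 1/x for large x).
.trigamma_inverse <- function(y) {
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2)
    x <- x + dif
    if (abs(dif) / x < 1e-10) break
  }
  x
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up adjusted p-values (monotone in rank, capped at 1).
#' `NA` values are passed through untouched and do not count towards the
#' number of tests.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\] (`NA` allowed).
#' @return Adjusted p-values, same length and order.
#' @export
adjust_fdr <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1))
    stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p_values))
  out[ok] <- stats::p.adjust(p_values[ok], method = "BH")
  out
}

#' Flag differentially expressed profiles
#'
#' A (gene, condition) profile is flagged as differentially expressed when
#' its adjusted p-value falls below `cutoff` at any treated time point.
#' Profiles whose p-values are all missing are excluded with a message.
#'
#' @param fc A `FoldChangeTable` (mRNA layer).
#' @param cutoff FDR cutoff in (0, 1) (default 0.05).
#' @return Data frame with columns `feature`, `condition`, `de_flag`,
#'   `min_p_adj`.
#' @export
flag_de_profiles <- function(fc, cutoff = 0.05) {
  if (cutoff <= 0 || cutoff >= 1) stop("cutoff must be in (0, 1)")
  key <- paste(fc$feature, fc$condition, sep = "\r")
  min_p <- tapply(fc$p_adj, key, function(p)
    if (all(is.na(p))) NA_real_ else min(p, na.rm = TRUE))
  info <- do.call(rbind, strsplit(names(min_p), "\r", fixed = TRUE))
  res <- data.frame(feature = info[, 1], condition = info[, 2],
                    min_p_adj = as.numeric(min_p), stringsAsFactors = FALSE)
  dropped <- is.na(res$min_p_adj)
  if (any(dropped)) {
    message(sum(dropped), " profile(s) dropped: all p-values missing")
    res <- res[!dropped, , drop = FALSE]
  }
  res$de_flag <- res$min_p_adj < cutoff
  rownames(res) <- NULL
  res[, c("feature", "condition", "de_flag", "min_p_adj")]
}
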