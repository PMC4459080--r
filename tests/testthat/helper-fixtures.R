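# Shared fixtures and independent oracles. Every oracle here is written from
# the textbook definition, independent of the package's code paths.

# Two-group single-contrast dataset: ng genes, treated at one time point vs
# controls of one tumour model.
two_group_dataset <- function(trt, ctl, condition = "drug", model = "M1",
                              layer = "mrna", time_point = 1) {
  vals <- cbind(trt, ctl)
  if (is.null(rownames(vals))) rownames(vals) <- sprintf("G%03d", seq_len(nrow(vals)))
  colnames(vals) <- c(sprintf("T%d", seq_len(ncol(trt))),
                      sprintf("C%d", seq_len(ncol(ctl))))
  meta <- data.frame(
    sample_id = colnames(vals),
    condition = c(rep(condition, ncol(trt)), rep("CONTROL", ncol(ctl))),
    tumour_model = model,
    time_point = c(rep(time_point, ncol(trt)), rep(0, ncol(ctl))),
    replicate = c(seq_len(ncol(trt)), seq_len(ncol(ctl))))
  expression_dataset(vals, meta, layer)
}

# Fold-change table built directly from a feature x time matrix of lfc values
# for one condition (p-values optional).
fc_table <- function(lfc, condition = "cond1", time_points = seq_len(ncol(lfc)),
                     p_adj = NA_real_) {
  if (is.null(rownames(lfc))) rownames(lfc) <- sprintf("G%03d", seq_len(nrow(lfc)))
  df <- expand.grid(feature = rownames(lfc), time_idx = seq_len(ncol(lfc)),
                    stringsAsFactors = FALSE)
  data.frame(feature = df$feature, condition = condition,
             time_point = time_points[df$time_idx],
             log_fc = lfc[cbind(match(df$feature, rownames(lfc)), df$time_idx)],
             p_raw = rep_len(p_adj, nrow(df)), p_adj = rep_len(p_adj, nrow(df)),
             stringsAsFactors = FALSE)
}

flag_table <- function(features, condition, de) {
  data.frame(feature = features, condition = condition, de_flag = de,
             min_p_adj = ifelse(de, 0.01, 0.5), stringsAsFactors = FALSE)
}

# Textbook Benjamini-Hochberg step-up, written independently of p.adjust.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 1
  for (i in m:1) {
    running <- min(running, m * p[o[i]] / i)
    adj[o[i]] <- running
  }
  pmin(adj, 1)
}

# Exhaustive two-sample enumeration null: exact P(D >= d) and exact one-sided
# rank-sum p for small samples without ties.
enum_ks_wilcox <- function(x, y) {
  pool <- c(x, y)
  n1 <- length(x); n <- length(pool)
  ksD <- function(a, b) {
    g <- sort(unique(c(a, b)))
    max(abs(vapply(g, function(v) mean(a <= v) - mean(b <= v), numeric(1))))
  }
  U <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  obsD <- ksD(x, y); obsU <- U(x, y)
  idx <- utils::combn(n, n1)
  Ds <- apply(idx, 2, function(i) ksD(pool[i], pool[-i]))
  Us <- apply(idx, 2, function(i) U(pool[i], pool[-i]))
  list(D = obsD, U = obsU,
       p_D = mean(Ds >= obsD - 1e-12),
       p_U_greater = mean(Us >= obsU - 1e-12))
}

# Closed-form simple linear regression: slope, intercept, slope t-stat, p.
ols_oracle <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  b1 <- sum((x - mean(x)) * (y - mean(y))) / sxx
  b0 <- mean(y) - b1 * mean(x)
  res <- y - b0 - b1 * x
  s2 <- sum(res^2) / (n - 2)
  tstat <- b1 / sqrt(s2 / sxx)
  list(b0 = b0, b1 = b1, t = tstat, df = n - 2,
       p = 2 * stats::pt(-abs(tstat), n - 2), residuals = res)
}

default_null_cfg <- function(seed) generate_null_experiment(sim_config(seed = seed))

# Run generator -> fold changes -> flags -> correlation set in one step.
quick_correlations <- function(sim, cutoff = 0.05) {
  fm <- compute_fold_changes(sim$mrna)
  fp <- compute_fold_changes(sim$protein)
  fl <- flag_de_profiles(fm, cutoff = cutoff)
  suppressWarnings(build_correlation_set(fm, fp, fl))
}
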