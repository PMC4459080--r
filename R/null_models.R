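# Fast statistic-only kernels used inside the 100,000-repetition simulation
# null, where ks.test()/wilcox.test() object construction would dominate.
# Both are cross-checked against the stats functions in the test suite.

# Two-sample Kolmogorov-Smirnov D = sup |F1 - F2|, tie-aware. Steps are
# accumulated in integer multiples of 1/(n1*n2) so ties cancel exactly.
.ks_D <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  w <- c(x, y)
  ord <- order(w)
  steps <- cumsum(ifelse(ord <= n1, n2, -n1))
  ws <- w[ord]
  keep <- c(ws[-1] != ws[-length(ws)], TRUE)  # evaluate after each distinct value
  max(abs(steps[keep])) / (n1 * n2)
}

# Mann-Whitney U of x vs y (number of (x_i, y_j) pairs with x_i > y_j,
# ties counting 1/2) — the convention wilcox.test calls W.
.mw_U <- function(x, y) {
  n1 <- length(x)
  r <- rank(c(x, y))
  sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
}

# Column-wise Pearson correlation of two T x K matrices.
.col_cor <- function(X, Y) {
  Xc <- sweep(X, 2, colMeans(X))
  Yc <- sweep(Y, 2, colMeans(Y))
  num <- colSums(Xc * Yc)
  den <- sqrt(colSums(Xc^2) * colSums(Yc^2))
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

#' Estimate the shared-relationship variance-model parameters
#'
#' The variance-matched simulation models every gene's protein fold-change as
#' a single shared linear function of its mRNA fold-change,
#' `y = m * x + b + e` with Gaussian noise `e`, and asks whether the higher
#' correlations of DE profiles could be a dynamic-range artifact: DE profiles
#' draw their mRNA values from a higher-variance distribution than non-DE
#' profiles, but the mRNA-protein relationship is identical. This estimates
#' all parameters from the data: `(m, b)` by ordinary least squares of
#' protein on mRNA fold-change over all matched measurements, `sigma_e` as
#' the SD of the OLS residuals, and the high/low-variance mRNA distributions
#' as the mean/SD of mRNA fold-changes belonging to DE and non-DE profiles
#' respectively.
#'
#' @param mrna_fc,prot_fc `FoldChangeTable`s for the two layers.
#' @param de_flags Output of [flag_de_profiles()].
#' @return A `SimpleModelParams` list: `m`, `b`, `sigma_e`, `mu_high`,
#'   `sd_high`, `mu_low`, `sd_low`, `n_high`, `n_low` (profile counts),
#'   `T` (profile length).
#' @export
estimate_simple_model_params <- function(mrna_fc, prot_fc, de_flags) {
  mm <- merge(mrna_fc[, c("feature", "condition", "time_point", "log_fc")],
              prot_fc[, c("feature", "condition", "time_point", "log_fc")],
              by = c("feature", "condition", "time_point"),
              suffixes = c("_mrna", "_prot"))
  ok <- is.finite(mm$log_fc_mrna) & is.finite(mm$log_fc_prot)
  mm <- mm[ok, , drop = FALSE]
  if (nrow(mm) < 3) stop("fewer than 3 matched fold-change pairs")
  fit <- stats::lm(log_fc_prot ~ log_fc_mrna, data = mm)
  flags <- stats::setNames(de_flags$de_flag,
                           paste(de_flags$feature, de_flags$condition, sep = "\r"))
  key <- paste(mm$feature, mm$condition, sep = "\r")
  de <- unname(flags[key])
  x_hi <- mm$log_fc_mrna[de %in% TRUE]
  x_lo <- mm$log_fc_mrna[de %in% FALSE]
  if (length(x_hi) < 2 || length(x_lo) < 2)
    stop("need at least one DE and one non-DE profile with >= 2 measurements")
  prof_de <- de[!duplicated(key)]
  tlen <- length(unique(mm$time_point))
  structure(list(m = unname(stats::coef(fit)[2]),
                 b = unname(stats::coef(fit)[1]),
                 sigma_e = stats::sd(stats::residuals(fit)),
                 mu_high = mean(x_hi), sd_high = stats::sd(x_hi),
                 mu_low = mean(x_lo), sd_low = stats::sd(x_lo),
                 n_high = sum(prof_de %in% TRUE),
                 n_low = sum(prof_de %in% FALSE),
                 T = tlen),
            class = "SimpleModelParams")
}

# Vectorised engine: simulate n_reps independent comparisons and return the
# KS D and Mann-Whitney U (high vs low) of each. Each comparison draws
# n_high profiles of T mRNA values from N(mu_high, sd_high) and n_low from
# N(mu_low, sd_low), maps them through y = m x + b + N(0, sigma_e), and
# correlates x with y per profile.
.simple_model_stats <- function(params, n_reps, chunk = 2000L) {
  p <- params
  P <- p$n_high + p$n_low
  mu <- rep(c(p$mu_high, p$mu_low), c(p$n_high, p$n_low))
  sdv <- rep(c(p$sd_high, p$sd_low), c(p$n_high, p$n_low))
  D <- numeric(n_reps); U <- numeric(n_reps)
  hi <- seq_len(p$n_high)
  lo <- p$n_high + seq_len(p$n_low)
  done <- 0L
  while (done < n_reps) {
    k <- min(chunk, n_reps - done)
    ncol_ <- P * k
    mu_col <- rep(mu, k); sd_col <- rep(sdv, k)
    X <- matrix(stats::rnorm(p$T * ncol_, mean = rep(mu_col, each = p$T),
                             sd = rep(sd_col, each = p$T)),
                nrow = p$T)
    Y <- p$m * X + p$b +
      matrix(stats::rnorm(p$T * ncol_, 0, p$sigma_e), nrow = p$T)
    r <- matrix(.col_cor(X, Y), nrow = P)
    # degenerate exact-fit case: correlations are sign(m) by construction;
    # avoid floating-point jitter breaking the ties
    if (p$sigma_e == 0) r[] <- sign(p$m)
    for (j in seq_len(k)) {
      rj <- r[, j]
      D[done + j] <- .ks_D(rj[hi], rj[lo])
      U[done + j] <- .mw_U(rj[hi], rj[lo])
    }
    done <- done + k
  }
  list(D = D, U = U)
}

#' One comparison from the variance-matched simulation null
#'
#' Simulates one full dataset-sized comparison under the shared-relationship
#' model — `n_high` high-variance and `n_low` low-variance profiles, each of
#' `T` points — and returns the two-sample KS D and Mann-Whitney U between
#' the two groups of simulated profile correlations.
#'
#' @param params A `SimpleModelParams`.
#' @param rng_seed Integer seed.
#' @return List with `ks_D` and `wilcoxon_W` (Mann-Whitney U, high vs low).
#' @export
simple_model_comparison <- function(params, rng_seed) {
  stopifnot(inherits(params, "SimpleModelParams"))
  set.seed(rng_seed)
  s <- .simple_model_stats(params, 1L)
  list(ks_D = s$D, wilcoxon_W = s$U)
}

#' Empirical p-values from the variance-matched simulation null
#'
#' Repeats the simulated comparison `n_reps` times (100,000 by default) and
#' reports, for each statistic independently, the empirical p-value: the
#' fraction of simulated statistics greater than or equal to the observed
#' one. By default no +1 smoothing is applied, so the p-value can be exactly
#' zero; `plus_one = TRUE` uses (count + 1) / (n_reps + 1) instead.
#'
#' @param params A `SimpleModelParams`.
#' @param observed_D Observed two-sample KS D between the DE and non-DE
#'   correlation distributions.
#' @param observed_W Observed Mann-Whitney U (DE vs non-DE), same convention
#'   as the simulated statistic.
#' @param n_reps Number of simulated comparisons (default 100000).
#' @param seed Integer seed.
#' @param plus_one Apply +1 smoothing to the empirical p-value.
#' @return List with two `NullResult`s, `D` and `W`. Each `NullResult` holds
#'   `observed`, `null_sample`, `p_empirical`, `n_reps`.
#' @export
simple_model_pvalues <- function(params, observed_D, observed_W,
                                 n_reps = 100000L, seed, plus_one = FALSE) {
  stopifnot(inherits(params, "SimpleModelParams"), n_reps >= 1)
  set.seed(seed)
  s <- .simple_model_stats(params, as.integer(n_reps))
  list(D = null_result(observed_D, s$D, plus_one = plus_one),
       W = null_result(observed_W, s$U, plus_one = plus_one))
}

#' Construct an empirical-null result
#'
#' @param observed Observed statistic.
#' @param null_sample Vector of null-model statistics.
#' @param plus_one Apply +1 smoothing.
#' @return A `NullResult` list: `observed`, `null_sample`, `p_empirical`,
#'   `n_reps`.
#' @export
null_result <- function(observed, null_sample, plus_one = FALSE) {
  n <- length(null_sample)
  cnt <- sum(null_sample >= observed)
  p <- if (plus_one) (cnt + 1) / (n + 1) else cnt / n
  structure(list(observed = observed, null_sample = null_sample,
                 p_empirical = p, n_reps = n),
            class = "NullResult")
}

#' @export
print.NullResult <- function(x, ...) {
  cat(sprintf("NullResult: observed = %.4g, p_empirical = %.4g (%d reps)\n",
              x$observed, x$p_empirical, x$n_reps))
  invisible(x)
}

#' Shuffle mRNA-protein profile pairings
#'
#' One shuffling event permutes the mRNA labels across whole profiles: each
#' profile keeps its internal time order, but which mRNA vector is paired
#' with which protein vector is randomised uniformly (fixed points allowed).
#' The multiset of mRNA vectors is conserved.
#'
#' @param profiles A `profile_pairs` object (or plain list of profile pairs),
#'   length >= 2.
#' @param rng_seed Integer seed.
#' @return A `profile_pairs` object with the mRNA vectors permuted.
#' @export
shuffle_profiles <- function(profiles, rng_seed) {
  if (length(profiles) < 2) stop("need >= 2 profiles to shuffle")
  set.seed(rng_seed)
  perm <- sample.int(length(profiles))
  out <- profiles
  for (i in seq_along(profiles)) out[[i]]$mrna_lfc <- profiles[[perm[i]]]$mrna_lfc
  out
}

#' Monte Carlo profile-shuffling null for one DE group
#'
#' Restricts to the profiles of the selected group (DE or non-DE), shuffles
#' the mRNA-protein pairing within that group `n_reps` times (1,000 by
#' default), recomputes the profile correlations after every shuffle, pools
#' all shuffled correlations into one reference distribution, and compares
#' the actual group correlations against it with KS and Wilcoxon tests
#' (alternative for Wilcoxon: actual greater, configurable). By default the
#' permutation crosses conditions — profiles are (gene, condition) units;
#' `within_condition = TRUE` restricts shuffling to profiles of the same
#' condition.
#'
#' @param profiles A `profile_pairs` object carrying `de_flag`s.
#' @param group `"de"` or `"nonde"`.
#' @param n_reps Number of shuffles (default 1000).
#' @param seed Integer seed.
#' @param wilcox_alternative Alternative for the Wilcoxon test (default
#'   `"greater"`).
#' @param within_condition Restrict permutations to within each condition.
#' @return A list with `ks_D`, `ks_p`, `wilcoxon_W`, `wilcoxon_p`,
#'   `n_actual`, `n_shuffled`, and `shuffled_r` (the pooled shuffled
#'   correlations).
#' @export
shuffle_null_test <- function(profiles, group = c("de", "nonde"),
                              n_reps = 1000L, seed,
                              wilcox_alternative = "greater",
                              within_condition = FALSE) {
  group <- match.arg(group)
  want <- group == "de"
  sel <- profiles[vapply(profiles, function(p) isTRUE(p$de_flag) == want,
                         logical(1))]
  n <- length(sel)
  if (n < 2) stop("selected group has fewer than 2 profiles; shuffling undefined")
  M <- vapply(sel, `[[`, numeric(length(sel[[1]]$mrna_lfc)), "mrna_lfc")
  P <- vapply(sel, `[[`, numeric(length(sel[[1]]$protein_lfc)), "protein_lfc")
  conds <- vapply(sel, `[[`, character(1), "condition")
  actual_r <- .col_cor(M, P)
  set.seed(seed)
  shuffled <- matrix(NA_real_, nrow = n, ncol = n_reps)
  for (b in seq_len(n_reps)) {
    if (within_condition) {
      perm <- seq_len(n)
      for (cc in unique(conds)) {
        idx <- which(conds == cc)
        if (length(idx) > 1) perm[idx] <- idx[sample.int(length(idx))]
      }
    } else {
      perm <- sample.int(n)
    }
    shuffled[, b] <- .col_cor(M[, perm, drop = FALSE], P)
  }
  pooled <- as.vector(shuffled)
  ok_a <- !is.na(actual_r); ok_s <- !is.na(pooled)
  ks <- suppressWarnings(stats::ks.test(actual_r[ok_a], pooled[ok_s]))
  wt <- suppressWarnings(stats::wilcox.test(actual_r[ok_a], pooled[ok_s],
                                            alternative = wilcox_alternative,
                                            exact = FALSE))
  list(ks_D = unname(ks$statistic), ks_p = ks$p.value,
       wilcoxon_W = unname(wt$statistic), wilcoxon_p = wt$p.value,
       n_actual = sum(ok_a), n_shuffled = sum(ok_s),
       shuffled_r = pooled)
}
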