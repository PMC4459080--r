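test_that("simple-model parameters match closed-form estimates", {
  # noiseless linear relationship
  lfc_m <- matrix(rnorm(20 * 5), 20, 5)
  rownames(lfc_m) <- sprintf("G%03d", 1:20)
  lfc_p <- 2 * lfc_m + 0.5
  fm <- fc_table(lfc_m, "c1"); fp <- fc_table(lfc_p, "c1")
  fl <- flag_table(rownames(lfc_m), "c1", rep(c(TRUE, FALSE), each = 10))
  par <- estimate_simple_model_params(fm, fp, fl)
  expect_equal(par$m, 2, tolerance = 1e-10)
  expect_equal(par$b, 0.5, tolerance = 1e-10)
  expect_equal(par$sigma_e, 0, tolerance = 1e-10)
  expect_equal(par$n_high, 10)
  expect_equal(par$n_low, 10)
  expect_equal(par$T, 5)

  # random fixture: normal-equation oracle for (m, b), group moments
  set.seed(77)
  lfc_p2 <- 0.4 * lfc_m + matrix(rnorm(100, 0, 0.3), 20, 5)
  fp2 <- fc_table(lfc_p2, "c1")
  par2 <- estimate_simple_model_params(fm, fp2, fl)
  o <- ols_oracle(as.vector(t(lfc_m)), as.vector(t(lfc_p2)))
  expect_equal(par2$m, o$b1, tolerance = 1e-10)
  expect_equal(par2$b, o$b0, tolerance = 1e-10)
  expect_equal(par2$sigma_e, sd(o$residuals), tolerance = 1e-10)
  hi <- lfc_m[1:10, ]; lo <- lfc_m[11:20, ]
  expect_equal(par2$mu_high, mean(hi), tolerance = 1e-12)
  expect_equal(par2$sd_high, sd(as.vector(hi)), tolerance = 1e-12)
  expect_equal(par2$mu_low, mean(lo), tolerance = 1e-12)
  # symmetric construction: identically distributed groups
  expect_equal(par2$sd_high, sd(as.vector(hi)))
})

test_that("fast KS and Mann-Whitney kernels agree with stats tests", {
  set.seed(55)
  for (i in 1:100) {
    n1 <- sample(3:12, 1); n2 <- sample(3:12, 1)
    x <- rnorm(n1); y <- rnorm(n2)
    expect_equal(profconcord:::.ks_D(x, y),
                 unname(ks.test(x, y)$statistic), tolerance = 1e-12)
    expect_equal(profconcord:::.mw_U(x, y),
                 unname(wilcox.test(x, y)$statistic), tolerance = 1e-12)
  }
  # tie handling
  x <- c(1, 2, 2, 3); y <- c(2, 3, 3)
  expect_equal(profconcord:::.ks_D(x, y),
               unname(suppressWarnings(ks.test(x, y)$statistic)),
               tolerance = 1e-12)
  expect_equal(profconcord:::.mw_U(x, y),
               unname(suppressWarnings(wilcox.test(x, y)$statistic)))
})

simple_params <- function(m = 0.5, b = 0, sigma_e = 0.3, sd_high = 0.5,
                          sd_low = 0.2, n_high = 8, n_low = 12) {
  structure(list(m = m, b = b, sigma_e = sigma_e, mu_high = 0,
                 sd_high = sd_high, mu_low = 0, sd_low = sd_low,
                 n_high = n_high, n_low = n_low, T = 5),
            class = "SimpleModelParams")
}

test_that("noise-free simple model gives perfectly correlated profiles", {
  par <- simple_params(m = 1.5, sigma_e = 0)
  cmp <- simple_model_comparison(par, rng_seed = 3)
  expect_equal(cmp$ks_D, 0)  # both groups sit at r = sign(m) = 1
  # all ties: U is the midpoint n_high * n_low / 2
  expect_equal(cmp$wilcoxon_W, par$n_high * par$n_low / 2)
  par_neg <- simple_params(m = -1.5, sigma_e = 0)
  expect_equal(simple_model_comparison(par_neg, rng_seed = 3)$ks_D, 0)
})

test_that("equal-variance groups reproduce the iid two-sample KS null", {
  # with sd_high = sd_low the simulated correlations are iid across groups,
  # so E[D] must match direct iid sampling at the same group sizes
  par <- simple_params(sd_high = 0.4, sd_low = 0.4, n_high = 10, n_low = 15)
  set.seed(61)
  D_sim <- profconcord:::.simple_model_stats(par, 4000L)$D
  D_iid <- replicate(4000, profconcord:::.ks_D(rnorm(10), rnorm(15)))
  se <- sqrt(var(D_sim) / 4000 + var(D_iid) / 4000)
  expect_lt(abs(mean(D_sim) - mean(D_iid)), 4 * se)
})

test_that("rank-sum symmetry: swapping groups mirrors the U statistic", {
  # U_xy + U_yx = n1 * n2 for any data, so swapping the high/low parameter
  # sets mirrors the stored Wilcoxon statistic
  set.seed(17)
  x <- rnorm(7); y <- rnorm(9)
  expect_equal(profconcord:::.mw_U(x, y) + profconcord:::.mw_U(y, x), 63)
  par <- simple_params(n_high = 7, n_low = 9)
  par_sw <- simple_params(sd_high = par$sd_low, sd_low = par$sd_high,
                          n_high = 9, n_low = 7)
  # distributions mirror under a high/low swap: E[U] + E[U_swapped] = 63
  set.seed(23)
  Ua <- profconcord:::.simple_model_stats(par, 2000L)$U
  set.seed(23)
  Ub <- profconcord:::.simple_model_stats(par_sw, 2000L)$U
  se <- sqrt(var(Ua) / 2000 + var(Ub) / 2000)
  expect_lt(abs(mean(Ua) + mean(Ub) - 63), 4 * se)
})

test_that("empirical p-values follow the >= counting rule", {
  nr <- null_result(0.3, c(0.1, 0.3, 0.5, 0.7))
  expect_equal(nr$p_empirical, 3 / 4)
  expect_equal(null_result(0.3, c(0.1, 0.3, 0.5, 0.7), plus_one = TRUE)$p_empirical,
               4 / 5)
  # monotone non-increasing in the observed statistic
  ns <- runif(50)
  ps <- sapply(seq(0, 1, 0.1), function(o) null_result(o, ns)$p_empirical)
  expect_true(all(diff(ps) <= 0))

  par <- simple_params()
  pv0 <- simple_model_pvalues(par, observed_D = 0, observed_W = 0,
                              n_reps = 200, seed = 5)
  expect_equal(pv0$D$p_empirical, 1)  # every null D >= 0
  expect_equal(pv0$W$p_empirical, 1)
  pv1 <- simple_model_pvalues(par, observed_D = 1.01, observed_W = Inf,
                              n_reps = 200, seed = 5)
  expect_equal(pv1$D$p_empirical, 0)
  expect_equal(pv1$W$p_empirical, 0)
})

test_that("profile shuffling is a uniform permutation conserving mRNA vectors", {
  mk_pairs <- function(n) {
    structure(lapply(seq_len(n), function(i) list(
      feature = sprintf("G%d", i), condition = "c",
      mrna_lfc = rnorm(5) + i, protein_lfc = rnorm(5), de_flag = TRUE)),
      class = "profile_pairs")
  }
  set.seed(1)
  pr2 <- mk_pairs(2)
  swapped <- vapply(1:200, function(s) {
    sh <- shuffle_profiles(pr2, rng_seed = s)
    !identical(sh[[1]]$mrna_lfc, pr2[[1]]$mrna_lfc)
  }, logical(1))
  expect_gt(mean(swapped), 0.35)  # both outcomes occur with ~1/2 frequency
  expect_lt(mean(swapped), 0.65)

  pr5 <- mk_pairs(5)
  sh <- shuffle_profiles(pr5, rng_seed = 7)
  ms_before <- sort(sapply(pr5, function(p) paste(signif(p$mrna_lfc, 12), collapse = ",")))
  ms_after <- sort(sapply(sh, function(p) paste(signif(p$mrna_lfc, 12), collapse = ",")))
  expect_identical(ms_before, ms_after)
  # protein side untouched
  expect_identical(lapply(sh, `[[`, "protein_lfc"), lapply(pr5, `[[`, "protein_lfc"))
  expect_error(shuffle_profiles(pr5[1], 1), ">= 2")

  # permutation frequencies uniform over the 120 orderings of 5 profiles
  pr5w <- structure(lapply(1:5, function(i) list(
    feature = sprintf("G%d", i), condition = "c",
    mrna_lfc = rep(i, 5), protein_lfc = rnorm(5), de_flag = TRUE)),
    class = "profile_pairs")
  perms <- vapply(1:12000, function(s) {
    sh <- shuffle_profiles(pr5w, rng_seed = 100000 + s)
    paste(sapply(sh, function(p) p$mrna_lfc[1]), collapse = "")
  }, character(1))
  tab <- table(perms)
  expect_equal(length(tab), 120)
  chi <- sum((tab - 100)^2 / 100)
  expect_lt(chi, qchisq(0.999, df = 119))
})

test_that("shuffle null is degenerate for exchangeable identical profiles", {
  base_m <- c(0.1, 0.4, -0.2, 0.3, 0.0)
  base_p <- c(0.2, 0.1, -0.1, 0.5, -0.3)
  pr <- structure(lapply(1:6, function(i) list(
    feature = sprintf("G%d", i), condition = "c",
    mrna_lfc = base_m, protein_lfc = base_p, de_flag = TRUE)),
    class = "profile_pairs")
  st <- shuffle_null_test(pr, "de", n_reps = 50, seed = 2)
  expect_equal(st$ks_D, 0)
  expect_error(shuffle_null_test(pr, "nonde", n_reps = 10, seed = 1),
               "fewer than 2")
})

test_that("coupled DE profiles beat their shuffled null", {
  ps <- numeric(3)
  for (i in 1:3) {
    sim <- generate_experiment(sim_config(seed = 300 + i, coupling = 0.9,
                                          effect_sd = 0.8, replicate_sd = 0.15))
    fm <- compute_fold_changes(sim$mrna); fp <- compute_fold_changes(sim$protein)
    fl <- flag_de_profiles(fm, cutoff = 0.05)
    pr <- suppressWarnings(build_profile_pairs(fm, fp, fl))
    ps[i] <- shuffle_null_test(pr, "de", n_reps = 300, seed = 400 + i)$wilcoxon_p
  }
  expect_true(all(ps < 0.01))
})

test_that("within-condition shuffling never crosses conditions", {
  # one profile per condition: within-condition permutations are all fixed,
  # so the shuffled distribution collapses onto the actual one (D = 0);
  # cross-condition shuffling of the same profiles does not
  set.seed(41)
  pr <- structure(lapply(1:2, function(i) list(
    feature = sprintf("G%d", i), condition = sprintf("c%d", i),
    mrna_lfc = rnorm(5), protein_lfc = rnorm(5), de_flag = TRUE)),
    class = "profile_pairs")
  st_within <- shuffle_null_test(pr, "de", n_reps = 40, seed = 3,
                                 within_condition = TRUE)
  expect_equal(st_within$ks_D, 0)
  st_cross <- shuffle_null_test(pr, "de", n_reps = 40, seed = 3)
  expect_gt(st_cross$ks_D, 0)
})
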