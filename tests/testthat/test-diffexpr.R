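test_that("fold change is mean treated minus mean pooled controls", {
  # zero within-group variance: moderation borrows a variance floor from the
  # other genes and the contrast stays testable
  trt <- rbind(c(6, 6, 6), c(5.1, 4.9, 5.0))
  ctl <- rbind(c(5, 5, 5), c(5.2, 4.8, 5.1))
  ds <- two_group_dataset(trt, ctl)
  fc <- compute_fold_changes(ds, moderation = "empirical_bayes")
  expect_equal(fc$log_fc[fc$feature == "G001"], 1.0)
  expect_true(is.finite(fc$p_raw[fc$feature == "G001"]))
  expect_lt(fc$p_raw[fc$feature == "G001"], 0.05)
})

test_that("identical treated and control groups give lfc 0 and p near 1", {
  x <- matrix(rnorm(12, 5, 0.5), 4, 3)
  ds <- two_group_dataset(x, x)
  fc <- compute_fold_changes(ds, moderation = "none")
  expect_equal(fc$log_fc, rep(0, 4))
  expect_equal(fc$p_raw, rep(1, 4), tolerance = 1e-12)
})

test_that("unmoderated p-values equal the pooled two-sample t-test", {
  set.seed(19)
  trt <- matrix(rnorm(20 * 3, 0.2, 0.7), 20, 3)
  ctl <- matrix(rnorm(20 * 4, 0, 0.7), 20, 4)
  fc <- compute_fold_changes(two_group_dataset(trt, ctl), moderation = "none")
  for (g in 1:20) {
    tt <- t.test(trt[g, ], ctl[g, ], var.equal = TRUE)
    expect_equal(fc$p_raw[g], tt$p.value, tolerance = 1e-10)
    expect_equal(fc$log_fc[g], unname(diff(rev(tt$estimate))), tolerance = 1e-10)
  }
})

test_that("moderated t matches an independent empirical-Bayes implementation", {
  skip_if_not_installed("limma")
  set.seed(42)
  ng <- 60; n1 <- 3; n0 <- 4
  sds <- sqrt(1 / rgamma(ng, shape = 4, rate = 4 * 0.04))
  trt <- matrix(rnorm(ng * n1, rep(c(0.5, 0), c(10, ng - 10)), sds), ng, n1)
  ctl <- matrix(rnorm(ng * n0, 0, sds), ng, n0)
  fc <- compute_fold_changes(two_group_dataset(trt, ctl),
                             moderation = "empirical_bayes")
  design <- cbind(1, c(rep(1, n1), rep(0, n0)))
  fit <- limma::eBayes(limma::lmFit(cbind(trt, ctl), design))
  tt <- limma::topTable(fit, coef = 2, number = Inf, sort.by = "none")
  expect_equal(fc$log_fc, unname(tt$logFC), tolerance = 1e-10)
  expect_equal(fc$p_raw, unname(tt$P.Value), tolerance = 1e-8)
})

test_that("contrasts with < 2 replicates get NA p-values with a warning", {
  trt <- matrix(rnorm(4), 4, 1)
  ctl <- matrix(rnorm(12), 4, 3)
  expect_warning(fc <- compute_fold_changes(two_group_dataset(trt, ctl)),
                 "< 2 replicates")
  expect_true(all(is.na(fc$p_raw)))
  expect_true(all(is.finite(fc$log_fc)))
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_fdr(0.2), 0.2)
  expect_error(adjust_fdr(c(0.1, 1.3)), "\\[0, 1\\]")
  set.seed(23)
  for (i in 1:10) {
    p <- runif(100)
    expect_equal(adjust_fdr(p), bh_oracle(p), tolerance = 1e-12)
  }
  # NA passthrough: adjusted non-missing values unaffected by NA positions
  p <- c(0.01, NA, 0.04, 0.2, NA)
  adj <- adjust_fdr(p)
  expect_true(all(is.na(adj[c(2, 5)])))
  expect_equal(adj[-c(2, 5)], bh_oracle(p[-c(2, 5)]))
  # permutation invariance
  p <- runif(50)
  o <- sample(50)
  expect_equal(adjust_fdr(p)[o], adjust_fdr(p[o]))
  # adjusted never below raw
  expect_true(all(adjust_fdr(p) >= p))
})

test_that("profiles are flagged by their minimum adjusted p-value", {
  lfc <- matrix(0, 2, 5)
  rownames(lfc) <- c("A", "B")
  fc <- fc_table(lfc, "cond1")
  fc <- fc[order(fc$feature, fc$time_point), ]
  fc$p_adj[fc$feature == "A"] <- c(0.2, 0.04, 0.9, 0.6, 0.7)
  fc$p_adj[fc$feature == "B"] <- 0.5
  fl <- flag_de_profiles(fc, cutoff = 0.05)
  expect_true(fl$de_flag[fl$feature == "A"])
  expect_false(fl$de_flag[fl$feature == "B"])
  # all-missing profiles are excluded with a message
  fc$p_adj[fc$feature == "B"] <- NA
  expect_message(fl2 <- flag_de_profiles(fc, cutoff = 0.05), "dropped")
  expect_equal(fl2$feature, "A")
})

test_that("flagged sets grow monotonically with the cutoff", {
  sim <- generate_experiment(sim_config(seed = 13))
  fc <- compute_fold_changes(sim$mrna)
  sets <- lapply(c(0.01, 0.05, 0.2, 0.5), function(cut) {
    fl <- flag_de_profiles(fc, cutoff = cut)
    paste(fl$feature, fl$condition)[fl$de_flag]
  })
  for (i in 1:3) expect_true(all(sets[[i]] %in% sets[[i + 1]]))
})

test_that("strong effects recover the responsive profile set", {
  # with strong trajectories every responsive profile is flagged; false
  # positives are bounded by the BH level compounded over the five
  # time points per profile, so pooled precision stays near 0.9
  n_true <- n_flagged <- n_hit <- 0
  for (i in 1:5) {
    sim <- generate_experiment(sim_config(seed = 80 + i, effect_sd = 1,
                                          replicate_sd = 0.1))
    fc <- compute_fold_changes(sim$mrna)
    fl <- flag_de_profiles(fc, cutoff = 0.05)
    resp <- sim$truth$feature[sim$truth$responsive]
    true_prof <- fl$feature %in% resp
    expect_true(all(fl$de_flag[true_prof]))  # perfect recall per seed
    n_true <- n_true + sum(true_prof)
    n_flagged <- n_flagged + sum(fl$de_flag)
    n_hit <- n_hit + sum(fl$de_flag & true_prof)
  }
  jacc <- n_hit / (n_true + n_flagged - n_hit)
  expect_gt(jacc, 0.85)
})
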