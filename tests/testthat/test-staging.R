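test_that("fixed-threshold staging reproduces the published decision logic", {
  expect_equal(stage_by_thresholds(8.0, 0.5), 1L)
  expect_equal(stage_by_thresholds(12.0, 0.5), 2L)
  expect_equal(stage_by_thresholds(20.0, 0.85), 3L)
  expect_equal(stage_by_thresholds(20.0, 0.95), 4L)
  # boundary values go to the lower branch
  expect_equal(stage_by_thresholds(14.463, 2), 2L)
  expect_equal(stage_by_thresholds(9.867, 2), 1L)
  expect_equal(stage_by_thresholds(20, 0.901), 3L)
})

test_that("staging is total and monotone on a grid of inputs", {
  limbic <- seq(0, 30, by = 0.5)
  eff <- seq(0, 2, by = 0.1)
  grid <- expand.grid(limbic_strength = limbic, global_efficiency = eff)
  st <- stage_by_thresholds(grid)
  expect_true(all(st %in% 1:4))
  # raising limbic strength at fixed efficiency never lowers the stage
  for (e in eff) {
    expect_true(all(diff(st[grid$global_efficiency == e]) >= 0))
  }
  # raising efficiency within the high-limbic branch never lowers the stage
  high <- grid$limbic_strength > 14.463
  for (l in unique(grid$limbic_strength[high])) {
    sel <- high & grid$limbic_strength == l
    expect_true(all(diff(st[sel][order(grid$global_efficiency[sel])]) >= 0))
  }
})

test_that("staging accepts measures objects and validates inputs", {
  m <- network_measures(regional_profile(c(1, 1.2, 2)), limbic_ids = 1:2)
  expect_true(stage_by_thresholds(m) %in% 1:4)
  expect_error(stage_by_thresholds(data.frame(limbic_strength = 1)),
               "global_efficiency")
  expect_error(stage_by_thresholds(NA_real_, 1), "finite")
})

test_that("a planted threshold is recovered by the tree", {
  set.seed(31)
  n <- 400
  feats <- data.frame(limbic = runif(n, 0, 20), eff = runif(n, 0.4, 1.4))
  y <- as.numeric(feats$limbic > 10)
  fit <- fit_stage_tree(feats, y, n_perm = 999, seed = 7)
  sp <- tree_splits(fit)
  expect_equal(sp$var[1], "limbic")
  expect_lt(abs(sp$threshold[1] - 10), 0.02 * 20)
  expect_equal(fit$n_stages, 2L)
  expect_equal(predict(fit, data.frame(limbic = c(2, 18), eff = c(1, 1))),
               c(1L, 2L))
})

test_that("two nested planted thresholds give the two-level topology", {
  set.seed(32)
  n <- 600
  feats <- data.frame(limbic = runif(n, 0, 30), eff = runif(n, 0.4, 1.4))
  y <- as.numeric(stage_by_thresholds(
    data.frame(limbic_strength = feats$limbic,
               global_efficiency = feats$eff)))
  fit <- fit_stage_tree(feats, y, n_perm = 999, seed = 7)
  expect_equal(fit$n_stages, 4L)
  expect_equal(fit$tree$var, "limbic")
  expect_lt(abs(fit$tree$threshold - 14.463), 0.02 * 30)
  expect_equal(fit$tree$left$var, "limbic")
  expect_lt(abs(fit$tree$left$threshold - 9.867), 0.02 * 30)
  expect_equal(fit$tree$right$var, "eff")
  expect_lt(abs(fit$tree$right$threshold - 0.901), 0.02 * 1)
  # leaves numbered by ascending limbic (first feature): depth-first order
  expect_equal(fit$tree$left$left$stage, 1L)
  expect_equal(fit$tree$left$right$stage, 2L)
})

test_that("tree fitting is deterministic given the seed", {
  set.seed(33)
  feats <- data.frame(a = runif(120), b = runif(120))
  y <- feats$a + rnorm(120, 0, 0.4)
  f1 <- fit_stage_tree(feats, y, n_perm = 499, seed = 11)
  f2 <- fit_stage_tree(feats, y, n_perm = 499, seed = 11)
  expect_identical(f1$tree, f2$tree)
})

test_that("degenerate inputs collapse to a single leaf", {
  feats <- data.frame(a = runif(80), b = runif(80))
  const <- fit_stage_tree(feats, rep(1, 80), n_perm = 199, seed = 1)
  expect_equal(const$n_stages, 1L)
  expect_equal(const$tree$type, "leaf")

  # constant features are skipped with a log message
  feats2 <- data.frame(a = rep(2, 80), b = runif(80))
  expect_message(
    fit2 <- fit_stage_tree(feats2, runif(80), n_perm = 199, seed = 1),
    "constant")

  # all features constant: nothing to test, single leaf
  feats3 <- data.frame(a = rep(2, 80), b = rep(5, 80))
  fit3 <- fit_stage_tree(feats3, runif(80), n_perm = 199, seed = 1)
  expect_equal(fit3$n_stages, 1L)
})

test_that("permutation p-values stay in [0, 1] and splits respect min_node", {
  set.seed(34)
  feats <- data.frame(a = runif(200))
  y <- as.numeric(feats$a > 0.5)
  fit <- fit_stage_tree(feats, y, min_node = 30, n_perm = 499, seed = 3)
  sp <- tree_splits(fit)
  expect_true(all(sp$p_adjusted >= 0 & sp$p_adjusted <= 1))
  counts <- table(predict(fit, feats))
  expect_true(all(counts >= 30))
})

test_that("stage summaries average profiles and strengths per stage", {
  p1 <- regional_profile(c(1, 1, 1), subject_id = "a")
  p2 <- regional_profile(c(1, 2, 3), subject_id = "b")
  p3 <- regional_profile(c(1, 2, 3), subject_id = "c")
  sm <- stage_summary(list(p1, p2, p3), c(1L, 2L, 2L))
  expect_equal(unname(sm$profile_means[1, ]), c(1, 1, 1))
  expect_equal(unname(sm$profile_means[2, ]), c(1, 2, 3))
  expect_equal(unname(sm$strength_means[2, ]),
               unname(nodal_strength(build_network(p2))))
  expect_equal(sm$n, c(1L, 2L))

  # empty stages are reported, not dropped
  sm4 <- stage_summary(list(p1, p2), c(1L, 4L))
  expect_equal(sm4$n, c(1L, 0L, 0L, 1L))
  expect_true(all(is.na(sm4$profile_means[2, ])))

  df <- data.frame(subject_id = c("b", "a"), stage = c(2L, 1L))
  sm_df <- stage_summary(list(p1, p2), df)
  expect_equal(sm_df$n, c(1L, 1L))
  expect_error(stage_summary(list(p1), data.frame(subject_id = "z",
                                                  stage = 1L)), "unassigned")
})

test_that("a graded cohort yields nondecreasing stage-mean limbic strength", {
  atlas <- make_phantom_atlas(grid = c(60, 60, 60), k = 20, seed = 3)
  cohort <- simulate_profiles(
    atlas, sim_config(noise_sd = 0, baseline_sd = 0, seed = 9),
    severities = seq(0, 1, length.out = 36))
  profs <- cohort_profiles(cohort)
  meas <- do.call(rbind, lapply(profs, function(p) {
    as.data.frame(network_measures(p, limbic_ids = atlas$limbic_ids))
  }))
  st <- stage_by_thresholds(meas)
  expect_equal(sort(unique(st)), 1:4)
  sm <- stage_summary(profs, st)
  limbic_cols <- as.character(atlas$limbic_ids)
  stage_limbic <- rowMeans(sm$strength_means[, limbic_cols])
  expect_true(all(diff(stage_limbic) >= 0))
})
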