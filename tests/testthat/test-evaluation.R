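test_that("confusion metrics follow their defining identities", {
  y <- c(1, 1, 0, 0, 1)
  expect_equal(confusion_metrics(y, y)[, c("acc", "sen", "spe")],
               tibble::tibble(acc = 1, sen = 1, spe = 1))
  # TP=3, FN=1, no negatives: sen defined, spe undefined
  m <- confusion_metrics(c(1, 1, 1, 1), c(1, 1, 1, 0))
  expect_equal(m$sen, 0.75)
  expect_true(is.na(m$spe))
  # TP=50, FP=10, TN=40, FN=0
  y_true <- c(rep(1, 50), rep(0, 50))
  y_pred <- c(rep(1, 50), rep(1, 10), rep(0, 40))
  m2 <- confusion_metrics(y_true, y_pred)
  expect_equal(m2$acc, 0.9)
  expect_equal(m2$sen, 1.0)
  expect_equal(m2$spe, 0.8)
  expect_equal(m2$tp + m2$tn, m2$acc * 100) # Acc identity holds exactly
  expect_error(confusion_metrics(integer(0), integer(0)),
               class = "msep_dimension_error")
})

test_that("rank-based AUC agrees with pairwise and reference computations", {
  expect_equal(auc_score(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8)), 0.75)
  expect_equal(auc_score(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1)
  expect_equal(auc_score(c(0, 1, 0, 1), rep(0.5, 4)), 0.5)
  expect_warning(expect_true(is.na(auc_score(c(1, 1), c(0.2, 0.3)))))
  set.seed(1)
  for (k in 1:5) {
    y <- rbinom(40, 1, 0.4)
    if (length(unique(y)) < 2) next
    s <- round(runif(40), 2) # rounded scores force ties
    expect_equal(auc_score(y, s), pair_auc(y, s))
  }
  skip_if_not_installed("pROC")
  y <- rbinom(60, 1, 0.5)
  s <- runif(60)
  expect_equal(
    auc_score(y, s),
    as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                   levels = c(0, 1), direction = "<")))
  )
})

test_that("stratified splits follow largest-remainder allocation", {
  labels <- c(rep(1L, 98), rep(0L, 116)) # the clinical cohort's class sizes
  sp <- split_dataset(labels, ratio = c(7, 2, 1), seed = 1)
  expect_equal(sort(c(sp$train, sp$prune, sp$test)), seq_along(labels))
  # per-class largest-remainder counts: 98 -> 69/19/10, 116 -> 81/23/12
  expect_equal(sum(labels[sp$train] == 1), 69)
  expect_equal(sum(labels[sp$prune] == 1), 19)
  expect_equal(sum(labels[sp$test] == 1), 10)
  expect_equal(sum(labels[sp$train] == 0), 81)
  expect_equal(sum(labels[sp$prune] == 0), 23)
  expect_equal(sum(labels[sp$test] == 0), 12)
  expect_error(split_dataset(c(rep(0L, 50), 1L)),
               class = "msep_degenerate_data_error")
  expect_error(split_dataset(labels, ratio = c(1, 2)),
               class = "msep_config_error")
})

test_that("the pipeline returns the configured pruned size", {
  feats <- gaussian_features(n_per_class = 60, seed = 1)
  res <- run_msep(feats, M = 21, T = 5, seed = 1)
  expect_length(res$pruned$selected, 5)
  expect_s3_class(res$metrics, "tbl_df")
  # T = M: pruning disabled, the selection is the whole pool
  res_full <- run_msep(feats, M = 7, T = 7, seed = 1)
  expect_setequal(res_full$pruned$selected, 1:7)
  expect_error(run_msep(feats, M = 7, T = 9), class = "msep_config_error")
})

test_that("ordering selection reproduces a step-by-step re-execution", {
  for (sd in 1:6) {
    vm <- simulate_vote_matrix(40, 15, accuracy = runif(15, 0.4, 0.9),
                               correlation = 0.3, seed = sd)
    sel <- top_classifiers(msm_scores(vm, theta = -0.8), 5)
    expect_equal(sel, naive_msep_select(vm$correct, vm$labels, 5,
                                        theta = -0.8, bonus = TRUE))
    sel_mep <- top_classifiers(msm_scores(vm, theta = -0.8, bonus = FALSE), 5)
    expect_equal(sel_mep, naive_msep_select(vm$correct, vm$labels, 5,
                                            theta = -0.8, bonus = FALSE))
  }
})

test_that("repeated validation is seeded and degenerates gracefully", {
  feats <- gaussian_features(n_per_class = 40, seed = 2)
  one <- cross_validate(feats, repetitions = 1, M = 9, T = 3, seed = 5)
  expect_equal(nrow(one$per_rep), 1)
  expect_true(all(one$summary$sd == 0 | is.na(one$summary$sd)))
  again <- cross_validate(feats, repetitions = 1, M = 9, T = 3, seed = 5)
  expect_identical(one$per_rep, again$per_rep)
  rep3 <- cross_validate(feats, repetitions = 3, M = 9, T = 3, seed = 5)
  expect_equal(rep3$per_rep[1, -1], one$per_rep[1, -1])
})

test_that("easy synthetic data is classified almost perfectly", {
  s <- simulate_breath_samples(n_per_class = 50, n_timesteps = 40,
                               class_separation = 3, noise_sd = 0.05,
                               drift_sd = 0.01, seed = 4)
  feats <- summarize_channels(s)
  cv <- cross_validate(feats, repetitions = 10, M = 21, T = 5, seed = 2)
  expect_gt(cv$summary$mean[cv$summary$metric == "acc"], 0.95)
})

test_that("rank scoring assigns points with shared ties", {
  tab <- tibble::tibble(
    model = c("a", "b"),
    m1 = c(0.9, 0.8),
    m2 = c(0.5, 0.5)
  )
  rs <- rank_scores(tab)
  expect_equal(rs$m1_points, c(2, 1))
  expect_equal(rs$m2_points, c(1.5, 1.5)) # tie shares mean of {1, 2}
  # distinct values yield a permutation of 1..n
  set.seed(3)
  tab2 <- tibble::tibble(model = letters[1:5], m = runif(5))
  expect_setequal(rank_scores(tab2)$m_points, 1:5)
  expect_error(rank_scores(tab[1, ]), class = "msep_config_error")
  tab3 <- tab
  tab3$m1[2] <- NA
  expect_warning(rank_scores(tab3))
})

test_that("pruning beats random same-size subsets on the pruning set", {
  set.seed(10)
  diffs <- numeric(50)
  for (sd in 1:50) {
    vm <- simulate_vote_matrix(60, 15, accuracy = runif(15, 0.5, 0.85),
                               correlation = 0.3, seed = sd)
    sel <- top_classifiers(msm_scores(vm), 5)
    acc_sel <- mean(rowSums(vm$correct[, sel, drop = FALSE]) >= 3)
    rnd <- sample(15, 5)
    acc_rnd <- mean(rowSums(vm$correct[, rnd, drop = FALSE]) >= 3)
    diffs[sd] <- acc_sel - acc_rnd
  }
  expect_gte(mean(diffs), 0)
})
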