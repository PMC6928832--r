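# Single-sample vote matrices make the measure formulas directly checkable.
one_row_votes <- function(correct_bits, label) {
  vote_matrix(matrix(as.integer(correct_bits), 1), label)
}

test_that("MSM marks match direct evaluation of the measure", {
  # classifier 1 correct, margin 0 is impossible with odd M, so build the
  # hypothetical 50/50 row with M = 10: NF = 0.5, margin = 0
  vm <- one_row_votes(c(1, rep(1, 4), rep(0, 5)), 1L)
  r <- msm_scores(vm, theta = -1)
  expect_equal(r$mark[1], exp(0.5)) # e^{y*NF} * e^{-0} with y = 1
  # same row, negative label: bonus exponent vanishes
  vm0 <- one_row_votes(c(1, rep(1, 4), rep(0, 5)), 0L)
  expect_equal(msm_scores(vm0, theta = -1)$mark[1], 1.0)
  # classifier wrong everywhere earns nothing
  C <- rbind(c(0L, 1L, 1L), c(0L, 1L, 0L))
  r2 <- msm_scores(vote_matrix(C, c(1L, 0L)), theta = -1)
  expect_equal(r2$mark[1], 0)
  expect_error(msm_scores(vm, theta = 0.5), class = "msep_config_error")
  expect_error(msm_scores(vm, theta = -1.5), class = "msep_config_error")
})

test_that("MSM reduces to MEP when no positive labels are present", {
  vm <- simulate_vote_matrix(80, 11, accuracy = 0.7, seed = 1)
  vm$labels <- rep(0L, 80)
  expect_equal(msm_scores(vm, bonus = TRUE)$mark,
               msm_scores(vm, bonus = FALSE)$mark)
})

test_that("UMEP neglects non-positive margins and matches the formula", {
  # margin 1: contributes -ln(1) = 0
  vm1 <- one_row_votes(rep(1, 5), 1L)
  expect_equal(umep_scores(vm1)$mark, rep(0, 5))
  # single sample with margin 0.5 (M = 4 hypothetical: 3 correct, 1 wrong)
  vm2 <- one_row_votes(c(1, 1, 1, 0), 1L)
  expect_equal(umep_scores(vm2)$mark[1], -log(0.5))
  expect_equal(umep_scores(vm2)$mark[4], 0) # wrong classifier earns nothing
  # negative margin sample contributes to no one
  vm3 <- one_row_votes(c(1, 0, 0, 0, 0), 1L)
  expect_equal(umep_scores(vm3)$mark, rep(0, 5))
})

test_that("MDM combines margin and diversity terms as specified", {
  # alpha = 1: pure margin term, |margin| = 0.5
  vm <- one_row_votes(c(1, 1, 1, 0), 1L)
  expect_equal(mdm_scores(vm, alpha = 1)$mark[1], -log(0.5))
  # wrong on all samples -> mark 0
  expect_equal(mdm_scores(vm, alpha = 0.3)$mark[4], 0)
  # alpha = 0 at unanimity: f_d = -ln(1) = 0
  vm1 <- one_row_votes(rep(1, 5), 1L)
  expect_equal(mdm_scores(vm1, alpha = 0)$mark, rep(0, 5))
  # negative margin uses the absolute value inside the log
  vm2 <- one_row_votes(c(1, 0, 0, 0), 1L) # margin -0.5
  expect_equal(mdm_scores(vm2, alpha = 1)$mark[1], -log(0.5))
  expect_error(mdm_scores(vm, alpha = 2), class = "msep_config_error")
})

test_that("SDAcc event marks follow the reward/penalty table", {
  expect_equal(sdacc_mark("e01", nt_sub = 0.8, nf_sub = 0.2), -0.2)
  expect_equal(sdacc_mark("e00", nt_sub = 0.2, nf_sub = 0.8), -0.2)
  expect_equal(sdacc_mark("e11", nt_sub = 0.7, nf_sub = 0.3), 0.3)
  expect_equal(sdacc_mark("e10", nt_sub = 0.4, nf_sub = 0.6), 0.6)
  expect_true(all(abs(c(
    sdacc_mark("e11", 0, 1), sdacc_mark("e00", 1, 0)
  )) <= 1))
  expect_error(sdacc_mark("e01", nt_sub = 0.8, nf_sub = 0.3),
               class = "msep_consistency_error")
})

test_that("greedy SDAcc selection matches a brute-force reference", {
  # seeding rule: T = 1 returns the single most accurate classifier
  vm <- simulate_vote_matrix(40, 7, accuracy = seq(0.3, 0.9, length.out = 7),
                             seed = 1)
  g1 <- sdacc_greedy_select(vm, 1)
  expect_equal(g1$selected, which.max(colMeans(vm$correct)))
  # an always-correct classifier is selected first
  vm$correct[, 4] <- 1L
  expect_equal(sdacc_greedy_select(vm, 3)$selected[1], 4L)
  # oracle equivalence on random matrices
  for (sd in 1:8) {
    vmr <- simulate_vote_matrix(30, 7, accuracy = runif(7, 0.3, 0.9),
                                correlation = 0.3, seed = sd)
    expect_equal(sdacc_greedy_select(vmr, 3)$selected,
                 naive_sdacc_greedy(vmr$correct, 3))
  }
  expect_error(sdacc_greedy_select(vm, 9), class = "msep_config_error")
})

test_that("marks are non-negative and monotone in sample hardness", {
  vm <- simulate_vote_matrix(60, 11, accuracy = 0.65, correlation = 0.3,
                             seed = 2)
  expect_true(all(msm_scores(vm)$mark >= 0))
  expect_true(all(umep_scores(vm)$mark >= 0))
  expect_true(all(mdm_scores(vm)$mark >= 0))
  # a correct vote on a harder (smaller-margin) sample contributes more:
  # two samples, classifiers 1 and 2 correct on exactly one each
  C <- rbind(
    c(1L, 0L, 1L, 1L, 1L, 1L, 1L), # margin 5/7
    c(0L, 1L, 1L, 1L, 0L, 0L, 0L)  # margin -1/7
  )
  r <- msm_scores(vote_matrix(C, c(0L, 0L)), theta = -1)
  expect_gt(r$mark[2], r$mark[1])
})

test_that("the bonus term favours correct votes on positive samples", {
  # classifiers A (col 1) and B (col 2) are identical except A is correct on
  # a positive sample and B on a negative one, both with the same margin
  C <- rbind(
    c(1L, 0L, 1L, 0L, 1L), # positive sample, margin 1/5
    c(0L, 1L, 1L, 0L, 1L)  # negative sample, same margin
  )
  vm <- vote_matrix(C, c(1L, 0L))
  r <- msm_scores(vm, theta = -1)
  expect_gt(r$mark[1], r$mark[2])
  # without the bonus the two are exactly tied
  r0 <- msm_scores(vm, theta = -1, bonus = FALSE)
  expect_equal(r0$mark[1], r0$mark[2])
})

test_that("the threshold excludes negative margins at 0 and none at -1", {
  vm <- simulate_vote_matrix(100, 11, accuracy = 0.55, correlation = 0.4,
                             seed = 3)
  mg <- compute_margins(vm)
  expect_true(any(mg$margin < 0)) # the regime actually produces hard samples
  r0 <- msm_scores(vm, theta = 0)
  # recompute keeping only positive-margin samples: must agree exactly
  keep <- mg$margin > 0
  manual <- as.numeric(
    crossprod(vm$correct[keep, , drop = FALSE],
              exp(vm$labels[keep] * mg$nf_pool[keep]) * exp(-mg$margin[keep]))
  ) / nrow(vm$correct)
  expect_equal(r0$mark, manual)
  # theta = -1 keeps every sample above margin -1
  rm1 <- msm_scores(vm, theta = -1)
  expect_true(all(rm1$mark >= r0$mark))
})

test_that("rankings are scale-invariant and deterministically tie-broken", {
  vm <- simulate_vote_matrix(50, 9, accuracy = 0.7, seed = 4)
  r <- msm_scores(vm)
  # multiplying all marks by a positive constant cannot change the order
  r2 <- r
  r2$mark <- r$mark * 3.7
  expect_equal(order(-r2$mark, r2$classifier), order(-r$mark, r$classifier))
  # exact ties break by ascending classifier index
  vm_tie <- vote_matrix(rbind(c(1L, 1L, 0L)), 1L)
  rt <- msm_scores(vm_tie, theta = -1)
  expect_equal(top_classifiers(rt, 1), 1L)
  expect_error(top_classifiers(rt, 2), class = "msep_config_error")
})
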