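test_that("reference range reproduces hand-derived order-statistic values", {
  # constant CpG
  expect_equal(reference_range(beta_tbl(matrix(0.3, 1, 10)))$range, 0)
  # 0.0, 0.1, ..., 0.9: q10 = 0.09, q90 = 0.81 by linear interpolation
  rr <- reference_range(beta_tbl(matrix(seq(0, 0.9, 0.1), 1)))
  expect_equal(rr$q_low, 0.09)
  expect_equal(rr$q_high, 0.81)
  expect_equal(rr$range, 0.72)
})

test_that("reference range is invariant to sample and CpG order", {
  b <- random_beta_tbl(50, 15, seed = 8)
  rr <- reference_range(b)
  shuffled <- withr::with_seed(9, b[sample(nrow(b)), c(1, 1 + sample(15))])
  rr2 <- reference_range(shuffled)
  expect_equal(rr2[match(rr$cpg_id, rr2$cpg_id), ], rr, ignore_attr = TRUE)
})

test_that("reference range matches the quantile oracle at non-default levels", {
  b <- random_beta_tbl(200, 13, seed = 21)
  p <- cpg_params(quantile_low = 0.25, quantile_high = 0.75)
  rr <- reference_range(b, p)
  m <- as.matrix(b[, -1])
  oracle <- t(apply(m, 1, stats::quantile, probs = c(0.25, 0.75),
                    type = 7, names = FALSE))
  expect_equal(rr$q_low, oracle[, 1], tolerance = 1e-14)
  expect_equal(rr$q_high, oracle[, 2], tolerance = 1e-14)
})

test_that("non-variable calling uses a strict boundary and is monotone in the threshold", {
  ranges <- tibble::tibble(cpg_id = c("a", "b", "c"),
                           range = c(0.049, 0.050, 0.20))
  nv <- call_nonvariable(ranges, cpg_params(nonvar_threshold = 0.05))
  expect_equal(nv$members, "a")
  # inclusive variant admits the boundary
  nvi <- call_nonvariable(ranges, cpg_params(nonvar_threshold = 0.05,
                                             nonvar_inclusive = TRUE))
  expect_setequal(nvi$members, c("a", "b"))
  # threshold 0 calls nothing; all-constant matrix calls everything
  expect_length(call_nonvariable(ranges, cpg_params(nonvar_threshold = 0))$members, 0)
  const <- reference_range(beta_tbl(matrix(0.5, 5, 6)))
  expect_length(call_nonvariable(const)$members, 5)
  # monotone: raising the threshold never shrinks the set
  b <- random_beta_tbl(300, 10, seed = 5)
  rr <- reference_range(b)
  sets <- lapply(c(0.02, 0.05, 0.2, 0.6),
                 function(th) call_nonvariable(rr, cpg_params(nonvar_threshold = th))$members)
  for (i in seq_len(length(sets) - 1)) {
    expect_true(all(sets[[i]] %in% sets[[i + 1]]))
  }
})

test_that("list intersection works on the common universe", {
  u <- sprintf("cg%d", 1:6)
  mk <- function(members, tissue) nonvariable_list(members, u, tissue, 0.05)
  la <- mk(c("cg1", "cg2", "cg3"), "blood")
  lb <- mk(c("cg2", "cg3", "cg4"), "buccal")
  lc <- mk(c("cg3", "cg2"), "placenta")
  ov <- intersect_lists(list(la, lb, lc))
  expect_setequal(ov$common_members, c("cg2", "cg3"))
  expect_equal(ov$pairwise$n_intersection[1], 2L)
  # identical lists intersect to themselves; disjoint lists to nothing
  expect_setequal(intersect_lists(list(la, la))$common_members, la$members)
  expect_length(intersect_lists(list(mk("cg1", "a"), mk("cg2", "b")))$common_members, 0)
})

test_that("overlap permutation p is exact for an enumerable draw space", {
  # two lists of size 1 in a shared universe of 2: P(overlap >= 1) = 1/2
  u <- c("cg1", "cg2")
  la <- nonvariable_list("cg1", u, "a")
  lb <- nonvariable_list("cg1", u, "b")
  res <- overlap_permutation_test(list(la, lb), n_perm = 2000, seed = 4)
  expect_equal(res$observed, 1L)
  se <- sqrt(0.5 * 0.5 / 2000)
  expect_lt(abs(res$p_value - 0.5), 3 * se + 1 / 2000)
})

test_that("overlap permutation test degenerates correctly and respects the add-one bound", {
  u <- sprintf("cg%d", 1:30)
  full <- nonvariable_list(u, u, "a")
  res <- overlap_permutation_test(list(full, full), n_perm = 50, seed = 1)
  expect_equal(res$p_value, 1.0)            # observed = permuted always
  expect_true(all(res$perm_overlaps == 30L))
  # minimum attainable p with maximal observed overlap
  la <- nonvariable_list(sprintf("cg%d", 1:20), u, "a")
  res2 <- overlap_permutation_test(list(la, la), n_perm = 199, seed = 2)
  expect_gte(res2$p_value, 1 / 200)
})

test_that("lists drawn from distinct universes are intersected on the shared part", {
  ua <- sprintf("cg%d", 1:40)
  ub <- sprintf("cg%d", 21:80)
  la <- nonvariable_list(sprintf("cg%d", 21:30), ua, "a")
  lb <- nonvariable_list(sprintf("cg%d", 21:30), ub, "b")
  res <- overlap_permutation_test(list(la, lb), n_perm = 500, seed = 6)
  expect_equal(res$observed, 10L)
  expect_lt(res$p_value, 0.05)
})

test_that("methylation state summary splits member means into the three states", {
  b <- beta_tbl(matrix(c(rep(0.9, 4), rep(0.5, 4), rep(0.1, 4)), 3, 4,
                       byrow = TRUE), cpg_ids = c("hi", "mid", "lo"))
  s <- methylation_state_summary(b, c("hi", "mid", "lo"))
  expect_equal(s$frac_high, 1 / 3)
  expect_equal(s$frac_low, 1 / 3)
  expect_equal(s$frac_intermediate, 1 / 3)
  expect_equal(s$frac_high + s$frac_low + s$frac_intermediate, 1)
  s_hi <- methylation_state_summary(b, "hi")
  expect_equal(s_hi$frac_high, 1)
  expect_error(methylation_state_summary(b, character()), "empty")
})

test_that("planted bimodal non-variable CpGs have no intermediate members at low noise", {
  sim <- simulate_beta_matrix(n_cpgs = 2000, n_samples = 30, noise_sd = 0.01,
                              seed = 12)
  planted <- sim$truth$cpg_id[startsWith(sim$truth$class, "nonvariable")]
  s <- methylation_state_summary(sim$betas, planted, high = 0.80, low = 0.16)
  expect_equal(s$frac_intermediate, 0)
  expect_gt(s$frac_high, 0.4)
  expect_gt(s$frac_low, 0.4)
})

test_that("list concordance reports overlap fraction and Jaccard", {
  expect_equal(list_concordance(c("x", "y"), c("y", "z", "w"))$overlap_fraction, 0.5)
  expect_equal(list_concordance(c("x", "y"), c("y", "z", "w"))$jaccard, 0.25)
  same <- list_concordance(c("a", "b"), c("a", "b"))
  expect_equal(same$overlap_fraction, 1)
  expect_equal(same$jaccard, 1)
  disj <- list_concordance(c("a"), c("b"))
  expect_equal(disj$overlap_fraction, 0)
  expect_equal(disj$jaccard, 0)
})
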