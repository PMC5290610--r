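test_that("delta beta is the raw difference of group means", {
  b <- beta_tbl(matrix(c(0.2, 0.3, 0.4, 0.6, 0.7, 0.8), 1), cpg_ids = "cg1")
  d <- tibble::tibble(sample_id = sprintf("s%03d", 1:6),
                      group = rep(c("a_ctrl", "b_exp"), each = 3))
  res <- fit_linear_ewas(b, d, exposure = "group")
  expect_equal(res$delta_beta, 0.4)
  # zero planted effect, zero noise
  b0 <- beta_tbl(matrix(0.5, 3, 6))
  res0 <- fit_linear_ewas(b0, design_for(b0))
  expect_equal(res0$delta_beta, rep(0, 3))
  expect_equal(res0$p_value, rep(1, 3))  # degenerate fits: p = 1
})

test_that("exposure t statistic equals the pooled two-sample t without covariates", {
  b <- random_beta_tbl(200, 16, seed = 31)
  d <- design_for(b)
  res <- fit_linear_ewas(b, d)
  m <- as.matrix(b[, -1])
  exp_idx <- d$group == "exposed"
  for (i in c(1, 7, 50, 200)) {
    tt <- stats::t.test(m[i, exp_idx], m[i, !exp_idx], var.equal = TRUE)
    expect_equal(res$statistic[i], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(res$p_value[i], tt$p.value, tolerance = 1e-10)
  }
})

test_that("covariates change the exposure estimate but never the delta beta", {
  b <- random_beta_tbl(50, 20, seed = 32)
  d <- design_for(b)
  d$age <- withr::with_seed(33, stats::rnorm(20, 40, 10))
  plain <- fit_linear_ewas(b, d)
  adj <- fit_linear_ewas(b, d, covariates = "age")
  expect_equal(adj$delta_beta, plain$delta_beta)
  expect_false(isTRUE(all.equal(adj$estimate, plain$estimate)))
  # M-value response keeps delta beta on the beta scale
  mres <- fit_linear_ewas(b, d, response = "m")
  expect_equal(mres$delta_beta, plain$delta_beta)
  # rank-deficient design errors
  d$dup <- as.numeric(d$group == "exposed")
  expect_error(fit_linear_ewas(b, d, covariates = "dup"), "rank")
})

test_that("hit calling gates on both FDR and effect size", {
  res <- tibble::tibble(cpg_id = c("a", "b", "c"),
                        delta_beta = c(0.12, 0.05, 0.30),
                        q_value = c(0.04, 0.04, 0.06))
  hits <- hit_calling(res)
  expect_equal(hits$hit, c(TRUE, FALSE, FALSE))
  # invariance to CpG order
  hits2 <- hit_calling(res[c(3, 1, 2), ])
  expect_equal(hits2$hit[match(res$cpg_id, hits2$cpg_id)], hits$hit)
})

test_that("confirm-and-remove filters only the confirmed intersection", {
  ranges <- tibble::tibble(cpg_id = sprintf("cg%d", 1:6),
                           range = c(0.01, 0.02, 0.20, 0.30, 0.01, 0.40))
  ref <- nonvariable_list(c("cg1", "cg3", "cg6"), sprintf("cg%d", 1:6))
  ft <- confirm_and_filter(ranges, ref)
  # cg1: nonvariable in study AND on reference -> removed
  # cg3, cg6: on reference but variable in study -> kept
  # cg5: nonvariable in study but not on reference -> kept
  expect_equal(ft$removed, c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))
  expect_length(retained_cpgs(ft), 5L)
  expect_equal(sum(!ft$removed), nrow(ft) - sum(ft$removed))
  # empty reference: nothing removed
  ft0 <- confirm_and_filter(ranges, character())
  expect_equal(retained_cpgs(ft0), ranges$cpg_id)
  # disjoint reference: warning, nothing removed
  expect_warning(ftd <- confirm_and_filter(ranges, c("other1", "other2")),
                 "nothing removed")
  expect_equal(retained_cpgs(ftd), ranges$cpg_id)
})

test_that("raw p-values at retained CpGs are identical between arms", {
  sim <- simulate_smoking_power(seed = 21, n_cpgs = 1500, n_samples = 24)
  p <- cpg_params()
  full <- fit_linear_ewas(sim$betas, sim$design)
  ranges <- reference_range(sim$betas, p)
  keep <- retained_cpgs(confirm_and_filter(ranges, sim$reference, p))
  filt <- fit_linear_ewas(sim$betas[sim$betas$cpg_id %in% keep, ], sim$design)
  expect_identical(filt$p_value,
                   full$p_value[match(filt$cpg_id, full$cpg_id)])
  # q-values differ only through the multiple-testing family
  expect_equal(filt$q_value,
               bh_fdr(full$p_value[match(filt$cpg_id, full$cpg_id)]))
})

test_that("removing only top-p CpGs can never worsen retained adjusted p-values", {
  # constructed so every removed CpG has raw p >= max raw p among retained
  withr::with_seed(40, {
    p_raw <- stats::runif(200)
  })
  ord <- order(p_raw)
  retained_idx <- ord[1:150]   # the 150 smallest
  full_adj <- bh_fdr(p_raw)
  sub_adj <- bh_fdr(p_raw[retained_idx])
  expect_true(all(sub_adj <= full_adj[retained_idx] + 1e-15))
})

test_that("the subsample experiment is deterministic and the null filter is a no-op", {
  sim <- simulate_smoking_power(seed = 22, n_cpgs = 800, n_samples = 30)
  p <- cpg_params(subsample_reps = 3, subsample_per_group = 5)
  tracked <- sim$signal_cpgs[1]
  a <- subsample_experiment(sim$betas, sim$design, sim$reference, p,
                            seed = 5, tracked = tracked)
  b <- subsample_experiment(sim$betas, sim$design, sim$reference, p,
                            seed = 5, tracked = tracked)
  expect_identical(a$tracked, b$tracked)
  expect_identical(a$hits, b$hits)
  expect_identical(a$draws, b$draws)

  # empty reference list: the two arms are identical in every replicate
  empty_ref <- nonvariable_list(character(), sim$reference$universe)
  n0 <- subsample_experiment(sim$betas, sim$design, empty_ref, p,
                             seed = 5, tracked = tracked)
  wide <- tidyr::pivot_wider(n0$hits, id_cols = "replicate",
                             names_from = "arm",
                             values_from = c("n_hits", "n_tested"))
  expect_equal(wide$n_hits_filtered, wide$n_hits_unfiltered)
  expect_equal(wide$n_tested_filtered, wide$n_tested_unfiltered)
  tr <- tidyr::pivot_wider(n0$tracked, id_cols = c("replicate", "cpg_id"),
                           names_from = "arm", values_from = "q_value")
  expect_equal(tr$filtered, tr$unfiltered)
})

test_that("tracked CpGs removed by the filter are recorded, not errors", {
  sim <- simulate_smoking_power(seed = 23, n_cpgs = 500, n_samples = 24)
  p <- cpg_params(subsample_reps = 2, subsample_per_group = 6)
  # track a planted non-variable CpG: confirm-and-remove should drop it
  nv_cpg <- sim$reference$members[1]
  ex <- subsample_experiment(sim$betas, sim$design, sim$reference, p,
                             seed = 9, tracked = nv_cpg)
  filt_rows <- ex$tracked[ex$tracked$arm == "filtered", ]
  expect_true(all(filt_rows$removed))
  expect_true(all(is.na(filt_rows$q_value)))
})
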