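test_that("probe bead filter removes strictly above the failing fraction", {
  # 20 samples; cg_fail has 2 failing samples (0.10 > 0.05), cg_edge exactly
  # 1 (0.05, not strictly greater), cg_ok none
  m <- matrix(10, 3, 20)
  m[1, 1:2] <- 2
  m[2, 1] <- 0
  beads <- beta_tbl(m, cpg_ids = c("cg_fail", "cg_edge", "cg_ok"))
  out <- probe_bead_filter(beads)
  expect_equal(out$removed, c(TRUE, FALSE, FALSE))
  expect_equal(out$fail_fraction, c(0.10, 0.05, 0))
})

test_that("sample bead filter removes at the threshold inclusively", {
  # 1000 CpGs; s_fail has 25 failing CpGs (2.5%), s_edge 24 (2.4%)
  m <- matrix(10, 1000, 3)
  m[1:25, 1] <- 1
  m[1:24, 2] <- 1
  beads <- beta_tbl(m, sample_ids = c("s_fail", "s_edge", "s_ok"))
  out <- sample_bead_filter(beads)
  expect_equal(out$removed, c(TRUE, FALSE, FALSE))
  # strict variant retains the boundary sample
  strict <- sample_bead_filter(beads, cpg_params(sample_fail_inclusive = FALSE))
  expect_equal(strict$removed, c(FALSE, FALSE, FALSE))
})

test_that("bead filters agree with a brute-force count oracle and commute with reordering", {
  for (seed in 1:5) {
    beads <- withr::with_seed(seed, beta_tbl(matrix(sample(0:10, 50 * 30, TRUE), 50, 30)))
    m <- as.matrix(beads[, -1])
    p <- cpg_params()
    probe <- probe_bead_filter(beads, p)
    oracle_probe <- vapply(seq_len(nrow(m)), function(i) {
      sum(m[i, ] < p$min_beads) / ncol(m) > p$probe_fail_fraction
    }, logical(1))
    expect_equal(probe$removed, oracle_probe)
    samp <- sample_bead_filter(beads, p)
    oracle_samp <- vapply(seq_len(ncol(m)), function(j) {
      sum(m[, j] < p$min_beads) / nrow(m) >= p$sample_fail_fraction
    }, logical(1))
    expect_equal(samp$removed, oracle_samp)

    # permutation invariance: shuffle rows and columns, same verdicts per id
    perm <- withr::with_seed(seed + 100, beads[sample(nrow(beads)), c(1, 1 + sample(30))])
    probe2 <- probe_bead_filter(perm, p)
    expect_equal(probe2$removed[match(probe$cpg_id, probe2$cpg_id)],
                 probe$removed)
    samp2 <- sample_bead_filter(perm, p)
    expect_equal(samp2$removed[match(samp$sample_id, samp2$sample_id)],
                 samp$removed)
  }
})

test_that("all-passing bead counts remove nothing", {
  beads <- beta_tbl(matrix(3, 10, 10))
  expect_false(any(probe_bead_filter(beads)$removed))
  expect_false(any(sample_bead_filter(beads)$removed))
})

test_that("sample correlation is symmetric with unit diagonal and exact on constructed cases", {
  b <- beta_tbl(cbind(c(0.1, 0.2, 0.3), c(0.3, 0.2, 0.1), c(0.2, 0.4, 0.6),
                      c(0.1, 0.2, 0.3)))
  cc <- unclass(sample_correlation(b))
  expect_equal(cc, t(cc))
  expect_equal(diag(cc), rep(1, 4), ignore_attr = TRUE)
  expect_equal(cc[1, 2], -1)        # perfect anti-linear
  expect_equal(cc[1, 3], 1)         # perfect linear
  expect_equal(cc[1, 4], 1)         # duplicated sample
  # zero-variance sample reported, not silently zeroed
  bz <- beta_tbl(cbind(c(0.1, 0.2, 0.3), c(0.5, 0.5, 0.5)))
  cz <- sample_correlation(bz)
  expect_equal(attr(cz, "zero_variance"), "s002")
  expect_true(is.na(unclass(cz)[1, 2]))
})

test_that("a shuffled sample among coherent replicates is flagged under robust_z", {
  # 10 samples from a shared bimodal profile + noise; one is an independent
  # shuffle of another's values, destroying its correlation to the rest
  n_cpg <- 400
  sim <- withr::with_seed(42, {
    profile <- c(stats::runif(n_cpg / 2, 0, 0.15), stats::runif(n_cpg / 2, 0.85, 1))
    m <- sapply(1:10, function(i) pmin(pmax(profile + stats::rnorm(n_cpg, 0, 0.02), 0), 1))
    m[, 10] <- sample(m[, 1])
    m
  })
  b <- beta_tbl(sim)
  fl <- flag_outlier_samples(sample_correlation(b), policy = "robust_z", k = 3)
  expect_true(fl$flagged[10])
  expect_false(any(fl$flagged[1:9]))
  # direct recomputation of the mean-correlation score
  cc <- unclass(sample_correlation(b))
  diag(cc) <- NA
  expect_equal(fl$mean_cor, rowMeans(cc, na.rm = TRUE), ignore_attr = TRUE)
})

test_that("no sample is flagged when all pairs are perfectly correlated", {
  m <- matrix(rep(c(0.1, 0.5, 0.9), 5), 3, 5)
  m <- sweep(m, 2, seq(0, 0.04, 0.01), `+`)  # shifted copies: correlation 1
  fl <- flag_outlier_samples(sample_correlation(beta_tbl(m)))
  expect_false(any(fl$flagged))
  fl2 <- flag_outlier_samples(sample_correlation(beta_tbl(m)),
                              policy = "absolute_floor", c0 = 0.9)
  expect_false(any(fl2$flagged))
})

test_that("run_qc applies probe, sample then correlation stages and logs sizes", {
  bc <- simulate_bead_counts(n_cpgs = 300, n_samples = 20,
                             fail_rate_probe = 0.05, fail_rate_sample = 0.05,
                             seed = 3)
  betas <- random_beta_tbl(300, 20, seed = 4)
  names(betas) <- names(bc$beads)
  betas$cpg_id <- bc$beads$cpg_id
  res <- run_qc(betas, bc$beads)
  expect_s3_class(res$report, "qc_report")
  expect_true(all(bc$failing_cpgs %in%
                    res$report$probe_filter$cpg_id[res$report$probe_filter$removed]))
  expect_true(all(bc$failing_samples %in%
                    res$report$sample_filter$sample_id[res$report$sample_filter$removed]))
  expect_equal(res$report$n_cpgs_out, nrow(res$betas))
  expect_false(any(res$betas$cpg_id %in% bc$failing_cpgs))
})

test_that("study-level flagging trips when most of a study's samples are flagged", {
  flags <- tibble::tibble(sample_id = sprintf("s%d", 1:6),
                          mean_cor = c(0.99, 0.99, 0.99, 0.5, 0.4, 0.99),
                          flagged = c(FALSE, FALSE, FALSE, TRUE, TRUE, FALSE))
  manifest <- tibble::tibble(sample_id = sprintf("s%d", 1:6),
                             study_id = rep(c("gseA", "gseB"), each = 3),
                             tissue = "blood")
  st <- flag_outlier_studies(flags, manifest)
  expect_equal(st$flagged[st$study_id == "gseB"], TRUE)
  expect_equal(st$flagged[st$study_id == "gseA"], FALSE)
})
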