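#' Simulate a beta matrix with known ground truth
#'
#' Generates a CpG-by-sample beta matrix that mimics the salient structure
#' of array methylation data for testing the pipeline end to end:
#'
#' * `nonvariable_high` / `nonvariable_low` CpGs sit at a fixed methylated
#'   (> 0.80) or unmethylated (< 0.16) state plus tight Gaussian noise —
#'   the bimodal non-variable background.
#' * `variable_null` CpGs draw per-sample values from a wide distribution
#'   whose 10th-90th percentile spread is at least 0.15, with no group
#'   effect.
#' * `variable_signal` CpGs are variable and additionally shift the exposed
#'   group's mean by `signal_delta` — the planted true positives.
#'
#' All values are truncated to \[0, 1\]. Output is deterministic for a fixed
#' seed.
#'
#' @param n_cpgs,n_samples Matrix dimensions. Defaults 50,000 CpGs and 60
#'   samples.
#' @param class_fractions Named fractions over the four CpG classes; must
#'   sum to 1. Defaults: 10% high non-variable, 10% low non-variable,
#'   0.1% signal, remainder variable null.
#' @param noise_sd Gaussian noise SD around the planted state of
#'   non-variable CpGs (default 0.005).
#' @param signal_delta Planted group difference in mean beta at signal CpGs
#'   (default 0.10).
#' @param group_assignment Optional character/factor vector of length
#'   `n_samples` with two levels; default splits samples half and half into
#'   `"control"` and `"exposed"`.
#' @param seed Integer seed.
#' @return A list: `betas` (beta tibble), `truth` (tibble: `cpg_id`,
#'   `class`, `state_mean`, `delta_beta`), `design` (tibble: `sample_id`,
#'   `group`).
#' @export
simulate_beta_matrix <- function(n_cpgs = 50000L, n_samples = 60L,
                                 class_fractions = c(nonvariable_high = 0.10,
                                                     nonvariable_low = 0.10,
                                                     variable_null = 0.799,
                                                     variable_signal = 0.001),
                                 noise_sd = 0.005, signal_delta = 0.10,
                                 group_assignment = NULL, seed = 1L) {
  classes <- c("nonvariable_high", "nonvariable_low",
               "variable_null", "variable_signal")
  if (!all(classes %in% names(class_fractions))) {
    abort(paste0("class_fractions must name: ", paste(classes, collapse = ", ")))
  }
  class_fractions <- class_fractions[classes]
  if (any(class_fractions < 0) || abs(sum(class_fractions) - 1) > 1e-8) {
    abort("class_fractions must be non-negative and sum to 1")
  }
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  n_class <- round(class_fractions * n_cpgs)
  # rounding drift lands on the largest class
  n_class[which.max(n_class)] <- n_class[which.max(n_class)] +
    (n_cpgs - sum(n_class))
  if (any(n_class < 0)) abort("infeasible class fractions")

  if (is.null(group_assignment)) {
    group_assignment <- rep(c("control", "exposed"), length.out = n_samples)
  }
  if (length(group_assignment) != n_samples) {
    abort("group_assignment must have length n_samples")
  }
  grp <- factor(group_assignment)
  if (nlevels(grp) != 2L) abort("group_assignment must have 2 levels")
  exposed <- grp == levels(grp)[2L]

  withr::with_seed(seed, {
    cpg_ids <- sprintf("cg%08d", seq_len(n_cpgs))
    cls <- rep(classes, times = n_class)
    cls <- sample(cls)  # interleave classes across the id space

    state <- numeric(n_cpgs)
    state[cls == "nonvariable_high"] <- stats::runif(sum(cls == "nonvariable_high"), 0.85, 0.98)
    state[cls == "nonvariable_low"] <- stats::runif(sum(cls == "nonvariable_low"), 0.02, 0.15)
    is_var <- cls %in% c("variable_null", "variable_signal")
    state[is_var] <- stats::runif(sum(is_var), 0.25, 0.70)

    m <- matrix(NA_real_, n_cpgs, n_samples)
    nv <- !is_var
    m[nv, ] <- state[nv] + stats::rnorm(sum(nv) * n_samples, sd = noise_sd)
    # variable CpGs: per-CpG spread sd >= 0.07 so the 10-90 range (~2.56 sd)
    # clears 0.15 even after truncation
    var_sd <- stats::runif(sum(is_var), 0.07, 0.15)
    m[is_var, ] <- state[is_var] + stats::rnorm(sum(is_var) * n_samples) * var_sd
    sig <- cls == "variable_signal"
    if (any(sig)) {
      m[sig, exposed] <- m[sig, exposed, drop = FALSE] + signal_delta
    }
    m <- pmin(pmax(m, 0), 1)
    sample_ids <- sprintf("sample_%03d", seq_len(n_samples))
    dimnames(m) <- list(cpg_ids, sample_ids)

    list(
      betas = matrix_to_beta(m),
      truth = tibble::tibble(
        cpg_id = cpg_ids, class = cls, state_mean = state,
        delta_beta = ifelse(sig, signal_delta, 0)
      ),
      design = tibble::tibble(sample_id = sample_ids,
                              group = as.character(grp))
    )
  })
}

#' Simulate a bead-count matrix with planted failures
#'
#' Baseline counts are 3 plus a Poisson draw (always passing the < 3 bead
#' rule). A designated fraction of probes and of samples is planted to
#' fail: within a failing probe, `probe_fail_rate` of samples get sub-3
#' counts; within a failing sample, `sample_fail_rate` of CpGs do.
#'
#' @param n_cpgs,n_samples Matrix dimensions.
#' @param fail_rate_probe Fraction of CpGs planted as failing probes
#'   (default 0.02).
#' @param fail_rate_sample Fraction of samples planted as failing
#'   (default 0.02).
#' @param probe_fail_rate Within a failing probe, fraction of samples with
#'   sub-3 counts (default 0.10 — clears the 5% removal rule).
#' @param sample_fail_rate Within a failing sample, fraction of CpGs with
#'   sub-3 counts (default 0.05 — clears the 2.5% removal rule).
#' @param seed Integer seed.
#' @return A list: `beads` (tibble, `cpg_id` + sample columns),
#'   `failing_cpgs`, `failing_samples` (planted ground truth).
#' @export
simulate_bead_counts <- function(n_cpgs = 1000L, n_samples = 40L,
                                 fail_rate_probe = 0.02,
                                 fail_rate_sample = 0.02,
                                 probe_fail_rate = 0.10,
                                 sample_fail_rate = 0.05,
                                 seed = 1L) {
  for (r in c(fail_rate_probe, fail_rate_sample, probe_fail_rate,
              sample_fail_rate)) {
    if (r < 0 || r > 1) abort("failure rates must lie in [0, 1]")
  }
  withr::with_seed(seed, {
    cpg_ids <- sprintf("cg%08d", seq_len(n_cpgs))
    sample_ids <- sprintf("sample_%03d", seq_len(n_samples))
    counts <- matrix(3L + stats::rpois(n_cpgs * n_samples, 12),
                     n_cpgs, n_samples, dimnames = list(cpg_ids, sample_ids))
    n_fp <- round(fail_rate_probe * n_cpgs)
    n_fs <- round(fail_rate_sample * n_samples)
    failing_cpgs <- if (n_fp > 0) sample(cpg_ids, n_fp) else character()
    failing_samples <- if (n_fs > 0) sample(sample_ids, n_fs) else character()
    for (cg in failing_cpgs) {
      k <- max(1L, ceiling(probe_fail_rate * n_samples))
      counts[cg, sample.int(n_samples, k)] <- sample(0:2, k, replace = TRUE)
    }
    for (s in failing_samples) {
      k <- max(1L, ceiling(sample_fail_rate * n_cpgs))
      counts[sample.int(n_cpgs, k), s] <- sample(0:2, k, replace = TRUE)
    }
    beads <- tibble::as_tibble(as.data.frame(counts)) %>%
      tibble::add_column(cpg_id = cpg_ids, .before = 1L)
    list(beads = beads, failing_cpgs = failing_cpgs,
         failing_samples = failing_samples)
  })
}

#' Simulate a genomic-feature annotation table
#'
#' Draws, independently per CpG, a gene feature and a CpG-island feature
#' from given category frequencies. An optional bias plants enrichment: for
#' a designated subset the island and promoter probabilities are multiplied
#' by `enrichment_bias` and renormalised, giving a known expected fold
#' change for testing the permutation machinery.
#'
#' @param cpg_ids CpG ids to annotate.
#' @param gene_feature_freqs Named frequencies over promoter, intragenic,
#'   three_prime, intergenic (sum to 1).
#' @param island_feature_freqs Named frequencies over island, north_shore,
#'   south_shore, north_shelf, south_shelf, none (sum to 1).
#' @param enrichment_bias Multiplier (>= 0) on the island and promoter
#'   probability for `biased_cpgs`; 1 = no bias.
#' @param biased_cpgs CpG ids receiving the bias.
#' @param seed Integer seed.
#' @return An annotation tibble (`cpg_id`, `gene_feature`,
#'   `island_feature`).
#' @export
simulate_annotation <- function(cpg_ids,
                                gene_feature_freqs = c(promoter = 0.25,
                                                       intragenic = 0.35,
                                                       three_prime = 0.10,
                                                       intergenic = 0.30),
                                island_feature_freqs = c(island = 0.30,
                                                         north_shore = 0.10,
                                                         south_shore = 0.10,
                                                         north_shelf = 0.05,
                                                         south_shelf = 0.05,
                                                         none = 0.40),
                                enrichment_bias = 1,
                                biased_cpgs = NULL,
                                seed = 1L) {
  check_freqs <- function(f, levels, nm) {
    if (!all(levels %in% names(f))) {
      abort(paste0(nm, " must name: ", paste(levels, collapse = ", ")))
    }
    f <- f[levels]
    if (any(f < 0) || abs(sum(f) - 1) > 1e-8) {
      abort(paste0(nm, " must be non-negative and sum to 1"))
    }
    f
  }
  gf <- check_freqs(gene_feature_freqs, gene_feature_levels, "gene_feature_freqs")
  isf <- check_freqs(island_feature_freqs, island_feature_levels, "island_feature_freqs")
  if (enrichment_bias < 0) abort("enrichment_bias must be >= 0")
  biased <- cpg_ids %in% (biased_cpgs %||% character())

  bias_probs <- function(f, target) {
    f[target] <- f[target] * enrichment_bias
    f / sum(f)
  }
  gf_b <- bias_probs(gf, "promoter")
  isf_b <- bias_probs(isf, "island")

  withr::with_seed(seed, {
    draw <- function(n, probs) {
      sample(names(probs), n, replace = TRUE, prob = probs)
    }
    gene <- character(length(cpg_ids))
    isl <- character(length(cpg_ids))
    gene[!biased] <- draw(sum(!biased), gf)
    isl[!biased] <- draw(sum(!biased), isf)
    if (any(biased)) {
      gene[biased] <- draw(sum(biased), gf_b)
      isl[biased] <- draw(sum(biased), isf_b)
    }
    tibble::tibble(cpg_id = as.character(cpg_ids),
                   gene_feature = gene, island_feature = isl)
  })
}

#' `%||%` fallback
#' @noRd
`%||%` <- function(x, y) if (is.null(x)) y else x

#' The smoking-power simulation preset
#'
#' One call producing everything the sub-sampling power experiment needs: a
#' cohort with the default class mix (20% planted non-variable, 50 planted
#' signal CpGs at delta beta 0.10), its design, the planted truth, an
#' annotation, and the reference non-variable list (the planted non-variable
#' CpGs over the full simulated universe — the stand-in for an independently
#' derived tissue list).
#'
#' @param seed Integer master seed.
#' @param n_cpgs,n_samples Passed to [simulate_beta_matrix()].
#' @param ... Further arguments to [simulate_beta_matrix()].
#' @return A list: `betas`, `design`, `truth`, `annotation`, `reference`
#'   (a [nonvariable_list()]), `signal_cpgs`.
#' @export
simulate_smoking_power <- function(seed = 1L, n_cpgs = 50000L,
                                   n_samples = 60L, ...) {
  seeds <- derive_seeds(seed, 2L)
  sim <- simulate_beta_matrix(n_cpgs = n_cpgs, n_samples = n_samples,
                              seed = seeds[1L], ...)
  ann <- simulate_annotation(
    sim$truth$cpg_id,
    enrichment_bias = 3,
    biased_cpgs = sim$truth$cpg_id[startsWith(sim$truth$class, "nonvariable")],
    seed = seeds[2L])
  reference <- nonvariable_list(
    members = sim$truth$cpg_id[startsWith(sim$truth$class, "nonvariable")],
    universe = sim$truth$cpg_id,
    tissue = "simulated_blood", threshold = 0.05)
  list(betas = sim$betas, design = sim$design, truth = sim$truth,
       annotation = ann, reference = reference,
       signal_cpgs = sim$truth$cpg_id[sim$truth$class == "variable_signal"])
}
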