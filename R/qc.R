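#' Probe-level bead-count filter
#'
#' A CpG is removed when strictly more than `probe_fail_fraction` of samples
#' measured it with fewer than `min_beads` beads: such probes are unreliable
#' across the cohort, not just in an individual sample.
#'
#' @param beads Bead-count tibble: `cpg_id` column plus one non-negative
#'   integer column per sample.
#' @param params [cpg_params()] list; uses `min_beads` and
#'   `probe_fail_fraction`.
#' @return A tibble with one row per CpG: `cpg_id`, `n_fail` (samples below
#'   `min_beads`), `fail_fraction`, and `removed`. Attributes record the
#'   thresholds used. Retain with `dplyr::filter(!removed)`.
#' @examples
#' beads <- tibble::tibble(cpg_id = c("cg1", "cg2"),
#'                         s1 = c(2L, 5L), s2 = c(2L, 6L), s3 = c(8L, 9L))
#' probe_bead_filter(beads)
#' @export
probe_bead_filter <- function(beads, params = cpg_params()) {
  m <- bead_matrix(beads)
  if (ncol(m) == 0L) abort("bead matrix has zero samples")
  fail <- rowSums(m < params$min_beads)
  frac <- fail / ncol(m)
  out <- tibble::tibble(
    cpg_id = rownames(m),
    n_fail = as.integer(unname(fail)),
    fail_fraction = unname(frac),
    removed = unname(frac > params$probe_fail_fraction)
  )
  attr(out, "min_beads") <- params$min_beads
  attr(out, "probe_fail_fraction") <- params$probe_fail_fraction
  out
}

#' Sample-level bead-count filter
#'
#' A sample is removed when the fraction of its CpGs measured with fewer
#' than `min_beads` beads reaches `sample_fail_fraction` (inclusive `>=` by
#' default; set `sample_fail_inclusive = FALSE` in [cpg_params()] for a
#' strict `>`).
#'
#' @inheritParams probe_bead_filter
#' @return A tibble with one row per sample: `sample_id`, `n_fail`,
#'   `fail_fraction`, `removed`.
#' @export
sample_bead_filter <- function(beads, params = cpg_params()) {
  m <- bead_matrix(beads)
  if (nrow(m) == 0L) abort("bead matrix has zero CpGs")
  fail <- colSums(m < params$min_beads)
  frac <- fail / nrow(m)
  removed <- if (params$sample_fail_inclusive) {
    frac >= params$sample_fail_fraction
  } else {
    frac > params$sample_fail_fraction
  }
  out <- tibble::tibble(
    sample_id = colnames(m),
    n_fail = as.integer(unname(fail)),
    fail_fraction = unname(frac),
    removed = unname(removed)
  )
  attr(out, "min_beads") <- params$min_beads
  attr(out, "sample_fail_fraction") <- params$sample_fail_fraction
  out
}

bead_matrix <- function(beads) {
  check_beta_frame(beads, arg = "beads")
  m <- as.matrix(beads[, setdiff(names(beads), "cpg_id"), drop = FALSE])
  storage.mode(m) <- "double"
  if (any(!is.na(m) & m < 0)) abort("bead counts must be non-negative")
  rownames(m) <- beads$cpg_id
  m
}

#' Pairwise sample-sample correlation
#'
#' Correlation between every pair of sample columns over their shared CpGs;
#' the standard first look at cohort coherence on methylation arrays.
#' Zero-variance samples have undefined correlations: they are reported in
#' the `"zero_variance"` attribute and left `NA`, never silently zeroed.
#'
#' @param betas Beta tibble with at least 2 samples and 2 CpGs, no missing
#'   values.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A symmetric correlation matrix of class `sample_cor` with unit
#'   diagonal, sample ids as dimnames.
#' @export
sample_correlation <- function(betas, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  m <- beta_to_matrix(betas)
  if (ncol(m) < 2L) abort("need at least 2 samples")
  if (nrow(m) < 2L) abort("need at least 2 CpGs")
  if (anyNA(m)) abort("missing values present; assemble the cohort first")
  zero_var <- colnames(m)[apply(m, 2L, stats::sd) == 0]
  cc <- suppressWarnings(stats::cor(m, method = method))
  diag(cc) <- 1
  structure(cc, class = c("sample_cor", class(cc)),
            method = method, zero_variance = zero_var)
}

#' @method tidy sample_cor
#' @export
tidy.sample_cor <- function(x, ...) {
  m <- unclass(x)
  tibble::as_tibble(as.data.frame(as.table(m)), .name_repair = "minimal") %>%
    stats::setNames(c("sample_a", "sample_b", "correlation")) %>%
    dplyr::mutate(sample_a = as.character(.data$sample_a),
                  sample_b = as.character(.data$sample_b))
}

#' Flag samples with low mean sample-sample correlation
#'
#' Each sample is scored by its mean correlation to all other samples; low
#' scores indicate outliers (swapped tissue, failed hybridisation, heavy
#' batch effects). Two policies: `robust_z` flags scores below
#' `median - k * MAD` (default, k = 3) and `absolute_floor` flags scores
#' below a fixed value `c0`. Both replace the visual inspection of
#' correlation heat maps with a logged, reproducible rule.
#'
#' @param corr A `sample_cor` matrix from [sample_correlation()].
#' @param policy `"robust_z"` or `"absolute_floor"`.
#' @param k MAD multiplier for `robust_z` (> 0).
#' @param c0 Correlation floor for `absolute_floor` (in \[-1, 1\]).
#' @return A tibble: `sample_id`, `mean_cor`, `flagged`, with the policy in
#'   attributes. Samples with undefined (zero-variance) correlations are
#'   always flagged.
#' @export
flag_outlier_samples <- function(corr, policy = c("robust_z", "absolute_floor"),
                                 k = 3, c0 = 0.9) {
  policy <- match.arg(policy)
  if (!inherits(corr, "sample_cor")) abort("`corr` must come from sample_correlation()")
  m <- unclass(corr)
  if (ncol(m) < 3L) abort("need at least 3 samples to score outliers")
  diag(m) <- NA_real_
  score <- rowMeans(m, na.rm = TRUE)
  undefined <- rownames(m) %in% attr(corr, "zero_variance")
  score[undefined] <- NA_real_
  if (policy == "robust_z") {
    if (!is.numeric(k) || k <= 0) abort("`k` must be positive")
    med <- stats::median(score, na.rm = TRUE)
    mad <- stats::mad(score, na.rm = TRUE)
    flagged <- !is.na(score) & mad > 0 & score < med - k * mad
  } else {
    if (!is.numeric(c0) || c0 < -1 || c0 > 1) abort("`c0` must be in [-1, 1]")
    flagged <- !is.na(score) & score < c0
  }
  flagged <- flagged | undefined
  out <- tibble::tibble(sample_id = rownames(m), mean_cor = unname(score),
                        flagged = unname(flagged))
  attr(out, "policy") <- policy
  attr(out, "k") <- if (policy == "robust_z") k else NULL
  attr(out, "c0") <- if (policy == "absolute_floor") c0 else NULL
  out
}

#' Flag whole studies by their fraction of flagged samples
#'
#' A study is flagged when more than `fraction` of its samples were flagged
#' by [flag_outlier_samples()] — the automated analogue of dropping a whole
#' low-correlation study from a meta-analysis.
#'
#' @param flags Output of [flag_outlier_samples()].
#' @param manifest Manifest tibble with `sample_id` and `study_id`.
#' @param fraction Flagged-sample fraction above which the study is flagged
#'   (default 0.5).
#' @return A tibble: `study_id`, `n_samples`, `n_flagged`, `flagged`.
#' @export
flag_outlier_studies <- function(flags, manifest, fraction = 0.5) {
  joined <- dplyr::inner_join(flags, manifest[c("sample_id", "study_id")],
                              by = "sample_id")
  joined %>%
    dplyr::group_by(.data$study_id) %>%
    dplyr::summarise(n_samples = dplyr::n(),
                     n_flagged = sum(.data$flagged),
                     .groups = "drop") %>%
    dplyr::mutate(flagged = .data$n_flagged / .data$n_samples > fraction)
}

#' Run the full quality-control sequence
#'
#' Applies, in order: the probe bead filter, the sample bead filter, then
#' the sample-correlation outlier screen on what survives. Returns the
#' filtered beta matrix together with a `qc_report` logging every removal
#' and the thresholds used.
#'
#' @param betas Beta tibble.
#' @param beads Matching bead-count tibble (optional; bead filters are
#'   skipped when `NULL`).
#' @param params [cpg_params()].
#' @param policy,k,c0 Passed to [flag_outlier_samples()].
#' @return A list of class `qc_result`: `betas` (filtered), `report`
#'   (class `qc_report`: the three per-stage tibbles plus a size log).
#' @export
run_qc <- function(betas, beads = NULL, params = cpg_params(),
                   policy = "robust_z", k = 3, c0 = 0.9) {
  check_beta_frame(betas)
  probe_rep <- NULL
  sample_rep <- NULL
  if (!is.null(beads)) {
    probe_rep <- probe_bead_filter(beads, params)
    sample_rep <- sample_bead_filter(beads, params)
    keep_cpg <- probe_rep$cpg_id[!probe_rep$removed]
    keep_sample <- sample_rep$sample_id[!sample_rep$removed]
    betas <- betas[betas$cpg_id %in% keep_cpg,
                   c("cpg_id", intersect(sample_ids_of(betas), keep_sample))]
  }
  cor_rep <- NULL
  if (length(sample_ids_of(betas)) >= 3L && nrow(betas) >= 2L) {
    corr <- sample_correlation(betas)
    cor_rep <- flag_outlier_samples(corr, policy = policy, k = k, c0 = c0)
    keep <- cor_rep$sample_id[!cor_rep$flagged]
    betas <- betas[, c("cpg_id", intersect(sample_ids_of(betas), keep))]
  }
  report <- structure(
    list(probe_filter = probe_rep, sample_filter = sample_rep,
         correlation_screen = cor_rep,
         n_cpgs_out = nrow(betas),
         n_samples_out = length(sample_ids_of(betas)),
         params = params),
    class = "qc_report")
  structure(list(betas = betas, report = report), class = "qc_result")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>\n")
  if (!is.null(x$probe_filter)) {
    cat("  probe bead filter:   ", sum(x$probe_filter$removed), "of",
        nrow(x$probe_filter), "CpGs removed\n")
  }
  if (!is.null(x$sample_filter)) {
    cat("  sample bead filter:  ", sum(x$sample_filter$removed), "of",
        nrow(x$sample_filter), "samples removed\n")
  }
  if (!is.null(x$correlation_screen)) {
    cat("  correlation screen:  ", sum(x$correlation_screen$flagged),
        "sample(s) flagged\n")
  }
  cat("  output:", x$n_cpgs_out, "CpGs x", x$n_samples_out, "samples\n")
  invisible(x)
}
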