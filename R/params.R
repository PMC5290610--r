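#' Analysis parameters
#'
#' Collects every numeric constant of the pipeline in one validated list:
#' quality-control thresholds, the non-variable calling rule, permutation
#' counts, EWAS hit thresholds and the sub-sampling design.
#'
#' @param nonvar_threshold Reference-range threshold below which a CpG is
#'   called non-variable. Beta-value units; default 0.05 (a 5% spread between
#'   the 10th and 90th percentile).
#' @param quantile_low,quantile_high Probability levels of the reference-range
#'   order statistics. Defaults 0.10 and 0.90.
#' @param min_beads Minimum bead count for a reliable probe measurement;
#'   counts below this are failures. Default 3.
#' @param probe_fail_fraction A CpG is removed when the fraction of samples
#'   failing the bead check is strictly greater than this. Default 0.05.
#' @param sample_fail_fraction A sample is removed when the fraction of CpGs
#'   failing the bead check reaches this value. Default 0.025.
#' @param sample_fail_inclusive Whether the sample bead filter removes at
#'   exactly `sample_fail_fraction` (`>=`, default) or only strictly above it.
#' @param nonvar_inclusive Whether non-variable calling uses `<=` instead of
#'   the default strict `<` at `nonvar_threshold`.
#' @param n_permutations Number of random-list permutations for the genomic
#'   enrichment test. Default 1000.
#' @param fdr_cutoff BH-adjusted p-value cutoff for EWAS hit calling.
#'   Default 0.05.
#' @param delta_beta_cutoff Minimum absolute delta beta for a hit.
#'   Default 0.1.
#' @param subsample_per_group Samples drawn per exposure group in each
#'   sub-sampling replicate. Default 12.
#' @param subsample_reps Number of sub-sampling replicates. Default 10.
#' @param random_seed Optional integer seed recorded with results.
#'
#' @return A named list of class `cpg_params`.
#' @examples
#' p <- cpg_params(nonvar_threshold = 0.10)
#' p$nonvar_threshold
#' @export
cpg_params <- function(nonvar_threshold = 0.05,
                       quantile_low = 0.10,
                       quantile_high = 0.90,
                       min_beads = 3,
                       probe_fail_fraction = 0.05,
                       sample_fail_fraction = 0.025,
                       sample_fail_inclusive = TRUE,
                       nonvar_inclusive = FALSE,
                       n_permutations = 1000,
                       fdr_cutoff = 0.05,
                       delta_beta_cutoff = 0.1,
                       subsample_per_group = 12,
                       subsample_reps = 10,
                       random_seed = NULL) {
  p <- list(
    nonvar_threshold = nonvar_threshold,
    quantile_low = quantile_low,
    quantile_high = quantile_high,
    min_beads = min_beads,
    probe_fail_fraction = probe_fail_fraction,
    sample_fail_fraction = sample_fail_fraction,
    sample_fail_inclusive = isTRUE(sample_fail_inclusive),
    nonvar_inclusive = isTRUE(nonvar_inclusive),
    n_permutations = n_permutations,
    fdr_cutoff = fdr_cutoff,
    delta_beta_cutoff = delta_beta_cutoff,
    subsample_per_group = subsample_per_group,
    subsample_reps = subsample_reps,
    random_seed = random_seed
  )
  validate_params(p)
  structure(p, class = "cpg_params")
}

validate_params <- function(p) {
  stopifnot(
    is.numeric(p$quantile_low), is.numeric(p$quantile_high),
    p$quantile_low >= 0, p$quantile_low < p$quantile_high,
    p$quantile_high <= 1
  )
  for (nm in c("nonvar_threshold", "probe_fail_fraction",
               "sample_fail_fraction", "fdr_cutoff", "delta_beta_cutoff")) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop("`", nm, "` must be a single value in [0, 1]", call. = FALSE)
    }
  }
  for (nm in c("min_beads", "n_permutations", "subsample_per_group",
               "subsample_reps")) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 1 ||
        v != as.integer(v)) {
      stop("`", nm, "` must be a positive integer", call. = FALSE)
    }
  }
  invisible(p)
}

#' @export
print.cpg_params <- function(x, ...) {
  cat("<cpg_params>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-22s %s\n", nm,
                if (is.null(v)) "NULL" else paste(format(v), collapse = " ")))
  }
  invisible(x)
}
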