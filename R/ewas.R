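#' Per-CpG linear-model EWAS
#'
#' Fits, for every CpG, an ordinary least-squares model of methylation on a
#' two-level exposure plus optional numeric covariates, fully vectorised
#' across CpGs. The exposure coefficient's two-sided p-value comes from the
#' t distribution on the residual degrees of freedom; BH adjustment runs
#' across all CpGs tested in the call. The delta-beta effect size is always
#' the raw difference of group mean betas (exposed minus unexposed),
#' regardless of covariates and of the modelling scale.
#'
#' Degenerate fits with zero residual variance get p = 1 by convention so
#' numerically constant CpGs can never become spurious hits.
#'
#' @param betas Beta tibble (`cpg_id` + sample columns), no missing values.
#' @param design Tibble with `sample_id`, the exposure column and any
#'   covariate columns; every beta sample needs a design row.
#' @param exposure Name of the exposure column (two levels; the second
#'   level in factor order is "exposed"). Default `"group"`.
#' @param covariates Character vector of numeric covariate column names.
#' @param response Modelling scale: `"beta"` (default) or `"m"` to fit on
#'   M-values (delta beta stays on the beta scale).
#' @return A tibble of class `cpg_ewas`: `cpg_id`, `estimate` (exposure
#'   coefficient on the modelling scale), `delta_beta`, `statistic`,
#'   `p_value`, `q_value`; attributes record the design.
#' @export
fit_linear_ewas <- function(betas, design, exposure = "group",
                            covariates = character(),
                            response = c("beta", "m")) {
  response <- match.arg(response)
  m <- beta_to_matrix(betas)
  if (anyNA(m)) abort("missing beta values; assemble the cohort first")
  if (!exposure %in% names(design)) {
    abort(paste0("design has no `", exposure, "` column"))
  }
  missing <- setdiff(colnames(m), design$sample_id)
  if (length(missing) > 0L) {
    abort(paste0("samples absent from design: ",
                 paste(utils::head(missing, 5L), collapse = ", ")))
  }
  design <- design[match(colnames(m), design$sample_id), ]
  grp <- factor(design[[exposure]])
  if (nlevels(grp) != 2L) abort("exposure must have exactly 2 levels")
  if (any(table(grp) < 2L)) abort("each exposure level needs >= 2 samples")
  g <- as.numeric(grp == levels(grp)[2L])
  X <- cbind(`(Intercept)` = 1, exposure = g)
  for (cv in covariates) {
    if (!cv %in% names(design)) abort(paste0("design has no `", cv, "` column"))
    v <- design[[cv]]
    if (!is.numeric(v)) abort(paste0("covariate `", cv, "` must be numeric"))
    X <- cbind(X, v)
    colnames(X)[ncol(X)] <- cv
  }
  if (qr(X)$rank < ncol(X)) abort("rank-deficient design matrix")
  n <- nrow(X)
  df <- n - ncol(X)
  if (df < 1L) abort("no residual degrees of freedom")

  Y <- if (response == "m") {
    ym <- pmin(pmax(m, 1e-6), 1 - 1e-6)  # guard the logit at the boundary
    log2(ym / (1 - ym))
  } else m

  XtXi <- solve(crossprod(X))
  H <- X %*% XtXi                       # n x p
  # row-wise products via sweep + rowSums: each CpG's fit is computed by the
  # same arithmetic regardless of how many CpGs share the matrix, so raw
  # statistics are bit-identical between a full and a filtered run
  B <- matrix(0, nrow(Y), ncol(X), dimnames = list(NULL, colnames(X)))
  for (j in seq_len(ncol(X))) {
    B[, j] <- rowSums(sweep(Y, 2L, H[, j], `*`))
  }
  resid <- Y
  for (k in seq_len(n)) {
    resid[, k] <- Y[, k] - rowSums(sweep(B, 2L, X[k, ], `*`))
  }
  rss <- rowSums(resid^2)
  sigma2 <- rss / df
  se <- sqrt(sigma2 * XtXi["exposure", "exposure"])
  est <- B[, "exposure"]
  tstat <- ifelse(se > 0, est / se, 0)
  p <- 2 * stats::pt(-abs(tstat), df)
  # zero-residual degenerate fits: p = 1 by convention
  degenerate <- rss <= n * .Machine$double.eps^0.75 * pmax(1, rowSums(Y^2))
  p[degenerate] <- 1
  tstat[degenerate] <- 0

  delta_beta <- rowMeans(m[, g == 1, drop = FALSE]) -
    rowMeans(m[, g == 0, drop = FALSE])

  out <- tibble::tibble(
    cpg_id = rownames(m),
    estimate = unname(est),
    delta_beta = unname(delta_beta),
    statistic = unname(tstat),
    p_value = unname(p),
    q_value = bh_fdr(unname(p))
  )
  structure(out, class = c("cpg_ewas", class(out)),
            exposure = exposure, exposure_levels = levels(grp),
            covariates = covariates, response = response,
            n_samples = n, df = df)
}

#' @method tidy cpg_ewas
#' @export
tidy.cpg_ewas <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("cpg_id", "estimate", "delta_beta",
                                 "statistic", "p_value", "q_value")])
}

#' @method glance cpg_ewas
#' @export
glance.cpg_ewas <- function(x, params = cpg_params(), ...) {
  hits <- hit_calling(x, params)
  tibble::tibble(n_cpgs = nrow(x), n_samples = attr(x, "n_samples"),
                 df = attr(x, "df"), n_hits = sum(hits$hit),
                 min_q = min(x$q_value))
}

#' Call EWAS hits
#'
#' A CpG is a hit when it clears both gates: BH-adjusted p below
#' `fdr_cutoff` (statistical) and |delta beta| at or above
#' `delta_beta_cutoff` (biological effect size).
#'
#' @param result A `cpg_ewas` tibble from [fit_linear_ewas()].
#' @param params [cpg_params()]; uses `fdr_cutoff` and `delta_beta_cutoff`.
#' @return `result` with a logical `hit` column appended.
#' @export
hit_calling <- function(result, params = cpg_params()) {
  stopifnot(all(c("q_value", "delta_beta") %in% names(result)))
  dplyr::mutate(
    result,
    hit = .data$q_value < params$fdr_cutoff &
      abs(.data$delta_beta) >= params$delta_beta_cutoff
  )
}

#' Confirm-and-remove variability filter
#'
#' Applies a reference non-variable list to a new study by the
#' confirm-and-remove rule: a CpG is removed only when it is BOTH on the
#' reference list AND non-variable within the study itself (study reference
#' range below the threshold). CpGs that the reference calls non-variable
#' but that do vary in the new data are kept, avoiding false negatives from
#' an over-eager filter.
#'
#' @param study_ranges [reference_range()] tibble computed on the study's
#'   own samples.
#' @param reference A [nonvariable_list()] (or character vector of CpG ids).
#' @param params [cpg_params()]; uses `nonvar_threshold` and
#'   `nonvar_inclusive`.
#' @return A tibble with one row per tested CpG: `cpg_id`, `range`,
#'   `study_nonvariable`, `in_reference`, `removed`; attribute `n_removed`.
#'   `sum(!x$removed)` always equals `nrow(x) - sum(x$removed)`.
#' @export
confirm_and_filter <- function(study_ranges, reference,
                               params = cpg_params()) {
  stopifnot(is.data.frame(study_ranges),
            all(c("cpg_id", "range") %in% names(study_ranges)))
  ref_members <- if (inherits(reference, "nonvariable_list")) {
    reference$members
  } else {
    as.character(reference)
  }
  study_nonvar <- if (params$nonvar_inclusive) {
    study_ranges$range <= params$nonvar_threshold
  } else {
    study_ranges$range < params$nonvar_threshold
  }
  in_ref <- study_ranges$cpg_id %in% ref_members
  if (length(ref_members) > 0L && !any(in_ref)) {
    warn("reference list shares no CpGs with the study; nothing removed")
  }
  out <- tibble::tibble(
    cpg_id = study_ranges$cpg_id,
    range = study_ranges$range,
    study_nonvariable = study_nonvar,
    in_reference = in_ref,
    removed = study_nonvar & in_ref
  )
  attr(out, "n_removed") <- sum(out$removed)
  attr(out, "threshold") <- params$nonvar_threshold
  out
}

#' Retained CpG ids after confirm-and-remove filtering
#'
#' @param filter_table Output of [confirm_and_filter()].
#' @return Character vector of retained CpG ids.
#' @export
retained_cpgs <- function(filter_table) {
  filter_table$cpg_id[!filter_table$removed]
}

#' Sub-sampling power experiment
#'
#' Emulates a low-powered study: repeatedly draws a small balanced
#' sub-cohort, runs the EWAS once on all CpGs (unfiltered arm) and once on
#' the CpGs retained by [confirm_and_filter()] (filtered arm, with study
#' reference ranges recomputed within the replicate), and compares
#' BH-adjusted p-values at tracked CpGs plus hit counts between arms. Raw
#' p-values at retained CpGs are identical between arms by construction;
#' only the multiple-testing family changes.
#'
#' @param betas Beta tibble of the full cohort.
#' @param design Design tibble (see [fit_linear_ewas()]).
#' @param reference [nonvariable_list()] used by the filter.
#' @param params [cpg_params()]; uses `subsample_per_group`,
#'   `subsample_reps`, the hit thresholds and the non-variable rule.
#' @param seed Master integer seed; per-replicate seeds are derived from it
#'   deterministically.
#' @param tracked Character vector of CpG ids whose adjusted p-values are
#'   reported per replicate (e.g. known true positives).
#' @param exposure,covariates Passed to [fit_linear_ewas()].
#' @param recompute_ranges Recompute study ranges within each replicate
#'   (default `TRUE`); `FALSE` confirms against full-cohort ranges instead.
#' @return A list of class `subsample_experiment`: `tracked` (tibble:
#'   replicate, cpg_id, arm, q_value, removed), `hits` (tibble: replicate,
#'   arm, n_hits, n_tested), `draws` (list of sample-id vectors), `seed`.
#' @export
subsample_experiment <- function(betas, design, reference,
                                 params = cpg_params(), seed = 1L,
                                 tracked = character(),
                                 exposure = "group",
                                 covariates = character(),
                                 recompute_ranges = TRUE) {
  check_beta_frame(betas)
  samples <- sample_ids_of(betas)
  design <- design[match(samples, design$sample_id), ]
  grp <- factor(design[[exposure]])
  if (nlevels(grp) != 2L) abort("exposure must have exactly 2 levels")
  per <- params$subsample_per_group
  if (any(table(grp) < per)) {
    abort(sprintf("each group needs >= %d samples", per))
  }
  reps <- params$subsample_reps
  rep_seeds <- derive_seeds(seed, reps)
  full_ranges <- if (!recompute_ranges) reference_range(betas, params) else NULL

  res <- purrr::map(seq_len(reps), function(r) {
    draw <- withr::with_seed(rep_seeds[r], {
      unlist(lapply(levels(grp), function(lv) {
        sample(samples[grp == lv], per)
      }))
    })
    sub <- betas[, c("cpg_id", draw)]
    sub_design <- design[match(draw, design$sample_id), ]
    unfiltered <- fit_linear_ewas(sub, sub_design, exposure = exposure,
                                  covariates = covariates)
    ranges <- if (recompute_ranges) reference_range(sub, params) else full_ranges
    filt <- confirm_and_filter(ranges, reference, params)
    keep <- retained_cpgs(filt)
    filtered <- fit_linear_ewas(sub[sub$cpg_id %in% keep, ], sub_design,
                                exposure = exposure, covariates = covariates)
    tracked_tbl <- NULL
    if (length(tracked) > 0L) {
      tracked_tbl <- dplyr::bind_rows(
        tibble::tibble(replicate = r, arm = "unfiltered", cpg_id = tracked,
                       q_value = unfiltered$q_value[match(tracked, unfiltered$cpg_id)],
                       removed = FALSE),
        tibble::tibble(replicate = r, arm = "filtered", cpg_id = tracked,
                       q_value = filtered$q_value[match(tracked, filtered$cpg_id)],
                       removed = !tracked %in% filtered$cpg_id)
      )
    }
    hits_tbl <- dplyr::bind_rows(
      tibble::tibble(replicate = r, arm = "unfiltered",
                     n_hits = sum(hit_calling(unfiltered, params)$hit),
                     n_tested = nrow(unfiltered)),
      tibble::tibble(replicate = r, arm = "filtered",
                     n_hits = sum(hit_calling(filtered, params)$hit),
                     n_tested = nrow(filtered))
    )
    list(tracked = tracked_tbl, hits = hits_tbl, draw = draw)
  })

  structure(list(
    tracked = dplyr::bind_rows(purrr::map(res, "tracked")),
    hits = dplyr::bind_rows(purrr::map(res, "hits")),
    draws = purrr::map(res, "draw"),
    seed = seed, params = params
  ), class = "subsample_experiment")
}

#' @export
print.subsample_experiment <- function(x, ...) {
  reps <- max(x$hits$replicate)
  cat(sprintf("<subsample_experiment> %d replicates\n", reps))
  wide <- tidyr::pivot_wider(x$hits, id_cols = "replicate",
                             names_from = "arm",
                             values_from = c("n_hits", "n_tested"))
  print(wide, n = reps)
  invisible(x)
}

#' @method glance subsample_experiment
#' @export
glance.subsample_experiment <- function(x, ...) {
  hw <- tidyr::pivot_wider(x$hits, id_cols = "replicate",
                           names_from = "arm", values_from = "n_hits")
  out <- tibble::tibble(
    n_replicates = nrow(hw),
    reps_filtered_more_hits = sum(hw$filtered > hw$unfiltered),
    reps_any_hits = sum(hw$filtered > 0 | hw$unfiltered > 0)
  )
  if (nrow(x$tracked) > 0L) {
    tw <- x$tracked %>%
      dplyr::group_by(.data$replicate, .data$arm) %>%
      dplyr::summarise(mean_q = mean(.data$q_value, na.rm = TRUE),
                       .groups = "drop") %>%
      tidyr::pivot_wider(names_from = "arm", values_from = "mean_q")
    out$reps_filtered_q_le <- sum(tw$filtered <= tw$unfiltered, na.rm = TRUE)
  }
  out
}
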