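#' Per-CpG reference-range variability statistic
#'
#' For each CpG the betas across samples are reduced to the spread between
#' two order statistics — by default the 10th and 90th percentile — whose
#' difference is the reference range. Trimming the outer 10% on each side
#' makes the statistic robust to a few outlying samples while still
#' reflecting population-level variability.
#'
#' Percentiles use linear interpolation of order statistics: with sorted
#' values x_(1..n) and level p, h = (n-1)p + 1 and
#' q = x_(floor(h)) + (h - floor(h)) (x_(floor(h)+1) - x_(floor(h))).
#' The estimator is fixed and documented because list membership near the
#' threshold depends on it.
#'
#' @param betas Beta tibble (`cpg_id` + sample columns), at least 2 samples,
#'   no missing values, all values in \[0, 1\].
#' @param params [cpg_params()]; uses `quantile_low` and `quantile_high`.
#' @return A tibble: `cpg_id`, `q_low`, `q_high`, `range`.
#' @examples
#' b <- tibble::tibble(cpg_id = "cg1",
#'                     !!!stats::setNames(as.list(seq(0, 0.9, 0.1)),
#'                                        paste0("s", 1:10)))
#' reference_range(b)  # q_low 0.09, q_high 0.81, range 0.72
#' @export
reference_range <- function(betas, params = cpg_params()) {
  m <- beta_to_matrix(betas)
  n <- ncol(m)
  if (n < 2L) abort("need at least 2 samples to compute a reference range")
  if (anyNA(m)) abort("missing values present; assemble the cohort first")
  check_beta_range(m)
  # row-wise sort; columns of `s` are the per-CpG order statistics
  s <- apply(m, 1L, sort.int, method = "quick")
  q_low <- interp_quantile(s, n, params$quantile_low)
  q_high <- interp_quantile(s, n, params$quantile_high)
  tibble::tibble(cpg_id = rownames(m), q_low = unname(q_low),
                 q_high = unname(q_high), range = unname(q_high - q_low))
}

# s: n x m matrix, each column sorted ascending; interpolated quantile at p.
interp_quantile <- function(s, n, p) {
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- min(lo + 1, n)
  g <- h - lo
  s[lo, ] + g * (s[hi, ] - s[lo, ])
}

#' Call non-variable CpGs from a reference-range table
#'
#' CpGs whose reference range falls below `nonvar_threshold` (strictly, by
#' default) are called non-variable in the tissue: across the cohort their
#' central 80% of beta values spans less than the threshold, so they carry
#' essentially no information for association testing in that tissue.
#'
#' @param ranges Tibble from [reference_range()].
#' @param params [cpg_params()]; uses `nonvar_threshold` and
#'   `nonvar_inclusive`.
#' @param tissue Label stored with the list (e.g. `"blood"`).
#' @return A [nonvariable_list()]: members, universe (all CpGs tested),
#'   tissue and threshold.
#' @export
call_nonvariable <- function(ranges, params = cpg_params(),
                             tissue = "unspecified") {
  stopifnot(is.data.frame(ranges), all(c("cpg_id", "range") %in% names(ranges)))
  keep <- if (params$nonvar_inclusive) {
    ranges$range <= params$nonvar_threshold
  } else {
    ranges$range < params$nonvar_threshold
  }
  nonvariable_list(members = ranges$cpg_id[keep],
                   universe = ranges$cpg_id,
                   tissue = tissue,
                   threshold = params$nonvar_threshold)
}

#' A tissue-labelled non-variable CpG list
#'
#' Bundles the called members with the universe they were tested on, the
#' tissue label and the threshold — everything needed to reuse the list as a
#' filter or to permute it against its own universe.
#'
#' @param members Character vector of called CpG ids.
#' @param universe Character vector of all CpG ids tested (must contain
#'   `members`).
#' @param tissue Tissue label.
#' @param threshold Reference-range threshold that produced the list.
#' @return An object of class `nonvariable_list`.
#' @export
nonvariable_list <- function(members, universe, tissue = "unspecified",
                             threshold = NA_real_) {
  members <- unique(as.character(members))
  universe <- unique(as.character(universe))
  if (!all(members %in% universe)) {
    abort("list members must be a subset of the universe")
  }
  structure(list(members = members, universe = universe,
                 tissue = tissue, threshold = threshold),
            class = "nonvariable_list")
}

#' @export
print.nonvariable_list <- function(x, ...) {
  cat(sprintf("<nonvariable_list> %s: %d of %d CpGs (threshold %s)\n",
              x$tissue, length(x$members), length(x$universe),
              format(x$threshold)))
  invisible(x)
}

#' @export
length.nonvariable_list <- function(x) length(x$members)

#' @method tidy nonvariable_list
#' @export
tidy.nonvariable_list <- function(x, ...) {
  tibble::tibble(cpg_id = x$universe,
                 nonvariable = x$universe %in% x$members,
                 tissue = x$tissue)
}

#' @method glance nonvariable_list
#' @export
glance.nonvariable_list <- function(x, ...) {
  tibble::tibble(tissue = x$tissue, threshold = x$threshold,
                 n_universe = length(x$universe),
                 n_members = length(x$members),
                 fraction = length(x$members) / length(x$universe))
}

#' Intersect non-variable lists across tissues
#'
#' Computes the k-way intersection of list members on the common universe
#' (the intersection of the lists' universes), plus per-list and pairwise
#' overlap sizes — the cross-tissue comparison of non-variable CpG lists.
#'
#' @param lists A list of [nonvariable_list()] objects (at least 2).
#' @return A list of class `list_overlap`: `common_members`,
#'   `common_universe`, `sizes` (per-list tibble), `pairwise` (tibble of
#'   pairwise intersection sizes on the common universe).
#' @export
intersect_lists <- function(lists) {
  if (length(lists) < 2L) abort("need at least 2 lists")
  purrr::walk(lists, function(l) {
    if (!inherits(l, "nonvariable_list")) abort("all inputs must be nonvariable_list objects")
  })
  common_universe <- Reduce(intersect, lapply(lists, `[[`, "universe"))
  if (length(common_universe) == 0L) abort("lists share no universe CpGs")
  members_common <- lapply(lists, function(l) intersect(l$members, common_universe))
  common <- Reduce(intersect, members_common)
  labels <- vapply(seq_along(lists), function(i) {
    t <- lists[[i]]$tissue
    if (is.null(t) || t == "unspecified") paste0("list", i) else t
  }, character(1L))
  sizes <- tibble::tibble(
    list = labels,
    n_members = vapply(lists, function(l) length(l$members), integer(1L)),
    n_members_on_common = lengths(members_common)
  )
  pairs <- utils::combn(seq_along(lists), 2L)
  pairwise <- tibble::tibble(
    list_a = labels[pairs[1L, ]],
    list_b = labels[pairs[2L, ]],
    n_intersection = apply(pairs, 2L, function(ij) {
      length(intersect(members_common[[ij[1L]]], members_common[[ij[2L]]]))
    })
  )
  structure(list(common_members = common, common_universe = common_universe,
                 sizes = sizes, pairwise = pairwise),
            class = "list_overlap")
}

#' @export
print.list_overlap <- function(x, ...) {
  cat(sprintf("<list_overlap> %d lists, common universe %d, overall intersection %d\n",
              nrow(x$sizes), length(x$common_universe), length(x$common_members)))
  print(x$sizes)
  invisible(x)
}

#' @method glance list_overlap
#' @export
glance.list_overlap <- function(x, ...) {
  tibble::tibble(n_lists = nrow(x$sizes),
                 n_common_universe = length(x$common_universe),
                 n_intersection = length(x$common_members))
}

#' Permutation test for cross-tissue list overlap
#'
#' Is the observed k-way overlap larger than expected for random lists of
#' the same sizes? Each permutation draws, from each list's own universe, a
#' uniform random subset of that list's size, and records the size of the
#' k-way intersection on the common universe. The empirical p-value uses the
#' add-one estimator, so the smallest reportable p is 1/(n_perm + 1);
#' resolving p < 1e-4 therefore needs n_perm >= 10,000 (the default).
#'
#' @param lists A list of [nonvariable_list()] objects.
#' @param n_perm Number of permutations (default 10,000).
#' @param seed Optional integer seed.
#' @return A list of class `overlap_permutation`: `observed`, `perm_overlaps`
#'   (integer vector of permuted intersection sizes), `p_value`, `n_perm`,
#'   `seed`.
#' @export
overlap_permutation_test <- function(lists, n_perm = 10000L, seed = NULL) {
  if (n_perm < 1L) abort("`n_perm` must be >= 1")
  ov <- intersect_lists(lists)
  observed <- length(ov$common_members)
  common <- ov$common_universe
  sizes <- vapply(lists, function(l) length(l$members), integer(1L))
  universes <- lapply(lists, `[[`, "universe")
  purrr::walk2(sizes, universes, function(s, u) {
    if (s > length(u)) abort("list larger than its universe")
  })
  # For intersection counting only membership of common-universe CpGs matters;
  # map each universe onto the common set once.
  common_index <- lapply(universes, function(u) match(u, common))
  n_common <- length(common)
  perm_overlaps <- with_seed_if(seed, {
    vapply(seq_len(n_perm), function(i) {
      tally <- integer(n_common)
      for (j in seq_along(lists)) {
        drawn <- sample.int(length(universes[[j]]), sizes[j])
        idx <- common_index[[j]][drawn]
        idx <- idx[!is.na(idx)]
        tally[idx] <- tally[idx] + 1L
      }
      sum(tally == length(lists))
    }, integer(1L))
  })
  structure(list(observed = observed, perm_overlaps = perm_overlaps,
                 p_value = empirical_p(sum(perm_overlaps >= observed), n_perm),
                 n_perm = n_perm, seed = seed),
            class = "overlap_permutation")
}

#' @export
print.overlap_permutation <- function(x, ...) {
  cat(sprintf("<overlap_permutation> observed %d, mean permuted %.2f, p = %.4g (%d permutations)\n",
              x$observed, mean(x$perm_overlaps), x$p_value, x$n_perm))
  invisible(x)
}

#' @method glance overlap_permutation
#' @export
glance.overlap_permutation <- function(x, ...) {
  tibble::tibble(observed = x$observed,
                 perm_mean = mean(x$perm_overlaps),
                 p_value = x$p_value,
                 n_perm = x$n_perm)
}

#' Methylation-state summary of a CpG list
#'
#' Non-variable CpGs are expected to sit at the extremes of the beta scale —
#' fully methylated or fully unmethylated. This summarises the per-CpG mean
#' betas of list members into the fractions above `high`, below `low` and in
#' between, plus the 0.5th and 99.5th percentiles of the member means.
#'
#' @param betas Beta tibble containing all list members.
#' @param list A [nonvariable_list()] or character vector of CpG ids.
#' @param high,low State boundaries on the mean-beta scale (defaults 0.80
#'   and 0.16).
#' @return A one-row tibble: `n`, `frac_high`, `frac_low`,
#'   `frac_intermediate`, `mean_p005`, `mean_p995`.
#' @export
methylation_state_summary <- function(betas, list, high = 0.80, low = 0.16) {
  members <- if (inherits(list, "nonvariable_list")) list$members else as.character(list)
  if (length(members) == 0L) abort("empty CpG list")
  m <- beta_to_matrix(betas)
  missing <- setdiff(members, rownames(m))
  if (length(missing) > 0L) {
    abort(paste0("list members absent from betas: ",
                 paste(utils::head(missing, 5L), collapse = ", ")))
  }
  mu <- rowMeans(m[members, , drop = FALSE])
  qs <- stats::quantile(mu, c(0.005, 0.995), names = FALSE, type = 7)
  tibble::tibble(
    n = length(mu),
    frac_high = mean(mu > high),
    frac_low = mean(mu < low),
    frac_intermediate = mean(mu >= low & mu <= high),
    mean_p005 = qs[1L],
    mean_p995 = qs[2L]
  )
}

#' Concordance between two CpG lists
#'
#' Reports the overlap fraction |a n b| / min(|a|, |b|) — the robustness
#' metric for comparing lists built under different processing strategies —
#' together with the Jaccard index |a n b| / |a u b|.
#'
#' @param a,b [nonvariable_list()] objects (or character vectors).
#' @return A one-row tibble: `n_a`, `n_b`, `n_intersection`,
#'   `overlap_fraction`, `jaccard`.
#' @export
list_concordance <- function(a, b) {
  ma <- if (inherits(a, "nonvariable_list")) a$members else as.character(a)
  mb <- if (inherits(b, "nonvariable_list")) b$members else as.character(b)
  if (length(ma) == 0L || length(mb) == 0L) abort("lists must be non-empty")
  inter <- length(intersect(ma, mb))
  tibble::tibble(
    n_a = length(ma), n_b = length(mb), n_intersection = inter,
    overlap_fraction = inter / min(length(ma), length(mb)),
    jaccard = inter / length(union(ma, mb))
  )
}
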