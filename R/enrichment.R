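#' Count CpG list members per genomic feature
#'
#' Tallies a CpG list over the two annotation families: gene features
#' (promoter, intragenic, three_prime, intergenic) and CpG-island features
#' (island, shores, shelves, none). Each family is a partition, so each
#' family's counts sum to the list size. Features absent from the list are
#' reported with count 0.
#'
#' @param list A [nonvariable_list()] or character vector of CpG ids.
#' @param annotation Annotation tibble (`cpg_id`, `gene_feature`,
#'   `island_feature`), covering every list member.
#' @return A tibble: `family` ("gene" or "island"), `feature`, `count`.
#' @export
feature_counts <- function(list, annotation) {
  members <- if (inherits(list, "nonvariable_list")) list$members else as.character(list)
  annotation <- validate_annotation(annotation)
  missing <- setdiff(members, annotation$cpg_id)
  if (length(missing) > 0L) {
    abort(paste0("unannotated CpGs: ",
                 paste(utils::head(missing, 5L), collapse = ", ")))
  }
  ann <- annotation[match(members, annotation$cpg_id), ]
  gene <- table(factor(ann$gene_feature, levels = gene_feature_levels))
  isl <- table(factor(ann$island_feature, levels = island_feature_levels))
  dplyr::bind_rows(
    tibble::tibble(family = "gene", feature = names(gene),
                   count = as.integer(gene)),
    tibble::tibble(family = "island", feature = names(isl),
                   count = as.integer(isl))
  )
}

#' Random-list permutation test for genomic-feature enrichment
#'
#' Tests whether a CpG list is enriched or depleted in gene and CpG-island
#' features relative to its tested background. Each permutation draws a
#' uniform random subset of the background of the same size as the list and
#' tallies it per feature; fold change is observed count over the mean
#' permuted count, and the empirical p-value (add-one estimator) is
#' two-sided by default: twice the smaller tail probability, capped at 1.
#' BH adjustment runs across all features of one call — jointly over the 9
#' features of both families by default, or per family.
#'
#' @param list A [nonvariable_list()] or character vector (must be a subset
#'   of `background`).
#' @param annotation Annotation tibble covering the whole background.
#' @param background Character vector of background CpG ids: the tissue's
#'   tested universe, never the full array. Defaults to the list's own
#'   universe when `list` is a [nonvariable_list()].
#' @param params [cpg_params()]; uses `n_permutations`.
#' @param seed Optional integer seed; results are reproducible given
#'   (seed, n_permutations).
#' @param alternative `"two.sided"` (default), `"greater"` (enrichment
#'   only) or `"less"` (depletion only).
#' @param families `"joint"` (one BH family across gene + island features,
#'   default) or `"separate"`.
#' @return A tibble of class `cpg_enrichment`: `family`, `feature`,
#'   `observed`, `perm_mean`, `fold_change` (`NA` with a warning when the
#'   permutation mean is 0), `p_value`, `q_value`; attributes `n_perm`,
#'   `seed`, `alternative`.
#' @export
enrichment_permutation <- function(list, annotation, background = NULL,
                                   params = cpg_params(), seed = NULL,
                                   alternative = c("two.sided", "greater", "less"),
                                   families = c("joint", "separate")) {
  alternative <- match.arg(alternative)
  families <- match.arg(families)
  members <- if (inherits(list, "nonvariable_list")) list$members else as.character(list)
  if (is.null(background)) {
    if (!inherits(list, "nonvariable_list")) {
      abort("`background` is required when `list` is a bare id vector")
    }
    background <- list$universe
  }
  background <- unique(as.character(background))
  if (!all(members %in% background)) abort("list must be a subset of the background")
  n_perm <- params$n_permutations
  if (n_perm < 1L) abort("`n_permutations` must be >= 1")
  annotation <- validate_annotation(annotation)
  missing <- setdiff(background, annotation$cpg_id)
  if (length(missing) > 0L) {
    abort(paste0("unannotated background CpGs: ",
                 paste(utils::head(missing, 5L), collapse = ", ")))
  }
  observed <- feature_counts(members, annotation)

  ann_bg <- annotation[match(background, annotation$cpg_id), ]
  # joint label per background CpG (gene feature index, island feature index)
  gene_idx <- match(ann_bg$gene_feature, gene_feature_levels)
  isl_idx <- match(ann_bg$island_feature, island_feature_levels)
  n_gene <- length(gene_feature_levels)
  n_isl <- length(island_feature_levels)
  s <- length(members)
  n_bg <- length(background)

  perm_counts <- with_seed_if(seed, {
    out <- matrix(0L, nrow = n_perm, ncol = n_gene + n_isl)
    for (i in seq_len(n_perm)) {
      draw <- sample.int(n_bg, s)
      out[i, seq_len(n_gene)] <- tabulate(gene_idx[draw], nbins = n_gene)
      out[i, n_gene + seq_len(n_isl)] <- tabulate(isl_idx[draw], nbins = n_isl)
    }
    out
  })
  colnames(perm_counts) <- c(gene_feature_levels, island_feature_levels)

  obs_vec <- observed$count
  perm_mean <- colMeans(perm_counts)
  fold <- ifelse(perm_mean > 0, obs_vec / perm_mean, NA_real_)
  if (any(perm_mean == 0 & obs_vec > 0)) {
    warn("feature(s) with permutation mean 0: fold change undefined (NA)")
  }
  p_ge <- vapply(seq_along(obs_vec), function(j) {
    empirical_p(sum(perm_counts[, j] >= obs_vec[j]), n_perm)
  }, numeric(1L))
  p_le <- vapply(seq_along(obs_vec), function(j) {
    empirical_p(sum(perm_counts[, j] <= obs_vec[j]), n_perm)
  }, numeric(1L))
  p <- switch(alternative,
              two.sided = pmin(1, 2 * pmin(p_ge, p_le)),
              greater = p_ge,
              less = p_le)
  out <- dplyr::rename(observed, observed = "count")
  out$perm_mean <- unname(perm_mean)
  out$fold_change <- unname(fold)
  out$p_value <- p
  if (families == "joint") {
    out$q_value <- bh_fdr(out$p_value)
  } else {
    out <- out %>%
      dplyr::group_by(.data$family) %>%
      dplyr::mutate(q_value = bh_fdr(.data$p_value)) %>%
      dplyr::ungroup()
  }
  structure(out, class = c("cpg_enrichment", class(out)),
            n_perm = n_perm, seed = seed, alternative = alternative,
            n_list = s, n_background = n_bg)
}

#' @method tidy cpg_enrichment
#' @export
tidy.cpg_enrichment <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("family", "feature", "observed", "perm_mean",
                                 "fold_change", "p_value", "q_value")])
}

#' @method glance cpg_enrichment
#' @export
glance.cpg_enrichment <- function(x, ...) {
  tibble::tibble(n_list = attr(x, "n_list"),
                 n_background = attr(x, "n_background"),
                 n_perm = attr(x, "n_perm"),
                 n_significant = sum(x$q_value < 0.05, na.rm = TRUE))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: with sorted p-values p_(1) <= ... <= p_(m), the
#' adjusted value at rank i is min over j >= i of p_(j) * m / j, capped at
#' 1, returned in the input order. Thin validating wrapper so every module
#' shares one multiple-testing entry point.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Adjusted p-values, same length and order as `p`.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bh_fdr <- function(p) {
  if (!is.numeric(p)) abort("`p` must be numeric")
  if (any(is.na(p) | p <= 0 | p > 1)) abort("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}
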