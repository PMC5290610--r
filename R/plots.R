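#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Volcano plot of an EWAS result
#'
#' Delta beta against -log10 BH-adjusted p, with the hit thresholds drawn
#' as reference lines and hits coloured.
#'
#' @param object A `cpg_ewas` tibble.
#' @param params [cpg_params()] supplying the hit thresholds.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cpg_ewas
#' @export
autoplot.cpg_ewas <- function(object, params = cpg_params(), ...) {
  df <- hit_calling(object, params)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$delta_beta,
                                   y = -log10(.data$q_value),
                                   colour = .data$hit)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * params$delta_beta_cutoff,
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(params$fdr_cutoff),
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "delta beta (exposed - unexposed)",
                  y = expression(-log[10] ~ "BH adjusted p"),
                  colour = "hit") +
    ggplot2::theme_minimal()
}

#' Fold-change bars for an enrichment result
#'
#' @param object A `cpg_enrichment` tibble.
#' @param ... Unused.
#' @return A ggplot object, one panel per feature family, the no-enrichment
#'   line at fold change 1.
#' @method autoplot cpg_enrichment
#' @export
autoplot.cpg_enrichment <- function(object, ...) {
  df <- tidy(object)
  df$feature <- factor(df$feature, levels = unique(df$feature))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$feature, y = .data$fold_change,
                                   fill = .data$q_value < 0.05)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::facet_wrap(~family, scales = "free_x") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60",
                                          `TRUE` = "steelblue"),
                               name = "FDR < 0.05") +
    ggplot2::labs(x = NULL, y = "fold change over background") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Paired adjusted-p trajectories across sub-sampling replicates
#'
#' For each tracked CpG, connects the BH-adjusted p-value of the unfiltered
#' and filtered arm within each replicate — the paired view of what the
#' confirm-and-remove filter does to borderline true positives in
#' low-powered sub-cohorts.
#'
#' @param object A `subsample_experiment`.
#' @param fdr_line Reference line (default 0.05).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot subsample_experiment
#' @export
autoplot.subsample_experiment <- function(object, fdr_line = 0.05, ...) {
  df <- object$tracked
  if (is.null(df) || nrow(df) == 0L) {
    abort("no tracked CpGs recorded; rerun subsample_experiment() with `tracked`")
  }
  df$arm <- factor(df$arm, levels = c("unfiltered", "filtered"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$arm, y = .data$q_value,
                                   group = interaction(.data$replicate,
                                                       .data$cpg_id))) +
    ggplot2::geom_line(alpha = 0.5, colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$arm), size = 2) +
    ggplot2::geom_hline(yintercept = fdr_line, linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~cpg_id) +
    ggplot2::labs(x = NULL, y = "BH adjusted p (log scale)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Sample-correlation heat map
#'
#' Tile view of the pairwise sample-correlation matrix, the standard visual
#' check for outlying samples or studies.
#'
#' @param corr A `sample_cor` matrix from [sample_correlation()].
#' @return A ggplot object.
#' @export
plot_sample_correlation <- function(corr) {
  if (!inherits(corr, "sample_cor")) abort("`corr` must come from sample_correlation()")
  df <- tidy(corr)
  ids <- rownames(unclass(corr))
  df$sample_a <- factor(df$sample_a, levels = ids)
  df$sample_b <- factor(df$sample_b, levels = ids)
  ggplot2::ggplot(df, ggplot2::aes(.data$sample_a, .data$sample_b,
                                   fill = .data$correlation)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(min(df$correlation, na.rm = TRUE), 1)) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
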