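# Shared builders: all fixtures are generated in code, none stored on disk.

# Wrap a numeric matrix as a beta tibble (cpg_id + sample columns).
beta_tbl <- function(m, cpg_ids = NULL, sample_ids = NULL) {
  if (is.null(cpg_ids)) cpg_ids <- sprintf("cg%05d", seq_len(nrow(m)))
  if (is.null(sample_ids)) sample_ids <- sprintf("s%03d", seq_len(ncol(m)))
  dimnames(m) <- list(cpg_ids, sample_ids)
  tibble::as_tibble(as.data.frame(m)) |>
    tibble::add_column(cpg_id = cpg_ids, .before = 1L)
}

# Random beta matrix, uniform values.
random_beta_tbl <- function(n_cpgs, n_samples, seed = 1) {
  withr::with_seed(seed, beta_tbl(matrix(stats::runif(n_cpgs * n_samples),
                                         n_cpgs, n_samples)))
}

# A two-group design for a beta tibble.
design_for <- function(betas, n_exposed = NULL) {
  ids <- setdiff(names(betas), "cpg_id")
  if (is.null(n_exposed)) n_exposed <- length(ids) %/% 2
  tibble::tibble(sample_id = ids,
                 group = rep(c("control", "exposed"),
                             c(length(ids) - n_exposed, n_exposed)))
}

# Annotation where every CpG is intergenic / one of `island` or `none`.
island_annotation <- function(cpg_ids, island_ids) {
  tibble::tibble(
    cpg_id = cpg_ids,
    gene_feature = "intergenic",
    island_feature = ifelse(cpg_ids %in% island_ids, "island", "none")
  )
}
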