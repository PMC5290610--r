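#' Read a CpG-by-sample beta (or M-value) matrix
#'
#' Reads a delimited text matrix in the GEO series-matrix value-block
#' convention: a header row of sample ids, first column of CpG ids, one row
#' per CpG. Lines starting with `#` are treated as comments. Values are
#' validated against the declared scale: beta values must lie in \[0, 1\];
#' M-values are converted to betas with [m_to_beta()].
#'
#' @param path Path to a tab- or comma-delimited text file.
#' @param values Scale of the stored values: `"beta"` (default) or `"m"`.
#'   Never auto-detected: betas and M-values overlap numerically near 0-1.
#' @param delim Field delimiter; `NULL` (default) auto-detects tab vs comma
#'   from the header line.
#' @param transposed Set `TRUE` if the file stores samples as rows and CpGs
#'   as columns.
#' @return A tibble with a `cpg_id` column followed by one numeric column per
#'   sample, values on the beta scale.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("cpg_id\ts1\ts2", "cg01\t0.1\t0.9", "cg02\t0.5\t0.4"), f)
#' read_beta_matrix(f)
#' @export
read_beta_matrix <- function(path, values = c("beta", "m"), delim = NULL,
                             transposed = FALSE) {
  values <- match.arg(values)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (is.null(delim)) delim <- detect_delim(path)
  df <- readr::read_delim(path, delim = delim, comment = "#",
                          show_col_types = FALSE, progress = FALSE,
                          name_repair = "minimal")
  if (ncol(df) < 2L) abort("malformed header: need an id column plus at least one data column")
  names(df)[1L] <- "cpg_id"
  if (anyDuplicated(names(df)[-1L])) {
    abort("malformed header: duplicated sample ids")
  }
  if (transposed) {
    m <- as.matrix(df[, -1L, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- as.character(df[[1L]])
    df <- matrix_to_beta(t(m))
  }
  df$cpg_id <- as.character(df$cpg_id)
  check_beta_frame(df)
  num <- vapply(df[-1L], is.numeric, logical(1L))
  if (!all(num)) {
    abort(paste0("non-numeric value columns: ",
                 paste(names(df)[-1L][!num], collapse = ", ")))
  }
  m <- beta_to_matrix(df)
  if (values == "beta") {
    check_beta_range(m)
    df
  } else {
    if (any(!is.finite(m) & !is.na(m))) abort("non-finite M-values")
    matrix_to_beta(m_to_beta_mat(m))
  }
}

detect_delim <- function(path) {
  header <- readLines(path, n = 25L)
  header <- header[!startsWith(header, "#")][1L]
  if (is.na(header)) abort("empty file")
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

#' Write a beta matrix to delimited text
#'
#' @param betas Beta tibble (`cpg_id` + sample columns).
#' @param path Output path.
#' @param delim Field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(betas, path, delim = "\t") {
  check_beta_frame(betas)
  readr::write_delim(betas, path, delim = delim, progress = FALSE)
  invisible(path)
}

#' Convert M-values to beta values
#'
#' The logit-like M-value scale maps back to the beta (methylation
#' proportion) scale through `beta = 2^M / (2^M + 1)`; the transform is
#' strictly increasing, with M = 0 at beta = 0.5.
#'
#' @param m Numeric vector of finite M-values.
#' @return Beta values in (0, 1).
#' @examples
#' m_to_beta(c(-2, 0, 2))  # 0.2, 0.5, 0.8
#' @export
m_to_beta <- function(m) {
  if (!is.numeric(m)) abort("`m` must be numeric")
  if (any(!is.finite(m))) abort("non-finite M-values")
  m_to_beta_mat(m)
}

m_to_beta_mat <- function(m) {
  # 1/(1 + 2^-m) is algebraically 2^m/(2^m + 1) but stable for large |m|
  1 / (1 + 2^(-m))
}

#' Convert beta values to M-values
#'
#' Inverse of [m_to_beta()]: `M = log2(beta / (1 - beta))`.
#'
#' @param beta Numeric vector of beta values strictly inside (0, 1).
#' @return M-values.
#' @export
beta_to_m <- function(beta) {
  if (!is.numeric(beta)) abort("`beta` must be numeric")
  if (any(!is.na(beta) & (beta <= 0 | beta >= 1))) {
    abort("beta values must be strictly inside (0, 1) for the M transform")
  }
  log2(beta / (1 - beta))
}

#' Assemble a multi-study cohort on the common complete-case CpG set
#'
#' Joins per-study beta matrices into one cohort matrix restricted to the
#' minimal CpG set measured in every sample: the intersection of the studies'
#' CpG sets, further restricted to CpGs with no missing value anywhere. The
#' result carries an `"assembly_log"` attribute recording per-study CpG
#' counts and losses.
#'
#' @param studies A list of beta tibbles (or a single tibble), sample ids
#'   disjoint across studies.
#' @return A beta tibble whose columns are all studies' samples and whose
#'   rows are the shared, complete-case CpGs; attribute `assembly_log` is a
#'   tibble of per-study input sizes.
#' @examples
#' a <- tibble::tibble(cpg_id = c("cg1", "cg2", "cg3"), s1 = c(.1, .2, .3))
#' b <- tibble::tibble(cpg_id = c("cg2", "cg3", "cg4"), s2 = c(.4, .5, .6))
#' assemble_cohort(list(a, b))
#' @export
assemble_cohort <- function(studies) {
  if (is.data.frame(studies)) studies <- list(studies)
  if (length(studies) < 1L) abort("need at least one study")
  purrr::walk(studies, check_beta_frame)
  all_samples <- unlist(lapply(studies, sample_ids_of))
  dup <- unique(all_samples[duplicated(all_samples)])
  if (length(dup) > 0L) {
    abort(paste0("duplicate sample ids across studies: ",
                 paste(utils::head(dup, 5L), collapse = ", ")))
  }
  common <- Reduce(intersect, lapply(studies, function(s) s$cpg_id))
  if (length(common) == 0L) abort("no CpG shared by all studies")
  mats <- lapply(studies, function(s) beta_to_matrix(s)[common, , drop = FALSE])
  joint <- do.call(cbind, mats)
  complete <- rowSums(is.na(joint)) == 0L
  if (!any(complete)) abort("no CpG with complete values across all samples")
  log <- tibble::tibble(
    study = seq_along(studies),
    n_cpgs_in = vapply(studies, nrow, integer(1L)),
    n_samples = vapply(studies, function(s) length(sample_ids_of(s)), integer(1L)),
    n_cpgs_shared = length(common),
    n_cpgs_out = sum(complete)
  )
  out <- matrix_to_beta(joint[complete, , drop = FALSE])
  attr(out, "assembly_log") <- log
  out
}

gene_feature_levels <- c("promoter", "intragenic", "three_prime", "intergenic")
island_feature_levels <- c("island", "north_shore", "south_shore",
                           "north_shelf", "south_shelf", "none")

#' Read a CpG genomic-feature annotation table
#'
#' Expects a delimited table with columns `cpg_id`, `gene_feature` (one of
#' promoter, intragenic, three_prime, intergenic) and `island_feature` (one
#' of island, north_shore, south_shore, north_shelf, south_shelf, none). The
#' vocabularies are closed; unknown labels are rejected with the offending
#' rows named.
#'
#' @param path Path to the delimited file.
#' @param delim Field delimiter; auto-detected when `NULL`.
#' @return A tibble with columns `cpg_id`, `gene_feature`, `island_feature`.
#' @export
read_annotation <- function(path, delim = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (is.null(delim)) delim <- detect_delim(path)
  df <- readr::read_delim(path, delim = delim, comment = "#",
                          show_col_types = FALSE, progress = FALSE)
  validate_annotation(df)
}

validate_annotation <- function(df) {
  need <- c("cpg_id", "gene_feature", "island_feature")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    abort(paste0("annotation missing column(s): ", paste(missing, collapse = ", ")))
  }
  df <- tibble::as_tibble(df[need])
  df$cpg_id <- as.character(df$cpg_id)
  if (anyDuplicated(df$cpg_id)) abort("duplicate CpG ids in annotation")
  bad_gene <- which(!df$gene_feature %in% gene_feature_levels)
  if (length(bad_gene) > 0L) {
    abort(sprintf("unknown gene_feature %s at row %d (id %s)",
                  df$gene_feature[bad_gene[1L]], bad_gene[1L],
                  df$cpg_id[bad_gene[1L]]))
  }
  bad_isl <- which(!df$island_feature %in% island_feature_levels)
  if (length(bad_isl) > 0L) {
    abort(sprintf("unknown island_feature %s at row %d (id %s)",
                  df$island_feature[bad_isl[1L]], bad_isl[1L],
                  df$cpg_id[bad_isl[1L]]))
  }
  df
}

#' @rdname read_annotation
#' @param annotation Annotation tibble to write.
#' @export
write_annotation <- function(annotation, path, delim = "\t") {
  validate_annotation(annotation)
  readr::write_delim(annotation, path, delim = delim, progress = FALSE)
  invisible(path)
}

#' Read and validate a sample manifest
#'
#' The manifest maps samples to studies, tissues and optional exposure
#' groups/covariates. Required columns: `sample_id`, `study_id`, `tissue`;
#' any further columns (e.g. `group`, covariates, a free-text
#' `preprocessing` note) are carried through untouched.
#'
#' @param path Path to a delimited file.
#' @param delim Field delimiter; auto-detected when `NULL`.
#' @return A tibble, one row per sample.
#' @export
read_manifest <- function(path, delim = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (is.null(delim)) delim <- detect_delim(path)
  df <- readr::read_delim(path, delim = delim, comment = "#",
                          show_col_types = FALSE, progress = FALSE)
  need <- c("sample_id", "study_id", "tissue")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    abort(paste0("manifest missing column(s): ", paste(missing, collapse = ", ")))
  }
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) abort("duplicate sample ids in manifest")
  tibble::as_tibble(df)
}

#' @rdname read_manifest
#' @param manifest Manifest tibble to write.
#' @export
write_manifest <- function(manifest, path, delim = "\t") {
  readr::write_delim(manifest, path, delim = delim, progress = FALSE)
  invisible(path)
}

#' Cross-check a beta matrix against a manifest
#'
#' Errors if any sample column of `betas` has no manifest row.
#'
#' @param betas Beta tibble.
#' @param manifest Manifest tibble from [read_manifest()].
#' @return `betas`, invisibly.
#' @export
check_manifest <- function(betas, manifest) {
  check_beta_frame(betas)
  missing <- setdiff(sample_ids_of(betas), manifest$sample_id)
  if (length(missing) > 0L) {
    abort(paste0("samples absent from manifest: ",
                 paste(utils::head(missing, 5L), collapse = ", ")))
  }
  invisible(betas)
}

#' Write / read a CpG list file
#'
#' The on-disk format is one CpG id per line, preceded by `#`-prefixed
#' metadata lines (tissue, threshold, universe size, tool version) so a list
#' file is self-describing. [read_cpg_list()] returns a [nonvariable_list()]
#' when the metadata is present, otherwise a plain character vector.
#'
#' @param list A [nonvariable_list()] or character vector of CpG ids.
#' @param path Output (or input) path.
#' @return `write_cpg_list()` returns `path` invisibly; `read_cpg_list()`
#'   returns the list object.
#' @export
write_cpg_list <- function(list, path) {
  if (inherits(list, "nonvariable_list")) {
    header <- c(
      paste0("# tool: cpgnonvar ", utils::packageVersion("cpgnonvar")),
      paste0("# tissue: ", list$tissue),
      paste0("# threshold: ", format(list$threshold, digits = 15)),
      paste0("# universe_size: ", length(list$universe)),
      paste0("# n_members: ", length(list$members))
    )
    writeLines(c(header, list$members), path)
  } else {
    writeLines(c(paste0("# tool: cpgnonvar ", utils::packageVersion("cpgnonvar")),
                 as.character(list)), path)
  }
  invisible(path)
}

#' @rdname write_cpg_list
#' @param universe Optional universe to attach when reading a bare id file.
#' @export
read_cpg_list <- function(path, universe = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  ids <- lines[!startsWith(lines, "#") & nzchar(lines)]
  get_meta <- function(key) {
    hit <- grep(paste0("^#\\s*", key, ":"), meta, value = TRUE)
    if (length(hit) == 0L) return(NULL)
    trimws(sub(paste0("^#\\s*", key, ":\\s*"), "", hit[1L]))
  }
  tissue <- get_meta("tissue")
  threshold <- get_meta("threshold")
  if (!is.null(tissue) && !is.null(threshold)) {
    nonvariable_list(members = ids,
                     universe = if (is.null(universe)) ids else universe,
                     tissue = tissue,
                     threshold = as.numeric(threshold))
  } else {
    ids
  }
}
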