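# Internal helpers shared across modules.

#' @importFrom rlang .data abort warn
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>%
NULL

# Convert a wide beta tibble (cpg_id + one numeric column per sample) to a
# numeric matrix with CpG rownames. Validation of value range is the caller's
# job (M-value matrices pass through here too).
beta_to_matrix <- function(betas) {
  check_beta_frame(betas)
  m <- as.matrix(betas[, setdiff(names(betas), "cpg_id"), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- betas$cpg_id
  m
}

matrix_to_beta <- function(m) {
  tibble::as_tibble(as.data.frame(m), .name_repair = "minimal") %>%
    tibble::add_column(cpg_id = rownames(m), .before = 1L)
}

check_beta_frame <- function(betas, arg = "betas") {
  if (!is.data.frame(betas)) {
    abort(paste0("`", arg, "` must be a data frame"))
  }
  if (!"cpg_id" %in% names(betas)) {
    abort(paste0("`", arg, "` must have a `cpg_id` column"))
  }
  if (ncol(betas) < 2L) {
    abort(paste0("`", arg, "` has no sample columns"))
  }
  dups <- unique(betas$cpg_id[duplicated(betas$cpg_id)])
  if (length(dups) > 0L) {
    abort(paste0("duplicate CpG ids: ",
                 paste(utils::head(dups, 5L), collapse = ", ")))
  }
  invisible(betas)
}

check_beta_range <- function(m, what = "beta") {
  bad <- m[!is.na(m) & (m < 0 | m > 1)]
  if (length(bad) > 0L) {
    abort(sprintf(
      "%d %s value(s) outside [0, 1] (e.g. %s); declare `values = \"m\"` if these are M-values",
      length(bad), what, format(bad[1L], digits = 4)))
  }
  invisible(m)
}

sample_ids_of <- function(betas) setdiff(names(betas), "cpg_id")

# Run code under a seed without disturbing the caller's RNG stream.
# seed = NULL leaves the ambient RNG in charge.
with_seed_if <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(seed, code)
}

# Deterministically derive child seeds from one master seed (kept < 2^31).
derive_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Phipson-Smyth style add-one empirical p so zero is never reported.
empirical_p <- function(n_as_extreme, n_perm) {
  (1 + n_as_extreme) / (1 + n_perm)
}
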