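# Internal helpers shared across the pipeline: validation of the two core
# tables (wide counts: `protein_id` + one numeric column per sample; samples:
# `sample_id`, `group` with exactly two groups) and conversion to matrices.

check_counts <- function(counts, call = rlang::caller_env()) {
  if (!is.data.frame(counts)) {
    abort("`counts` must be a data frame.", call = call)
  }
  if (!"protein_id" %in% names(counts)) {
    abort("`counts` must have a `protein_id` column.", call = call)
  }
  if (anyDuplicated(counts$protein_id)) {
    abort("`counts` has duplicated protein identifiers.", call = call)
  }
  sample_cols <- setdiff(names(counts), "protein_id")
  if (length(sample_cols) == 0) {
    abort("`counts` has no sample columns.", call = call)
  }
  bad <- sample_cols[!vapply(counts[sample_cols], is.numeric, logical(1))]
  if (length(bad)) {
    abort(paste0("Non-numeric sample column(s): ", toString(bad), "."),
          call = call)
  }
  vals <- as.matrix(counts[sample_cols])
  if (anyNA(vals) || any(vals < 0)) {
    abort("Counts must be non-negative and non-missing.", call = call)
  }
  invisible(counts)
}

check_samples <- function(samples, counts = NULL, call = rlang::caller_env()) {
  if (!is.data.frame(samples) ||
      !all(c("sample_id", "group") %in% names(samples))) {
    abort("`samples` must be a data frame with `sample_id` and `group`.",
          call = call)
  }
  if (anyDuplicated(samples$sample_id)) {
    abort("`samples` has duplicated sample identifiers.", call = call)
  }
  grps <- unique(as.character(samples$group))
  if (length(grps) != 2) {
    abort("`samples$group` must contain exactly two groups.", call = call)
  }
  if (!is.null(counts)) {
    missing <- setdiff(samples$sample_id, setdiff(names(counts), "protein_id"))
    if (length(missing)) {
      abort(paste0("Sample(s) absent from `counts`: ", toString(missing), "."),
            call = call)
    }
  }
  invisible(samples)
}

# Group labels in a stable order: "A"/"B" if used, else sorted; `group_a`
# overrides which group plays the numerator role (group 1, e.g. myopic).
group_levels <- function(samples, group_a = NULL, call = rlang::caller_env()) {
  grps <- sort(unique(as.character(samples$group)))
  if (!is.null(group_a)) {
    if (!group_a %in% grps) {
      abort(paste0("`group_a` = \"", group_a, "\" is not a group label."),
            call = call)
    }
    grps <- c(group_a, setdiff(grps, group_a))
  }
  grps
}

counts_matrix <- function(counts) {
  m <- as.matrix(counts[setdiff(names(counts), "protein_id")])
  rownames(m) <- counts$protein_id
  m
}

matrix_counts <- function(m) {
  tibble::as_tibble(m, rownames = "protein_id")
}

group_samples <- function(samples, group) {
  as.character(samples$sample_id[as.character(samples$group) == group])
}

row_sds <- function(m) {
  n <- ncol(m)
  if (n < 2) return(rep(NA_real_, nrow(m)))
  mu <- rowMeans(m)
  sqrt(rowSums((m - mu)^2) / (n - 1))
}
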