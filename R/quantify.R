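# Between-sample normalization of spectral counts (N-SC), per-group
# mean/SD summaries, and presence detection.

#' Normalize spectral counts between samples (N-SC)
#'
#' Total-count scaling to the mean library size: each sample column j is
#' multiplied by (mean of all column totals) / (column-j total). After
#' scaling, all column totals are equal and the grand total is preserved,
#' so the operation is idempotent.
#'
#' @param counts Wide counts tibble (`protein_id` + one numeric column per
#'   sample).
#' @return A tibble of the same shape with normalized (real-valued) counts.
#' @examples
#' counts <- tibble::tibble(protein_id = c("P1", "P2"),
#'                          S1 = c(10, 90), S2 = c(5, 45))
#' normalize_counts(counts)
#' @export
normalize_counts <- function(counts) {
  check_counts(counts)
  m <- counts_matrix(counts)
  totals <- colSums(m)
  if (any(totals == 0)) {
    abort(paste0("Sample(s) with all-zero counts cannot be normalized: ",
                 toString(colnames(m)[totals == 0]), "."))
  }
  m <- sweep(m, 2, mean(totals) / totals, `*`)
  matrix_counts(m)
}

#' Per-group means and standard deviations of normalized counts
#'
#' For each protein, the mean and sample SD (n - 1 denominator) of the N-SC
#' values in each group: the inputs to the SAM-like weight statistic and the
#' fold change. Each group must have at least 2 samples.
#'
#' @param nsc Normalized counts tibble (see [normalize_counts()]).
#' @param samples Data frame with `sample_id` and `group` (two groups).
#' @param group_a Which group label plays the numerator role (group 1);
#'   defaults to `"A"` if present, else the alphabetically first label.
#' @return A tibble: `protein_id`, `mu_a`, `mu_b`, `delta_a`, `delta_b`.
#' @export
group_summary <- function(nsc, samples, group_a = NULL) {
  check_counts(nsc)
  check_samples(samples, nsc)
  grps <- group_levels(samples, group_a)
  m <- counts_matrix(nsc)
  a <- m[, group_samples(samples, grps[1]), drop = FALSE]
  b <- m[, group_samples(samples, grps[2]), drop = FALSE]
  if (ncol(a) < 2 || ncol(b) < 2) {
    abort("Each group needs at least 2 samples for mean/SD summaries.")
  }
  tibble::tibble(
    protein_id = rownames(m),
    mu_a = unname(rowMeans(a)), mu_b = unname(rowMeans(b)),
    delta_a = unname(row_sds(a)), delta_b = unname(row_sds(b))
  )
}

#' Presence flags per protein per group
#'
#' A protein is present in a group when at least `min_samples` of the
#' group's samples have a nonzero count. The default rule (one nonzero
#' sample) is the loosest detection rule and matches the structural-zero
#' semantics of group-unique proteins.
#'
#' @inheritParams group_summary
#' @param counts Raw counts tibble.
#' @param min_samples Minimum nonzero samples per group.
#' @return A tibble: `protein_id`, `present_a`, `present_b`.
#' @export
detect_presence <- function(counts, samples, min_samples = 1L, group_a = NULL) {
  check_counts(counts)
  check_samples(samples, counts)
  grps <- group_levels(samples, group_a)
  m <- counts_matrix(counts)
  a <- m[, group_samples(samples, grps[1]), drop = FALSE]
  b <- m[, group_samples(samples, grps[2]), drop = FALSE]
  if (min_samples < 1 || min_samples > min(ncol(a), ncol(b))) {
    abort("`min_samples` must lie between 1 and the smaller group size.")
  }
  tibble::tibble(
    protein_id = rownames(m),
    present_a = unname(rowSums(a > 0) >= min_samples),
    present_b = unname(rowSums(b > 0) >= min_samples)
  )
}
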