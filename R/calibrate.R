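# Empirical fold-change-threshold calibration from control (null) replicate
# comparisons: ln-ln analysis of the inner-quartile proteins, returning the
# smallest threshold on a [1.5, 2.0] grid whose ratio band covers the target
# fraction of proteins.

#' Split one group's samples into two control halves
#'
#' Technical-control comparison requires two replicate measurements of the
#' same condition; with none available, a seeded random halving of one
#' group's samples stands in. Returns per-protein mean N-SC of each half,
#' restricted to proteins detected (nonzero mean) in both halves.
#'
#' @inheritParams group_summary
#' @param counts Counts tibble (raw counts are normalized internally).
#' @param group Group label whose samples are split (needs >= 4 samples).
#' @param seed Integer seed for the halving.
#' @return A tibble: `protein_id`, `control_a`, `control_b`, with the sample
#'   assignment attached as attribute `"halves"`.
#' @export
split_control_pairs <- function(counts, samples, group = "B", seed = 1L) {
  check_counts(counts)
  check_samples(samples, counts)
  ids <- group_samples(samples, group)
  if (length(ids) == 0) abort(paste0("No samples in group \"", group, "\"."))
  if (length(ids) < 4) {
    abort("Control splitting needs at least 4 samples in the chosen group.")
  }
  set.seed(seed)
  perm <- sample(ids)
  half1 <- perm[seq_len(floor(length(ids) / 2))]
  half2 <- setdiff(perm, half1)
  m <- counts_matrix(normalize_counts(counts))
  ca <- rowMeans(m[, half1, drop = FALSE])
  cb <- rowMeans(m[, half2, drop = FALSE])
  keep <- ca > 0 & cb > 0
  structure(
    tibble::tibble(protein_id = rownames(m)[keep],
                   control_a = ca[keep], control_b = cb[keep]),
    halves = list(half1 = half1, half2 = half2)
  )
}

#' Calibrate the fold-change threshold from control comparisons
#'
#' Proteins whose mean ln abundance (average of the two ln control values)
#' lies within the inner quartiles [Q1, Q3] of that distribution form the
#' calibration set. On that set the Pearson correlation of the ln-ln plot is
#' reported, and the threshold is the smallest grid value `t` for which the
#' fraction of proteins with `|ln(a/b)| <= ln t` reaches `target_coverage`.
#' If no grid value reaches it, the threshold is clamped at the grid maximum
#' (2.0 by convention) with a warning and the achieved coverage is reported
#' as-is.
#'
#' @param controls A data frame with `control_a` and `control_b` columns of
#'   mean N-SC over a shared protein list (e.g. from
#'   [split_control_pairs()]). Pairs with a non-positive value are excluded
#'   and counted.
#' @param grid Ascending candidate thresholds within [1.5, 2.0].
#' @param target_coverage Required fraction of inner-quartile proteins
#'   within the ratio band; default 0.99.
#' @param trim `"abundance"` (default): inner-quartile by mean ln abundance;
#'   `"ratio"`: inner-quartile by ln ratio.
#' @return A one-row tibble of class `fc_calibration`: `pearson_r`,
#'   `coverage` (at the returned threshold), `fc_threshold`,
#'   `n_inner_quartile`, `n_dropped_zero`.
#' @export
calibrate_fc_threshold <- function(controls,
                                   grid = seq(1.5, 2.0, by = 0.05),
                                   target_coverage = 0.99,
                                   trim = c("abundance", "ratio")) {
  trim <- match.arg(trim)
  if (!all(c("control_a", "control_b") %in% names(controls))) {
    abort("`controls` needs `control_a` and `control_b` columns.")
  }
  if (length(grid) == 0 || is.unsorted(grid) ||
      min(grid) < 1.5 - 1e-9 || max(grid) > 2.0 + 1e-9) {
    abort("`grid` must be a non-empty ascending vector within [1.5, 2.0].")
  }
  if (target_coverage <= 0 || target_coverage > 1) {
    abort("`target_coverage` must lie in (0, 1].")
  }
  a <- controls$control_a
  b <- controls$control_b
  pos <- is.finite(a) & is.finite(b) & a > 0 & b > 0
  n_dropped <- sum(!pos)
  a <- a[pos]; b <- b[pos]
  if (length(a) < 8) {
    abort("Fewer than 8 proteins with positive values in both controls; quartiles are meaningless.")
  }
  la <- log(a); lb <- log(b)
  key <- if (trim == "abundance") (la + lb) / 2 else la - lb
  qs <- quantile(key, c(0.25, 0.75), names = FALSE)
  inner <- key >= qs[1] & key <= qs[2]
  la_i <- la[inner]; lb_i <- lb[inner]

  r <- if (sd(la_i) == 0 || sd(lb_i) == 0) {
    if (all(abs(la_i - lb_i) < 1e-12)) 1 else NA_real_
  } else {
    cor(la_i, lb_i)
  }

  ratio <- abs(la_i - lb_i)
  cov_at <- vapply(grid, function(t) mean(ratio <= log(t) + 1e-12), numeric(1))
  hit <- which(cov_at >= target_coverage)
  if (length(hit)) {
    fc_threshold <- grid[hit[1]]
    coverage <- cov_at[hit[1]]
  } else {
    fc_threshold <- 2.0
    coverage <- mean(ratio <= log(2.0) + 1e-12)
    warn(paste0("Control ratio spread exceeds the 2.0-fold band: coverage ",
                signif(coverage, 3), " < target ", target_coverage,
                "; threshold clamped at 2.0."))
  }
  structure(
    tibble::tibble(pearson_r = r, coverage = coverage,
                   fc_threshold = fc_threshold,
                   n_inner_quartile = sum(inner),
                   n_dropped_zero = n_dropped),
    class = c("fc_calibration", class(tibble::tibble()))
  )
}
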