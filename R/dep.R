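# The three-criterion significance gate: SAM-like weight W, one-tailed
# unequal-variance (Welch) t-test, and signed fold change. A protein is
# called differential only when all three pass.

#' Thresholds for the conjunction significance gate
#'
#' @param w_cut Cutoff on |W|; a protein passes the SAM criterion when
#'   `|W| > w_cut`. Default 0.8.
#' @param p_cut One-tailed Welch p-value cutoff (strict `<`). Default 0.05.
#' @param fc_cut Signed fold-change magnitude threshold, in ratio units
#'   (>= 1). Default 1.5; [calibrate_fc_threshold()] can supply a value on
#'   [1.5, 2.0].
#' @param w_variant Denominator of the weight statistic: `"difference"`
#'   (as printed, `(delta1 - delta2)`) or `"sum"` (`(delta1 + delta2)`, the
#'   sign-stable reading). Default `"difference"`.
#' @return A list of class `gate_thresholds`.
#' @export
gate_thresholds <- function(w_cut = 0.8, p_cut = 0.05, fc_cut = 1.5,
                            w_variant = c("difference", "sum")) {
  w_variant <- match.arg(w_variant)
  if (w_cut <= 0) abort("`w_cut` must be positive.")
  if (p_cut <= 0 || p_cut >= 1) abort("`p_cut` must lie in (0, 1).")
  if (fc_cut < 1) abort("`fc_cut` must be at least 1 (ratio units).")
  structure(list(w_cut = w_cut, p_cut = p_cut, fc_cut = fc_cut,
                 w_variant = w_variant),
            class = "gate_thresholds")
}

#' SAM-like group-separation weight
#'
#' `W = (mu1 - mu2) / (delta1 - delta2)` with the `"difference"` variant (as
#' printed in the procedure this package implements), or
#' `W = (mu1 - mu2) / (delta1 + delta2)` with the `"sum"` variant. W grows
#' as the group means separate and the spreads shrink. A denominator of
#' magnitude below 1e-12 yields `NaN` with a warning; the gate treats a
#' non-finite W as a failed criterion.
#'
#' All arguments are vectorized.
#'
#' @param mu1,mu2 Group means of normalized counts.
#' @param delta1,delta2 Group sample SDs.
#' @param variant `"difference"` (default) or `"sum"`.
#' @return Numeric vector of weights (`NaN` where degenerate).
#' @examples
#' sam_weight(6, 2, 3, 1)                    # 2
#' sam_weight(6, 2, 3, 1, variant = "sum")   # 1
#' @export
sam_weight <- function(mu1, mu2, delta1, delta2,
                       variant = c("difference", "sum")) {
  variant <- match.arg(variant)
  den <- if (variant == "difference") delta1 - delta2 else delta1 + delta2
  num <- mu1 - mu2
  degenerate <- abs(den) < 1e-12
  w <- ifelse(degenerate, NaN, num / den)
  w[degenerate & num == 0] <- 0  # zero numerator dominates: no separation
  if (any(degenerate & num != 0)) {
    warn(paste0(sum(degenerate & num != 0),
                " protein(s) have a degenerate W denominator (|",
                if (variant == "difference") "delta1 - delta2" else
                  "delta1 + delta2",
                "| < 1e-12); W set to NaN and the SAM criterion fails."))
  }
  w
}

# Vectorized Welch machinery shared by the scalar wrapper and run_dep().
welch_rows <- function(a, b) {
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- row_sds(a)^2; vb <- row_sds(b)^2
  se2 <- va / na + vb / nb
  t <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- pt(abs(t), df, lower.tail = FALSE)
  zero_se <- se2 == 0
  p[zero_se] <- ifelse(ma[zero_se] == mb[zero_se], 0.5, 0)
  list(t = t, df = df, p = p)
}

#' One-tailed Welch (unequal-variance) t-test p-value
#'
#' The Welch t statistic with Welch–Satterthwaite degrees of freedom; the
#' single tail is taken in the direction of the observed mean difference, so
#' the returned p never exceeds 0.5. Two constant, equal groups give p = 0.5
#' by the t = 0 convention; constant groups with different means give p = 0.
#'
#' @param values_a,values_b Numeric vectors, each of length >= 2.
#' @return A single p-value in (0, 0.5].
#' @examples
#' welch_one_tailed_p(c(3, 5, 7), c(3, 5, 7))  # 0.5
#' @export
welch_one_tailed_p <- function(values_a, values_b) {
  if (length(values_a) < 2 || length(values_b) < 2) {
    abort("Each group needs at least 2 values for the Welch test.")
  }
  welch_rows(matrix(values_a, nrow = 1), matrix(values_b, nrow = 1))$p
}

#' Signed fold change with the negative-reciprocal convention
#'
#' The ratio `r = (mu_a + pseudocount) / (mu_b + pseudocount)` is reported
#' as `+r` when `r >= 1` and as `-1/r` otherwise, so `|fc| >= 1` always and
#' depletion appears as a negative value (ratio 0.467 becomes -2.14). With a
#' zero pseudocount, a zero mean on one side has no finite ratio: the value
#' is `NA`, the unique-presence marker, and such proteins are classified
#' structurally rather than gated.
#'
#' Vectorized over all arguments.
#'
#' @param mu_a,mu_b Non-negative group means (A is the numerator group).
#' @param pseudocount Non-negative stabilizer added to both means; default 0.
#' @return Signed fold changes (`NA` marks a unique-presence protein).
#' @examples
#' signed_fold_change(c(4, 2, 3), c(2, 4, 3))  # +2, -2, +1
#' @export
signed_fold_change <- function(mu_a, mu_b, pseudocount = 0) {
  if (pseudocount < 0) abort("`pseudocount` must be non-negative.")
  if (any(mu_a < 0 | mu_b < 0, na.rm = TRUE)) {
    abort("Group means must be non-negative.")
  }
  if (any(mu_a == 0 & mu_b == 0)) {
    abort("Fold change undefined: both group means are zero.")
  }
  a <- mu_a + pseudocount
  b <- mu_b + pseudocount
  out <- rep(NA_real_, length(a))
  ok <- a > 0 & b > 0
  r <- a[ok] / b[ok]
  out[ok] <- ifelse(r >= 1, r, -1 / r)
  out
}

#' Apply the three-criterion conjunction gate
#'
#' A protein is `up` iff `|W| > w_cut` and `p < p_cut` and `fc >= +fc_cut`;
#' `down` iff the first two hold and `fc <= -fc_cut`; otherwise `ns`. All
#' three criteria must pass — a non-finite W or an `NA` (unique-marker) fold
#' change can never yield an up/down call here.
#'
#' Vectorized over `w`, `p`, `fc`.
#'
#' @param w Weight statistic values (see [sam_weight()]).
#' @param p One-tailed Welch p-values.
#' @param fc Signed fold changes (see [signed_fold_change()]).
#' @param thresholds A [gate_thresholds()].
#' @return Character vector of statuses in `{"up", "down", "ns"}`.
#' @examples
#' gate_call(1.445, 0.014, 2.27)    # "up"
#' gate_call(-1.246, 0.004, -2.41)  # "down"
#' gate_call(0.686, 0.098, 3.04)    # "ns": fails |W| > 0.8 and p < 0.05
#' @export
gate_call <- function(w, p, fc, thresholds = gate_thresholds()) {
  stopifnot(inherits(thresholds, "gate_thresholds"))
  n <- max(length(w), length(p), length(fc))
  w <- rep_len(w, n); p <- rep_len(p, n); fc <- rep_len(fc, n)
  pass_w <- is.finite(w) & abs(w) > thresholds$w_cut
  pass_p <- is.finite(p) & p < thresholds$p_cut
  dplyr::case_when(
    pass_w & pass_p & !is.na(fc) & fc >= thresholds$fc_cut ~ "up",
    pass_w & pass_p & !is.na(fc) & fc <= -thresholds$fc_cut ~ "down",
    TRUE ~ "ns"
  )
}

#' Run the full differential-expression procedure on raw counts
#'
#' Normalizes the raw counts between samples, detects presence, classifies
#' proteins absent from one group as `unique_a`/`unique_b` (these bypass the
#' gate and the multiple-testing family), and for the remaining proteins
#' computes the weight W, the one-tailed Welch p, the signed fold change,
#' Benjamini–Hochberg adjusted p (`q`, across tested proteins only), and the
#' conjunction-gate status. The gate uses the raw p; `q` is reported for the
#' volcano representation.
#'
#' @inheritParams detect_presence
#' @param counts Raw counts tibble (`protein_id` + one column per sample).
#' @param thresholds A [gate_thresholds()].
#' @param pseudocount Passed to [signed_fold_change()]; default 0.
#' @param min_samples Presence rule passed to [detect_presence()].
#' @return A tibble of class `dep_table`: `protein_id`, `mu_a`, `mu_b`,
#'   `delta_a`, `delta_b`, `w`, `p`, `q`, `fc`, `log2fc`,
#'   `status` in `{up, down, ns, unique_a, unique_b}`. Thresholds and
#'   options are attached as attributes.
#' @examples
#' study <- simulate_counts(sim_config(total_proteins = 80, n_unique_a = 6,
#'                                     n_unique_b = 5, n_up = 10, n_down = 10,
#'                                     seed = 11))
#' dep <- run_dep(study$counts, study$samples)
#' glance(dep)
#' @export
run_dep <- function(counts, samples, thresholds = gate_thresholds(),
                    pseudocount = 0, min_samples = 1L, group_a = NULL) {
  stopifnot(inherits(thresholds, "gate_thresholds"))
  check_counts(counts)
  check_samples(samples, counts)
  grps <- group_levels(samples, group_a)

  presence <- detect_presence(counts, samples, min_samples = min_samples,
                              group_a = grps[1])
  nsc <- normalize_counts(counts)
  summ <- group_summary(nsc, samples, group_a = grps[1])

  m <- counts_matrix(nsc)
  a <- m[, group_samples(samples, grps[1]), drop = FALSE]
  b <- m[, group_samples(samples, grps[2]), drop = FALSE]

  status <- dplyr::case_when(
    presence$present_a & !presence$present_b ~ "unique_a",
    !presence$present_a & presence$present_b ~ "unique_b",
    TRUE ~ "tested"
  )
  tested <- status == "tested"

  w <- p <- q <- fc <- rep(NA_real_, nrow(summ))
  if (any(tested)) {
    w[tested] <- sam_weight(summ$mu_a[tested], summ$mu_b[tested],
                            summ$delta_a[tested], summ$delta_b[tested],
                            variant = thresholds$w_variant)
    p[tested] <- welch_rows(a[tested, , drop = FALSE],
                            b[tested, , drop = FALSE])$p
    fc[tested] <- signed_fold_change(summ$mu_a[tested], summ$mu_b[tested],
                                     pseudocount = pseudocount)
    q[tested] <- bh_adjust(p[tested])
    status[tested] <- gate_call(w[tested], p[tested], fc[tested], thresholds)
  }

  out <- tibble::tibble(
    protein_id = summ$protein_id,
    mu_a = summ$mu_a, mu_b = summ$mu_b,
    delta_a = summ$delta_a, delta_b = summ$delta_b,
    w = w, p = p, q = q, fc = fc,
    log2fc = ifelse(is.na(fc), NA_real_, sign(fc) * log2(abs(fc))),
    status = status
  )
  structure(out,
            class = c("dep_table", class(out)),
            thresholds = thresholds,
            pseudocount = pseudocount,
            groups = grps,
            tail = "direction of observed mean difference")
}

#' @export
print.dep_table <- function(x, ...) {
  th <- attr(x, "thresholds")
  cat("Differential spectral-count table (", nrow(x), " proteins; gate: |W| > ",
      th$w_cut, ", p < ", th$p_cut, ", |FC| >= ", th$fc_cut, ", W variant ",
      th$w_variant, ")\n", sep = "")
  NextMethod()
}

#' @describeIn run_dep Return the per-protein table as a plain tibble.
#' @param x A `dep_table`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.dep_table <- function(x, ...) {
  tibble::as_tibble(unclass(x)[names(x)])
}

#' @describeIn run_dep One-row summary: status counts and thresholds.
#' @exportS3Method generics::glance
glance.dep_table <- function(x, ...) {
  th <- attr(x, "thresholds")
  tibble::tibble(
    n_proteins = nrow(x),
    n_up = sum(x$status == "up"),
    n_down = sum(x$status == "down"),
    n_ns = sum(x$status == "ns"),
    n_unique_a = sum(x$status == "unique_a"),
    n_unique_b = sum(x$status == "unique_b"),
    w_cut = th$w_cut, p_cut = th$p_cut, fc_cut = th$fc_cut,
    w_variant = th$w_variant
  )
}
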