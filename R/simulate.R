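#' Configuration for a simulated two-group spectral-count study
#'
#' Defaults emulate the study design the package targets: 4 vs 7 biological
#' replicates, 506 proteins of which 48 are unique to group A and 41 to group
#' B, with 79 up- and 70 down-regulated proteins planted among the common
#' ones. Baseline expected counts are log-normal, counts are negative
#' binomial (the standard overdispersed model for spectral counts), and each
#' sample carries a log-normal library-size factor.
#'
#' @param total_proteins Total number of proteins in the study.
#' @param n_unique_a,n_unique_b Proteins detected only in group A / only in
#'   group B (structural zeros in the other group).
#' @param n_up,n_down Common proteins with planted positive / negative log2
#'   fold changes (group A relative to group B).
#' @param n_a,n_b Samples per group; both must be at least 2.
#' @param baseline_log_mean,baseline_log_sd Mean and SD of the natural-log
#'   baseline expected count per protein.
#' @param dispersion Negative-binomial overdispersion phi, so that
#'   `Var = mu + phi * mu^2` (`size = 1/phi`). Must be positive.
#' @param effect_log2fc_range Interval from which planted |log2 FC| values
#'   are drawn uniformly; the default straddles the 1.5-fold gate so some
#'   planted effects are below it.
#' @param size_factor_sd SD of the natural-log per-sample size factor.
#' @param seed Integer seed; all randomness in [simulate_counts()] derives
#'   from it.
#'
#' @return A list of class `sim_config`.
#' @seealso [simulate_counts()]
#' @export
sim_config <- function(total_proteins = 506,
                       n_unique_a = 48,
                       n_unique_b = 41,
                       n_up = 79,
                       n_down = 70,
                       n_a = 4,
                       n_b = 7,
                       baseline_log_mean = log(25),
                       baseline_log_sd = 1.2,
                       dispersion = 0.15,
                       effect_log2fc_range = c(0.8, 2.0),
                       size_factor_sd = 0.15,
                       seed = 1L) {
  cfg <- list(
    total_proteins = as.integer(total_proteins),
    n_unique_a = as.integer(n_unique_a),
    n_unique_b = as.integer(n_unique_b),
    n_up = as.integer(n_up),
    n_down = as.integer(n_down),
    n_a = as.integer(n_a),
    n_b = as.integer(n_b),
    baseline_log_mean = as.numeric(baseline_log_mean),
    baseline_log_sd = as.numeric(baseline_log_sd),
    dispersion = as.numeric(dispersion),
    effect_log2fc_range = as.numeric(effect_log2fc_range),
    size_factor_sd = as.numeric(size_factor_sd),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg, call = rlang::caller_env()) {
  with(cfg, {
    if (total_proteins < 1) abort("`total_proteins` must be positive.", call = call)
    if (any(c(n_unique_a, n_unique_b, n_up, n_down) < 0)) {
      abort("Class counts must be non-negative.", call = call)
    }
    if (n_unique_a + n_unique_b + n_up + n_down > total_proteins) {
      abort("Class counts exceed `total_proteins`: infeasible configuration.",
            call = call)
    }
    if (n_a < 2 || n_b < 2) abort("Each group needs at least 2 samples.", call = call)
    if (dispersion <= 0) abort("`dispersion` must be positive.", call = call)
    if (size_factor_sd < 0) abort("`size_factor_sd` must be non-negative.", call = call)
    if (length(effect_log2fc_range) != 2 ||
        any(effect_log2fc_range <= 0) ||
        diff(effect_log2fc_range) < 0) {
      abort("`effect_log2fc_range` must be an ascending pair of positive reals.",
            call = call)
    }
  })
  invisible(cfg)
}

#' Simulate a two-group spectral-count study with known ground truth
#'
#' Draws raw spectral counts from a negative-binomial model with log-normal
#' per-protein baselines and per-sample size factors. Group-unique proteins
#' have structural zeros in the absent group; presence classes are enforced
#' exactly: any protein whose sampled row would violate its configured class
#' (a unique protein with no nonzero count in its own group, or a common
#' protein all-zero in either group) is redrawn from its own substream, so
#' class membership is deterministic given the configuration.
#'
#' One RNG stream is seeded from `config$seed`; per-protein substream seeds
#' are derived from it, so identical configurations give bit-identical
#' studies.
#'
#' @param config A [sim_config()].
#' @param max_retries Redraw attempts per protein before giving up.
#'
#' @return A list of class `sim_study` with elements `counts` (wide tibble,
#'   `protein_id` plus one integer column per sample), `samples` (tibble with
#'   `sample_id`, `group` in {"A","B"}), `truth` (tibble with `protein_id`,
#'   `label` in {null, up, down, unique_a, unique_b}, `true_log2fc`) and
#'   `config`.
#' @examples
#' study <- simulate_counts(sim_config(total_proteins = 60, n_unique_a = 5,
#'                                     n_unique_b = 4, n_up = 8, n_down = 8,
#'                                     seed = 7))
#' dplyr::count(study$truth, label)
#' @export
simulate_counts <- function(config = sim_config(), max_retries = 100L) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  p <- config$total_proteins
  n_a <- config$n_a
  n_b <- config$n_b
  size <- 1 / config$dispersion

  labels <- rep("null", p)
  idx <- 1L
  assign_class <- function(lab, n) {
    if (n > 0) labels[seq.int(idx, length.out = n)] <<- lab
    idx <<- idx + n
  }
  assign_class("unique_a", config$n_unique_a)
  assign_class("unique_b", config$n_unique_b)
  assign_class("up", config$n_up)
  assign_class("down", config$n_down)

  protein_ids <- sprintf("P%04d", seq_len(p))
  sample_ids <- c(sprintf("A%d", seq_len(n_a)), sprintf("B%d", seq_len(n_b)))

  set.seed(config$seed)
  baselines <- exp(rnorm(p, config$baseline_log_mean, config$baseline_log_sd))
  lfc <- numeric(p)
  mag <- runif(p, config$effect_log2fc_range[1], config$effect_log2fc_range[2])
  lfc[labels == "up"] <- mag[labels == "up"]
  lfc[labels == "down"] <- -mag[labels == "down"]
  sf <- exp(rnorm(n_a + n_b, 0, config$size_factor_sd))
  protein_seeds <- sample.int(.Machine$integer.max - 1L, p)

  counts <- matrix(0L, nrow = p, ncol = n_a + n_b,
                   dimnames = list(protein_ids, sample_ids))
  ia <- seq_len(n_a)
  ib <- n_a + seq_len(n_b)

  for (i in seq_len(p)) {
    mu_a <- baselines[i] * 2^lfc[i] * sf[ia]
    mu_b <- baselines[i] * sf[ib]
    set.seed(protein_seeds[i])
    for (try in seq_len(max_retries)) {
      row <- switch(labels[i],
        unique_a = c(rnbinom(n_a, mu = mu_a, size = size), integer(n_b)),
        unique_b = c(integer(n_a), rnbinom(n_b, mu = mu_b, size = size)),
        c(rnbinom(n_a, mu = mu_a, size = size),
          rnbinom(n_b, mu = mu_b, size = size))
      )
      ok <- switch(labels[i],
        unique_a = any(row[ia] > 0),
        unique_b = any(row[ib] > 0),
        any(row[ia] > 0) && any(row[ib] > 0)
      )
      if (ok) break
      if (try == max_retries) {
        abort(paste0("Protein ", protein_ids[i], " (", labels[i],
                     ") violated its presence class after ", max_retries,
                     " redraws; raise the baseline or lower the dispersion."))
      }
    }
    counts[i, ] <- as.integer(row)
  }

  structure(list(
    counts = matrix_counts(counts),
    samples = tibble::tibble(sample_id = sample_ids,
                             group = rep(c("A", "B"), c(n_a, n_b))),
    truth = tibble::tibble(protein_id = protein_ids, label = labels,
                           true_log2fc = lfc),
    config = config
  ), class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  cat("Simulated spectral-count study:", nrow(x$truth), "proteins,",
      x$config$n_a, "vs", x$config$n_b, "samples\n")
  print(table(x$truth$label))
  invisible(x)
}

#' Score a differential-expression table against simulation ground truth
#'
#' @param dep A differential-expression table from [run_dep()] (or any data
#'   frame with `protein_id`, `status`, `log2fc`).
#' @param study The `sim_study` the table was computed from.
#'
#' @return A one-row tibble: `tpr` (fraction of truly up/down proteins called
#'   up or down), `fdr` (fraction of up/down calls that are truly null; 0
#'   when there are no calls), `venn_exact` (do the unique_a/unique_b/common
#'   assignments match the truth exactly), and `fc_bias`/`fc_rmse` of the
#'   estimated vs true log2 fold change over truly differential proteins.
#' @export
evaluate_recovery <- function(dep, study) {
  stopifnot(inherits(study, "sim_study"))
  truth <- study$truth
  if (!setequal(dep$protein_id, truth$protein_id)) {
    abort("`dep` and `study` cover different protein identifiers.")
  }
  d <- dplyr::inner_join(dep, truth, by = "protein_id")
  called <- d$status %in% c("up", "down")
  truly_de <- d$label %in% c("up", "down")
  tpr <- if (any(truly_de)) mean(called[truly_de]) else NA_real_
  fdr <- if (any(called)) mean(d$label[called] == "null") else 0
  venn_exact <-
    identical(sort(d$protein_id[d$status == "unique_a"]),
              sort(d$protein_id[d$label == "unique_a"])) &&
    identical(sort(d$protein_id[d$status == "unique_b"]),
              sort(d$protein_id[d$label == "unique_b"]))
  err <- d$log2fc[truly_de] - d$true_log2fc[truly_de]
  tibble::tibble(
    tpr = tpr, fdr = fdr, venn_exact = venn_exact,
    fc_bias = if (length(err)) mean(err) else NA_real_,
    fc_rmse = if (length(err)) sqrt(mean(err^2)) else NA_real_
  )
}
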