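# End-to-end pipeline driver: simulate (or load) -> normalize -> calibrate
# -> differential expression -> Venn -> report tables, writing each stage's
# artifact plus a JSON manifest. All randomness flows from the config seed.

pipeline_defaults <- function() {
  list(
    seed = 1L,
    simulate = TRUE,
    counts_file = NULL,
    samples_file = NULL,
    sim = list(),                # overrides for sim_config()
    calibrate = TRUE,
    calibration_group = "B",
    target_coverage = 0.99,
    w_cut = 0.8,
    p_cut = 0.05,
    fc_cut = 1.5,
    w_variant = "difference",
    pseudocount = 0,
    min_samples = 1L,
    allow_nonpaper_thresholds = FALSE
  )
}

#' Validate a pipeline configuration
#'
#' Unknown keys are rejected. By default `fc_cut` must lie in the published
#' calibration range [1.5, 2.0]; set `allow_nonpaper_thresholds = TRUE` to
#' run with other values.
#'
#' @param config A named list of overrides over the defaults (see
#'   [run_pipeline()]), or a path to a JSON file of the same shape.
#' @return The completed config list, invisibly classed `run_config`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    abort(paste0("Unknown config key(s): ", toString(unknown), "."))
  }
  cfg <- utils::modifyList(defaults, config)
  if (!isTRUE(cfg$allow_nonpaper_thresholds) &&
      (cfg$fc_cut < 1.5 || cfg$fc_cut > 2.0)) {
    abort(paste0("`fc_cut` = ", cfg$fc_cut, " is outside the calibrated ",
                 "range [1.5, 2.0]; set `allow_nonpaper_thresholds = TRUE` ",
                 "to override."))
  }
  if (!cfg$simulate && (is.null(cfg$counts_file) || is.null(cfg$samples_file))) {
    abort("Without simulation, `counts_file` and `samples_file` are required.")
  }
  structure(cfg, class = "run_config")
}

#' Run the full differential spectral-count pipeline
#'
#' Chains the stages end to end: obtain raw counts (simulated with known
#' truth, or loaded from TSV), normalize, optionally calibrate the
#' fold-change threshold from a within-group control split, run the
#' three-criterion differential-expression procedure, partition the
#' inventory by presence, and write volcano/PCA/heatmap tables. Every
#' artifact is a TSV or JSON file under `out_dir`, and a `manifest.json`
#' records thresholds, seeds, and an MD5 digest per artifact; reruns with
#' the same config are byte-identical.
#'
#' @param config See [pipeline_config()]: a named list (or JSON path) with
#'   any of `seed`, `simulate`, `counts_file`, `samples_file`, `sim`
#'   (overrides for [sim_config()]), `calibrate`, `calibration_group`,
#'   `target_coverage`, `w_cut`, `p_cut`, `fc_cut`, `w_variant`,
#'   `pseudocount`, `min_samples`, `allow_nonpaper_thresholds`.
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly, as a list.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("exodep_run_")) {
  cfg <- pipeline_config(if (inherits(config, "run_config")) unclass(config)
                         else config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- character(0)
  emit <- function(name, writer) {
    path <- file.path(out_dir, name)
    writer(path)
    artifacts <<- c(artifacts, stats::setNames(path, name))
    path
  }

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("Pipeline stage `", name, "` failed: ",
                   conditionMessage(e)))
    })
  }

  truth <- NULL
  if (isTRUE(cfg$simulate)) {
    study <- stage("simulate", {
      sim_args <- utils::modifyList(list(seed = cfg$seed), as.list(cfg$sim))
      simulate_counts(do.call(sim_config, sim_args))
    })
    counts <- study$counts
    samples <- study$samples
    truth <- study$truth
    emit("counts.tsv", function(p) write_counts(counts, p))
    emit("samples.tsv", function(p) write_samples(samples, p))
    emit("truth.tsv", function(p) write_truth(truth, p))
  } else {
    counts <- stage("load", read_counts(cfg$counts_file))
    samples <- stage("load", read_samples(cfg$samples_file))
  }

  nsc <- stage("quantify", normalize_counts(counts))
  emit("nsc.tsv", function(p) write_counts(nsc, p))

  fc_cut <- cfg$fc_cut
  calib <- NULL
  if (isTRUE(cfg$calibrate)) {
    calib <- stage("calibrate", {
      ctl <- split_control_pairs(counts, samples,
                                 group = cfg$calibration_group,
                                 seed = cfg$seed)
      calibrate_fc_threshold(ctl, target_coverage = cfg$target_coverage)
    })
    fc_cut <- calib$fc_threshold
    emit("calibration.json", function(p) {
      jsonlite::write_json(as.list(calib), p, auto_unbox = TRUE, digits = NA)
    })
  }

  thresholds <- gate_thresholds(w_cut = cfg$w_cut, p_cut = cfg$p_cut,
                                fc_cut = fc_cut, w_variant = cfg$w_variant)
  dep <- stage("dep", run_dep(counts, samples, thresholds,
                              pseudocount = cfg$pseudocount,
                              min_samples = cfg$min_samples))
  emit("dep.tsv", function(p) write_dep(dep, p))

  venn <- stage("venn", venn_partition(
    detect_presence(counts, samples, min_samples = cfg$min_samples)))
  emit("venn.tsv", function(p) readr::write_tsv(tidy(venn), p))

  stage("report", {
    emit("volcano.tsv", function(p) {
      readr::write_tsv(tibble::as_tibble(volcano_table(dep)), p)
    })
    pca <- pca_scores(nsc, k = min(3, nrow(samples) - 1), samples = samples)
    emit("pca_scores.tsv", function(p) readr::write_tsv(tidy(pca), p))
    de_ids <- dep$protein_id[dep$status %in% c("up", "down")]
    if (length(de_ids) >= 2) {
      ord <- heatmap_order(nsc[counts$protein_id %in% de_ids, , drop = FALSE])
      emit("heatmap_order.tsv", function(p) {
        readr::write_tsv(tibble::tibble(
          axis = c(rep("row", length(ord$row_order)),
                   rep("column", length(ord$col_order))),
          position = c(seq_along(ord$row_order), seq_along(ord$col_order)),
          id = c(ord$row_order, ord$col_order)
        ), p)
      })
    }
  })

  summary <- glance(dep)
  manifest <- list(
    package = "exodep",
    version = as.character(utils::packageVersion("exodep")),
    seed = cfg$seed,
    thresholds = list(w_cut = thresholds$w_cut, p_cut = thresholds$p_cut,
                      fc_cut = thresholds$fc_cut,
                      w_variant = thresholds$w_variant),
    calibrated = isTRUE(cfg$calibrate),
    status_counts = as.list(summary[c("n_up", "n_down", "n_ns",
                                      "n_unique_a", "n_unique_b")]),
    venn = as.list(glance(venn)),
    artifacts = lapply(artifacts, function(p) {
      list(file = basename(p), md5 = unname(tools::md5sum(p)))
    })
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
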