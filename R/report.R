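# Reporting tables behind the standard figures: volcano coordinates, PCA
# sample scores, and clustered heatmap orderings. The tested artifacts are
# the tables; plots are thin ggplot2 layers over them.

#' Volcano-plot coordinates from a differential-expression table
#'
#' `log2fc = sign(fc) * log2(|fc|)` and `neg_log10_q = -log10(q)` with the
#' Benjamini–Hochberg adjusted p. Group-unique proteins have no finite fold
#' change and are excluded.
#'
#' @param dep A `dep_table` from [run_dep()].
#' @return A tibble: `protein_id`, `log2fc`, `neg_log10_q`, `category` in
#'   `{up, down, ns}`. Gate thresholds are attached as attributes for the
#'   reference lines.
#' @export
volcano_table <- function(dep) {
  stopifnot(inherits(dep, "dep_table"))
  th <- attr(dep, "thresholds")
  tested <- dep[dep$status %in% c("up", "down", "ns"), , drop = FALSE]
  structure(
    tibble::tibble(
      protein_id = tested$protein_id,
      log2fc = tested$log2fc,
      neg_log10_q = -log10(tested$q),
      category = tested$status
    ),
    thresholds = th
  )
}

#' PCA sample scores from a normalized count matrix
#'
#' Counts are transformed as `log2(N-SC + 1)`, centred per protein, and
#' decomposed exactly by SVD with samples as observations. Component signs
#' are fixed deterministically by making each component's largest-magnitude
#' protein loading positive.
#'
#' @inheritParams group_summary
#' @param nsc Normalized counts tibble.
#' @param k Number of components (at most `min(#samples - 1, #proteins)`).
#' @param samples Optional samples table; when given, group labels are
#'   joined onto the scores.
#' @return A list of class `pca_scores`: `scores` (tibble `sample_id`,
#'   `PC1..PCk`, and `group` when available) and `var_explained`
#'   (non-increasing fractions). `tidy()` returns the scores, `glance()` the
#'   variance fractions.
#' @export
pca_scores <- function(nsc, k = 2, samples = NULL) {
  check_counts(nsc)
  m <- counts_matrix(nsc)
  kmax <- min(ncol(m) - 1, nrow(m))
  if (k < 1 || k > kmax) {
    abort(paste0("`k` must lie between 1 and ", kmax,
                 " (= min(#samples - 1, #proteins))."))
  }
  x <- t(log2(m + 1))            # samples x proteins
  fit <- prcomp(x, center = TRUE, scale. = FALSE)
  scores <- fit$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    load <- fit$rotation[, j]
    if (load[which.max(abs(load))] < 0) scores[, j] <- -scores[, j]
  }
  ve <- fit$sdev^2 / sum(fit$sdev^2)
  sc <- tibble::as_tibble(scores)
  names(sc) <- paste0("PC", seq_len(k))
  sc <- dplyr::bind_cols(tibble::tibble(sample_id = rownames(x)), sc)
  if (!is.null(samples)) {
    sc <- dplyr::left_join(sc, dplyr::select(samples, "sample_id", "group"),
                           by = "sample_id")
  }
  structure(list(scores = sc,
                 var_explained = ve[seq_len(min(k, length(ve)))]),
            class = "pca_scores")
}

#' @export
print.pca_scores <- function(x, ...) {
  cat("PCA scores (", nrow(x$scores), " samples); variance explained: ",
      paste(signif(x$var_explained, 3), collapse = ", "), "\n", sep = "")
  print(x$scores)
  invisible(x)
}

#' @rdname pca_scores
#' @param x A `pca_scores`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.pca_scores <- function(x, ...) x$scores

#' @rdname pca_scores
#' @exportS3Method generics::glance
glance.pca_scores <- function(x, ...) {
  tibble::tibble(component = seq_along(x$var_explained),
                 var_explained = x$var_explained)
}

#' Row and column orderings for a clustered expression heatmap
#'
#' Selected rows are z-scored per protein, then rows and columns are ordered
#' by average-linkage agglomerative clustering under the chosen metric.
#' `hclust` ties are resolved deterministically by original index.
#'
#' @param nsc Normalized counts tibble, usually restricted to the proteins
#'   of interest (needs >= 2 rows).
#' @param metric `"euclidean"` or `"correlation"` (distance `1 - r`). A
#'   zero-variance row is an error under the correlation metric.
#' @return A list of class `heatmap_order`: `row_order` and `col_order`
#'   (identifier vectors), `row_hclust`/`col_hclust` (the `hclust` objects),
#'   and `z` (the z-scored matrix).
#' @export
heatmap_order <- function(nsc, metric = c("euclidean", "correlation")) {
  metric <- match.arg(metric)
  check_counts(nsc)
  m <- counts_matrix(nsc)
  if (nrow(m) < 2) abort("Heatmap ordering needs at least 2 rows.")
  sds <- row_sds(m)
  if (metric == "correlation" && any(sds == 0)) {
    abort(paste0("Zero-variance row(s) under the correlation metric: ",
                 toString(rownames(m)[sds == 0]), "."))
  }
  z <- (m - rowMeans(m)) / ifelse(sds == 0, 1, sds)
  dist_of <- function(x) {
    if (metric == "euclidean") dist(x) else as.dist(1 - cor(t(x)))
  }
  hr <- hclust(dist_of(z), method = "average")
  hc <- hclust(dist(t(z)), method = "average")
  structure(list(
    row_order = rownames(z)[hr$order],
    col_order = colnames(z)[hc$order],
    row_hclust = hr, col_hclust = hc, z = z
  ), class = "heatmap_order")
}

#' Volcano plot of a differential-expression table
#'
#' @param object A `dep_table`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.dep_table <- function(object, ...) {
  th <- attr(object, "thresholds")
  v <- volcano_table(object)
  ggplot2::ggplot(v, ggplot2::aes(.data$log2fc, .data$neg_log10_q,
                                  colour = .data$category)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * log2(th$fc_cut),
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(0.05), linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(up = "#d73027", down = "#1a9850",
                                            ns = "grey60")) +
    ggplot2::labs(x = "log2 fold change (A / B)",
                  y = "-log10 BH-adjusted p", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Score plot for PCA results
#'
#' @param object A `pca_scores`.
#' @param ... Unused.
#' @return A ggplot of the first two components.
#' @exportS3Method ggplot2::autoplot
autoplot.pca_scores <- function(object, ...) {
  sc <- object$scores
  if (!"PC2" %in% names(sc)) abort("Need at least 2 components to plot.")
  aes <- if ("group" %in% names(sc)) {
    ggplot2::aes(.data$PC1, .data$PC2, colour = .data$group)
  } else {
    ggplot2::aes(.data$PC1, .data$PC2)
  }
  ggplot2::ggplot(sc, aes) +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$var_explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$var_explained[2])
    ) +
    ggplot2::theme_minimal()
}

#' Clustered heatmap of z-scored expression
#'
#' @param ord A `heatmap_order`.
#' @return A ggplot tile map in clustered order.
#' @export
plot_heatmap <- function(ord) {
  stopifnot(inherits(ord, "heatmap_order"))
  df <- tibble::as_tibble(ord$z, rownames = "protein_id")
  df <- tidyr::pivot_longer(df, -"protein_id", names_to = "sample_id",
                            values_to = "z")
  df$protein_id <- factor(df$protein_id, levels = rev(ord$row_order))
  df$sample_id <- factor(df$sample_id, levels = ord$col_order)
  ggplot2::ggplot(df, ggplot2::aes(.data$sample_id, .data$protein_id,
                                   fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#1a9850", mid = "black",
                                  high = "#d73027") +
    ggplot2::labs(x = NULL, y = NULL, fill = "z") +
    ggplot2::theme_minimal()
}
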