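# Presence/absence Venn partition of the protein inventory and generic
# over-representation analysis (one-sided hypergeometric) against GMT sets.

#' Venn partition of the protein inventory by group presence
#'
#' @param flags Presence flags (`protein_id`, `present_a`, `present_b`),
#'   e.g. from [detect_presence()]. A protein absent from both groups is
#'   rejected (it cannot occur in a matrix assembled from retained
#'   evidence).
#' @return A list of class `venn_partition`: `counts` (one-row tibble
#'   `n_common`, `n_only_a`, `n_only_b`, `n_total`) and `classes`
#'   (per-protein tibble with `class` in `{common, only_a, only_b}`).
#'   `tidy()` returns the classes, `glance()` the counts.
#' @export
venn_partition <- function(flags) {
  if (!all(c("protein_id", "present_a", "present_b") %in% names(flags))) {
    abort("`flags` needs `protein_id`, `present_a`, `present_b`.")
  }
  if (nrow(flags) == 0) abort("`flags` is empty.")
  if (any(!flags$present_a & !flags$present_b)) {
    abort("Protein(s) absent from both groups: invalid presence table.")
  }
  cls <- dplyr::case_when(
    flags$present_a & flags$present_b ~ "common",
    flags$present_a ~ "only_a",
    TRUE ~ "only_b"
  )
  structure(list(
    counts = tibble::tibble(
      n_common = sum(cls == "common"),
      n_only_a = sum(cls == "only_a"),
      n_only_b = sum(cls == "only_b"),
      n_total = length(cls)
    ),
    classes = tibble::tibble(protein_id = flags$protein_id, class = cls)
  ), class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  with(x$counts, cat("Venn partition:", n_total, "proteins =", n_common,
                     "common +", n_only_a, "only-A +", n_only_b, "only-B\n"))
  invisible(x)
}

#' @rdname venn_partition
#' @param x A `venn_partition`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.venn_partition <- function(x, ...) x$classes

#' @rdname venn_partition
#' @exportS3Method generics::glance
glance.venn_partition <- function(x, ...) x$counts

#' Benjamini–Hochberg step-up adjustment
#'
#' Validated wrapper over the standard step-up procedure: adjusted values
#' are clipped to 1 and returned in the original order.
#'
#' @param p_values Numeric vector of p-values in [0, 1].
#' @return Adjusted values (q), same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (any(!is.finite(p_values) | p_values < 0 | p_values > 1)) {
    abort("All p-values must be finite and in [0, 1].")
  }
  p.adjust(p_values, method = "BH")
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one term per line, tab-separated as
#' `term_id<TAB>description<TAB>member1<TAB>member2...`.
#'
#' @param path Path to a GMT file.
#' @return A tibble with `term_id`, `term_name`, and a `members` list-column
#'   of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3
  if (any(bad)) {
    abort(paste0("GMT line(s) with fewer than 3 fields: line ",
                 which(bad)[1], "."))
  }
  tibble::tibble(
    term_id = vapply(parts, `[[`, character(1), 1),
    term_name = vapply(parts, `[[`, character(1), 2),
    members = lapply(parts, function(x) unique(x[-(1:2)]))
  )
}

#' Write a GMT gene-set file
#'
#' @param gmt A tibble as returned by [read_gmt()].
#' @param path Output path.
#' @export
write_gmt <- function(gmt, path) {
  lines <- mapply(function(id, nm, mem) {
    paste(c(id, nm, mem), collapse = "\t")
  }, gmt$term_id, gmt$term_name, gmt$members)
  writeLines(unname(lines), path)
  invisible(path)
}

#' Over-representation analysis against GMT annotation sets
#'
#' For each term, the one-sided hypergeometric upper-tail probability of
#' observing at least the realized overlap between the query and the term
#' (both intersected with the background), identical to a one-sided Fisher
#' test on the 2x2 table. P-values are BH-adjusted across terms and results
#' are sorted by p, ties broken by term id. The background defaults to the
#' standard ORA choice: every protein identified in the experiment.
#'
#' @param query Character vector of query identifiers; must be a subset of
#'   `background`.
#' @param gmt Annotation sets from [read_gmt()] (or a tibble of the same
#'   shape).
#' @param background Character vector of background identifiers.
#' @param alpha Significance level used only to flag records; default 0.05.
#' @return A tibble: `term_id`, `term_name`, `k` (overlap), `K` (term size
#'   in background), `n` (query size), `N` (background size), `p`, `q`,
#'   `significant`.
#' @export
ora <- function(query, gmt, background, alpha = 0.05) {
  query <- unique(as.character(query))
  background <- unique(as.character(background))
  outside <- setdiff(query, background)
  if (length(outside)) {
    abort(paste0("Query identifier(s) not in background: ",
                 toString(head(outside, 10)),
                 if (length(outside) > 10) ", ..." else "", "."))
  }
  if (length(query) == 0 || nrow(gmt) == 0) {
    return(tibble::tibble(term_id = character(0), term_name = character(0),
                          k = integer(0), K = integer(0), n = integer(0),
                          N = integer(0), p = numeric(0), q = numeric(0),
                          significant = logical(0)))
  }
  N <- length(background)
  n <- length(query)
  res <- purrr::map_dfr(seq_len(nrow(gmt)), function(i) {
    term <- intersect(gmt$members[[i]], background)
    K <- length(term)
    k <- length(intersect(query, term))
    # P(X >= k) for X ~ Hypergeom(N, K, n); k = 0 gives the certain event.
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    tibble::tibble(term_id = gmt$term_id[i], term_name = gmt$term_name[i],
                   k = k, K = K, n = n, N = N, p = p)
  })
  res$q <- bh_adjust(res$p)
  res$significant <- res$q <= alpha
  dplyr::arrange(res, .data$p, .data$term_id)
}
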