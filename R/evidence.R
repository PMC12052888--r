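# Scaffold-style evidence filtering: peptide-level retention rules followed
# by protein-level rules, emitting a raw spectral-count matrix. Spectral
# count = number of retained peptide-spectrum records; distinct peptide
# sequences enter only the >=2-peptides-per-protein rule.

#' Retention thresholds for evidence filtering
#'
#' Defaults are the standard high-stringency export settings: peptides longer
#' than 5 amino acids, no singly-charged (MH+1) precursors, peptide
#' probability above 80%, at least 2 distinct peptides per protein, protein
#' probability above 99.0%, and protein FDR below 1%. All probability
#' cutoffs are strict inequalities.
#'
#' @param min_peptide_length_exclusive Peptides must be strictly longer than
#'   this many residues.
#' @param forbid_charge_one Drop charge-state-1 precursors.
#' @param min_peptide_prob Peptide probability must exceed this.
#' @param min_peptides_per_protein Minimum distinct retained peptide
#'   sequences per protein, counted across the whole experiment.
#' @param min_protein_prob Protein probability must exceed this.
#' @param max_protein_fdr Protein FDR must be below this.
#' @export
filter_thresholds <- function(min_peptide_length_exclusive = 5L,
                              forbid_charge_one = TRUE,
                              min_peptide_prob = 0.80,
                              min_peptides_per_protein = 2L,
                              min_protein_prob = 0.99,
                              max_protein_fdr = 0.01) {
  th <- list(
    min_peptide_length_exclusive = as.integer(min_peptide_length_exclusive),
    forbid_charge_one = isTRUE(forbid_charge_one),
    min_peptide_prob = as.numeric(min_peptide_prob),
    min_peptides_per_protein = as.integer(min_peptides_per_protein),
    min_protein_prob = as.numeric(min_protein_prob),
    max_protein_fdr = as.numeric(max_protein_fdr)
  )
  if (th$min_peptide_prob < 0 || th$min_peptide_prob > 1 ||
      th$min_protein_prob < 0 || th$min_protein_prob > 1 ||
      th$max_protein_fdr < 0 || th$max_protein_fdr > 1) {
    abort("Probability thresholds must lie in [0, 1].")
  }
  structure(th, class = "filter_thresholds")
}

evidence_cols <- c("sample_id", "protein_id", "peptide_seq", "charge",
                   "peptide_prob", "protein_prob", "protein_fdr")

check_evidence <- function(records, call = rlang::caller_env()) {
  if (!is.data.frame(records)) abort("`records` must be a data frame.", call = call)
  missing <- setdiff(evidence_cols, names(records))
  if (length(missing)) {
    abort(paste0("Evidence table is missing column(s): ", toString(missing), "."),
          call = call)
  }
  fail_row <- function(field, bad) {
    if (any(bad)) {
      abort(paste0("Malformed evidence: field `", field, "` invalid at row ",
                   which(bad)[1], "."), call = call)
    }
  }
  fail_row("peptide_seq", is.na(records$peptide_seq) |
             !grepl("^[A-Za-z]+$", records$peptide_seq))
  fail_row("charge", is.na(records$charge) | records$charge < 1 |
             records$charge != round(records$charge))
  for (field in c("peptide_prob", "protein_prob", "protein_fdr")) {
    fail_row(field, is.na(records[[field]]) |
               records[[field]] < 0 | records[[field]] > 1)
  }
  invisible(records)
}

#' Apply peptide-level retention rules to an evidence table
#'
#' A record is kept iff its peptide sequence is strictly longer than the
#' length cutoff, its charge state is not 1 (when MH+1 precursors are
#' forbidden), and its peptide probability strictly exceeds the probability
#' cutoff. Row order is preserved; the operation is idempotent.
#'
#' @param records Evidence table with columns `sample_id`, `protein_id`,
#'   `peptide_seq`, `charge`, `peptide_prob`, `protein_prob`, `protein_fdr`.
#' @param thresholds A [filter_thresholds()].
#' @return The retained rows, as a tibble.
#' @export
filter_peptides <- function(records, thresholds = filter_thresholds()) {
  stopifnot(inherits(thresholds, "filter_thresholds"))
  check_evidence(records)
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0) return(records)
  keep <- nchar(records$peptide_seq) > thresholds$min_peptide_length_exclusive &
    records$peptide_prob > thresholds$min_peptide_prob
  if (thresholds$forbid_charge_one) keep <- keep & records$charge != 1
  records[keep, , drop = FALSE]
}

#' Assemble a raw spectral-count matrix from filtered evidence
#'
#' Re-applies [filter_peptides()] defensively, then keeps a protein iff it
#' has at least `min_peptides_per_protein` distinct retained peptide
#' sequences across the experiment, protein probability strictly above the
#' cutoff, and protein FDR strictly below the cutoff. Cell (i, j) is the
#' number of retained records (spectra) for protein i in sample j; declared
#' samples with no surviving records get zero columns.
#'
#' @inheritParams filter_peptides
#' @param samples Either a character vector of sample identifiers or a data
#'   frame with a `sample_id` column, fixing the column order of the output.
#' @return A wide counts tibble (`protein_id` + one column per sample).
#' @export
assemble_protein_counts <- function(records,
                                    samples,
                                    thresholds = filter_thresholds()) {
  sample_ids <- if (is.data.frame(samples)) as.character(samples$sample_id)
                else as.character(samples)
  if (anyDuplicated(sample_ids)) abort("Duplicated sample identifiers.")
  kept <- filter_peptides(records, thresholds)

  if (nrow(kept)) {
    prot <- dplyr::summarise(
      dplyr::group_by(kept, .data$protein_id),
      n_peptides = dplyr::n_distinct(.data$peptide_seq),
      n_prob = dplyr::n_distinct(.data$protein_prob),
      protein_prob = .data$protein_prob[1],
      protein_fdr = max(.data$protein_fdr),
      .groups = "drop"
    )
    incons <- prot$protein_id[prot$n_prob > 1]
    if (length(incons)) {
      abort(paste0("Conflicting protein_prob values for protein(s): ",
                   toString(incons), " (evidence table inconsistent)."))
    }
    keep_prot <- prot$protein_id[
      prot$n_peptides >= thresholds$min_peptides_per_protein &
        prot$protein_prob > thresholds$min_protein_prob &
        prot$protein_fdr < thresholds$max_protein_fdr]
    kept <- kept[kept$protein_id %in% keep_prot, , drop = FALSE]
  }

  extra <- setdiff(unique(kept$sample_id), sample_ids)
  if (length(extra)) {
    abort(paste0("Record sample(s) not in declared sample list: ",
                 toString(extra), "."))
  }

  if (nrow(kept) == 0) {
    out <- tibble::tibble(protein_id = character(0))
    for (s in sample_ids) out[[s]] <- integer(0)
    return(out)
  }

  tab <- table(factor(kept$protein_id, levels = sort(unique(kept$protein_id))),
               factor(kept$sample_id, levels = sample_ids))
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = dimnames(tab))
  matrix_counts(m)
}

#' Simulate a peptide-evidence table with planted rule violations
#'
#' A light-weight generator of evidence records for exercising the filtering
#' rules: clean proteins emit multi-peptide, high-probability records, and a
#' configurable fraction of records violate one rule each (short peptide,
#' charge 1, or low peptide probability). Not a mass-spectrum model.
#'
#' @param n_proteins Number of clean proteins.
#' @param sample_ids Sample identifiers.
#' @param spectra_per_peptide Mean retained spectra per peptide per sample.
#' @param violation_rate Fraction of extra records that violate one peptide
#'   rule.
#' @param seed Integer seed.
#' @return An evidence tibble suitable for [filter_peptides()].
#' @export
simulate_evidence <- function(n_proteins = 20,
                              sample_ids = c("A1", "A2", "B1", "B2"),
                              spectra_per_peptide = 2,
                              violation_rate = 0.2,
                              seed = 1L) {
  set.seed(seed)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  rand_pep <- function(len) paste(sample(aa, len, replace = TRUE), collapse = "")
  rows <- purrr::map_dfr(seq_len(n_proteins), function(i) {
    pid <- sprintf("SIM%03d", i)
    peps <- vapply(2:4, function(k) rand_pep(sample(7:15, 1)), character(1))
    purrr::map_dfr(sample_ids, function(s) {
      n_spec <- pmax(1, stats::rpois(length(peps), spectra_per_peptide))
      tibble::tibble(
        sample_id = s,
        protein_id = pid,
        peptide_seq = rep(peps, n_spec),
        charge = sample(2:4, sum(n_spec), replace = TRUE),
        peptide_prob = runif(sum(n_spec), 0.85, 1),
        protein_prob = 0.995,
        protein_fdr = 0.005
      )
    })
  })
  n_bad <- ceiling(violation_rate * nrow(rows))
  if (n_bad > 0) {
    bad <- tibble::tibble(
      sample_id = sample(sample_ids, n_bad, replace = TRUE),
      protein_id = sprintf("BAD%03d", seq_len(n_bad)),
      peptide_seq = vapply(seq_len(n_bad), function(i) rand_pep(9), character(1)),
      charge = 2L,
      peptide_prob = 0.95,
      protein_prob = 0.995,
      protein_fdr = 0.005
    )
    kind <- sample(3, n_bad, replace = TRUE)
    bad$peptide_seq[kind == 1] <-
      vapply(which(kind == 1), function(i) rand_pep(5), character(1))
    bad$charge[kind == 2] <- 1L
    bad$peptide_prob[kind == 3] <- runif(sum(kind == 3), 0, 0.8)
    rows <- dplyr::bind_rows(rows, bad)
  }
  rows
}
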