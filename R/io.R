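# TSV readers/writers for the pipeline's tabular artifacts. All files are
# plain tab-separated text with a header row.

#' Read and write pipeline tables
#'
#' Counts tables are wide (`protein_id` plus one numeric column per sample);
#' sample tables have `sample_id` and `group`; truth tables have
#' `protein_id`, `label`, `true_log2fc`; evidence tables follow the layout
#' documented in [filter_peptides()].
#'
#' @param path File path.
#' @name exodep-io
NULL

read_tsv_quiet <- function(path, col_types) {
  readr::read_tsv(path, col_types = col_types, progress = FALSE)
}

#' @rdname exodep-io
#' @export
read_counts <- function(path) {
  out <- read_tsv_quiet(path, readr::cols(protein_id = readr::col_character(),
                                          .default = readr::col_double()))
  check_counts(out)
  out
}

#' @rdname exodep-io
#' @param counts,samples,truth,records,dep Tables to write.
#' @export
write_counts <- function(counts, path) {
  check_counts(counts)
  readr::write_tsv(counts, path)
  invisible(path)
}

#' @rdname exodep-io
#' @export
read_samples <- function(path) {
  out <- read_tsv_quiet(path, readr::cols(.default = readr::col_character()))
  check_samples(out)
  out
}

#' @rdname exodep-io
#' @export
write_samples <- function(samples, path) {
  check_samples(samples)
  readr::write_tsv(samples, path)
  invisible(path)
}

#' @rdname exodep-io
#' @export
read_truth <- function(path) {
  read_tsv_quiet(path, readr::cols(protein_id = readr::col_character(),
                                   label = readr::col_character(),
                                   true_log2fc = readr::col_double()))
}

#' @rdname exodep-io
#' @export
write_truth <- function(truth, path) {
  readr::write_tsv(truth, path)
  invisible(path)
}

#' @rdname exodep-io
#' @export
read_evidence <- function(path) {
  out <- read_tsv_quiet(path, readr::cols(
    sample_id = readr::col_character(),
    protein_id = readr::col_character(),
    peptide_seq = readr::col_character(),
    charge = readr::col_integer(),
    peptide_prob = readr::col_double(),
    protein_prob = readr::col_double(),
    protein_fdr = readr::col_double()
  ))
  check_evidence(out)
  out
}

#' @rdname exodep-io
#' @export
write_evidence <- function(records, path) {
  check_evidence(records)
  readr::write_tsv(records, path)
  invisible(path)
}

#' @rdname exodep-io
#' @export
write_dep <- function(dep, path) {
  readr::write_tsv(tibble::as_tibble(unclass(dep)[names(dep)]), path)
  invisible(path)
}
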