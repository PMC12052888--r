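test_that("peptide retention applies all three rules with strict cutoffs", {
  records <- dplyr::bind_rows(
    ev_record(peptide_seq = "PEPTID", charge = 2, peptide_prob = 0.85),  # keep
    ev_record(peptide_seq = "PEPTI", charge = 2, peptide_prob = 0.99),   # len 5
    ev_record(peptide_seq = "PEPTIDEPEPTI", charge = 1, peptide_prob = 0.99),
    ev_record(peptide_seq = "PEPTIDK", charge = 2, peptide_prob = 0.80)  # == cut
  )
  kept <- filter_peptides(records)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$peptide_seq, "PEPTID")

  # charge-1 records survive when MH+1 exclusion is turned off
  th <- filter_thresholds(forbid_charge_one = FALSE)
  expect_equal(nrow(filter_peptides(records, th)), 2)

  expect_equal(nrow(filter_peptides(records[0, ])), 0)
})

test_that("malformed records are rejected with field and row", {
  bad <- ev_record(peptide_prob = 1.2)
  expect_error(filter_peptides(bad), "peptide_prob.*row 1")
  bad2 <- dplyr::bind_rows(ev_record(), ev_record(peptide_seq = "PEP2TIDE"))
  expect_error(filter_peptides(bad2), "peptide_seq.*row 2")
})

test_that("filtering is idempotent and order-preserving", {
  set.seed(1)
  records <- simulate_evidence(n_proteins = 12, violation_rate = 0.3, seed = 2)
  records$row_index <- seq_len(nrow(records))
  once <- filter_peptides(records)
  expect_identical(filter_peptides(once), once)
  expect_true(!is.unsorted(once$row_index, strictly = TRUE))
})

test_that("protein assembly counts retained spectra and applies protein rules", {
  records <- dplyr::bind_rows(
    ev_record("S1", "P", "AAAAAAA", peptide_prob = 0.9),
    ev_record("S1", "P", "AAAAAAA", peptide_prob = 0.9),
    ev_record("S1", "P", "AAAAAAA", peptide_prob = 0.9),
    ev_record("S1", "P", "CCCCCCC", peptide_prob = 0.9),
    ev_record("S1", "P", "CCCCCCC", peptide_prob = 0.9),
    ev_record("S1", "P", "CCCCCCC", peptide_prob = 0.9),
    ev_record("S1", "P", "CCCCCCC", peptide_prob = 0.9),
    ev_record("S2", "P", "AAAAAAA", peptide_prob = 0.9),
    ev_record("S2", "P", "CCCCCCC", peptide_prob = 0.9),
    # one distinct peptide only, despite many spectra:
    ev_record("S1", "Q", rep("DDDDDDD", 10), peptide_prob = 0.9),
    # fails protein probability:
    ev_record("S1", "R", "EEEEEEE", protein_prob = 0.98),
    ev_record("S1", "R", "FFFFFFF", protein_prob = 0.98),
    # fails protein FDR:
    ev_record("S1", "T", "GGGGGGG", protein_fdr = 0.02),
    ev_record("S1", "T", "HHHHHHH", protein_fdr = 0.02)
  )
  counts <- assemble_protein_counts(records, c("S1", "S2", "S3"))
  expect_equal(counts$protein_id, "P")
  expect_equal(as.numeric(counts[1, c("S1", "S2", "S3")]), c(7, 2, 0))
})

test_that("empty survivors give a zero-row matrix with declared columns", {
  records <- ev_record(peptide_prob = 0.5)
  counts <- assemble_protein_counts(records, c("S1", "S2"))
  expect_equal(nrow(counts), 0)
  expect_equal(names(counts), c("protein_id", "S1", "S2"))
})

test_that("inconsistent protein probabilities are an error", {
  records <- dplyr::bind_rows(
    ev_record("S1", "P", "AAAAAAA", protein_prob = 0.995),
    ev_record("S1", "P", "CCCCCCC", protein_prob = 0.992)
  )
  expect_error(assemble_protein_counts(records, "S1"), "Conflicting")
})

test_that("tightening thresholds never increases counts or retained proteins", {
  records <- simulate_evidence(n_proteins = 15, violation_rate = 0.3, seed = 5)
  samples <- sort(unique(records$sample_id))
  loose <- assemble_protein_counts(records, samples)
  for (th in list(filter_thresholds(min_peptide_prob = 0.9),
                  filter_thresholds(min_peptide_length_exclusive = 9),
                  filter_thresholds(min_peptides_per_protein = 3))) {
    tight <- assemble_protein_counts(records, samples, th)
    expect_lte(nrow(tight), nrow(loose))
    shared <- intersect(tight$protein_id, loose$protein_id)
    expect_true(all(as.matrix(tight[match(shared, tight$protein_id), -1]) <=
                      as.matrix(loose[match(shared, loose$protein_id), -1])))
  }
})

test_that("the matrix grand total equals the retained record count", {
  records <- simulate_evidence(n_proteins = 10, violation_rate = 0.25, seed = 7)
  samples <- sort(unique(records$sample_id))
  counts <- assemble_protein_counts(records, samples)
  kept <- filter_peptides(records)
  kept <- kept[kept$protein_id %in% counts$protein_id, ]
  expect_equal(sum(counts[-1]), nrow(kept))
})
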