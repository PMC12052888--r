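test_that("truth labels match the configured class counts", {
  study <- simulate_counts(sim_config(seed = 5))
  tab <- table(study$truth$label)
  expect_equal(unname(tab[["unique_a"]]), 48)
  expect_equal(unname(tab[["unique_b"]]), 41)
  expect_equal(unname(tab[["up"]]), 79)
  expect_equal(unname(tab[["down"]]), 70)
  expect_equal(nrow(study$truth), 506)
  expect_equal(nrow(study$samples), 11)
})

test_that("structural classes are exact and effect signs match labels", {
  study <- simulate_counts(small_config(seed = 9))
  m <- as.matrix(study$counts[-1])
  a_cols <- study$samples$sample_id[study$samples$group == "A"]
  b_cols <- study$samples$sample_id[study$samples$group == "B"]
  for (lab in c("unique_a", "unique_b")) {
    rows <- which(study$truth$label == lab)
    own <- if (lab == "unique_a") a_cols else b_cols
    other <- if (lab == "unique_a") b_cols else a_cols
    expect_true(all(rowSums(m[rows, other, drop = FALSE]) == 0))
    expect_true(all(rowSums(m[rows, own, drop = FALSE] > 0) >= 1))
  }
  common <- which(!study$truth$label %in% c("unique_a", "unique_b"))
  expect_true(all(rowSums(m[common, a_cols] > 0) >= 1))
  expect_true(all(rowSums(m[common, b_cols] > 0) >= 1))
  expect_true(all(study$truth$true_log2fc[study$truth$label == "up"] > 0))
  expect_true(all(study$truth$true_log2fc[study$truth$label == "down"] < 0))
  expect_true(all(study$truth$true_log2fc[
    study$truth$label %in% c("null", "unique_a", "unique_b")] == 0))
})

test_that("an all-null configuration plants nothing", {
  study <- simulate_counts(sim_config(total_proteins = 40, n_unique_a = 0,
                                      n_unique_b = 0, n_up = 0, n_down = 0,
                                      seed = 3))
  expect_true(all(study$truth$label == "null"))
  expect_true(all(study$truth$true_log2fc == 0))
})

test_that("same config and seed are bit-identical; seeds differ, structure holds", {
  s1 <- simulate_counts(small_config(seed = 11))
  s2 <- simulate_counts(small_config(seed = 11))
  s3 <- simulate_counts(small_config(seed = 12))
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$truth, s2$truth)
  expect_false(identical(s1$counts, s3$counts))
  expect_identical(table(s1$truth$label), table(s3$truth$label))
})

test_that("infeasible class counts are rejected", {
  expect_error(sim_config(total_proteins = 10, n_unique_a = 6, n_unique_b = 6),
               "infeasible")
  expect_error(sim_config(n_a = 1), "at least 2")
  expect_error(sim_config(dispersion = 0), "positive")
})

test_that("null counts have the configured negative-binomial mean", {
  # Monte-Carlo oracle: with constant baseline m and no size-factor noise,
  # the empirical mean over 10,000 samples must sit within 3 standard
  # errors of m, where Var = m + phi * m^2.
  m <- 50
  phi <- 0.15
  study <- simulate_counts(sim_config(
    total_proteins = 1, n_unique_a = 0, n_unique_b = 0, n_up = 0, n_down = 0,
    n_a = 5000, n_b = 5000, baseline_log_mean = log(m), baseline_log_sd = 0,
    dispersion = phi, size_factor_sd = 0, seed = 21
  ))
  x <- as.numeric(study$counts[1, -1])
  se <- sqrt((m + phi * m^2) / length(x))
  expect_lt(abs(mean(x) - m), 3 * se)
})

test_that("recovery metrics follow their conventions", {
  study <- simulate_counts(small_config(seed = 31))
  truth <- study$truth
  perfect <- tibble::tibble(
    protein_id = truth$protein_id,
    status = dplyr::recode(truth$label, null = "ns"),
    log2fc = truth$true_log2fc
  )
  r <- evaluate_recovery(perfect, study)
  expect_equal(r$tpr, 1)
  expect_equal(r$fdr, 0)
  expect_true(r$venn_exact)
  expect_equal(r$fc_bias, 0)
  expect_equal(r$fc_rmse, 0)

  none <- dplyr::mutate(perfect,
                        status = ifelse(status %in% c("up", "down"), "ns", status))
  r0 <- evaluate_recovery(none, study)
  expect_equal(r0$tpr, 0)
  expect_equal(r0$fdr, 0)

  bad_ids <- dplyr::mutate(perfect, protein_id = paste0("X", protein_id))
  expect_error(evaluate_recovery(bad_ids, study), "identifiers")
})

test_that("coin-flip calls on a half-null study give FDR near 0.5", {
  # Monte-Carlo oracle: with half the proteins null and calls independent
  # of truth, the expected fraction of false calls is the null fraction.
  set.seed(77)
  study <- simulate_counts(sim_config(total_proteins = 100, n_unique_a = 0,
                                      n_unique_b = 0, n_up = 25, n_down = 25,
                                      seed = 8))
  fdrs <- replicate(200, {
    calls <- sample(c("up", "ns"), 100, replace = TRUE)
    dep <- tibble::tibble(protein_id = study$truth$protein_id,
                          status = calls, log2fc = 0)
    evaluate_recovery(dep, study)$fdr
  })
  expect_lt(abs(mean(fdrs) - 0.5), 0.02)
})
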