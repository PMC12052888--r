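test_that("the weight statistic follows its closed form in both variants", {
  expect_equal(sam_weight(6, 2, 3, 1), 2)
  expect_equal(sam_weight(6, 2, 3, 1, variant = "sum"), 1)
  expect_equal(sam_weight(5, 5, 3, 1), 0)          # zero numerator
  expect_warning(w <- sam_weight(6, 2, 1, 1), "degenerate")
  expect_true(is.nan(w))
  expect_identical(gate_call(w, 0.001, 3), "ns")   # flagged W fails the gate
})

test_that("the printed-variant W is group-swap invariant, the sum variant antisymmetric", {
  set.seed(4)
  mu1 <- runif(50, 0, 20); mu2 <- runif(50, 0, 20)
  d1 <- runif(50, 0.5, 5); d2 <- runif(50, 0.5, 5)
  expect_equal(sam_weight(mu1, mu2, d1, d2), sam_weight(mu2, mu1, d2, d1))
  expect_equal(sam_weight(mu1, mu2, d1, d2, variant = "sum"),
               -sam_weight(mu2, mu1, d2, d1, variant = "sum"))
})

test_that("the Welch p-value handles degenerate and extreme inputs", {
  expect_equal(welch_one_tailed_p(c(3, 5, 7), c(3, 5, 7)), 0.5)
  expect_lt(welch_one_tailed_p(c(10.1, 9.9, 10.0, 10.2),
                               c(0.1, 0.0, 0.2, -0.1, 0.1, 0.0, 0.1)), 1e-6)
  expect_equal(welch_one_tailed_p(c(2, 2, 2), c(2, 2)), 0.5)
  expect_equal(welch_one_tailed_p(c(2, 2, 2), c(5, 5)), 0)
  expect_error(welch_one_tailed_p(1, c(1, 2)), "at least 2")
})

test_that("the Welch p-value matches the t-distribution oracle on 1,000 random pairs", {
  set.seed(123)
  for (i in seq_len(1000)) {
    a <- rnorm(sample(3:9, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(3:9, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
    oracle <- stats::t.test(a, b, var.equal = FALSE)$p.value / 2
    expect_lt(abs(welch_one_tailed_p(a, b) - oracle), 1e-10)
  }
})

test_that("signed fold change uses the negative-reciprocal convention", {
  expect_equal(signed_fold_change(4, 2), 2)
  expect_equal(signed_fold_change(2, 4), -2)
  expect_equal(signed_fold_change(3, 3), 1)
  expect_true(is.na(signed_fold_change(5, 0)))     # unique marker
  expect_error(signed_fold_change(0, 0), "both group means are zero")
  # antisymmetry whenever the ratio is not 1
  set.seed(6)
  a <- runif(100, 0.1, 50); b <- runif(100, 0.1, 50)
  keep <- abs(a - b) > 1e-9
  expect_equal(signed_fold_change(a, b)[keep], -signed_fold_change(b, a)[keep])
  expect_true(all(abs(signed_fold_change(a, b)) >= 1))
  # pseudocount keeps one-sided zeros finite
  expect_equal(signed_fold_change(5, 0, pseudocount = 0.5), 5.5 / 0.5)
})

test_that("the conjunction gate requires all three criteria", {
  expect_identical(gate_call(1.445, 0.014, 2.27), "up")
  expect_identical(gate_call(-1.246, 0.004, -2.41), "down")
  expect_identical(gate_call(0.686, 0.098, 3.04), "ns")    # fails W and p
  expect_identical(gate_call(2.0, 0.01, 1.3), "ns")        # fails FC
  expect_identical(gate_call(2.0, 0.2, 2.0), "ns")         # fails p
  expect_identical(gate_call(0.5, 0.01, 2.0), "ns")        # fails W
  expect_identical(gate_call(2.0, 0.01, NA_real_), "ns")   # unique marker
})

test_that("loosening any threshold never converts a call to ns", {
  set.seed(10)
  w <- rnorm(300, 0, 2)
  p <- runif(300, 0, 0.5)
  fc <- ifelse(runif(300) < 0.5, 1, -1) * exp(runif(300, 0, 1.5))
  base <- gate_thresholds()
  calls <- gate_call(w, p, fc, base)
  looser <- list(gate_thresholds(w_cut = 0.5),
                 gate_thresholds(p_cut = 0.1),
                 gate_thresholds(fc_cut = 1.2))
  for (th in looser) {
    relaxed <- gate_call(w, p, fc, th)
    expect_true(all(relaxed[calls != "ns"] == calls[calls != "ns"]))
  }
})

test_that("run_dep assigns one coherent status per protein", {
  study <- simulate_counts(small_config(seed = 13))
  dep <- run_dep(study$counts, study$samples)
  th <- attr(dep, "thresholds")
  expect_equal(nrow(dep), 60)
  expect_true(all(dep$status %in% c("up", "down", "ns", "unique_a", "unique_b")))
  up <- dep[dep$status == "up", ]
  expect_true(all(up$fc >= th$fc_cut & abs(up$w) > th$w_cut & up$p < th$p_cut))
  down <- dep[dep$status == "down", ]
  expect_true(all(down$fc <= -th$fc_cut & abs(down$w) > th$w_cut &
                    down$p < th$p_cut))
  uniq <- dep[dep$status %in% c("unique_a", "unique_b"), ]
  expect_true(all(is.na(uniq$p)) && all(is.na(uniq$q)) && all(is.na(uniq$fc)))
  tested <- dep[!dep$status %in% c("unique_a", "unique_b"), ]
  expect_true(all(tested$q >= tested$p))           # BH never decreases p
  expect_equal(tested$q, bh_adjust(tested$p))      # family excludes uniques
  # log2 representation is consistent with the signed ratio
  expect_equal(tested$log2fc, sign(tested$fc) * log2(abs(tested$fc)))
})

test_that("unique statuses mirror the planted structural classes", {
  study <- simulate_counts(small_config(seed = 17))
  dep <- run_dep(study$counts, study$samples)
  expect_equal(sum(dep$status == "unique_a"), 5)
  expect_equal(sum(dep$status == "unique_b"), 4)
  joined <- dplyr::inner_join(dep, study$truth, by = "protein_id")
  expect_true(all(joined$status[joined$label == "unique_a"] == "unique_a"))
})

test_that("tidy and glance summarise a dep table", {
  study <- simulate_counts(small_config(seed = 23))
  dep <- run_dep(study$counts, study$samples)
  td <- tidy(dep)
  expect_false(inherits(td, "dep_table"))
  expect_equal(nrow(td), nrow(dep))
  g <- glance(dep)
  expect_equal(g$n_proteins, 60)
  expect_equal(g$n_up + g$n_down + g$n_ns + g$n_unique_a + g$n_unique_b, 60)
})

test_that("the sign-stable weight variant keeps the null call rate below alpha", {
  # With the sum-denominator W the weight criterion is genuinely selective
  # and the three-way conjunction controls the per-protein null call rate
  # under 0.05 (the difference-denominator variant does not; see the
  # methods vignette for the operating-characteristics discussion).
  th <- gate_thresholds(w_variant = "sum")
  calls <- vapply(seq_len(60), function(s) {
    study <- simulate_counts(sim_config(total_proteins = 150, n_unique_a = 0,
                                        n_unique_b = 0, n_up = 0, n_down = 0,
                                        seed = 5000 + s))
    dep <- run_dep(study$counts, study$samples, thresholds = th)
    sum(dep$status %in% c("up", "down"))
  }, numeric(1))
  n_tot <- 60 * 150
  expect_lte(sum(calls) / n_tot, 0.05 + 3 * sqrt(0.05 * 0.95 / n_tot))
})

test_that("BH adjustment is monotone in p-rank and exact for a single test", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  set.seed(2)
  p <- runif(50)
  q <- bh_adjust(p)
  expect_equal(q, bh_oracle(p))
  expect_true(all(q[order(p)] == cummax(q[order(p)])))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})
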